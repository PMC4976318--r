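spec_fast <- morlet_spec(f_min_hz = 6, f_max_hz = 30, f_step_hz = 2,
                         cycles_at_fmin = 3 + 17 * 2 / 36,
                         cycles_at_fmax = 3 + 17 * 26 / 36,
                         output_window_ms = c(-1000, 1000))

test_that("stationary input reads approximately 0 dB everywhere", {
  ep <- noise_epochs(n_trials = 100, seed = 2)
  m <- compute_ersp(ep, "C3", spec_fast)
  expect_lt(abs(mean(m$values)), 0.2)
  expect_lt(quantile(abs(m$values), 0.95), 1)
})

test_that("amplitude doubling and halving read +/- 6.02 dB", {
  ep2 <- gain_step_epochs(n_trials = 60, f_hz = 10, post_gain = 2, seed = 3)
  m2 <- compute_ersp(ep2, "C3", spec_fast)
  i10 <- which(m2$freqs_hz == 10)
  late <- m2$times_ms >= 300 & m2$times_ms <= 800
  expect_equal(mean(m2$values[i10, late]), 10 * log10(4), tolerance = 0.05)

  ep_h <- gain_step_epochs(n_trials = 60, f_hz = 10, post_gain = 0.5,
                           seed = 4)
  m_h <- compute_ersp(ep_h, "C3", spec_fast)
  expect_equal(mean(m_h$values[i10, late]), -10 * log10(4), tolerance = 0.05)
})

test_that("ERSP is invariant to a global gain on the epoch set", {
  ep <- gain_step_epochs(n_trials = 20, noise_sd = 0.3, seed = 5)
  m1 <- compute_ersp(ep, "C3", spec_fast)
  ep$data <- ep$data * 7.3
  m2 <- compute_ersp(ep, "C3", spec_fast)
  expect_equal(m2$values, m1$values, tolerance = 1e-10)
})

test_that("degenerate zero input is rejected", {
  ep <- noise_epochs(n_trials = 4)
  ep$data[] <- 0
  expect_error(compute_ersp(ep, "C3", spec_fast), "baseline power")
})

test_that("ROI averaging resolves labels and averages element-wise", {
  maps <- list(C1 = ersp_map(matrix(1, 3, 4), 1:3, 1:4),
               C3 = ersp_map(matrix(3, 3, 4), 1:3, 1:4),
               C5 = ersp_map(matrix(5, 3, 4), 1:3, 1:4),
               C2 = ersp_map(matrix(100, 3, 4), 1:3, 1:4))
  out <- roi_average(maps, c("C1", "C3", "C5"))
  expect_true(all(out$values == 3))
  ## identical inputs reproduce themselves
  same <- roi_average(maps[c("C1", "C1")], c("C1"))
  expect_equal(same$values, maps$C1$values)
  expect_error(roi_average(maps, c("C1", "C9")), "C9")
})

test_that("subject averaging and ROI averaging commute", {
  withr::with_seed(6, {
    subj <- lapply(1:4, function(s)
      list(C1 = ersp_map(matrix(rnorm(12), 3, 4), 1:3, 1:4),
           C3 = ersp_map(matrix(rnorm(12), 3, 4), 1:3, 1:4)))
    roi_then_group <- group_average(lapply(subj, roi_average,
                                           roi = c("C1", "C3")))
    group_then_roi <- roi_average(
      list(C1 = group_average(lapply(subj, `[[`, "C1")),
           C3 = group_average(lapply(subj, `[[`, "C3"))),
      c("C1", "C3"))
    expect_equal(roi_then_group$values, group_then_roi$values,
                 tolerance = 1e-12)
  })
})

test_that("batched condition-wise ERSP equals the per-subset reference", {
  d <- build_design(tiny_design_config(), seed = 4)
  rec <- simulate_recording(d, tiny_sim_config(), subject_seed = 3)
  cfg <- tiny_preproc_config()
  ep <- epoch_and_baseline(preprocess_continuous(rec, cfg), d, cfg)
  g <- paste(ep$metadata$syllable, ep$metadata$stimulation, sep = ".")
  batched <- ersp_by_condition(ep, c("C3", "C4"), spec_fast, groups = g)
  for (cond in unique(g)) {
    for (ch in c("C3", "C4")) {
      ref <- compute_ersp(epochs_subset(ep, g == cond), ch, spec_fast)
      expect_equal(batched[[ch]][[cond]]$values, ref$values,
                   tolerance = 1e-10)
    }
  }
})

test_that("ERSP maps round-trip through TSV and JSON writers", {
  m <- ersp_map(matrix(rnorm(12), 3, 4), c(8, 10, 12), c(-100, 0, 100, 200))
  for (ext in c(".tsv", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_ersp_map(m, path)
    back <- read_ersp_map(path)
    expect_equal(back$values, m$values, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(back$freqs_hz, m$freqs_hz)
    expect_equal(back$times_ms, m$times_ms)
  }
})

test_that("baseline bootstrap flags an injected rebound, not noise", {
  ## stationary noise: flagged fraction near alpha
  ep <- noise_epochs(n_trials = 40, seed = 7)
  m <- compute_ersp(ep, "C3", spec_fast, keep_trials = TRUE)
  mask <- baseline_significance(m, alpha = 0.05, n_boot = 400, seed = 1)
  expect_lt(mean(mask$mask), 0.15)
  ## a strong rebound is flagged at its frequency and window
  ep2 <- gain_step_epochs(n_trials = 40, f_hz = 10, post_gain = 2,
                          noise_sd = 0.5, seed = 8)
  m2 <- compute_ersp(ep2, "C3", spec_fast, keep_trials = TRUE)
  mask2 <- baseline_significance(m2, alpha = 0.01, n_boot = 400, seed = 2)
  i10 <- which(m2$freqs_hz == 10)
  late <- m2$times_ms >= 300 & m2$times_ms <= 800
  expect_gt(mean(mask2$mask[i10, late]), 0.9)
  expect_error(baseline_significance(m2, n_boot = 0), "n_boot")
})
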