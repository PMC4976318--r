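make_cont <- function(n = 5000, sfreq = 500, n_eeg = 4, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm((n_eeg + 1) * n, sd = 10), n_eeg + 1, n)
    eeg_recording(x, sfreq,
                  c(paste0("C", seq_len(n_eeg)), "EOG_L"),
                  c(rep("eeg", n_eeg), "eog"),
                  data.frame(onset_s = c(2, 4), label = "vowel",
                             trial_id = 1:2))
  })
}

test_that("decimation 500 -> 250 Hz yields floor(N/2) samples", {
  for (n in c(5000, 5001)) {
    rec <- make_cont(n = n)
    out <- preprocess_continuous(rec, preproc_config())
    expect_equal(out$sfreq, 250)
    expect_equal(ncol(out$data), n %/% 2)
  }
})

test_that("a DC offset is removed by the 0.5 Hz high-pass", {
  rec <- make_cont(n = 20000)                # 40 s at 500 Hz
  rec$data[1, ] <- 100                       # constant input on one channel
  rec$data[-1, ] <- 0
  out <- preprocess_continuous(rec, preproc_config())
  ## a 0.5 Hz zero-phase high-pass settles over seconds; judge the interior
  mid <- out$data[1, 2500:(ncol(out$data) - 2500)]
  expect_lt(max(abs(mid)), 1)               # < 1% of 100 uV
})

test_that("after re-referencing the per-sample EEG mean is zero", {
  rec <- make_cont()
  out <- preprocess_continuous(rec, preproc_config())
  eeg <- out$ch_types == "eeg"
  expect_lt(max(abs(colMeans(out$data[eeg, ]))), 1e-10)
  ## EOG channel is not pulled into the reference
  expect_false(isTRUE(all.equal(out$data[5, ], rec$data[5, ])))
})

test_that("band edges beyond Nyquist and bad rates are rejected", {
  rec <- make_cont(sfreq = 90)
  expect_error(preprocess_continuous(rec, preproc_config()), "Nyquist")
  rec2 <- make_cont()
  expect_error(preprocess_continuous(
    rec2, preproc_config(resample_hz = 300)), "divide")
})

test_that("marker latencies survive filtering plus resampling", {
  rec <- make_cont()
  out <- preprocess_continuous(rec, preproc_config())
  ## event seconds unchanged; sample index at the new rate within 1 sample
  expect_equal(out$events$onset_s, rec$events$onset_s)
  idx_old <- round(rec$events$onset_s * rec$sfreq)
  idx_new <- round(out$events$onset_s * out$sfreq)
  expect_true(all(abs(idx_new - idx_old / 2) <= 1))
})

test_that("epoching uses the half-open window convention", {
  d <- build_design(tiny_design_config(), seed = 1)
  rec <- simulate_recording(d, tiny_sim_config(), subject_seed = 1)
  cfg <- tiny_preproc_config()
  prep <- preprocess_continuous(rec, cfg)
  ep <- epoch_and_baseline(prep, d, cfg)
  expect_equal(dim(ep$data), c(nrow(d), nrow(rec$data), 4 * 250))
  expect_equal(min(ep$times_ms), -1500)
  expect_equal(max(ep$times_ms), 2500 - 4)   # last sample before +2.5 s
})

test_that("baseline correction zeroes the baseline mean and is idempotent", {
  d <- build_design(tiny_design_config(), seed = 1)
  rec <- simulate_recording(d, tiny_sim_config(), subject_seed = 1)
  cfg <- tiny_preproc_config()
  prep <- preprocess_continuous(rec, cfg)
  ep <- epoch_and_baseline(prep, d, cfg)
  bl <- ep$times_ms >= -1000 & ep$times_ms <= -150
  mu <- apply(ep$data[, , bl], c(1, 2), mean)
  expect_lt(max(abs(mu)), 1e-10)
  ## re-epoching the already-corrected continuous data changes nothing more
  ## than the first correction did: correcting epochs again is a no-op
  mu2 <- apply((ep$data - array(apply(ep$data[, , bl], c(1, 2), mean),
                                dim = dim(ep$data)))[, , bl], c(1, 2), mean)
  expect_equal(mu2, mu, tolerance = 1e-12)
})

test_that("trials too close to a recording edge are dropped with a warning", {
  d <- build_design(tiny_design_config(), seed = 1)
  d$vowel_onset_s[1] <- 0.5                  # not enough pre-stimulus signal
  rec <- simulate_recording(d, tiny_sim_config(), subject_seed = 1)
  cfg <- tiny_preproc_config()
  prep <- preprocess_continuous(rec, cfg)
  expect_warning(ep <- epoch_and_baseline(prep, d, cfg), "excluded")
  expect_equal(dim(ep$data)[1], nrow(d) - 1)
  expect_false(1 %in% ep$metadata$trial_id)
})

test_that("behavioral selection keeps only valid correct trials", {
  d <- build_design(tiny_design_config(), seed = 1)
  rec <- simulate_recording(d, tiny_sim_config(), subject_seed = 1)
  cfg <- tiny_preproc_config()
  ep <- epoch_and_baseline(preprocess_continuous(rec, cfg), d, cfg)
  beh <- data.frame(trial_id = d$trial_id, valid = TRUE,
                    direction = "left", rt_ms = 400, correct = TRUE)
  expect_equal(dim(select_valid_trials(ep, beh)$data)[1], 16)
  beh$correct[1:2] <- FALSE                  # 2 of 16 incorrect -> 14 kept
  expect_equal(dim(select_valid_trials(ep, beh)$data)[1], 14)
  beh$valid[3] <- FALSE
  expect_equal(dim(select_valid_trials(ep, beh)$data)[1], 13)
})

test_that("a 13.1% incorrect rate retains 86.9% of trials", {
  n <- 1000
  beh <- data.frame(trial_id = 1:n, valid = TRUE, direction = "left",
                    rt_ms = 400, correct = rep(c(FALSE, TRUE),
                                               c(131, 869)))
  ep <- noise_epochs(n_trials = n, window_s = c(-1.5, 0.5))
  ep$metadata <- data.frame(trial_id = 1:n)
  kept <- select_valid_trials(ep, beh)
  expect_equal(dim(kept$data)[1] / n, 0.869)
})
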