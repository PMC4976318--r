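test_that("identical seeds reproduce recordings bit for bit", {
  d <- build_design(tiny_design_config(), seed = 1)
  cfg <- tiny_sim_config()
  r1 <- simulate_recording(d, cfg, subject_seed = 11)
  r2 <- simulate_recording(d, cfg, subject_seed = 11)
  expect_identical(r1$data, r2$data)
  r3 <- simulate_recording(d, cfg, subject_seed = 12)
  expect_false(identical(r1$data, r3$data))
})

test_that("marker counts match the design", {
  d <- build_design(design_config(), seed = 2)
  rec <- simulate_recording(d, tiny_sim_config(), subject_seed = 1)
  expect_equal(sum(rec$events$label == "vowel"), 192)
  expect_equal(sum(rec$events$label == "stim"), 96)
  expect_equal(sum(rec$events$label == "question"), 192)
})

test_that("missing central channels are a configuration error", {
  d <- build_design(tiny_design_config(), seed = 1)
  cfg <- tiny_sim_config()
  cfg$montage <- c("C1", "C3", "C2", "C4", "Cz")   # no C5/C6
  expect_error(simulate_recording(d, cfg, 1), "C5")
})

test_that("event-locked gain profile sets exact band-power ratios", {
  ## single noise-free beta oscillator: the trial-averaged window/baseline
  ## power ratio equals the squared gain to within 1%
  d <- build_design(design_config(n_speakers = 2, repetitions_per_audio = 4,
                                  iti_range_s = c(2.5, 2.6)), seed = 3)
  cfg <- tiny_sim_config(noise_1f_amp = 0, eog_noise_uv = 0, mu_amp_uv = 0,
                         saccade_amp_uv = 0, subject_amp_sdlog = 0,
                         trial_amp_sdlog = 0, carrier = "sinusoid")
  rec <- simulate_recording(d, cfg, subject_seed = 7)
  sf <- rec$sfreq
  win_pow <- function(tr, ch, w_ms) {
    i0 <- round(d$vowel_onset_s[tr] * sf)
    idx <- (i0 + round(w_ms[1] / 1000 * sf)):(i0 + round(w_ms[2] / 1000 * sf))
    mean(rec$data[ch, idx]^2)
  }
  plain <- which(!(d$syllable == "bilabial" & d$stimulation == "present"))
  ratio <- function(w_ms) mean(vapply(plain, function(tr)
    win_pow(tr, "C3", w_ms) / win_pow(tr, "C3", c(-1000, -150)), numeric(1)))
  expect_equal(ratio(cfg$ers_window_ms), cfg$ers_gain^2, tolerance = 0.01)
  expect_equal(ratio(cfg$erd_window_ms), cfg$erd_gain^2, tolerance = 0.01)
})

test_that("rebound attenuation is confined to weighted (left) channels", {
  d <- build_design(design_config(n_speakers = 2, repetitions_per_audio = 4,
                                  iti_range_s = c(2.5, 2.6)), seed = 3)
  cfg <- tiny_sim_config(noise_1f_amp = 0, eog_noise_uv = 0, mu_amp_uv = 0,
                         saccade_amp_uv = 0, subject_amp_sdlog = 0,
                         trial_amp_sdlog = 0, rebound_attenuation = 0.5,
                         carrier = "sinusoid")
  rec <- simulate_recording(d, cfg, subject_seed = 7)
  sf <- rec$sfreq
  ratio <- function(tr, ch) {
    i0 <- round(d$vowel_onset_s[tr] * sf)
    w <- function(w_ms) mean(rec$data[
      ch, (i0 + round(w_ms[1] / 1000 * sf)):(i0 + round(w_ms[2] / 1000 * sf))]^2)
    w(cfg$ers_window_ms) / w(c(-1000, -150))
  }
  cell_ratio <- function(sy, st, ch) {
    trs <- which(d$syllable == sy & d$stimulation == st)
    mean(vapply(trs, ratio, numeric(1), ch = ch))
  }
  ## left channel: attenuated gain 1.5 - 0.5 * 0.5 = 1.25
  expect_equal(cell_ratio("bilabial", "present", "C3"), 1.25^2,
               tolerance = 0.01)
  expect_equal(cell_ratio("dental", "present", "C3"), 1.5^2,
               tolerance = 0.01)
  ## right channel: zero lateralization weight, full rebound in both cells
  expect_equal(cell_ratio("bilabial", "present", "C4"), 1.5^2,
               tolerance = 0.01)
  expect_equal(cell_ratio("dental", "present", "C4"), 1.5^2,
               tolerance = 0.01)
})

test_that("zero attenuation leaves the syllables statistically exchangeable", {
  ## expected band-power profiles identical across syllables: compare
  ## trial-mean rebound ratios across many seeds
  cfg <- tiny_sim_config(rebound_attenuation = 0)
  dcfg <- tiny_design_config()
  diffs <- vapply(1:50, function(s) {
    d <- build_design(dcfg, seed = s)
    rec <- simulate_recording(d, cfg, subject_seed = 1000 + s)
    sf <- rec$sfreq
    ers <- function(tr) {
      i0 <- round(d$vowel_onset_s[tr] * sf)
      idx <- (i0 + round(0.5 * sf)):(i0 + round(0.8 * sf))
      mean(rec$data["C3", idx]^2)
    }
    v <- vapply(seq_len(nrow(d)), ers, numeric(1))
    mean(v[d$syllable == "bilabial"]) - mean(v[d$syllable == "dental"])
  }, numeric(1))
  expect_lt(abs(mean(diffs)) / (sd(diffs) / sqrt(length(diffs))), 3)
})

test_that("EOG deflection encodes the executed response side", {
  d <- build_design(tiny_design_config(), seed = 4)
  cfg <- tiny_sim_config(incorrect_rate = 0, eog_noise_uv = 0,
                         noise_1f_amp = 0, mu_amp_uv = 0, beta_amp_uv = 0)
  rec <- simulate_recording(d, cfg, subject_seed = 5)
  sf <- rec$sfreq
  for (tr in 1:6) {
    i0 <- round(d$question_onset_s[tr] * sf)
    seg <- rec$data["EOG_R", i0:(i0 + 3 * sf)] -
      rec$data["EOG_L", i0:(i0 + 3 * sf)]
    peak_sign <- sign(seg[which.max(abs(seg))])
    expect_equal(peak_sign,
                 if (d$true_response_side[tr] == "right") 1 else -1)
  }
})

test_that("total duration follows the generated event schedule", {
  dcfg <- design_config(iti_range_s = c(7, 8))
  d <- build_design(dcfg, seed = 6)
  rec <- simulate_recording(d, tiny_sim_config(), subject_seed = 2)
  last_q <- max(rec$events$onset_s[rec$events$label == "question"])
  expect_equal(ncol(rec$data) / rec$sfreq, last_q + 4, tolerance = 0.01)
  ## mean trial period = question delay + mean ITI
  periods <- diff(sort(rec$events$onset_s[rec$events$label == "vowel"]))
  expect_true(all(periods >= 1.5 + 7 - 1e-6 & periods <= 1.5 + 8 + 1e-6))
})

test_that("multi-subject studies counterbalance the response mapping", {
  study <- simulate_study(tiny_design_config(),
                          tiny_sim_config(n_subjects = 4), seed = 9)
  expect_length(study, 4)
  maps <- vapply(study, function(s) s$side_mapping[["yes"]], "")
  expect_setequal(unique(maps), c("left", "right"))
  ## different subjects get different trial orders
  expect_false(identical(study[[1]]$trials$syllable,
                         study[[2]]$trials$syllable))
})
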