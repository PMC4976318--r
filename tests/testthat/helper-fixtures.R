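# Shared fixtures: everything is generated in code at test time.

# Small fast design: 16 trials (2 speakers x 2 syllables x 2 reps x 2 stim)
tiny_design_config <- function(iti = c(2.5, 2.6)) {
  design_config(n_speakers = 2, repetitions_per_audio = 2, iti_range_s = iti)
}

# Quiet, fast simulation at 250 Hz with a reduced montage that still holds
# the six central channels
tiny_sim_config <- function(...) {
  sim_config(sfreq_hz = 250,
             montage = c("C1", "C3", "C5", "C2", "C4", "C6",
                         "Fz", "Cz", "Pz", "Oz"),
             ...)
}

tiny_preproc_config <- function(...) {
  preproc_config(resample_hz = 250, ...)
}

# Mu+beta wavelet grid at the canonical cycle ramp (anchored 3 cycles at
# 4 Hz -> 20 at 40 Hz, restricted to 8-30 Hz)
restricted_morlet_spec <- function(f_step = 1) {
  morlet_spec(f_min_hz = 8, f_max_hz = 30, f_step_hz = f_step,
              cycles_at_fmin = 3 + 17 * 4 / 36,
              cycles_at_fmax = 3 + 17 * 26 / 36)
}

# Epochs of pure synthetic content for ERSP calibration tests: `n_trials`
# epochs of a sinusoid whose amplitude is multiplied by `post_gain` after
# t = 0, embedded (optionally) in white noise.
gain_step_epochs <- function(n_trials = 50, f_hz = 10, amp = 1,
                             post_gain = 2, noise_sd = 0, sfreq = 250,
                             window_s = c(-1.5, 2.5), seed = 1) {
  withr::with_seed(seed, {
    rel <- seq(round(window_s[1] * sfreq), round(window_s[2] * sfreq) - 1L)
    t_s <- rel / sfreq
    gain <- ifelse(t_s >= 0, post_gain, 1)
    dat <- array(0, dim = c(n_trials, 1L, length(t_s)))
    for (k in seq_len(n_trials)) {
      ph <- runif(1, 0, 2 * pi)
      dat[k, 1, ] <- amp * gain * sin(2 * pi * f_hz * t_s + ph) +
        rnorm(length(t_s), sd = noise_sd)
    }
    eeg_epochs(dat, t_s * 1000, "C3", "eeg", sfreq,
               data.frame(trial_id = seq_len(n_trials)))
  })
}

# White-noise epochs (stationary, no event-locked structure)
noise_epochs <- function(n_trials = 50, sfreq = 250,
                         window_s = c(-1.5, 2.5), seed = 1) {
  withr::with_seed(seed, {
    rel <- seq(round(window_s[1] * sfreq), round(window_s[2] * sfreq) - 1L)
    dat <- array(rnorm(n_trials * length(rel)),
                 dim = c(n_trials, 1L, length(rel)))
    eeg_epochs(dat, rel / sfreq * 1000, "C3", "eeg", sfreq,
               data.frame(trial_id = seq_len(n_trials)))
  })
}

# Random per-subject ERSP-like maps on a small grid
random_maps <- function(n_subjects, nf = 8, nt = 12, seed = 1, shift = 0) {
  withr::with_seed(seed, {
    lapply(seq_len(n_subjects), function(s)
      ersp_map(matrix(rnorm(nf * nt) + shift, nf, nt),
               freqs_hz = seq_len(nf), times_ms = seq_len(nt) * 10))
  })
}

# Scaled-down detection study: 12 subjects, 48 trials each (12 per
# syllable x stimulation cell), shortened inter-trial interval, 250 Hz
# acquisition, full abolition of the beta rebound on bilabial+stimulation
# trials, and a clearly expressed (4 uV RMS) beta rhythm. Used for the
# power-recovery and type-I calibration studies.
detection_study_config <- function(rebound_attenuation = 1) {
  pipeline_config(
    design = design_config(n_speakers = 2, repetitions_per_audio = 6,
                           iti_range_s = c(2.5, 3.2)),
    sim = sim_config(sfreq_hz = 250, rebound_attenuation = rebound_attenuation,
                     beta_amp_uv = 4),
    preproc = preproc_config(resample_hz = 250),
    morlet = morlet_spec(f_min_hz = 8, f_max_hz = 30, f_step_hz = 2,
                         cycles_at_fmin = 3 + 17 * 4 / 36,
                         cycles_at_fmax = 3 + 17 * 26 / 36),
    n_perm = 1000)
}

# Band/window cell table for an arbitrary ROI side from a pipeline report
report_band_cells <- function(report, side, bw_set = canonical_band_windows()) {
  rows <- list()
  for (s in seq_along(report$subject_maps)) {
    maps <- report$subject_maps[[s]][[side]]
    for (cond in names(maps)) {
      parts <- strsplit(cond, ".", fixed = TRUE)[[1]]
      for (nm in names(bw_set)) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, syllable = parts[1], stimulation = parts[2],
          measure = nm,
          value = extract_band_window_means(maps[[cond]], bw_set[[nm]]))
      }
    }
  }
  do.call(rbind, rows)
}
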