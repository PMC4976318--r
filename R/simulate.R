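#' Synthetic EEG/EOG simulation configuration
#'
#' Parameters of the generative model used to emulate the study's recordings:
#' a 1/f ("pink") background on every channel, continuous-phase mu and beta
#' oscillators over the central electrodes whose amplitude follows an
#' event-locked gain profile (unity in baseline, `erd_gain` during the
#' desynchronization window, `ers_gain` during the rebound window), and a
#' condition-dependent attenuation of the beta rebound on bilabial trials
#' with lip stimulation, spatially confined by `left_lateralization`.
#' Horizontal EOG channels carry the saccadic response to the identification
#' question.
#'
#' Oscillator amplitudes default to values at which band power at the
#' oscillator frequency is comparable to the 1/f background power falling
#' inside the analysing wavelet's bandwidth, so that group ERSP values come
#' out of order +/- 0.5-2 dB, as observed over sensorimotor cortex.
#'
#' @param n_subjects Number of subjects to simulate.
#' @param sfreq_hz Acquisition sampling rate, Hz.
#' @param montage EEG channel labels; must contain the six central channels
#'   C1, C3, C5 (left) and C2, C4, C6 (right).
#' @param eog_channels Labels of the two horizontal EOG channels
#'   (left canthus, right canthus).
#' @param noise_1f_amp RMS amplitude of the 1/f background per EEG channel,
#'   microvolts.
#' @param mu_freq_hz,beta_freq_hz Oscillator center frequencies, Hz.
#' @param mu_bw_hz,beta_bw_hz Oscillator bandwidths, Hz: each rhythm is
#'   band-limited Gaussian noise spanning `center +/- bw/2` (mu 8-12 Hz,
#'   beta 13-27 Hz by default), as sensorimotor rhythms are broadband rather
#'   than sinusoidal.
#' @param mu_amp_uv,beta_amp_uv Baseline oscillator RMS amplitudes,
#'   microvolts.
#' @param carrier `"band_noise"` (default) renders each rhythm as
#'   band-limited Gaussian noise; `"sinusoid"` uses a pure center-frequency
#'   sinusoid with a random phase per trial, for which windowed band-power
#'   ratios equal the squared gain profile exactly.
#' @param osc_weights Named non-negative weights giving each central
#'   channel's share of its hemisphere's oscillatory source (left and right
#'   perirolandic sources have independent phases; non-central montage
#'   channels carry background noise only, as focal sensorimotor rhythms do
#'   not project there).
#' @param erd_window_ms,ers_window_ms Event-locked windows (relative to vowel
#'   onset) in which the ERD and ERS gains hold, milliseconds.
#' @param erd_gain Amplitude gain during the ERD window (< 1).
#' @param ers_gain Amplitude gain during the rebound window (> 1).
#' @param rebound_attenuation Fraction in [0, 1] of the beta rebound excess
#'   gain removed on bilabial + stimulation trials (0 = no effect, 1 = the
#'   rebound is fully abolished on those trials). Applied to the beta
#'   oscillator only; the mu rhythm carries no syllable-specific effect.
#' @param left_lateralization Named non-negative weights, one per central
#'   channel, scaling the attenuation effect spatially. The default confines
#'   it to the left region of interest (C1, C3, C5).
#' @param ramp_ms Raised-cosine ramp length on each side of a gain window
#'   (the plateau spans the window exactly; ramps sit outside it).
#' @param subject_amp_sdlog,trial_amp_sdlog Log-normal SDs of per-subject and
#'   per-trial oscillator amplitude variability.
#' @param eog_noise_uv RMS of the EOG channel noise, microvolts.
#' @param saccade_amp_uv Peak-to-peak amplitude of the horizontal EOG
#'   deflection produced by a response saccade, microvolts.
#' @param rt_mean_ms,rt_sd_ms Mean and SD of saccade latency from question
#'   onset (log-normal), milliseconds.
#' @param rt_stim_shift_ms Latency shift when lip stimulation is present
#'   (negative = faster, a startle-like speeding).
#' @param rt_negative_shift_ms Latency shift for questions requiring a "no"
#'   answer (positive = slower).
#' @param incorrect_rate Probability that the executed saccade goes to the
#'   wrong side.
#' @param line_noise_uv Optional 50 Hz line-noise amplitude (0 disables).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 12L,
                       sfreq_hz = 500,
                       montage = c("C1", "C3", "C5", "C2", "C4", "C6",
                                   "Fz", "Cz", "Pz", "F3", "F4", "P3", "P4",
                                   "O1", "O2", "T7"),
                       eog_channels = c("EOG_L", "EOG_R"),
                       noise_1f_amp = 10,
                       mu_freq_hz = 10,
                       beta_freq_hz = 20,
                       mu_bw_hz = 4,
                       beta_bw_hz = 14,
                       carrier = c("band_noise", "sinusoid"),
                       mu_amp_uv = 2.5,
                       beta_amp_uv = 1.5,
                       osc_weights = c(C1 = 0.8, C3 = 1, C5 = 0.7,
                                       C2 = 0.8, C4 = 1, C6 = 0.7),
                       erd_window_ms = c(200, 400),
                       erd_gain = 0.6,
                       ers_window_ms = c(500, 800),
                       ers_gain = 1.5,
                       rebound_attenuation = 0.5,
                       left_lateralization = c(C1 = 1, C3 = 1, C5 = 1,
                                               C2 = 0, C4 = 0, C6 = 0),
                       ramp_ms = 50,
                       subject_amp_sdlog = 0.2,
                       trial_amp_sdlog = 0.1,
                       eog_noise_uv = 5,
                       saccade_amp_uv = 60,
                       rt_mean_ms = 530,
                       rt_sd_ms = 90,
                       rt_stim_shift_ms = -22,
                       rt_negative_shift_ms = 49,
                       incorrect_rate = 0.131,
                       line_noise_uv = 0) {
  if (erd_gain <= 0 || ers_gain <= 0) stop("gains must be strictly positive",
                                           call. = FALSE)
  if (rebound_attenuation < 0 || rebound_attenuation > 1) {
    stop("`rebound_attenuation` must lie in [0, 1]", call. = FALSE)
  }
  if (any(left_lateralization < 0)) {
    stop("lateralization weights must be non-negative", call. = FALSE)
  }
  carrier <- match.arg(carrier)
  stopifnot_interval(erd_window_ms, "erd_window_ms")
  stopifnot_interval(ers_window_ms, "ers_window_ms")
  structure(as.list(environment()), class = "sim_config")
}

## 1/f ("pink") noise of a given RMS, synthesized by shaping a white spectrum
## with amplitude proportional to 1/sqrt(f) (power ~ 1/f). The DC bin is
## zeroed; frequencies below 0.5 Hz are flattened to keep the variance finite.
pink_noise <- function(n, sfreq, rms) {
  if (rms == 0) return(numeric(n))
  nf <- stats::nextn(n, 2L)                    # power-of-two FFT length
  spec <- fft(rnorm(nf))
  f <- seq(0, sfreq, length.out = nf + 1L)[seq_len(nf)]
  f <- pmin(f, sfreq - f)                      # two-sided frequency axis
  shape <- 1 / sqrt(pmax(f, 0.5))
  shape[1] <- 0
  x <- Re(fft(spec * shape, inverse = TRUE))[seq_len(n)] / nf
  x * (rms / sd(x))
}

## Band-limited unit-RMS Gaussian noise carrier: white noise spectrally
## masked to [center - bw/2, center + bw/2]. Phase is random by construction,
## so the rhythm is induced (non-phase-locked) activity.
band_limited_noise <- function(n, sfreq, center_hz, bw_hz) {
  nf <- stats::nextn(n, 2L)
  spec <- fft(rnorm(nf))
  f <- seq(0, sfreq, length.out = nf + 1L)[seq_len(nf)]
  f <- pmin(f, sfreq - f)
  mask <- f >= center_hz - bw_hz / 2 & f <= center_hz + bw_hz / 2
  x <- Re(fft(spec * mask, inverse = TRUE))[seq_len(n)] / nf
  x / sd(x)
}

## Event-locked amplitude gain profile. The plateau holds the window exactly;
## raised-cosine ramps of `ramp_ms` sit just outside each edge, so mean power
## measured inside the window equals gain^2 times baseline power.
gain_profile <- function(t_ms, windows, gains, ramp_ms) {
  g <- rep(1, length(t_ms))
  for (k in seq_along(gains)) {
    w <- windows[[k]]; gk <- gains[k]
    up <- t_ms >= (w[1] - ramp_ms) & t_ms < w[1]
    g[up] <- 1 + (gk - 1) * 0.5 *
      (1 - cos(pi * (t_ms[up] - (w[1] - ramp_ms)) / ramp_ms))
    inside <- t_ms >= w[1] & t_ms <= w[2]
    g[inside] <- gk
    down <- t_ms > w[2] & t_ms <= (w[2] + ramp_ms)
    g[down] <- 1 + (gk - 1) * 0.5 *
      (1 + cos(pi * (t_ms[down] - w[2]) / ramp_ms))
  }
  g
}

#' Simulate one subject's continuous recording
#'
#' Renders a continuous multichannel voltage trace realizing the trial table:
#' 1/f background everywhere, event-locked mu and beta oscillatory segments
#' with randomized phase (induced, non-phase-locked activity) over the
#' central channels, the conditional beta-rebound attenuation, and saccadic
#' EOG deflections after each question (executed towards the wrong side with
#' probability `incorrect_rate`). Event markers are written for vowel onset
#' (`"vowel"`), stimulation delivery (`"stim"`) and question onset
#' (`"question"`).
#'
#' @param design Trial table from [build_design()].
#' @param cfg A [sim_config()].
#' @param subject_seed Integer seed; the same seed reproduces the recording
#'   bit for bit.
#' @return An [eeg_recording()].
#' @export
simulate_recording <- function(design, cfg = sim_config(), subject_seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (nrow(design) == 0L) stop("`design` must contain at least one trial",
                               call. = FALSE)
  central <- c("C1", "C3", "C5", "C2", "C4", "C6")
  missing_ch <- setdiff(central, cfg$montage)
  if (length(missing_ch) > 0L) {
    stop(sprintf("montage lacks required central channels: %s",
                 paste(missing_ch, collapse = ", ")), call. = FALSE)
  }
  if (length(cfg$eog_channels) != 2L) {
    stop("exactly two EOG channels are required", call. = FALSE)
  }
  sf <- cfg$sfreq_hz
  ch_names <- c(cfg$montage, cfg$eog_channels)
  ch_types <- c(rep("eeg", length(cfg$montage)),
                rep("eog", length(cfg$eog_channels)))
  n_ch <- length(ch_names)
  dur_s <- max(design$question_onset_s) + 4
  n <- ceiling(dur_s * sf)

  lat_w <- setNames(rep(0, length(cfg$montage)), cfg$montage)
  lat_w[names(cfg$left_lateralization)] <- cfg$left_lateralization

  with_seed(subject_seed, {
    x <- matrix(0, n_ch, n)
    for (i in seq_along(cfg$montage)) {
      x[i, ] <- pink_noise(n, sf, cfg$noise_1f_amp)
    }
    for (i in length(cfg$montage) + seq_along(cfg$eog_channels)) {
      x[i, ] <- pink_noise(n, sf, cfg$eog_noise_uv)
    }
    if (cfg$line_noise_uv > 0) {
      tt <- seq_len(n) / sf
      x[seq_along(cfg$montage), ] <- x[seq_along(cfg$montage), ] +
        rep(cfg$line_noise_uv * sin(2 * pi * 50 * tt), each = length(cfg$montage))
    }

    subj_amp <- rlnorm(1, 0, cfg$subject_amp_sdlog)
    ## oscillator segment around each trial; tapered at its outer edges
    seg_ms <- c(-1600, 1600)
    seg_idx_rel <- seq(round(seg_ms[1] / 1000 * sf),
                       round(seg_ms[2] / 1000 * sf) - 1L)
    t_ms <- seg_idx_rel / sf * 1000
    taper <- rep(1, length(t_ms))
    edge <- 100                                     # ms
    lo <- t_ms < seg_ms[1] + edge
    hi <- t_ms > seg_ms[2] - edge
    taper[lo] <- 0.5 * (1 - cos(pi * (t_ms[lo] - seg_ms[1]) / edge))
    taper[hi] <- 0.5 * (1 - cos(pi * (seg_ms[2] - t_ms[hi]) / edge))

    osc_w <- setNames(rep(0, length(central)), central)
    osc_w[names(cfg$osc_weights)] <- cfg$osc_weights
    hemis <- list(left = c("C1", "C3", "C5"), right = c("C2", "C4", "C6"))
    for (k in seq_len(nrow(design))) {
      onset <- round(design$vowel_onset_s[k] * sf)
      idx <- onset + seg_idx_rel
      keep <- idx >= 1L & idx <= n
      attenuated <- design$syllable[k] == "bilabial" &&
        design$stimulation[k] == "present"
      trial_amp <- rlnorm(1, 0, cfg$trial_amp_sdlog) * subj_amp
      g_mu <- gain_profile(t_ms, list(cfg$erd_window_ms, cfg$ers_window_ms),
                           c(cfg$erd_gain, cfg$ers_gain), cfg$ramp_ms)
      for (side in names(hemis)) {      # independent realizations per side
        if (cfg$carrier == "band_noise") {
          car_mu <- band_limited_noise(length(t_ms), sf, cfg$mu_freq_hz,
                                       cfg$mu_bw_hz)
          car_beta <- band_limited_noise(length(t_ms), sf, cfg$beta_freq_hz,
                                         cfg$beta_bw_hz)
        } else {                        # pure sinusoid, random phase (RMS 1)
          car_mu <- sqrt(2) * sin(2 * pi * cfg$mu_freq_hz * t_ms / 1000 +
                                    runif(1, 0, 2 * pi))
          car_beta <- sqrt(2) * sin(2 * pi * cfg$beta_freq_hz * t_ms / 1000 +
                                      runif(1, 0, 2 * pi))
        }
        osc_mu <- cfg$mu_amp_uv * trial_amp * taper * g_mu * car_mu
        for (ch in hemis[[side]]) {
          row <- match(ch, ch_names)
          ers_eff <- if (attenuated) {
            cfg$ers_gain - lat_w[ch] * cfg$rebound_attenuation *
              (cfg$ers_gain - 1)
          } else cfg$ers_gain
          g_beta <- gain_profile(t_ms,
                                 list(cfg$erd_window_ms, cfg$ers_window_ms),
                                 c(cfg$erd_gain, ers_eff), cfg$ramp_ms)
          osc_beta <- cfg$beta_amp_uv * trial_amp * taper * g_beta * car_beta
          x[row, idx[keep]] <- x[row, idx[keep]] +
            osc_w[ch] * (osc_mu[keep] + osc_beta[keep])
        }
      }
    }

    ## EOG saccades: boxcar deflection of the horizontal dipole, rightward
    ## saccades positive on (right - left). Wrong-side execution with
    ## probability incorrect_rate.
    executed <- design$true_response_side
    flip <- runif(nrow(design)) < cfg$incorrect_rate
    executed[flip] <- ifelse(executed[flip] == "left", "right", "left")
    rt_ms <- pmax(180, rlnorm(nrow(design),
                              meanlog = log(cfg$rt_mean_ms) -
                                0.5 * log(1 + (cfg$rt_sd_ms / cfg$rt_mean_ms)^2),
                              sdlog = sqrt(log(1 + (cfg$rt_sd_ms / cfg$rt_mean_ms)^2))) +
                    ifelse(design$stimulation == "present",
                           cfg$rt_stim_shift_ms, 0) +
                    ifelse(design$question_polarity == "negative",
                           cfg$rt_negative_shift_ms, 0))
    eog_l <- match(cfg$eog_channels[1], ch_names)
    eog_r <- match(cfg$eog_channels[2], ch_names)
    hold_ms <- 300; ramp <- 40
    for (k in seq_len(nrow(design))) {
      s0 <- round((design$question_onset_s[k] + rt_ms[k] / 1000) * sf)
      shape_t <- seq(0, hold_ms + 2 * ramp, by = 1000 / sf)
      shape <- rep(1, length(shape_t))
      shape[shape_t < ramp] <- shape_t[shape_t < ramp] / ramp
      fall <- shape_t > hold_ms + ramp
      shape[fall] <- pmax(0, 1 - (shape_t[fall] - hold_ms - ramp) / ramp)
      idx <- s0 + seq_along(shape) - 1L
      keep <- idx >= 1L & idx <= n
      sgn <- if (executed[k] == "right") 1 else -1
      half <- sgn * cfg$saccade_amp_uv / 2
      x[eog_r, idx[keep]] <- x[eog_r, idx[keep]] + half * shape[keep]
      x[eog_l, idx[keep]] <- x[eog_l, idx[keep]] - half * shape[keep]
    }

    ev <- rbind(
      data.frame(onset_s = design$vowel_onset_s, label = "vowel",
                 trial_id = design$trial_id),
      data.frame(onset_s = design$vowel_onset_s[design$stimulation == "present"],
                 label = "stim",
                 trial_id = design$trial_id[design$stimulation == "present"]),
      data.frame(onset_s = design$question_onset_s, label = "question",
                 trial_id = design$trial_id)
    )
    ev <- ev[order(ev$onset_s, ev$label), ]
    rownames(ev) <- NULL
    eeg_recording(x, sf, ch_names, ch_types, ev)
  })
}

#' Simulate a full multi-subject study
#'
#' Builds one pseudo-randomized trial table per subject (independent
#' randomizations from seeds derived from `seed`), counterbalances the
#' yes/no-to-side mapping across subjects, and renders each subject's
#' continuous recording.
#'
#' @param design_cfg A [design_config()].
#' @param cfg A [sim_config()].
#' @param seed Master seed; subject seeds are derived deterministically.
#' @return A list with one element per subject, each containing `recording`
#'   (an [eeg_recording()]), `trials` (the subject's trial table) and
#'   `side_mapping` (named yes/no to left/right vector).
#' @export
simulate_study <- function(design_cfg = design_config(),
                           cfg = sim_config(), seed = 1L) {
  lapply(seq_len(cfg$n_subjects), function(s) {
    mapping <- if (s %% 2L == 1L) c(yes = "right", no = "left")
               else c(yes = "left", no = "right")
    dcfg <- design_cfg
    dcfg$response_sides <- mapping
    trials <- build_design(dcfg, seed = derive_seed(seed, s))
    rec <- simulate_recording(trials, cfg,
                              subject_seed = derive_seed(seed, 1000 + s))
    list(subject = s, recording = rec, trials = trials,
         side_mapping = mapping)
  })
}
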