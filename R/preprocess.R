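#' Preprocessing configuration
#'
#' @param bandpass_hz Band-pass corner frequencies for the EEG channels, Hz.
#' @param resample_hz Target sampling rate after anti-aliased decimation, Hz.
#'   Must divide the acquisition rate.
#' @param epoch_window_s Epoch limits around vowel onset, seconds; the end is
#'   exclusive (half-open convention), so a `[-1.5, 2.5)` window at 250 Hz
#'   yields exactly 1000 samples.
#' @param baseline_window_ms Pre-stimulus baseline used for voltage baseline
#'   correction (and later as the ERSP divisor window), milliseconds.
#' @param reference Only `"common_average"` is implemented: each EEG sample
#'   is re-referenced to the mean over all EEG channels (EOG excluded).
#' @return An object of class `preproc_config`.
#' @export
preproc_config <- function(bandpass_hz = c(0.5, 50),
                           resample_hz = 250,
                           epoch_window_s = c(-1.5, 2.5),
                           baseline_window_ms = c(-1000, -150),
                           reference = "common_average") {
  stopifnot_interval(bandpass_hz, "bandpass_hz")
  stopifnot_interval(epoch_window_s, "epoch_window_s")
  stopifnot_interval(baseline_window_ms, "baseline_window_ms")
  if (baseline_window_ms[1] < epoch_window_s[1] * 1000 ||
      baseline_window_ms[2] > epoch_window_s[2] * 1000) {
    stop("baseline window must lie within the epoch window", call. = FALSE)
  }
  reference <- match.arg(reference, "common_average")
  structure(list(bandpass_hz = bandpass_hz, resample_hz = resample_hz,
                 epoch_window_s = epoch_window_s,
                 baseline_window_ms = baseline_window_ms,
                 reference = reference),
            class = "preproc_config")
}

## zero-phase Butterworth band-pass, order 4, applied forward-backward
bandpass_filtfilt <- function(x, sfreq, band) {
  bf <- signal::butter(4, band / (sfreq / 2), type = "pass")
  signal::filtfilt(bf, x)
}

#' Filter, resample and re-reference a continuous recording
#'
#' EEG channels are band-passed with a zero-phase 4th-order Butterworth
#' filter, all channels are decimated to `resample_hz` after a 20-order FIR
#' anti-aliasing low-pass, and EEG channels are re-referenced to their common
#' average. EOG channels bypass the EEG band-pass (they receive their own
#' 20 Hz low-pass inside the saccade detector) but are resampled alongside.
#' Event times, held in seconds, are unchanged; their sample indices simply
#' map onto the new rate.
#'
#' @param rec An [eeg_recording()].
#' @param cfg A [preproc_config()].
#' @return A preprocessed [eeg_recording()] at `resample_hz`.
#' @export
preprocess_continuous <- function(rec, cfg = preproc_config()) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(cfg, "preproc_config"))
  if (cfg$bandpass_hz[2] >= rec$sfreq / 2) {
    stop("upper band edge must be below the Nyquist frequency", call. = FALSE)
  }
  if (cfg$resample_hz > rec$sfreq) {
    stop("`resample_hz` must not exceed the acquisition rate", call. = FALSE)
  }
  q <- rec$sfreq / cfg$resample_hz
  if (abs(q - round(q)) > 1e-9) {
    stop("`resample_hz` must divide the acquisition rate (integer decimation)",
         call. = FALSE)
  }
  q <- as.integer(round(q))
  x <- rec$data
  is_eeg <- rec$ch_types == "eeg"
  for (i in which(is_eeg)) {
    x[i, ] <- bandpass_filtfilt(x[i, ], rec$sfreq, cfg$bandpass_hz)
  }
  if (q > 1L) {
    ## 20-order FIR anti-alias at 90% of the new Nyquist, zero phase
    fir <- signal::fir1(20, 0.9 / q)
    x <- t(apply(x, 1L, function(v) signal::filtfilt(fir, v)))
    ## keep floor(N/q) samples so the output length is N * new_rate / old_rate
    x <- x[, seq(1L, (ncol(x) %/% q) * q, by = q), drop = FALSE]
  }
  if (any(is_eeg)) {
    x[is_eeg, ] <- sweep(x[is_eeg, , drop = FALSE], 2L,
                         colMeans(x[is_eeg, , drop = FALSE]))
  }
  eeg_recording(x, cfg$resample_hz, rec$ch_names, rec$ch_types, rec$events)
}

#' Epoch a recording around vowel onsets and baseline-correct
#'
#' Cuts one epoch per trial-table row, time-locked to `vowel_onset_s`, using
#' the half-open `[start, end)` sample convention, and subtracts each
#' trial-and-channel mean voltage over the baseline window. Trials whose
#' epoch would extend past either end of the recording are dropped with a
#' warning.
#'
#' @param rec A (preprocessed) [eeg_recording()].
#' @param trials Trial table covering the recording.
#' @param cfg A [preproc_config()].
#' @return An [eeg_epochs()] whose `metadata` holds the retained trial rows.
#' @export
epoch_and_baseline <- function(rec, trials, cfg = preproc_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  sf <- rec$sfreq
  rel <- seq(round(cfg$epoch_window_s[1] * sf),
             round(cfg$epoch_window_s[2] * sf) - 1L)
  times_ms <- rel / sf * 1000
  n <- ncol(rec$data)
  onset_idx <- round(trials$vowel_onset_s * sf) + 1L
  ok <- (onset_idx + rel[1]) >= 1L & (onset_idx + rel[length(rel)]) <= n
  if (any(!ok)) {
    warning(sprintf("%d trial(s) too close to a recording edge were excluded: %s",
                    sum(!ok),
                    paste(trials$trial_id[!ok], collapse = ", ")),
            call. = FALSE)
  }
  kept <- which(ok)
  dat <- array(0, dim = c(length(kept), nrow(rec$data), length(rel)))
  for (j in seq_along(kept)) {
    dat[j, , ] <- rec$data[, onset_idx[kept[j]] + rel, drop = FALSE]
  }
  bl <- times_ms >= cfg$baseline_window_ms[1] &
        times_ms <= cfg$baseline_window_ms[2]
  if (!any(bl)) stop("baseline window contains no samples", call. = FALSE)
  mu <- apply(dat[, , bl, drop = FALSE], c(1L, 2L), mean)
  dat <- dat - array(mu, dim = dim(dat))   # recycles over the time axis
  eeg_epochs(dat, times_ms, rec$ch_names, rec$ch_types, sf,
             trials[kept, , drop = FALSE])
}

#' Keep only valid, correct trials
#'
#' Restricts an epoch set to the trials the behavioral scoring marked as
#' having a detectable saccade toward the demanded side.
#'
#' @param epochs An [eeg_epochs()].
#' @param behavior Behavior table from [score_trials()] covering every epoch.
#' @return The filtered [eeg_epochs()]; may be empty (a message is logged).
#' @export
select_valid_trials <- function(epochs, behavior) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  idx <- match(epochs$metadata$trial_id, behavior$trial_id)
  if (anyNA(idx)) stop("behavior table does not cover all epochs",
                       call. = FALSE)
  keep <- behavior$valid[idx] & behavior$correct[idx]
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) message("no valid correct trials retained")
  eeg_epochs(epochs$data[keep, , , drop = FALSE], epochs$times_ms,
             epochs$ch_names, epochs$ch_types, epochs$sfreq,
             epochs$metadata[keep, , drop = FALSE])
}
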