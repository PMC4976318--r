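#' Morlet wavelet specification
#'
#' Defines the time-frequency decomposition grid: frequencies from
#' `f_min_hz` to `f_max_hz` in steps of `f_step_hz`, with a cycle count that
#' ramps linearly from `cycles_at_fmin` to `cycles_at_fmax` (3 cycles at
#' 4 Hz rising to 20 cycles at 40 Hz by default, i.e. 73 frequency rows),
#' and the output window over which maps are reported.
#'
#' @param f_min_hz,f_max_hz,f_step_hz Frequency grid, Hz.
#' @param cycles_at_fmin,cycles_at_fmax Wavelet cycle counts at the grid
#'   endpoints; the count interpolates linearly in between.
#' @param output_window_ms Time window of the reported maps, milliseconds
#'   relative to the locking event.
#' @return An object of class `morlet_spec`.
#' @export
morlet_spec <- function(f_min_hz = 4, f_max_hz = 40, f_step_hz = 0.5,
                        cycles_at_fmin = 3, cycles_at_fmax = 20,
                        output_window_ms = c(-1000, 1000)) {
  stopifnot(f_min_hz > 0, f_max_hz > f_min_hz, f_step_hz > 0,
            cycles_at_fmin > 0, cycles_at_fmax >= cycles_at_fmin)
  stopifnot_interval(output_window_ms, "output_window_ms")
  structure(list(f_min_hz = f_min_hz, f_max_hz = f_max_hz,
                 f_step_hz = f_step_hz,
                 cycles_at_fmin = cycles_at_fmin,
                 cycles_at_fmax = cycles_at_fmax,
                 output_window_ms = output_window_ms),
            class = "morlet_spec")
}

#' Frequency grid of a wavelet specification
#' @param spec A [morlet_spec()].
#' @return Numeric vector of analysis frequencies, Hz.
#' @export
morlet_freqs <- function(spec = morlet_spec()) {
  seq(spec$f_min_hz, spec$f_max_hz, by = spec$f_step_hz)
}

#' Cycle count of the wavelet at a frequency
#'
#' Linear ramp: `n(f) = c_min + (c_max - c_min) * (f - f_min)/(f_max - f_min)`.
#'
#' @param f_hz Frequency (vectorized), Hz; must lie inside the grid range.
#' @param spec A [morlet_spec()].
#' @return Cycle count(s).
#' @export
#' @examples
#' wavelet_cycles(4)    # 3
#' wavelet_cycles(40)   # 20
wavelet_cycles <- function(f_hz, spec = morlet_spec()) {
  if (any(f_hz < spec$f_min_hz | f_hz > spec$f_max_hz)) {
    stop(sprintf("frequency outside [%g, %g] Hz",
                 spec$f_min_hz, spec$f_max_hz), call. = FALSE)
  }
  spec$cycles_at_fmin + (spec$cycles_at_fmax - spec$cycles_at_fmin) *
    (f_hz - spec$f_min_hz) / (spec$f_max_hz - spec$f_min_hz)
}

#' Complex Morlet kernel
#'
#' A complex sinusoid under a Gaussian envelope with SD
#' `n(f) / (2 * pi * f)` seconds, truncated at +/- 5 SD and L2-normalized to
#' unit energy.
#'
#' @param f_hz Center frequency, Hz.
#' @param n_cycles Cycle count.
#' @param sfreq Sampling rate, Hz.
#' @return Complex vector of odd length (kernel centred on its midpoint).
#' @export
morlet_kernel <- function(f_hz, n_cycles, sfreq) {
  sigma_t <- n_cycles / (2 * pi * f_hz)
  half <- ceiling(5 * sigma_t * sfreq)
  t <- (-half:half) / sfreq
  k <- exp(2i * pi * f_hz * t) * exp(-t^2 / (2 * sigma_t^2))
  k / sqrt(sum(Mod(k)^2))
}

## FFT-based "same" convolution of each column of `x` (samples x series) with
## complex kernel `k` centred on its midpoint. Returns complex matrix of the
## same shape as x.
fft_convolve_same <- function(x, k) {
  n <- nrow(x)
  m <- length(k)
  nf <- stats::nextn(n + m - 1L, 2L)
  kf <- fft(c(k, rep(0, nf - m)))
  xf <- mvfft(rbind(x, matrix(0, nf - n, ncol(x))))
  full <- mvfft(xf * kf, inverse = TRUE) / nf
  half <- (m - 1L) %/% 2L
  full[(half + 1L):(half + n), , drop = FALSE]
}

## Edge safety: at least +/- 3 Gaussian SD of the wavelet must lie inside
## the epoch at every output time (the kernel is truncated at 5 SD; the
## outermost tails, < 0.01 of peak amplitude, see zero-padding).
morlet_edge_check <- function(times_ms, out_keep, spec) {
  for (f in morlet_freqs(spec)) {
    half_ms <- 3 * wavelet_cycles(f, spec) / (2 * pi * f) * 1000
    if (times_ms[out_keep[1]] - half_ms < times_ms[1] - 1e-9 ||
        times_ms[out_keep[length(out_keep)]] + half_ms >
          times_ms[length(times_ms)] + 1e-9) {
      stop(sprintf(
        "epoch too short for edge-safe output at %.2f Hz (needs +/- %.0f ms)",
        f, half_ms), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Morlet transform of single-channel epochs
#'
#' Convolves each epoch with a unit-energy complex Morlet kernel per
#' frequency (spectral-domain convolution) and crops the result to the
#' spec's output window. The epoch must be long enough that, at every output
#' time, at least +/- 3 Gaussian SD of the wavelet envelope lies inside the
#' epoch (edge-safe region); otherwise an error names the offending
#' frequency. Kernel tails beyond the epoch (under 1% of peak amplitude)
#' fall on zero-padding.
#'
#' @param x Either a numeric vector (one epoch) or a samples x trials
#'   matrix.
#' @param times_ms Sample times of the epoch, milliseconds.
#' @param spec A [morlet_spec()].
#' @param sfreq Sampling rate, Hz.
#' @return A list with `coef` (complex array frequencies x times x trials),
#'   `freqs_hz`, and `times_ms` (the cropped output grid).
#' @export
morlet_transform <- function(x, times_ms, spec = morlet_spec(), sfreq) {
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  stopifnot(nrow(x) == length(times_ms))
  freqs <- morlet_freqs(spec)
  out_keep <- which(times_ms >= spec$output_window_ms[1] &
                    times_ms <= spec$output_window_ms[2])
  if (length(out_keep) == 0L) stop("output window is empty", call. = FALSE)
  morlet_edge_check(times_ms, out_keep, spec)
  kernels <- lapply(freqs, function(f)
    morlet_kernel(f, wavelet_cycles(f, spec), sfreq))
  n <- nrow(x)
  m_max <- max(lengths(kernels))
  nf <- stats::nextn(n + m_max - 1L, 2L)
  xf <- mvfft(rbind(x, matrix(0, nf - n, ncol(x))))   # one FFT, all freqs
  coef <- array(0i, dim = c(length(freqs), length(out_keep), ncol(x)))
  for (i in seq_along(freqs)) {
    k <- kernels[[i]]
    kf <- fft(c(k, rep(0, nf - length(k))))
    full <- mvfft(xf * kf, inverse = TRUE) / nf
    half <- (length(k) - 1L) %/% 2L
    coef[i, , ] <- full[half + out_keep, , drop = FALSE]
  }
  list(coef = coef, freqs_hz = freqs, times_ms = times_ms[out_keep])
}
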