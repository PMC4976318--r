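#' Event-related spectral perturbation map container
#'
#' @param values Frequencies x times numeric matrix (dB unless noted).
#' @param freqs_hz,times_ms Grid vectors.
#' @param level One of `"trial"`, `"subject"`, `"group"`.
#' @return An object of class `ersp_map`.
#' @export
ersp_map <- function(values, freqs_hz, times_ms, level = "subject") {
  stopifnot(is.matrix(values), nrow(values) == length(freqs_hz),
            ncol(values) == length(times_ms))
  structure(list(values = values, freqs_hz = freqs_hz, times_ms = times_ms,
                 level = level), class = "ersp_map")
}

#' @export
print.ersp_map <- function(x, ...) {
  cat(sprintf("<ersp_map level=%s> %d freqs [%g-%g Hz] x %d times [%g-%g ms], range [%.2f, %.2f] dB\n",
              x$level, length(x$freqs_hz), min(x$freqs_hz), max(x$freqs_hz),
              length(x$times_ms), min(x$times_ms), max(x$times_ms),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Compute the ERSP of one channel
#'
#' Per trial, Morlet power is computed at each grid point; trial powers are
#' averaged and expressed as normalized decibels relative to the mean
#' baseline power at the same frequency:
#' `ERSP(f, t) = 10 * log10(mean_k |W_k(f, t)|^2 / P0(f))`, where `P0(f)`
#' averages power over all trials and all baseline time points.
#'
#' @param epochs An [eeg_epochs()].
#' @param channel Channel label to decompose.
#' @param spec A [morlet_spec()].
#' @param baseline_ms Baseline window used for the divisor, milliseconds.
#' @param keep_trials If `TRUE`, also return the trials x freqs x times
#'   linear-power array (needed by [baseline_significance()]).
#' @return An [ersp_map()]; with `keep_trials = TRUE`, attribute
#'   `"trial_power"` holds the per-trial power array.
#' @export
compute_ersp <- function(epochs, channel, spec = morlet_spec(),
                         baseline_ms = c(-1000, -150), keep_trials = FALSE) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (dim(epochs$data)[1] < 1L) stop("at least one trial required",
                                     call. = FALSE)
  ci <- channel_index(epochs, channel)
  x <- t(epochs$data[, ci, , drop = TRUE])       # samples x trials
  if (dim(epochs$data)[1] == 1L) x <- matrix(epochs$data[1, ci, ], ncol = 1L)
  tf <- morlet_transform(x, epochs$times_ms, spec, epochs$sfreq)
  pow <- Mod(tf$coef)^2                          # freqs x times x trials
  mean_pow <- apply(pow, c(1L, 2L), mean)
  bl <- tf$times_ms >= baseline_ms[1] & tf$times_ms <= baseline_ms[2]
  if (!any(bl)) stop("baseline window lies outside the wavelet output grid",
                     call. = FALSE)
  p0 <- rowMeans(mean_pow[, bl, drop = FALSE])
  if (any(p0 <= 0)) stop("degenerate input: zero baseline power",
                         call. = FALSE)
  vals <- 10 * log10(mean_pow / p0)
  out <- ersp_map(vals, tf$freqs_hz, tf$times_ms, level = "subject")
  if (keep_trials) {
    attr(out, "trial_power") <- aperm(pow, c(3L, 1L, 2L))
    attr(out, "baseline_cols") <- which(bl)
  }
  out
}

#' Condition-wise ERSP maps for several channels in one pass
#'
#' Computes, for every channel and every level of a trial grouping, the same
#' ERSP as [compute_ersp()] restricted to that condition's trials, but with
#' a single spectral-domain convolution batched over all trials and
#' channels. Used by the pipeline; numerically identical to calling
#' [compute_ersp()] per condition subset.
#'
#' @param epochs An [eeg_epochs()].
#' @param channels Channel labels to decompose.
#' @param spec A [morlet_spec()].
#' @param baseline_ms Baseline window for the dB divisor.
#' @param groups Factor (or character) of length n-trials defining the
#'   conditions.
#' @return Nested list: `maps[[channel]][[group level]]`, each an
#'   [ersp_map()].
#' @export
ersp_by_condition <- function(epochs, channels, spec = morlet_spec(),
                              baseline_ms = c(-1000, -150), groups) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  n_tr <- dim(epochs$data)[1]
  groups <- as.factor(groups)
  stopifnot(length(groups) == n_tr)
  ci <- channel_index(epochs, channels)
  times_ms <- epochs$times_ms
  out_keep <- which(times_ms >= spec$output_window_ms[1] &
                    times_ms <= spec$output_window_ms[2])
  morlet_edge_check(times_ms, out_keep, spec)
  freqs <- morlet_freqs(spec)
  out_times <- times_ms[out_keep]
  bl <- out_times >= baseline_ms[1] & out_times <= baseline_ms[2]
  if (!any(bl)) stop("baseline window lies outside the wavelet output grid",
                     call. = FALSE)

  ## samples x (trial, channel) column blocks, one block per channel
  n_s <- dim(epochs$data)[3]
  x <- matrix(0, n_s, n_tr * length(ci))
  for (j in seq_along(ci)) {
    x[, (j - 1L) * n_tr + seq_len(n_tr)] <- t(epochs$data[, ci[j], ,
                                                          drop = TRUE])
  }
  if (n_tr == 1L) {
    for (j in seq_along(ci)) x[, j] <- epochs$data[1, ci[j], ]
  }
  kernels <- lapply(freqs, function(f)
    morlet_kernel(f, wavelet_cycles(f, spec), epochs$sfreq))
  nf <- stats::nextn(n_s + max(lengths(kernels)) - 1L, 2L)
  xf <- mvfft(rbind(x, matrix(0, nf - n_s, ncol(x))))
  lev <- levels(groups)
  gidx <- lapply(lev, function(g) which(groups == g))
  if (any(lengths(gidx) == 0L)) stop("empty condition group", call. = FALSE)
  mp <- array(0, dim = c(length(channels), length(lev), length(freqs),
                         length(out_keep)))
  for (i in seq_along(freqs)) {
    k <- kernels[[i]]
    kf <- fft(c(k, rep(0, nf - length(k))))
    full <- mvfft(xf * kf, inverse = TRUE) / nf
    half <- (length(k) - 1L) %/% 2L
    pow <- Mod(full[half + out_keep, , drop = FALSE])^2  # times x columns
    for (j in seq_along(ci)) {
      block <- (j - 1L) * n_tr
      for (g in seq_along(lev)) {
        mp[j, g, i, ] <- rowMeans(pow[, block + gidx[[g]], drop = FALSE])
      }
    }
  }
  maps <- setNames(vector("list", length(channels)), channels)
  for (j in seq_along(channels)) {
    maps[[j]] <- setNames(vector("list", length(lev)), lev)
    for (g in seq_along(lev)) {
      m <- mp[j, g, , ]
      p0 <- rowMeans(m[, bl, drop = FALSE])
      if (any(p0 <= 0)) stop("degenerate input: zero baseline power",
                             call. = FALSE)
      maps[[j]][[g]] <- ersp_map(10 * log10(m / p0), freqs, out_times,
                                 level = "subject")
    }
  }
  maps
}

#' Average ERSP maps over a region of interest
#'
#' Element-wise mean (in dB) of per-channel maps over the named channels.
#'
#' @param maps Named list of [ersp_map()] objects, one per channel.
#' @param roi Character vector of channel labels to average.
#' @return An [ersp_map()].
#' @export
roi_average <- function(maps, roi) {
  missing_ch <- setdiff(roi, names(maps))
  if (length(missing_ch) > 0L) {
    stop(sprintf("ROI channel(s) missing from the map set: %s",
                 paste(missing_ch, collapse = ", ")), call. = FALSE)
  }
  sel <- maps[roi]
  ref <- sel[[1]]
  for (m in sel[-1]) {
    if (!isTRUE(all.equal(m$freqs_hz, ref$freqs_hz)) ||
        !isTRUE(all.equal(m$times_ms, ref$times_ms))) {
      stop("ROI maps have mismatched grids", call. = FALSE)
    }
  }
  vals <- Reduce(`+`, lapply(sel, `[[`, "values")) / length(sel)
  ersp_map(vals, ref$freqs_hz, ref$times_ms, level = ref$level)
}

#' Average ERSP maps across subjects
#' @param maps List of [ersp_map()] with identical grids.
#' @return Group-level [ersp_map()].
#' @export
group_average <- function(maps) {
  ref <- maps[[1]]
  vals <- Reduce(`+`, lapply(maps, `[[`, "values")) / length(maps)
  ersp_map(vals, ref$freqs_hz, ref$times_ms, level = "group")
}

#' Write an ERSP map as TSV (matrix with grid headers) or JSON
#' @param map An [ersp_map()].
#' @param path Output path; format chosen by extension (`.tsv` or `.json`).
#' @return The path, invisibly. `read_ersp_map` returns the map.
#' @export
write_ersp_map <- function(map, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(freqs_hz = map$freqs_hz,
                              times_ms = map$times_ms,
                              level = map$level,
                              values = map$values),
                         path, digits = NA, auto_unbox = TRUE,
                         matrix = "rowmajor")
  } else {
    m <- cbind(freq_hz = map$freqs_hz, as.data.frame(map$values))
    names(m)[-1] <- sprintf("t%+.1fms", map$times_ms)
    utils::write.table(m, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_ersp_map
#' @export
read_ersp_map <- function(path) {
  if (grepl("\\.json$", path)) {
    o <- jsonlite::read_json(path, simplifyVector = TRUE)
    ersp_map(o$values, o$freqs_hz, o$times_ms, o$level)
  } else {
    m <- utils::read.delim(path, check.names = FALSE)
    freqs <- m[[1]]
    times <- as.numeric(sub("ms$", "", sub("^t", "", names(m)[-1])))
    ersp_map(as.matrix(m[, -1, drop = FALSE]), freqs, times, "subject")
  }
}
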