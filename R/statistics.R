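#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up rule: with ordered p-values `p(1) <= ... <= p(m)`, find the
#' largest `k` with `p(k) <= (k/m) * q` and reject every hypothesis with
#' `p <= p(k)`. Ties are handled by the stable ordering of the sort.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param q Target false discovery rate.
#' @return Logical rejection flags, aligned with the input.
#' @export
#' @examples
#' fdr_correct(c(0.001, 0.02, 0.03, 0.04), q = 0.05)  # all TRUE
fdr_correct <- function(p_values, q = 0.01) {
  m <- length(p_values)
  if (m == 0L) return(logical(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  o <- order(p_values)
  ps <- p_values[o]
  ok <- ps <= (seq_len(m) / m) * q
  if (!any(ok)) return(rep(FALSE, m))
  k_star <- max(which(ok))
  reject <- rep(FALSE, m)
  reject[o[seq_len(k_star)]] <- TRUE
  reject
}

## paired t statistics for each column of a subjects x points difference
## matrix (returns NaN -> 0 where all differences are zero)
paired_t_cols <- function(d) {
  n <- nrow(d)
  m <- colMeans(d)
  s <- sqrt((colSums(d^2) - n * m^2) / (n - 1))
  t <- m / (s / sqrt(n))
  t[!is.finite(t)] <- 0
  t
}

#' Significance mask container
#' @param mask Logical frequencies x times matrix.
#' @param p Matrix of (permutation) p-values, same shape.
#' @param statistic Matrix of observed statistics.
#' @param alpha,n_permutations,correction Inference settings used.
#' @param freqs_hz,times_ms Grid vectors.
#' @return Object of class `significance_mask`.
#' @export
significance_mask <- function(mask, p, statistic, alpha, n_permutations,
                              correction, freqs_hz, times_ms) {
  structure(list(mask = mask, p = p, statistic = statistic, alpha = alpha,
                 n_permutations = n_permutations, correction = correction,
                 freqs_hz = freqs_hz, times_ms = times_ms),
            class = "significance_mask")
}

#' @export
print.significance_mask <- function(x, ...) {
  cat(sprintf("<significance_mask> %d / %d points significant (alpha=%g, %s, %d permutations)\n",
              sum(x$mask), length(x$mask), x$alpha, x$correction,
              x$n_permutations))
  invisible(x)
}

#' Paired condition contrast of time-frequency maps with a permutation null
#'
#' For each time-frequency point a paired t statistic across subjects is
#' computed on the per-subject map difference (a - b). The null distribution
#' is built by randomly flipping the sign of each subject's difference
#' (exchangeable under the hypothesis of no condition effect); when `n_perm`
#' reaches the number of distinct sign patterns (`2^n` subjects) the
#' enumeration is exhaustive, otherwise `n_perm` random patterns are drawn.
#' Two-tailed permutation p-values are floored at `1/(n_perm + 1)`, then
#' corrected across all points.
#'
#' @param maps_a,maps_b Lists of per-subject [ersp_map()] objects, paired by
#'   position, with identical grids.
#' @param n_perm Number of sign-flip permutations.
#' @param alpha Significance level applied after correction.
#' @param correction `"FDR"` (Benjamini-Hochberg across all points) or
#'   `"none"`.
#' @param seed Seed for the permutation draw.
#' @return A [significance_mask()].
#' @export
compare_maps_permutation <- function(maps_a, maps_b, n_perm = 10000,
                                     alpha = 0.01,
                                     correction = c("FDR", "none"),
                                     seed = 1L) {
  correction <- match.arg(correction)
  if (length(maps_a) != length(maps_b) || length(maps_a) < 2L) {
    stop("need >= 2 paired subjects", call. = FALSE)
  }
  if (n_perm < 1L) stop("`n_perm` must be >= 1", call. = FALSE)
  ref <- maps_a[[1]]
  for (m in c(maps_a, maps_b)) {
    if (!isTRUE(all.equal(m$freqs_hz, ref$freqs_hz)) ||
        !isTRUE(all.equal(m$times_ms, ref$times_ms))) {
      stop("maps have mismatched time-frequency grids", call. = FALSE)
    }
  }
  n <- length(maps_a)
  d <- t(vapply(seq_len(n),
                function(s) as.vector(maps_a[[s]]$values - maps_b[[s]]$values),
                numeric(length(ref$values))))    # subjects x points
  t_obs <- paired_t_cols(d)

  exhaustive <- n_perm >= 2^n
  signs <- if (exhaustive) {
    as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    with_seed(seed, matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                           nrow = n_perm))
  }
  n_eff <- nrow(signs)
  ## t under sign flips: sum of squares is flip-invariant, so only the mean
  ## changes; chunk over points to bound memory
  ss <- colSums(d^2)
  count_ge <- numeric(ncol(d))
  chunk <- max(1L, floor(2e7 / n_eff))
  for (start in seq(1L, ncol(d), by = chunk)) {
    cols <- start:min(start + chunk - 1L, ncol(d))
    ms <- (signs %*% d[, cols, drop = FALSE]) / n       # n_eff x |cols|
    denom <- sqrt(sweep(-n * ms^2, 2L, ss[cols], `+`) / (n - 1)) / sqrt(n)
    tp <- abs(ms / denom)
    tp[!is.finite(tp)] <- 0
    count_ge[cols] <- colSums(tp >= rep(abs(t_obs[cols]), each = n_eff) - 1e-12)
  }
  p <- if (exhaustive) count_ge / n_eff else (1 + count_ge) / (n_eff + 1)
  reject <- if (correction == "FDR") fdr_correct(p, alpha) else p <= alpha
  shp <- dim(ref$values)
  significance_mask(matrix(reject, shp[1], shp[2]),
                    matrix(p, shp[1], shp[2]),
                    matrix(t_obs, shp[1], shp[2]),
                    alpha, n_eff, correction, ref$freqs_hz, ref$times_ms)
}

#' Baseline-significance mask of an ERSP map via bootstrap resampling
#'
#' Tests, per time-frequency point, whether the ERSP differs from the
#' baseline by building a null distribution of map values: on each bootstrap
#' iteration, one baseline time point is drawn (with replacement) per trial,
#' the trial powers at those points are averaged and converted to dB against
#' the observed baseline mean, giving the distribution of ERSP values
#' expected from baseline fluctuation alone. The observed map is thresholded
#' at the two-tailed `alpha` percentiles of the per-frequency null.
#'
#' @param map An [ersp_map()] computed with `keep_trials = TRUE`.
#' @param alpha Two-tailed significance level.
#' @param n_boot Number of bootstrap resamples.
#' @param seed RNG seed.
#' @return A [significance_mask()] (its `p` slot holds `NA`; the bootstrap
#'   thresholds are percentile-based).
#' @export
baseline_significance <- function(map, alpha = 0.01, n_boot = 10000,
                                  seed = 1L) {
  if (n_boot < 1L) stop("`n_boot` must be >= 1", call. = FALSE)
  pow <- attr(map, "trial_power")
  bl_cols <- attr(map, "baseline_cols")
  if (is.null(pow) || is.null(bl_cols)) {
    stop("map lacks trial powers; recompute with keep_trials = TRUE",
         call. = FALSE)
  }
  n_trials <- dim(pow)[1]
  if (n_trials < 2L) stop("need >= 2 trials", call. = FALSE)
  n_freq <- dim(pow)[2]
  p0 <- vapply(seq_len(n_freq),
               function(f) mean(pow[, f, bl_cols]), numeric(1))
  null_q <- with_seed(seed, {
    lo <- numeric(n_freq); hi <- numeric(n_freq)
    draw <- matrix(sample(bl_cols, n_boot * n_trials, replace = TRUE),
                   nrow = n_trials)
    for (f in seq_len(n_freq)) {
      slab <- pow[, f, , drop = TRUE]            # trials x times
      boots <- colMeans(matrix(slab[cbind(rep(seq_len(n_trials), n_boot),
                                          as.vector(draw))],
                               nrow = n_trials))
      db <- 10 * log10(boots / p0[f])
      qs <- quantile(db, c(alpha / 2, 1 - alpha / 2), names = FALSE)
      lo[f] <- qs[1]; hi[f] <- qs[2]
    }
    list(lo = lo, hi = hi)
  })
  mask <- map$values < null_q$lo | map$values > null_q$hi
  significance_mask(mask, matrix(NA_real_, nrow(mask), ncol(mask)),
                    map$values, alpha, n_boot, "none",
                    map$freqs_hz, map$times_ms)
}

#' Band and window specification
#' @param band_hz Frequency band, Hz (closed interval on the grid).
#' @param window_ms Time window, milliseconds (closed interval).
#' @param label Short label.
#' @return Object of class `band_window_spec`.
#' @export
band_window_spec <- function(band_hz, window_ms, label = "") {
  stopifnot_interval(band_hz, "band_hz")
  stopifnot_interval(window_ms, "window_ms")
  structure(list(band_hz = band_hz, window_ms = window_ms, label = label),
            class = "band_window_spec")
}

#' Canonical band/window set
#'
#' Mu (8-12 Hz) and beta (13-30 Hz) bands crossed with the ERD window
#' (200-400 ms) and the band-specific rebound window (mu 400-600 ms,
#' beta 600-800 ms).
#' @return Named list of [band_window_spec()] objects.
#' @export
canonical_band_windows <- function() {
  list(
    mu_erd    = band_window_spec(c(8, 12),  c(200, 400), "mu ERD"),
    mu_ers    = band_window_spec(c(8, 12),  c(400, 600), "mu ERS"),
    beta_erd  = band_window_spec(c(13, 30), c(200, 400), "beta ERD"),
    beta_ers  = band_window_spec(c(13, 30), c(600, 800), "beta ERS")
  )
}

#' Mean ERSP over a band and time window
#'
#' Average of the map cells whose frequency lies in the band and whose time
#' lies in the window (closed intervals on the grid).
#'
#' @param map An [ersp_map()].
#' @param spec A [band_window_spec()].
#' @return Scalar mean, dB.
#' @export
extract_band_window_means <- function(map, spec) {
  stopifnot(inherits(spec, "band_window_spec"))
  if (spec$band_hz[1] < min(map$freqs_hz) - 1e-9 ||
      spec$band_hz[2] > max(map$freqs_hz) + 1e-9 ||
      spec$window_ms[1] < min(map$times_ms) - 1e-9 ||
      spec$window_ms[2] > max(map$times_ms) + 1e-9) {
    stop("band/window region extends outside the map grids", call. = FALSE)
  }
  fi <- map$freqs_hz >= spec$band_hz[1] & map$freqs_hz <= spec$band_hz[2]
  ti <- map$times_ms >= spec$window_ms[1] & map$times_ms <= spec$window_ms[2]
  mean(map$values[fi, ti])
}

#' Within-subject 2x2x2 repeated-measures ANOVA
#'
#' Contrast-based engine for a fully-crossed three-factor within-subject
#' design with two levels per factor: for each of the seven effects (three
#' mains, three two-way, one three-way), the per-subject contrast score is
#' the mean of the eight cell values weighted by the +/-1 design vector, and
#' `F = (mean score / SE of score)^2` with `(1, n - 1)` degrees of freedom
#' (identical to the squared paired t of the contrast). Factor labels are
#' arbitrary, so the engine serves both ERSP and reaction-time analyses.
#'
#' @param cells Long `data.frame` with columns `subject`, three factor
#'   columns (each with exactly two levels) and `value`. One value per
#'   subject and cell (aggregate beforehand if necessary).
#' @param factors Names of the three factor columns; defaults to every
#'   column except `subject` and `value`.
#' @return Object of class `anova_rm`: a table with `effect`, `F`, `df1`,
#'   `df2`, `p`, plus the cell means +/- SE table in `$cell_means`.
#' @export
rm_anova_2x2x2 <- function(cells, factors = NULL) {
  stopifnot(is.data.frame(cells), all(c("subject", "value") %in% names(cells)))
  if (is.null(factors)) factors <- setdiff(names(cells), c("subject", "value"))
  if (length(factors) != 3L) stop("exactly three factors are required",
                                  call. = FALSE)
  for (f in factors) {
    if (length(unique(cells[[f]])) != 2L) {
      stop(sprintf("factor `%s` must have exactly two levels", f),
           call. = FALSE)
    }
  }
  subjects <- sort(unique(cells$subject))
  n <- length(subjects)
  if (n < 2L) stop("need >= 2 subjects", call. = FALSE)
  lv <- lapply(factors, function(f) sort(unique(as.character(cells[[f]]))))
  grid <- expand.grid(lv, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  names(grid) <- factors
  ## subjects x 8 cell matrix
  key_cells <- do.call(paste, c(lapply(factors, function(f)
    as.character(cells[[f]])), sep = "\r"))
  key_grid <- do.call(paste, c(grid[factors], sep = "\r"))
  cm <- matrix(NA_real_, n, nrow(grid))
  for (i in seq_len(n)) {
    rows <- cells$subject == subjects[i]
    pos <- match(key_grid, key_cells[rows])
    if (anyNA(pos)) {
      stop(sprintf("subject %s is missing %d cell(s)", subjects[i],
                   sum(is.na(pos))), call. = FALSE)
    }
    cm[i, ] <- cells$value[rows][pos]
  }
  code <- lapply(factors, function(f) ifelse(grid[[f]] == lv[[match(f, factors)]][1], -1, 1))
  names(code) <- factors
  effects <- list()
  for (k in 1:3) {
    for (combo in utils::combn(factors, k, simplify = FALSE)) {
      effects[[paste(combo, collapse = ":")]] <-
        Reduce(`*`, code[combo])
    }
  }
  res <- lapply(names(effects), function(nm) {
    w <- effects[[nm]]
    score <- (cm %*% w) / length(w)
    mS <- mean(score)
    seS <- sd(score) / sqrt(n)
    Fv <- if (seS == 0) 0 else (mS / seS)^2
    data.frame(effect = nm, F = Fv, df1 = 1L, df2 = n - 1L,
               p = if (seS == 0) 1 else pf(Fv, 1, n - 1, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  rownames(tab) <- NULL
  cell_means <- grid
  cell_means$mean <- colMeans(cm)
  cell_means$se <- apply(cm, 2L, sd) / sqrt(n)
  structure(list(table = tab, cell_means = cell_means, n_subjects = n,
                 factors = factors),
            class = "anova_rm")
}

#' @export
print.anova_rm <- function(x, ...) {
  cat(sprintf("Within-subject 2x2x2 ANOVA (n = %d)\n", x$n_subjects))
  tab <- x$table
  tab$F <- sprintf("%.4g", tab$F)
  tab$p <- sprintf("%.4g", tab$p)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Bonferroni-corrected paired post-hoc comparisons
#'
#' Two-tailed paired t-test per comparison; each is declared significant at
#' `family_alpha / n_pairs` (e.g. 0.025 per test for two comparisons at a
#' family level of 0.05).
#'
#' @param pairs Named list; each element a list/data.frame with elements `x`
#'   and `y`, paired samples of equal length.
#' @param family_alpha Family-wise alpha.
#' @return `data.frame` with `comparison`, `t`, `df`, `p`, `alpha_adj`,
#'   `significant`.
#' @export
posthoc_bonferroni <- function(pairs, family_alpha = 0.05) {
  stopifnot(length(pairs) >= 1L)
  alpha_adj <- family_alpha / length(pairs)
  nm <- names(pairs) %||% paste0("pair", seq_along(pairs))
  rows <- lapply(seq_along(pairs), function(i) {
    x <- pairs[[i]]$x; y <- pairs[[i]]$y
    if (length(x) != length(y) || length(x) < 2L) {
      stop("each pair needs equal-length samples of size >= 2", call. = FALSE)
    }
    d <- x - y
    if (sd(d) <= 1e-10 * max(1, abs(mean(d)))) {
      warning(sprintf("comparison `%s` has zero-variance differences; p = 1",
                      nm[i]), call. = FALSE)
      return(data.frame(comparison = nm[i], t = 0, df = length(d) - 1L,
                        p = 1, alpha_adj = alpha_adj, significant = FALSE,
                        stringsAsFactors = FALSE))
    }
    tv <- mean(d) / (sd(d) / sqrt(length(d)))
    p <- 2 * pt(abs(tv), df = length(d) - 1L, lower.tail = FALSE)
    data.frame(comparison = nm[i], t = tv, df = length(d) - 1L, p = p,
               alpha_adj = alpha_adj, significant = p <= alpha_adj,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
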