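#' Pipeline configuration
#'
#' Bundles every stage's configuration and validates cross-references (ROI
#' channels must exist in the montage, analysis bands and windows must lie
#' inside the wavelet output grid) before any stage runs.
#'
#' @param design A [design_config()].
#' @param sim A [sim_config()].
#' @param preproc A [preproc_config()].
#' @param morlet A [morlet_spec()].
#' @param roi Named list with `left` and `right` channel label vectors.
#' @param band_windows Named list of [band_window_spec()]; defaults to
#'   [canonical_band_windows()].
#' @param n_perm Sign-flip permutations for the map contrasts.
#' @param alpha Map-level significance level (after FDR).
#' @param posthoc_alpha Family-wise alpha of the post-hoc comparisons.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(design = design_config(),
                            sim = sim_config(),
                            preproc = preproc_config(),
                            morlet = morlet_spec(),
                            roi = list(left = c("C1", "C3", "C5"),
                                       right = c("C2", "C4", "C6")),
                            band_windows = canonical_band_windows(),
                            n_perm = 10000,
                            alpha = 0.01,
                            posthoc_alpha = 0.05) {
  missing_ch <- setdiff(unlist(roi), sim$montage)
  if (length(missing_ch) > 0L) {
    stop(sprintf("ROI channel(s) absent from the montage: %s",
                 paste(missing_ch, collapse = ", ")), call. = FALSE)
  }
  for (nm in names(band_windows)) {
    bw <- band_windows[[nm]]
    if (bw$band_hz[1] < morlet$f_min_hz || bw$band_hz[2] > morlet$f_max_hz) {
      stop(sprintf("band `%s` outside the wavelet frequency grid", nm),
           call. = FALSE)
    }
    if (bw$window_ms[1] < morlet$output_window_ms[1] ||
        bw$window_ms[2] > morlet$output_window_ms[2]) {
      stop(sprintf("window `%s` outside the wavelet output window", nm),
           call. = FALSE)
    }
  }
  structure(list(design = design, sim = sim, preproc = preproc,
                 morlet = morlet, roi = roi, band_windows = band_windows,
                 n_perm = n_perm, alpha = alpha,
                 posthoc_alpha = posthoc_alpha),
            class = "pipeline_config")
}

#' Subset an epoch set by trial index
#' @param epochs An [eeg_epochs()].
#' @param idx Logical or integer index into trials.
#' @return The subset [eeg_epochs()].
#' @export
epochs_subset <- function(epochs, idx) {
  eeg_epochs(epochs$data[idx, , , drop = FALSE], epochs$times_ms,
             epochs$ch_names, epochs$ch_types, epochs$sfreq,
             epochs$metadata[idx, , drop = FALSE])
}

## Preprocess, score and decompose one subject; returns condition-wise ROI
## maps, band/window cell values and RT cell means.
process_subject <- function(subj, cfg, verbose = FALSE) {
  rec <- subj$recording
  trials <- subj$trials
  behavior <- score_trials(rec, trials, subj$side_mapping)
  prep <- preprocess_continuous(rec, cfg$preproc)
  epochs <- epoch_and_baseline(prep, trials, cfg$preproc)
  n_total <- dim(epochs$data)[1]
  epochs <- select_valid_trials(epochs, behavior)
  n_kept <- dim(epochs$data)[1]
  if (verbose) {
    message(sprintf("subject %s: %d/%d trials retained (%.1f%% discarded)",
                    subj$subject, n_kept, n_total,
                    100 * (1 - n_kept / n_total)))
  }
  channels <- unique(unlist(cfg$roi))
  syllables <- sort(unique(trials$syllable))
  stim_levels <- sort(unique(trials$stimulation))
  md <- epochs$metadata

  cond_of <- paste(md$syllable, md$stimulation, sep = ".")
  if (length(unique(cond_of)) < length(syllables) * length(stim_levels)) {
    stop(sprintf("subject %s has an empty condition cell", subj$subject),
         call. = FALSE)
  }
  ch_maps <- ersp_by_condition(epochs, channels, cfg$morlet,
                               baseline_ms = cfg$preproc$baseline_window_ms,
                               groups = cond_of)
  roi_maps <- list()
  band_cells <- list()
  for (sy in syllables) {
    for (st in stim_levels) {
      cond <- paste(sy, st, sep = ".")
      cmaps <- lapply(ch_maps, `[[`, cond)
      for (side in names(cfg$roi)) {
        roi_maps[[side]][[cond]] <- roi_average(cmaps, cfg$roi[[side]])
      }
      for (bw_name in names(cfg$band_windows)) {
        band_cells[[length(band_cells) + 1L]] <- data.frame(
          subject = subj$subject, syllable = sy, stimulation = st,
          measure = bw_name,
          value = extract_band_window_means(roi_maps$left[[cond]],
                                            cfg$band_windows[[bw_name]]),
          stringsAsFactors = FALSE)
      }
    }
  }

  beh <- merge(behavior, trials, by = "trial_id")
  beh <- beh[beh$valid & beh$correct, , drop = FALSE]
  rt_cells <- aggregate(rt_ms ~ syllable + stimulation + question_polarity,
                        data = beh, FUN = mean)
  rt_cells$subject <- subj$subject

  list(subject = subj$subject, roi_maps = roi_maps,
       band_cells = do.call(rbind, band_cells), rt_cells = rt_cells,
       n_total = n_total, n_kept = n_kept,
       n_invalid = sum(!behavior$valid),
       n_incorrect = sum(behavior$valid & !behavior$correct))
}

#' Run the full analysis pipeline
#'
#' Simulates (or accepts) a multi-subject study and carries it through
#' preprocessing, behavioral scoring, ERSP computation, map-level
#' permutation statistics and the band/window ANOVAs:
#' per subject and condition, ROI-averaged ERSP maps are computed from the
#' valid, correct trials; group maps and dental-minus-bilabial significance
#' masks (sign-flip permutation, FDR) are derived per ROI and stimulation
#' level; mu- and beta-band window means from the left ROI enter a
#' syllable x stimulation x time-window within-subject ANOVA with Bonferroni
#' post-hoc tests of the syllable effect in the rebound window; reaction
#' times enter a syllable x stimulation x question-polarity ANOVA.
#'
#' @param cfg A [pipeline_config()].
#' @param seed Master seed; all stage seeds derive from it.
#' @param subjects Optional pre-built subject list (as returned by
#'   [simulate_study()], or real recordings arranged the same way); when
#'   `NULL` the synthetic study defined by `cfg` is generated.
#' @param run_map_stats If `FALSE`, the (slow) map-level permutation stage is
#'   skipped; ANOVAs still run.
#' @param verbose Log per-subject trial counts.
#' @return A `rebound_report`: list with `group_maps`, `map_stats`,
#'   `band_table`, `anova` (one per band), `posthoc`, `rt_anova`, `counts`
#'   and a reproducibility `manifest`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), seed = 1L,
                         subjects = NULL, run_map_stats = TRUE,
                         verbose = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.null(subjects)) {
    subjects <- simulate_study(cfg$design, cfg$sim, seed = seed)
  }
  per_subj <- lapply(subjects, process_subject, cfg = cfg, verbose = verbose)

  conds <- names(per_subj[[1]]$roi_maps$left)
  group_maps <- list()
  for (side in names(cfg$roi)) {
    for (cond in conds) {
      group_maps[[side]][[cond]] <-
        group_average(lapply(per_subj, function(s) s$roi_maps[[side]][[cond]]))
    }
  }

  syllables <- sort(unique(per_subj[[1]]$band_cells$syllable))
  stim_levels <- sort(unique(per_subj[[1]]$band_cells$stimulation))
  map_stats <- NULL
  if (run_map_stats && length(syllables) == 2L) {
    map_stats <- list()
    k <- 0L
    for (side in names(cfg$roi)) {
      for (st in stim_levels) {
        k <- k + 1L
        a <- lapply(per_subj, function(s)
          s$roi_maps[[side]][[paste(syllables[2], st, sep = ".")]])
        b <- lapply(per_subj, function(s)
          s$roi_maps[[side]][[paste(syllables[1], st, sep = ".")]])
        map_stats[[side]][[st]] <- compare_maps_permutation(
          a, b, n_perm = cfg$n_perm, alpha = cfg$alpha,
          seed = derive_seed(seed, 5000 + k))
      }
    }
  }

  band_table <- do.call(rbind, lapply(per_subj, `[[`, "band_cells"))
  rownames(band_table) <- NULL

  ## band-wise ANOVA: ERD window vs the band's rebound window, left ROI
  bands <- unique(sub("_(erd|ers)$", "", names(cfg$band_windows)))
  anovas <- list()
  posthocs <- list()
  for (b in bands) {
    erd_nm <- paste0(b, "_erd"); ers_nm <- paste0(b, "_ers")
    if (!all(c(erd_nm, ers_nm) %in% names(cfg$band_windows))) next
    sub_tab <- band_table[band_table$measure %in% c(erd_nm, ers_nm), ]
    sub_tab$window <- ifelse(sub_tab$measure == erd_nm, "ERD", "ERS")
    anovas[[b]] <- rm_anova_2x2x2(
      sub_tab[, c("subject", "syllable", "stimulation", "window", "value")],
      factors = c("syllable", "stimulation", "window"))
    ers_tab <- sub_tab[sub_tab$window == "ERS", ]
    pairs <- lapply(stim_levels, function(st) {
      w <- ers_tab[ers_tab$stimulation == st, ]
      w <- w[order(w$subject), ]
      list(x = w$value[w$syllable == syllables[2]],
           y = w$value[w$syllable == syllables[1]])
    })
    names(pairs) <- sprintf("%s_vs_%s_ers_stim_%s",
                            syllables[2], syllables[1], stim_levels)
    posthocs[[b]] <- posthoc_bonferroni(pairs,
                                        family_alpha = cfg$posthoc_alpha)
  }

  rt_table <- do.call(rbind, lapply(per_subj, `[[`, "rt_cells"))
  rt_long <- rt_table[, c("subject", "syllable", "stimulation",
                          "question_polarity", "rt_ms")]
  names(rt_long)[5] <- "value"
  rt_anova <- tryCatch(
    rm_anova_2x2x2(rt_long,
                   factors = c("syllable", "stimulation",
                               "question_polarity")),
    error = function(e) {
      warning("reaction-time ANOVA skipped: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })

  counts <- data.frame(
    subject = vapply(per_subj, function(s) as.numeric(s$subject), numeric(1)),
    n_total = vapply(per_subj, `[[`, numeric(1), "n_total"),
    n_kept = vapply(per_subj, `[[`, numeric(1), "n_kept"),
    n_invalid = vapply(per_subj, `[[`, numeric(1), "n_invalid"),
    n_incorrect = vapply(per_subj, `[[`, numeric(1), "n_incorrect"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("betarebound")),
    seed = seed,
    n_subjects = length(subjects),
    n_perm = cfg$n_perm, alpha = cfg$alpha,
    posthoc_alpha = cfg$posthoc_alpha,
    preproc = unclass(cfg$preproc),
    morlet = unclass(cfg$morlet),
    roi = cfg$roi,
    band_windows = lapply(cfg$band_windows, unclass),
    sim = unclass(cfg$sim), design = unclass(cfg$design))

  structure(list(group_maps = group_maps, map_stats = map_stats,
                 band_table = band_table, anova = anovas,
                 posthoc = posthocs, rt_table = rt_table,
                 rt_anova = rt_anova, counts = counts, manifest = manifest,
                 subject_maps = lapply(per_subj, `[[`, "roi_maps")),
            class = "rebound_report")
}

#' @export
print.rebound_report <- function(x, ...) {
  cat(sprintf("<rebound_report> %d subjects, %.1f%% trials discarded\n",
              nrow(x$counts),
              100 * (1 - sum(x$counts$n_kept) / sum(x$counts$n_total))))
  for (b in names(x$anova)) {
    cat(sprintf("\n-- %s band ERSP ANOVA (left ROI) --\n", b))
    print(x$anova[[b]])
    print(x$posthoc[[b]], row.names = FALSE)
  }
  if (!is.null(x$rt_anova)) {
    cat("\n-- reaction times ANOVA --\n")
    print(x$rt_anova)
  }
  invisible(x)
}

#' Write a pipeline report bundle to disk
#'
#' Emits JSON for the ANOVA/post-hoc/RT tables, counts and manifest, and TSV
#' for group maps and significance masks.
#'
#' @param report A `rebound_report` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  j <- list(
    anova = lapply(report$anova, function(a)
      list(table = a$table, cell_means = a$cell_means)),
    posthoc = report$posthoc,
    rt_anova = if (!is.null(report$rt_anova)) {
      list(table = report$rt_anova$table,
           cell_means = report$rt_anova$cell_means)
    },
    counts = report$counts,
    manifest = report$manifest)
  jsonlite::write_json(j, file.path(out_dir, "report.json"),
                       digits = NA, auto_unbox = TRUE, dataframe = "rows",
                       force = TRUE)
  utils::write.table(report$band_table,
                     file.path(out_dir, "band_window_table.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (side in names(report$group_maps)) {
    for (cond in names(report$group_maps[[side]])) {
      write_ersp_map(report$group_maps[[side]][[cond]],
                     file.path(out_dir,
                               sprintf("group_ersp_%s_%s.tsv", side, cond)))
    }
    if (!is.null(report$map_stats)) {
      for (st in names(report$map_stats[[side]])) {
        m <- report$map_stats[[side]][[st]]
        utils::write.table(m$mask * 1L,
                           file.path(out_dir,
                                     sprintf("mask_%s_stim_%s.tsv", side, st)),
                           sep = "\t", row.names = FALSE, col.names = FALSE)
      }
    }
  }
  invisible(out_dir)
}

#' Read / write pipeline configuration as YAML or JSON
#'
#' Serializes every stage's fields; [read_pipeline_config()] rebuilds the
#' validated `pipeline_config` object.
#' @param cfg A [pipeline_config()].
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_pipeline_config` returns the [pipeline_config()].
#' @export
write_pipeline_config <- function(cfg, path) {
  o <- list(design = unclass(cfg$design), sim = unclass(cfg$sim),
            preproc = unclass(cfg$preproc), morlet = unclass(cfg$morlet),
            roi = cfg$roi,
            band_windows = lapply(cfg$band_windows, unclass),
            n_perm = cfg$n_perm, alpha = cfg$alpha,
            posthoc_alpha = cfg$posthoc_alpha)
  o$design$response_sides <- as.list(cfg$design$response_sides)
  o$sim$left_lateralization <- as.list(cfg$sim$left_lateralization)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(o, path, digits = NA, auto_unbox = TRUE)
  } else {
    yaml::write_yaml(o, path)
  }
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  o <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  num2 <- function(v) as.numeric(unlist(v))
  design <- design_config(
    n_speakers = o$design$n_speakers,
    syllables = unlist(o$design$syllables),
    repetitions_per_audio = o$design$repetitions_per_audio,
    stimulation_levels = unlist(o$design$stimulation_levels),
    iti_range_s = num2(o$design$iti_range_s),
    question_delay_s = o$design$question_delay_s,
    response_sides = unlist(o$design$response_sides))
  sim_args <- o$sim
  sim_args$montage <- unlist(sim_args$montage)
  sim_args$eog_channels <- unlist(sim_args$eog_channels)
  sim_args$left_lateralization <- unlist(sim_args$left_lateralization)
  for (f in c("erd_window_ms", "ers_window_ms")) sim_args[[f]] <- num2(sim_args[[f]])
  sim <- do.call(sim_config, sim_args)
  preproc <- preproc_config(
    bandpass_hz = num2(o$preproc$bandpass_hz),
    resample_hz = o$preproc$resample_hz,
    epoch_window_s = num2(o$preproc$epoch_window_s),
    baseline_window_ms = num2(o$preproc$baseline_window_ms),
    reference = o$preproc$reference)
  morlet <- morlet_spec(
    f_min_hz = o$morlet$f_min_hz, f_max_hz = o$morlet$f_max_hz,
    f_step_hz = o$morlet$f_step_hz,
    cycles_at_fmin = o$morlet$cycles_at_fmin,
    cycles_at_fmax = o$morlet$cycles_at_fmax,
    output_window_ms = num2(o$morlet$output_window_ms))
  bw <- lapply(o$band_windows, function(b)
    band_window_spec(num2(b$band_hz), num2(b$window_ms), b$label %||% ""))
  pipeline_config(design = design, sim = sim, preproc = preproc,
                  morlet = morlet,
                  roi = lapply(o$roi, unlist),
                  band_windows = bw,
                  n_perm = o$n_perm, alpha = o$alpha,
                  posthoc_alpha = o$posthoc_alpha)
}
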