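#' Experimental design configuration
#'
#' Parameters of the factorial listening task: consonant-vowel syllables
#' differing in place of articulation (bilabial vs dental), uttered by
#' several speakers, each audio token repeated a fixed number of times, and
#' crossed with the presence/absence of lip somatosensory stimulation. The
#' defaults reproduce the canonical design: 6 speakers x 2 syllables x
#' 8 repetitions x 2 stimulation levels = 192 trials, 96 with stimulation.
#'
#' @param n_speakers Number of distinct speakers (audio tokens per syllable).
#' @param syllables Character vector of place-of-articulation labels.
#' @param repetitions_per_audio Repetitions of each audio file per
#'   stimulation level.
#' @param stimulation_levels Character vector of stimulation conditions.
#' @param iti_range_s Inter-trial interval range in seconds, drawn uniformly
#'   per trial (measured from question onset to the next vowel onset).
#' @param question_delay_s Delay from vowel onset to the identification
#'   question, seconds.
#' @param response_sides Named character vector mapping `"yes"`/`"no"`
#'   answers to saccade sides `"left"`/`"right"` (counterbalanced across
#'   subjects by the pipeline).
#' @return An object of class `design_config`.
#' @export
#' @examples
#' cfg <- design_config()
#' nrow(build_design(cfg, seed = 1))
design_config <- function(n_speakers = 6L,
                          syllables = c("bilabial", "dental"),
                          repetitions_per_audio = 8L,
                          stimulation_levels = c("present", "absent"),
                          iti_range_s = c(7, 8),
                          question_delay_s = 1.5,
                          response_sides = c(yes = "right", no = "left")) {
  if (n_speakers < 1L || repetitions_per_audio < 1L) {
    stop("counts must be >= 1", call. = FALSE)
  }
  if (length(syllables) == 0L || length(stimulation_levels) == 0L) {
    stop("syllable and stimulation level sets must be non-empty",
         call. = FALSE)
  }
  stopifnot_interval(iti_range_s, "iti_range_s")
  if (!setequal(names(response_sides), c("yes", "no")) ||
      !all(response_sides %in% c("left", "right"))) {
    stop("`response_sides` must map yes/no to left/right", call. = FALSE)
  }
  structure(list(
    n_speakers = as.integer(n_speakers),
    syllables = syllables,
    repetitions_per_audio = as.integer(repetitions_per_audio),
    stimulation_levels = stimulation_levels,
    iti_range_s = iti_range_s,
    question_delay_s = question_delay_s,
    response_sides = response_sides
  ), class = "design_config")
}

#' Build a pseudo-randomized trial table
#'
#' Fully crosses speakers, syllables, repetitions and stimulation levels,
#' shuffles the row order, schedules event times (vowel onset, question
#' onset) with a uniform inter-trial interval, and assigns question
#' polarities balanced to within one trial of an even split. A positive
#' polarity question is one whose correct answer is "yes"; the required
#' saccade side follows from `response_sides`.
#'
#' @param cfg A [design_config()].
#' @param seed Integer seed controlling shuffling, polarity assignment and
#'   inter-trial intervals.
#' @return A `data.frame` (the trial table) with columns `trial_id`,
#'   `syllable`, `speaker`, `stimulation`, `vowel_onset_s`,
#'   `question_onset_s`, `question_polarity`, `true_response_side`.
#' @export
build_design <- function(cfg = design_config(), seed = 1L) {
  stopifnot(inherits(cfg, "design_config"))
  grid <- expand.grid(
    speaker = seq_len(cfg$n_speakers),
    syllable = cfg$syllables,
    rep = seq_len(cfg$repetitions_per_audio),
    stimulation = cfg$stimulation_levels,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  n <- nrow(grid)
  with_seed(seed, {
    grid <- grid[sample.int(n), , drop = FALSE]
    ## polarity balanced within each syllable x stimulation cell (and hence
    ## overall to within one trial): half the questions demand "yes"
    polarity <- rep("negative", n)
    cell <- paste(grid$syllable, grid$stimulation)
    for (cl in unique(cell)) {
      rows <- which(cell == cl)
      m <- length(rows)
      n_pos <- floor(m / 2) + (m %% 2L) * sample(0:1, 1L)
      polarity[sample(rows, n_pos)] <- "positive"
    }
    iti <- runif(n, cfg$iti_range_s[1], cfg$iti_range_s[2])
    ## first vowel onset leaves room for the pre-stimulus epoch segment
    vowel <- numeric(n)
    vowel[1] <- 2.0
    if (n > 1L) {
      for (i in 2:n) {
        vowel[i] <- vowel[i - 1] + cfg$question_delay_s + iti[i - 1]
      }
    }
    answer <- ifelse(polarity == "positive", "yes", "no")
    out <- data.frame(
      trial_id = seq_len(n),
      syllable = grid$syllable,
      speaker = grid$speaker,
      stimulation = grid$stimulation,
      vowel_onset_s = vowel,
      question_onset_s = vowel + cfg$question_delay_s,
      question_polarity = polarity,
      true_response_side = unname(cfg$response_sides[answer]),
      stringsAsFactors = FALSE
    )
    rownames(out) <- NULL
    out
  })
}

#' Write / read a trial table as CSV
#'
#' Column names are fixed by the interchange contract of the trial table.
#' @param trials A trial table from [build_design()].
#' @param path File path.
#' @return `read_trial_table` returns the trial table `data.frame`.
#' @export
write_trial_table <- function(trials, path) {
  write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
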