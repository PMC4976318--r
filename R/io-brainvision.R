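## Minimal BrainVision (vhdr/vmrk/eeg) reader and writer: binary multiplexed
## data in IEEE_FLOAT_32 or INT_16, markers from the .vmrk file. Covers the
## layout produced by common acquisition setups; not a full format library.

parse_vhdr_section <- function(lines, section) {
  start <- grep(sprintf("^\\[%s\\]", section), lines)
  if (length(start) == 0L) return(character(0))
  rest <- lines[(start[1] + 1L):length(lines)]
  stop_ <- grep("^\\[", rest)
  if (length(stop_) > 0L) rest <- rest[seq_len(stop_[1] - 1L)]
  rest[grepl("=", rest) & !grepl("^;", rest)]
}

kv <- function(entries) {
  keys <- sub("=.*$", "", entries)
  vals <- sub("^[^=]*=", "", entries)
  setNames(vals, keys)
}

#' Read a BrainVision recording
#'
#' Parses the `.vhdr` header, the binary `.eeg` payload (multiplexed,
#' `IEEE_FLOAT_32` or `INT_16` with per-channel resolution) and the `.vmrk`
#' marker file. Marker descriptions become event labels; positions (1-based
#' data points) are converted to onset seconds.
#'
#' @param vhdr_path Path to the `.vhdr` header file.
#' @return An [eeg_recording()].
#' @export
read_brainvision <- function(vhdr_path) {
  lines <- readLines(vhdr_path, warn = FALSE)
  common <- kv(parse_vhdr_section(lines, "Common Infos"))
  binary <- kv(parse_vhdr_section(lines, "Binary Infos"))
  chans <- parse_vhdr_section(lines, "Channel Infos")
  if (!identical(toupper(common[["DataFormat"]]), "BINARY")) {
    stop("only BINARY BrainVision data is supported", call. = FALSE)
  }
  if (!identical(toupper(common[["DataOrientation"]] %||% "MULTIPLEXED"),
                 "MULTIPLEXED")) {
    stop("only MULTIPLEXED orientation is supported", call. = FALSE)
  }
  n_ch <- as.integer(common[["NumberOfChannels"]])
  sfreq <- 1e6 / as.numeric(common[["SamplingInterval"]])
  ch_fields <- strsplit(sub("^[^=]*=", "", chans), ",")
  ch_names <- vapply(ch_fields, `[[`, "", 1L)
  resolution <- vapply(ch_fields, function(f)
    if (length(f) >= 3L && nzchar(f[3])) as.numeric(f[3]) else 1, numeric(1))
  dir <- dirname(vhdr_path)
  eeg_path <- file.path(dir, common[["DataFile"]])
  fmt <- toupper(binary[["BinaryFormat"]] %||% "IEEE_FLOAT_32")
  sz <- file.info(eeg_path)$size
  raw_vals <- if (fmt == "IEEE_FLOAT_32") {
    readBin(eeg_path, "numeric", n = sz / 4, size = 4L, endian = "little")
  } else if (fmt == "INT_16") {
    readBin(eeg_path, "integer", n = sz / 2, size = 2L, signed = TRUE,
            endian = "little")
  } else stop(sprintf("unsupported BinaryFormat: %s", fmt), call. = FALSE)
  n_samp <- length(raw_vals) %/% n_ch
  x <- matrix(raw_vals[seq_len(n_samp * n_ch)], nrow = n_ch) * resolution

  events <- data.frame(onset_s = numeric(0), label = character(0),
                       trial_id = integer(0))
  mrk_file <- common[["MarkerFile"]]
  if (!is.null(mrk_file) && file.exists(file.path(dir, mrk_file))) {
    mlines <- readLines(file.path(dir, mrk_file), warn = FALSE)
    mk <- parse_vhdr_section(mlines, "Marker Infos")
    mk <- mk[grepl("^Mk[0-9]+=", mk)]
    fields <- strsplit(sub("^[^=]*=", "", mk), ",")
    keep <- vapply(fields, function(f) length(f) >= 3L, logical(1))
    fields <- fields[keep]
    desc <- vapply(fields, `[[`, "", 2L)
    pos <- as.numeric(vapply(fields, `[[`, "", 3L))
    drop <- vapply(fields, `[[`, "", 1L) == "New Segment"
    parts <- strsplit(desc, ":", fixed = TRUE)
    events <- data.frame(
      onset_s = (pos[!drop] - 1) / sfreq,
      label = vapply(parts[!drop], `[[`, "", 1L),
      trial_id = suppressWarnings(as.integer(vapply(parts[!drop], function(p)
        if (length(p) > 1L) p[2] else NA_character_, ""))),
      stringsAsFactors = FALSE
    )
  }
  eeg_recording(x, sfreq, ch_names,
                ifelse(grepl("^EOG", ch_names, ignore.case = TRUE),
                       "eog", "eeg"),
                events)
}

#' Write a recording in BrainVision format
#'
#' Emits the `.vhdr`/`.vmrk`/`.eeg` triplet (multiplexed `IEEE_FLOAT_32`,
#' resolution 1). Event labels are written as marker descriptions
#' (`"<label>:<trial_id>"`).
#'
#' @param rec An [eeg_recording()].
#' @param basename_path Output path without extension.
#' @return The `.vhdr` path, invisibly.
#' @export
write_brainvision <- function(rec, basename_path) {
  stopifnot(inherits(rec, "eeg_recording"))
  base <- basename(basename_path)
  vhdr <- paste0(basename_path, ".vhdr")
  vmrk <- paste0(basename_path, ".vmrk")
  eegf <- paste0(basename_path, ".eeg")
  writeLines(c(
    "BrainVision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nrow(rec$data)),
    sprintf("SamplingInterval=%.6f", 1e6 / rec$sfreq),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,uV", seq_len(nrow(rec$data)), rec$ch_names)
  ), vhdr)
  ev <- rec$events
  writeLines(c(
    "BrainVision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    "[Marker Infos]",
    if (nrow(ev) > 0L) {
      sprintf("Mk%d=Stimulus,%s:%s,%d,1,0", seq_len(nrow(ev)),
              ev$label, ev$trial_id %||% seq_len(nrow(ev)),
              round(ev$onset_s * rec$sfreq) + 1L)
    } else character(0)
  ), vmrk)
  con <- file(eegf, "wb")
  on.exit(close(con))
  writeBin(as.vector(rec$data), con, size = 4L, endian = "little")
  invisible(vhdr)
}
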