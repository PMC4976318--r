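## Minimal EDF(+C) writer/reader: 16-bit signals, one annotation channel
## carrying the event markers as time-stamped annotation lists. Covers what
## this package needs for interchange; not a general-purpose EDF library.

edf_pad <- function(x, width) {
  x <- substr(x, 1L, width)
  paste0(x, strrep(" ", width - nchar(x)))
}

#' Write a recording as EDF+
#'
#' Signals are scaled to 16-bit integers per channel (physical range taken
#' from the data); events are stored in an `EDF Annotations` signal as
#' onset-stamped annotations labelled `"<label>:<trial_id>"`. Record
#' duration is 1 s; the final record is zero-padded and the true sample
#' count is noted in the reserved header field so [read_edf()] can restore
#' the exact length.
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  sf <- rec$sfreq
  if (abs(sf - round(sf)) > 1e-9) {
    stop("EDF writer requires an integer sampling rate", call. = FALSE)
  }
  sf <- as.integer(round(sf))
  n_ch <- nrow(rec$data)
  n <- ncol(rec$data)
  n_rec <- ceiling(n / sf)

  ## annotation byte budget: record-start TAL + that record's event TALs
  ann_txt <- sprintf("%s:%s", rec$events$label,
                     rec$events$trial_id %||% seq_len(nrow(rec$events)))
  ev_rec <- pmin(floor(rec$events$onset_s), n_rec - 1L)
  tal_ev <- sprintf("+%.6f\x14%s\x14", rec$events$onset_s, ann_txt)
  bytes_per_rec <- vapply(seq_len(n_rec) - 1L, function(r) {
    nchar(sprintf("+%d\x14\x14", r), type = "bytes") + 1L +
      sum(nchar(tal_ev[ev_rec == r], type = "bytes"))
  }, numeric(1))
  ns_ann <- max(16L, ceiling(max(bytes_per_rec) / 2))

  pmin_ <- apply(rec$data, 1L, min)
  pmax_ <- apply(rec$data, 1L, max)
  flat <- pmax_ - pmin_ < 1e-6
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L * (1L + n_ch + 1L)
  writeChar(paste0(
    edf_pad("0", 8),
    edf_pad("X X X X", 80),
    edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(as.character(hdr_bytes), 8),
    edf_pad(sprintf("EDF+C ns=%d", n), 44),
    edf_pad(as.character(n_rec), 8),
    edf_pad("1", 8),
    edf_pad(as.character(n_ch + 1L), 4)
  ), con, eos = NULL)
  lab <- c(rec$ch_names, "EDF Annotations")
  fld <- function(vals, width) paste(vapply(vals, edf_pad, "", width),
                                     collapse = "")
  writeChar(paste0(
    fld(lab, 16),
    fld(rep("", n_ch + 1L), 80),
    fld(c(rep("uV", n_ch), ""), 8),
    fld(c(sprintf("%.6g", pmin_), "-1"), 8),
    fld(c(sprintf("%.6g", pmax_), "1"), 8),
    fld(rep(as.character(dmin), n_ch + 1L), 8),
    fld(rep(as.character(dmax), n_ch + 1L), 8),
    fld(rep("", n_ch + 1L), 80),
    fld(c(rep(as.character(sf), n_ch), as.character(ns_ann)), 8),
    fld(rep("", n_ch + 1L), 32)
  ), con, eos = NULL)

  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec) - 1L) {
    idx <- (r * sf + 1L):min((r + 1L) * sf, n)
    for (ch in seq_len(n_ch)) {
      seg <- rec$data[ch, idx]
      dig <- as.integer(round((seg - pmin_[ch]) * scale[ch]) + dmin)
      if (length(dig) < sf) {
        pad_val <- as.integer(round((0 - pmin_[ch]) * scale[ch]) + dmin)
        dig <- c(dig, rep(pad_val, sf - length(dig)))
      }
      writeBin(dig, con, size = 2L, endian = "little")
    }
    tal <- paste0(sprintf("+%d\x14\x14", r), rawToChar(as.raw(0L)),
                  paste(tal_ev[ev_rec == r], collapse = ""))
    raw_tal <- charToRaw(tal)
    raw_tal <- c(raw_tal, raw(2L * ns_ann - length(raw_tal)))
    writeBin(raw_tal, con)
  }
  invisible(path)
}

#' Read an EDF(+) file
#'
#' Reads 16-bit EDF signals and, when present, events from the
#' `EDF Annotations` channel. Channels named like `EOG*` are typed `"eog"`,
#' all others `"eeg"`.
#'
#' @param path EDF file path.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                # header bytes (recomputed)
  reserved <- rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  n_sig <- as.integer(rd(4))
  labels <- vapply(seq_len(n_sig), function(i) rd(16), "")
  for (i in seq_len(n_sig)) rd(80)
  for (i in seq_len(n_sig)) rd(8)      # physical dimension
  pmin_ <- as.numeric(vapply(seq_len(n_sig), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(n_sig), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(n_sig), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(n_sig), function(i) rd(8), ""))
  for (i in seq_len(n_sig)) rd(80)
  ns <- as.integer(vapply(seq_len(n_sig), function(i) rd(8), ""))
  for (i in seq_len(n_sig)) rd(32)

  is_ann <- labels == "EDF Annotations"
  sig_idx <- which(!is_ann)
  dat <- vector("list", length(sig_idx))
  names(dat) <- labels[sig_idx]
  for (j in seq_along(sig_idx)) dat[[j]] <- vector("list", n_rec)
  ann_raw <- raw(0)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(n_sig)) {
      if (is_ann[i]) {
        ann_raw <- c(ann_raw, readBin(con, "raw", 2L * ns[i]))
      } else {
        v <- readBin(con, "integer", ns[i], size = 2L, signed = TRUE,
                     endian = "little")
        j <- match(i, sig_idx)
        dat[[j]][[r]] <- pmin_[i] + (v - dmin[i]) *
          (pmax_[i] - pmin_[i]) / (dmax[i] - dmin[i])
      }
    }
  }
  x <- do.call(rbind, lapply(dat, function(ch) unlist(ch, use.names = FALSE)))
  sf <- ns[sig_idx[1]] / rec_dur
  m <- regmatches(reserved, regexec("ns=([0-9]+)", reserved))[[1]]
  if (length(m) == 2L) x <- x[, seq_len(as.integer(m[2])), drop = FALSE]

  events <- data.frame(onset_s = numeric(0), label = character(0),
                       trial_id = integer(0))
  if (any(is_ann) && length(ann_raw) > 0L) {
    txt <- strsplit(rawToChar(ann_raw[ann_raw != as.raw(0)]),
                    "\x14", fixed = TRUE)[[1]]
    ## TALs alternate "+onset" and "label" tokens; bare "+t" timestamps have
    ## no label and are skipped
    onsets <- c(); labs <- c(); ids <- c()
    i <- 1L
    while (i <= length(txt)) {
      tok <- txt[i]
      if (grepl("^[+-][0-9.]+$", tok)) {
        if (i + 1L <= length(txt) && nzchar(txt[i + 1L]) &&
            !grepl("^[+-][0-9.]+$", txt[i + 1L])) {
          onsets <- c(onsets, as.numeric(tok))
          labs <- c(labs, txt[i + 1L])
          i <- i + 2L
          next
        }
      }
      i <- i + 1L
    }
    if (length(onsets) > 0L) {
      parts <- strsplit(labs, ":", fixed = TRUE)
      events <- data.frame(
        onset_s = onsets,
        label = vapply(parts, `[[`, "", 1L),
        trial_id = suppressWarnings(as.integer(vapply(parts, function(p)
          if (length(p) > 1L) p[2] else NA_character_, ""))),
        stringsAsFactors = FALSE
      )
    }
  }
  ch_names <- names(dat)
  eeg_recording(x, sf, ch_names,
                ifelse(grepl("^EOG", ch_names, ignore.case = TRUE),
                       "eog", "eeg"),
                events)
}
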