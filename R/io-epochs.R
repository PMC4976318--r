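#' Persist an epoch set as a binary container with a JSON sidecar
#'
#' The voltage array is written as little-endian float64 in R array order
#' (trial index fastest) to `<base>.dat`; dimensions, grids, channel
#' labels/types, sampling rate and the trial metadata table go to
#' `<base>.json`.
#'
#' @param epochs An [eeg_epochs()].
#' @param basename_path Output path without extension.
#' @return The `.json` path, invisibly. `read_epochs` returns the
#'   [eeg_epochs()].
#' @export
write_epochs <- function(epochs, basename_path) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  dat <- paste0(basename_path, ".dat")
  side <- paste0(basename_path, ".json")
  con <- file(dat, "wb")
  on.exit(close(con))
  writeBin(as.vector(epochs$data), con, size = 8L, endian = "little")
  jsonlite::write_json(list(
    dim = dim(epochs$data),
    times_ms = epochs$times_ms,
    ch_names = epochs$ch_names,
    ch_types = epochs$ch_types,
    sfreq = epochs$sfreq,
    data_file = basename(dat),
    metadata = epochs$metadata
  ), side, digits = NA, auto_unbox = TRUE, dataframe = "columns")
  invisible(side)
}

#' @rdname write_epochs
#' @param json_path Path to the `.json` sidecar.
#' @export
read_epochs <- function(json_path) {
  side <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  dat <- file.path(dirname(json_path), side$data_file)
  n <- prod(side$dim)
  x <- readBin(dat, "numeric", n = n, size = 8L, endian = "little")
  eeg_epochs(array(x, dim = side$dim), side$times_ms, side$ch_names,
             side$ch_types, side$sfreq,
             as.data.frame(side$metadata, stringsAsFactors = FALSE))
}
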