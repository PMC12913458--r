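#' Write a recording as .fdt + JSON sidecar
#'
#' The data file is EEGLAB-compatible .fdt: 32-bit little-endian floats,
#' sample-major (all channels of sample 1, then sample 2, ...). Recording
#' parameters (fs, channel names, metadata) go to a JSON sidecar instead of
#' a MATLAB .set file, keeping the fixture format plain and portable.
#'
#' @param rec an [eeg_recording()].
#' @param path output path without extension; writes `path.fdt` and
#'   `path.json`.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(paste0(path, ".fdt"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec$data), con, size = 4, endian = "little")
  meta <- list(fs = rec$fs, n_channels = nrow(rec$data),
               n_samples = ncol(rec$data), ch_names = rec$ch_names,
               subject = rec$subject, group = rec$group)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read a recording written by [write_fixture()]
#'
#' @param path path without extension.
#' @return An [eeg_recording()].
#' @export
read_fixture <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(paste0(path, ".fdt"), "rb")
  on.exit(close(con))
  n <- meta$n_channels * meta$n_samples
  x <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  eeg_recording(matrix(x, nrow = meta$n_channels), fs = meta$fs,
                ch_names = meta$ch_names, subject = meta$subject,
                group = meta$group)
}

#' Write learned templates as CSV + JSON metadata
#'
#' @param templates a `template_set`.
#' @param path output path without extension.
#' @return `path`, invisibly.
#' @export
write_templates <- function(templates, path) {
  m <- as.data.frame(templates$maps)
  names(m) <- templates$ch_names
  utils::write.csv(m, paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(list(K = templates$K, n_channels = ncol(templates$maps)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Write per-epoch label sequences as CSV
#'
#' Long format: one row per sample with epoch index (1-based), sample
#' index within the epoch (0-based) and the 0-based state label.
#'
#' @param labels an [ms_labels()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "ms_labels"))
  rows <- do.call(rbind, lapply(seq_along(labels$epochs), function(i)
    data.frame(epoch = i, sample = seq_along(labels$epochs[[i]]) - 1L,
               label = labels$epochs[[i]])))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
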