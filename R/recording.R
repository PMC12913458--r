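#' EEG recording container
#'
#' A minimal in-memory container for one subject's multichannel EEG:
#' a channels x samples matrix plus sampling rate, channel names and
#' subject/group metadata.
#'
#' @param data numeric matrix, channels x samples.
#' @param fs sampling rate in Hz.
#' @param ch_names character vector of channel names (unique, one per row).
#' @param subject optional subject identifier.
#' @param group optional group label (e.g. `"ASD"` / `"NT"`).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, ch_names = NULL, subject = NULL,
                          group = NULL) {
  data <- as.matrix(data)
  if (is.null(ch_names)) ch_names <- paste0("ch", seq_len(nrow(data)))
  if (length(ch_names) != nrow(data))
    stopf("ch_names length (%d) != number of channels (%d)",
          length(ch_names), nrow(data))
  if (anyDuplicated(ch_names)) stopf("channel names must be unique")
  if (!is.numeric(fs) || fs <= 0) stopf("fs must be a positive number")
  rownames(data) <- ch_names
  structure(list(data = data, fs = fs, ch_names = ch_names,
                 subject = subject, group = group),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  if (!is.null(x$subject)) cat(sprintf("  subject=%s", x$subject))
  if (!is.null(x$group)) cat(sprintf("  group=%s", x$group))
  cat("\n")
  invisible(x)
}

#' Fixed-length epoch stack
#'
#' Holds overlapping fixed-length windows cut from one recording as a
#' 3-D array (epoch x channel x sample) together with the sampling rate
#' and a per-epoch rejection flag.
#'
#' @param epochs 3-D numeric array, epoch x channel x sample.
#' @param fs sampling rate in Hz.
#' @param ch_names channel names.
#' @param rejected logical per-epoch rejection flag (`TRUE` = rejected).
#' @param starts 0-based start sample index of each epoch.
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(epochs, fs, ch_names = NULL, rejected = NULL,
                       starts = NULL) {
  stopifnot(length(dim(epochs)) == 3)
  n <- dim(epochs)[1]
  if (is.null(rejected)) rejected <- rep(FALSE, n)
  if (length(rejected) != n) stopf("rejection mask length mismatch")
  if (is.null(ch_names)) ch_names <- paste0("ch", seq_len(dim(epochs)[2]))
  structure(list(epochs = epochs, fs = fs, ch_names = ch_names,
                 rejected = rejected, starts = starts),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf(
    "<eeg_epochs> %d epochs x %d channels x %d samples @ %g Hz (%d rejected)\n",
    d[1], d[2], d[3], x$fs, sum(x$rejected)))
  invisible(x)
}

#' Per-epoch microstate label sequences
#'
#' Integer state labels (0-based, in `0..K-1`) for every sample of every
#' accepted epoch of one subject.
#'
#' @param epochs list of integer vectors, one per accepted epoch.
#' @param K number of states.
#' @param fs sampling rate in Hz.
#' @return An object of class `ms_labels`.
#' @export
ms_labels <- function(epochs, K, fs) {
  epochs <- lapply(epochs, as.integer)
  bad <- vapply(epochs, function(e) any(e < 0L | e >= K), logical(1))
  if (any(bad)) stopf("labels outside [0, K)")
  structure(list(epochs = epochs, K = as.integer(K), fs = fs),
            class = "ms_labels")
}

#' Flatten per-epoch label sequences into one continuous sequence
#'
#' @param labels an `ms_labels` object (or a bare integer vector, returned
#'   unchanged).
#' @return Integer vector of state labels.
#' @export
flatten_labels <- function(labels) {
  if (inherits(labels, "ms_labels")) labels <- labels$epochs
  if (is.list(labels)) return(as.integer(unlist(labels, use.names = FALSE)))
  as.integer(labels)
}

#' @export
print.ms_labels <- function(x, ...) {
  cat(sprintf("<ms_labels> %d epochs, K=%d, %d samples total @ %g Hz\n",
              length(x$epochs), x$K, length(flatten_labels(x)), x$fs))
  invisible(x)
}
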