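#' @title Preprocessing: filtering, re-referencing, resampling, epoching
#' @description
#' Standard resting-state EEG preprocessing: zero-phase FIR band-pass
#' (1-45 Hz), zero-phase band-stop notch at the line frequency, common
#' average reference, polyphase resampling to 128 Hz, segmentation into 2-s
#' epochs with 50% overlap, automated amplitude/variance epoch rejection,
#' and cross-subject channel standardization to the modal montage.
#' @name preprocess
NULL

# Zero-phase FIR filtering: forward-backward FFT convolution with
# reflection padding to suppress edge transients. b is a linear-phase FIR.
fir_filtfilt <- function(b, x) {
  nb <- length(b)
  pad <- min(length(x) - 1, 3 * nb)
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[length(x)] - x[(length(x) - 1):(length(x) - pad)])
  one_pass <- function(v) {
    y <- signal::fftfilt(b, c(v, numeric(nb)))
    # compensate the linear-phase group delay (nb - 1)/2
    y[seq_along(v) + (nb - 1) / 2]
  }
  y <- one_pass(xp)
  y <- rev(one_pass(rev(y)))
  y[(pad + 1):(pad + length(x))]
}

# Hamming-window FIR design with length chosen from the transition width
# (3.3 / tw cycles, the classic Hamming rule), forced to odd length (type I).
design_fir <- function(fs, edges, type, trans_width) {
  n <- ceiling(3.3 * fs / trans_width)
  if (n %% 2 == 1) n <- n + 1 # fir1 order n -> n + 1 taps, keep taps odd
  signal::fir1(n, edges / (fs / 2), type = type)
}

#' Preprocess one recording
#'
#' Applies, in order: zero-phase FIR band-pass, zero-phase FIR notch
#' (band-stop of width `notch_width` around `notch`), common average
#' reference, and polyphase resampling to `target_fs`.
#'
#' @param rec an [eeg_recording()].
#' @param band band-pass edges in Hz, `c(low, high)`.
#' @param notch line frequency in Hz (`NULL` to skip).
#' @param target_fs output sampling rate in Hz.
#' @param notch_width width of the band-stop in Hz.
#' @param trans_width FIR transition width in Hz (controls filter length).
#' @return A preprocessed [eeg_recording()] at `target_fs`.
#' @export
preprocess_recording <- function(rec, band = c(1, 45), notch = 50,
                                 target_fs = 128, notch_width = 2,
                                 trans_width = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (band[1] >= band[2]) stopf("band low must be < band high")
  if (rec$fs < 2 * band[2])
    stopf("config error: fs (%g) below Nyquist of band high (%g)",
          rec$fs, band[2])
  x <- rec$data
  bp <- design_fir(rec$fs, band, "pass", trans_width)
  x <- t(apply(x, 1, function(ch) fir_filtfilt(bp, ch)))
  if (!is.null(notch) && notch < rec$fs / 2) {
    bs <- design_fir(rec$fs, c(notch - notch_width / 2, notch + notch_width / 2),
                     "stop", trans_width / 2)
    x <- t(apply(x, 1, function(ch) fir_filtfilt(bs, ch)))
  }
  x <- common_average_reference(x)
  if (target_fs != rec$fs) {
    fr <- rational_approx(target_fs / rec$fs)
    x <- t(apply(x, 1, function(ch) signal::resample(ch, fr[1], fr[2])))
  }
  eeg_recording(x, fs = target_fs, ch_names = rec$ch_names,
                subject = rec$subject, group = rec$group)
}

# small rational approximation p/q of a resampling ratio
rational_approx <- function(r, max_q = 1000) {
  best <- c(1, 1); err <- Inf
  for (q in 1:max_q) {
    p <- round(r * q)
    if (p < 1) next
    e <- abs(p / q - r)
    if (e < err - 1e-15) { err <- e; best <- c(p, q) }
    if (err == 0) break
  }
  best
}

#' Common average reference
#'
#' Subtracts the per-sample mean across channels.
#'
#' @param x channels x samples matrix.
#' @return Re-referenced matrix.
#' @export
common_average_reference <- function(x) {
  sweep(x, 2, colMeans(x))
}

#' Cut a recording into fixed-length overlapping epochs
#'
#' Windows are half-open sample ranges `[start, start + len)` with 0-based
#' start indices `0, len * (1 - overlap), ...`; the number of epochs is
#' `floor((n - len) / step) + 1`.
#'
#' @param rec an [eeg_recording()].
#' @param window window length in seconds.
#' @param overlap fractional overlap between consecutive windows.
#' @return An [eeg_epochs()].
#' @export
epoch_recording <- function(rec, window = 2, overlap = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  len <- round(window * rec$fs)
  n <- ncol(rec$data)
  if (n < len) stopf("recording shorter than one window")
  step <- round(len * (1 - overlap))
  if (step < 1) stopf("overlap too large")
  starts <- seq(0L, n - len, by = step)
  ep <- array(0, dim = c(length(starts), nrow(rec$data), len))
  for (i in seq_along(starts))
    ep[i, , ] <- rec$data[, (starts[i] + 1):(starts[i] + len)]
  eeg_epochs(ep, fs = rec$fs, ch_names = rec$ch_names, starts = starts)
}

#' Automated epoch rejection by amplitude and variance thresholds
#'
#' An epoch is rejected if any sample exceeds `amp_limit` in absolute value,
#' or if its largest per-channel variance z-score (z-scored across epochs,
#' per channel, then maximized over channels) exceeds `var_z_limit`. Data
#' are retained; only the rejection mask is updated.
#'
#' @param es an [eeg_epochs()].
#' @param amp_limit absolute amplitude threshold (same units as the data,
#'   conventionally microvolts).
#' @param var_z_limit variance z-score threshold.
#' @return The epoch set with an updated rejection mask.
#' @export
reject_epochs <- function(es, amp_limit = 100, var_z_limit = 3) {
  stopifnot(inherits(es, "eeg_epochs"))
  d <- dim(es$epochs)
  amp_bad <- apply(abs(es$epochs), 1, max) > amp_limit
  v <- apply(es$epochs, c(1, 2), stats::var) # epoch x channel variance
  mu <- colMeans(v)
  sdv <- apply(v, 2, stats::sd)
  sdv[sdv == 0] <- Inf # constant-variance channel can never flag
  z <- sweep(sweep(v, 2, mu), 2, sdv, "/")
  var_bad <- apply(z, 1, max) > var_z_limit
  rejected <- amp_bad | var_bad
  if (all(rejected)) stopf("all %d epochs rejected", d[1])
  es$rejected <- rejected
  es
}

#' Standardize channel layouts across subjects
#'
#' Picks the most frequent channel-name set across subjects as the
#' reference layout (ties broken by the lexicographically smallest sorted
#' name signature; channel order taken from the first subject carrying the
#' modal set), then conforms every recording: missing channels are appended
#' as all-zero flat series, extra channels dropped, and columns reordered
#' so all subjects share name set, order and count.
#'
#' @param recordings list of [eeg_recording()].
#' @return List with `layout` (character vector of channel names) and
#'   `recordings` (conformed list).
#' @export
standardize_channels <- function(recordings) {
  if (length(recordings) == 0) stopf("empty recording list")
  sigs <- vapply(recordings,
                 function(r) paste(sort(r$ch_names), collapse = "\x1f"), "")
  tab <- table(sigs)
  winners <- names(tab)[tab == max(tab)]
  ref_sig <- sort(winners)[1]
  first <- which(sigs == ref_sig)[1]
  layout <- recordings[[first]]$ch_names
  out <- lapply(recordings, function(r) {
    if (identical(r$ch_names, layout)) return(r)
    x <- matrix(0, nrow = length(layout), ncol = ncol(r$data),
                dimnames = list(layout, NULL))
    keep <- intersect(layout, r$ch_names)
    x[keep, ] <- r$data[keep, , drop = FALSE]
    eeg_recording(x, fs = r$fs, ch_names = layout,
                  subject = r$subject, group = r$group)
  })
  names(out) <- names(recordings)
  list(layout = layout, recordings = out)
}
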