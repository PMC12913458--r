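#' @title State-conditioned spectral band power
#' @description
#' For each microstate, samples carrying that state's label are pooled
#' within each epoch; an epoch-state is retained only if the pooled
#' duration reaches 1 s (reliable spectral estimation). Welch's method
#' (128-sample Hann segments, 50% overlap, per-segment demeaning) then
#' estimates the PSD of the pooled series per channel, and band power is
#' the mean PSD over each canonical band's bins, averaged across channels
#' and contributing epochs. Five bands x four states = 20 features.
#' @name features_spectral
NULL

#' Welch power spectral density
#'
#' One-sided PSD estimate by averaging modified periodograms of
#' overlapping, demeaned, Hann-windowed segments (density scaling:
#' integrating the PSD over frequency recovers signal variance).
#'
#' @param x numeric vector, or a samples x channels matrix (column-wise).
#' @param fs sampling rate in Hz.
#' @param nperseg segment length in samples.
#' @param noverlap overlap between segments in samples.
#' @return List with `freq` (Hz) and `psd` (matrix, frequency x channel).
#' @export
welch_psd <- function(x, fs, nperseg = 128, noverlap = nperseg %/% 2) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < nperseg) nperseg <- n # degrade to a single shorter segment
  step <- nperseg - noverlap
  if (step < 1) stopf("noverlap must be < nperseg")
  starts <- seq(1, n - nperseg + 1, by = max(1, step))
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nperseg - 1) / (nperseg - 1)) # Hann
  u <- sum(w^2) * fs
  nf <- nperseg %/% 2 + 1
  acc <- matrix(0, nf, ncol(x))
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1), , drop = FALSE]
    seg <- sweep(seg, 2, colMeans(seg)) * w
    sp <- stats::mvfft(seg)[seq_len(nf), , drop = FALSE]
    acc <- acc + (Mod(sp)^2) / u
  }
  psd <- acc / length(starts)
  if (nperseg %% 2 == 0) psd[2:(nf - 1), ] <- 2 * psd[2:(nf - 1), ]
  else psd[2:nf, ] <- 2 * psd[2:nf, ]
  list(freq = seq(0, by = fs / nperseg, length.out = nf), psd = psd)
}

#' Band powers of one microstate
#'
#' @param es an [eeg_epochs()].
#' @param labels an [ms_labels()] aligned sample-wise to the accepted
#'   epochs of `es`.
#' @param state 0-based state index.
#' @param bands named list of `c(lo, hi)` band edges in Hz; bins are
#'   half-open `[lo, hi)` so shared edges are not double counted.
#' @param min_pooled_sec minimum pooled per-epoch duration (seconds) for an
#'   epoch-state to contribute.
#' @param nperseg Welch segment length.
#' @return Named numeric vector of one mean band power per band
#'   (`NaN` with a warning if no epoch reaches the pooled minimum).
#' @export
state_band_powers <- function(es, labels, state, bands = canonical_bands(),
                              min_pooled_sec = 1, nperseg = 128) {
  stopifnot(inherits(es, "eeg_epochs"), inherits(labels, "ms_labels"))
  keep <- which(!es$rejected)
  if (length(keep) != length(labels$epochs))
    stopf("labels do not align with accepted epochs (%d vs %d)",
          length(labels$epochs), length(keep))
  fs <- es$fs
  min_n <- round(min_pooled_sec * fs)
  per_epoch <- list()
  for (j in seq_along(keep)) {
    sel <- labels$epochs[[j]] == state
    if (sum(sel) < min_n) next
    # dim-safe channels x samples slice, then samples x channels
    pooled <- t(matrix(es$epochs[keep[j], , sel], nrow = dim(es$epochs)[2]))
    wp <- welch_psd(pooled, fs, nperseg = min(nperseg, nrow(pooled)))
    bp <- vapply(bands, function(b) {
      bins <- wp$freq >= b[1] & wp$freq < b[2]
      mean(colMeans(wp$psd[bins, , drop = FALSE])) # band mean, then channels
    }, numeric(1))
    per_epoch[[length(per_epoch) + 1]] <- bp
  }
  if (!length(per_epoch)) {
    warnf("state %d: no epoch reaches %.2g s pooled duration", state,
          min_pooled_sec)
    return(setNames(rep(NaN, length(bands)), names(bands)))
  }
  colMeans(do.call(rbind, per_epoch))
}

#' Subject-level spectral feature vector
#'
#' @param es an [eeg_epochs()].
#' @param labels an [ms_labels()].
#' @param K number of states.
#' @param bands named band list (default: delta, theta, alpha, beta, gamma).
#' @param min_pooled_sec minimum pooled per-epoch state duration in seconds.
#' @return Named numeric vector `<band>_power_state<k>` of length
#'   `length(bands) * K` (20 by default); `NaN` marks state-bands with no
#'   qualifying data.
#' @export
spectral_vector <- function(es, labels, K = 4, bands = canonical_bands(),
                            min_pooled_sec = 1) {
  out <- numeric(0)
  for (k in 0:(K - 1)) {
    bp <- state_band_powers(es, labels, k, bands, min_pooled_sec)
    names(bp) <- sprintf("%s_power_state%d", names(bands), k)
    out <- c(out, bp)
  }
  out
}

#' Canonical spectral feature names
#' @param K number of states.
#' @return Character vector (length 20 for K = 4).
#' @export
spectral_feature_names <- function(K = 4) {
  bands <- names(canonical_bands())
  as.vector(vapply(0:(K - 1),
                   function(k) sprintf("%s_power_state%d", bands, k),
                   character(length(bands))))
}
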