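#' @title Temporal microstate features
#' @description
#' Per-epoch temporal statistics of the microstate label sequence:
#' per-state mean duration, coverage (fractional occupancy), occurrence
#' rate and dwell entropy; the first-order transition probability matrix;
#' switching rate; and recurrence quantification (recurrence rate and
#' determinism) of the symbolic sequence. With K = 4 this yields
#' 16 + 16 + 3 = 35 features per epoch, averaged over accepted epochs to
#' the subject level.
#' @name features_temporal
NULL

#' Per-state duration, coverage, occurrence and dwell entropy
#'
#' For each state k: mean duration of its uninterrupted runs (reported in
#' ms), fraction of samples spent in it, number of runs per second, and the
#' Shannon entropy (natural log) of the distribution of its run durations
#' (each run's duration divided by the state's total duration). States
#' never visited get zeros.
#'
#' @param seq integer 0-based label vector.
#' @param K number of states.
#' @param fs sampling rate in Hz.
#' @return Named numeric vector of 4K values
#'   (`state_k_mean_duration`, `state_k_coverage`, `state_k_occurrence`,
#'   `state_k_dwell_entropy`).
#' @export
per_state_stats <- function(seq, K, fs) {
  seq <- as.integer(seq)
  if (!length(seq)) stopf("empty sequence")
  T <- length(seq)
  rl <- run_lengths(seq)
  ks <- 0:(K - 1)
  dur <- cov <- occ <- ent <- numeric(K)
  for (k in ks) {
    d <- rl$length[rl$state == k]
    if (length(d)) {
      dur[k + 1] <- mean(d) / fs * 1000
      cov[k + 1] <- sum(d) / T
      occ[k + 1] <- length(d) / T * fs
      p <- d / sum(d)
      ent[k + 1] <- -sum(p * log(p))
    }
  }
  c(setNames(dur, sprintf("state_%d_mean_duration", ks)),
    setNames(cov, sprintf("state_%d_coverage", ks)),
    setNames(occ, sprintf("state_%d_occurrence", ks)),
    setNames(ent, sprintf("state_%d_dwell_entropy", ks)))
}

#' First-order transition probability matrix
#'
#' Counts consecutive ordered pairs (self-pairs included) and normalizes
#' each row by its sum; rows of states with no outgoing pair stay all-zero.
#'
#' @param seq integer 0-based label vector (length >= 2).
#' @param K number of states.
#' @return K x K row-stochastic (or all-zero-row) matrix.
#' @export
transition_probabilities <- function(seq, K) {
  seq <- as.integer(seq)
  if (length(seq) < 2) stopf("need at least 2 samples")
  from <- seq[-length(seq)] + 1L
  to <- seq[-1] + 1L
  N <- matrix(0, K, K)
  for (i in seq_along(from)) N[from[i], to[i]] <- N[from[i], to[i]] + 1
  rs <- rowSums(N)
  P <- N
  nz <- rs > 0
  P[nz, ] <- N[nz, , drop = FALSE] / rs[nz]
  P
}

#' Switching rate
#'
#' Fraction of consecutive sample pairs whose labels differ.
#'
#' @param seq integer label vector (length >= 2).
#' @return Value in `[0, 1]`.
#' @export
switching_rate <- function(seq) {
  seq <- as.integer(seq)
  if (length(seq) < 2) stopf("need at least 2 samples")
  mean(seq[-length(seq)] != seq[-1])
}

#' Recurrence rate and determinism of a symbolic sequence
#'
#' The recurrence matrix is `R[t, t'] = 1(s_t == s_t')`. Recurrence rate
#' is the fraction of recurrent (t, t') pairs over all T^2 pairs, main
#' diagonal included. Determinism is the fraction of off-main-diagonal
#' recurrence points lying on diagonal line segments of length >= `l_min`
#' (the standard RQA convention: including the trivial main diagonal would
#' pin determinism near 1).
#'
#' @param seq integer label vector.
#' @param l_min minimum diagonal line length.
#' @return Named vector `c(recurrence_rate, determinism)`.
#' @export
rqa_measures <- function(seq, l_min = 2) {
  seq <- as.integer(seq)
  T <- length(seq)
  if (T < l_min) stopf("sequence shorter than l_min")
  counts <- tabulate(seq + 1L)
  rr <- sum(counts^2) / T^2
  dc <- .rqa_det_counts(seq, l_min)
  det <- if (dc[2] > 0) dc[1] / dc[2] else 0
  c(recurrence_rate = rr, determinism = det)
}

#' Subject-level temporal feature vector
#'
#' Computes all temporal statistics per accepted epoch and averages them,
#' returning the canonical 35-feature temporal block.
#'
#' @param labels an [ms_labels()] or list of integer label vectors.
#' @param K number of states.
#' @param fs sampling rate in Hz (taken from `labels` when available).
#' @param l_min minimum RQA line length.
#' @return Named numeric vector of length `4K + K^2 + 3` (35 for K = 4).
#' @export
temporal_vector <- function(labels, K = 4, fs = NULL, l_min = 2) {
  if (inherits(labels, "ms_labels")) {
    fs <- fs %||% labels$fs
    K <- labels$K
    labels <- labels$epochs
  }
  if (is.null(fs)) stopf("fs required")
  if (!length(labels)) stopf("zero accepted epochs")
  per_epoch <- lapply(labels, function(s) {
    P <- transition_probabilities(s, K)
    tp <- as.vector(t(P)) # row-major: P[0,0], P[0,1], ...
    names(tp) <- sprintf("trans_prob_%d_to_%d",
                         rep(0:(K - 1), each = K), rep(0:(K - 1), K))
    c(per_state_stats(s, K, fs), tp,
      switching_rate = switching_rate(s),
      rqa_measures(s, l_min))
  })
  colMeans(do.call(rbind, per_epoch))
}

#' Canonical temporal feature names
#' @param K number of states.
#' @return Character vector (length 35 for K = 4).
#' @export
temporal_feature_names <- function(K = 4) {
  ks <- 0:(K - 1)
  c(sprintf("state_%d_mean_duration", ks), sprintf("state_%d_coverage", ks),
    sprintf("state_%d_occurrence", ks), sprintf("state_%d_dwell_entropy", ks),
    sprintf("trans_prob_%d_to_%d", rep(ks, each = K), rep(ks, K)),
    "switching_rate", "recurrence_rate", "determinism")
}
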