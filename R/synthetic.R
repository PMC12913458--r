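#' @title Synthetic resting-state EEG with planted microstate structure
#' @description
#' The generator produces cohorts of multichannel recordings built from a
#' small number of quasi-stable topographic states: a semi-Markov state
#' sequence (gamma-distributed dwell times, self-transition-free jumps)
#' drives a rank-1 spatial pattern per state, whose time course is a sum of
#' gain-weighted band-limited oscillations (delta/theta/alpha/beta/gamma)
#' plus 1/f background, on top of white sensor noise. Group differences are
#' planted as configurable offsets in state-band gains, dwell durations and
#' transition structure, giving a known ground truth for every downstream
#' stage of the analysis.
#' @name synthetic
NULL

canonical_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
       beta = c(13, 30), gamma = c(30, 45))
}

# First 54 labels of the Biosemi 64-channel montage (A1-A32, B1-B22),
# so synthetic and real-data paths share a layout convention.
biosemi_names <- function(n = 54) {
  nm <- c(paste0("A", 1:32), paste0("B", 1:32))
  if (n > length(nm)) stopf("at most %d channel names available", length(nm))
  nm[seq_len(n)]
}

#' Generate unit-norm microstate template topographies
#'
#' Draws `K` random topographies over `n_channels` channels, each scaled to
#' unit Euclidean norm, and regenerates until no pair is more than
#' moderately collinear (max pairwise |cosine| <= `max_cos`), so the planted
#' states are spatially distinguishable.
#'
#' @param K number of states (rows).
#' @param n_channels number of channels (columns); must be >= `K`.
#' @param seed RNG seed.
#' @param max_cos maximum allowed pairwise |cosine similarity|.
#' @return A `template_set`: list with `maps` (K x n_channels matrix, rows
#'   unit norm), `K` and `ch_names`.
#' @export
make_templates <- function(K, n_channels, seed = 42, max_cos = 0.6) {
  if (K < 1) stopf("K must be >= 1")
  if (K > n_channels) stopf("invalid config: K (%d) > n_channels (%d)",
                            K, n_channels)
  with_seed(seed, {
    repeat {
      maps <- matrix(rnorm(K * n_channels), nrow = K)
      maps <- maps / sqrt(rowSums(maps^2))
      if (K == 1) break
      cs <- abs(tcrossprod(maps))
      diag(cs) <- 0
      if (max(cs) <= max_cos) break
    }
    template_set(maps, ch_names = biosemi_names(n_channels))
  })
}

#' Simulate a semi-Markov microstate label sequence
#'
#' Dwell lengths are drawn per state from a discretized gamma distribution
#' (`round`, minimum 1 sample); on dwell expiry the next state is drawn from
#' the self-transition-free renormalized row of the transition matrix. A row
#' with zero off-diagonal mass is absorbing: the chain stays in that state
#' for the remainder of the sequence.
#'
#' @param transition K x K row-stochastic matrix (diagonal mass is ignored
#'   for jumps; it only matters for detecting absorbing rows).
#' @param dwell_mean mean dwell per state, in samples (scalar or length K).
#' @param dwell_shape gamma shape per state (scalar or length K); `Inf`
#'   gives deterministic dwells of `round(dwell_mean)`.
#' @param n_samples sequence length.
#' @param seed RNG seed.
#' @param start optional 0-based start state; default drawn uniformly.
#' @return Integer vector of 0-based labels, length `n_samples`.
#' @export
simulate_labels <- function(transition, dwell_mean, dwell_shape = 2,
                            n_samples, seed = 42, start = NULL) {
  transition <- as.matrix(transition)
  K <- nrow(transition)
  if (ncol(transition) != K) stopf("transition matrix must be square")
  if (any(transition < 0)) stopf("transition probabilities must be >= 0")
  if (any(abs(rowSums(transition) - 1) > 1e-8))
    stopf("transition matrix rows must sum to 1")
  if (n_samples < 1) stopf("n_samples must be >= 1")
  dwell_mean <- rep_len(dwell_mean, K)
  dwell_shape <- rep_len(dwell_shape, K)
  if (any(dwell_mean < 1)) stopf("dwell_mean must be >= 1 sample")

  with_seed(seed, {
    s <- if (is.null(start)) sample.int(K, 1) - 1L else as.integer(start)
    if (s < 0 || s >= K) stopf("start state outside [0, K)")
    out <- integer(n_samples)
    t <- 0L
    while (t < n_samples) {
      k <- s + 1L
      d <- if (is.infinite(dwell_shape[k])) round(dwell_mean[k]) else
        round(rgamma(1, shape = dwell_shape[k],
                     scale = dwell_mean[k] / dwell_shape[k]))
      d <- max(1L, as.integer(d))
      take <- min(d, n_samples - t)
      out[(t + 1L):(t + take)] <- s
      t <- t + take
      if (t >= n_samples) break
      row <- transition[k, ]
      row[k] <- 0
      if (sum(row) <= 0) { # absorbing state: stay put for the remainder
        out[(t + 1L):n_samples] <- s
        break
      }
      s <- sample.int(K, 1, prob = row / sum(row)) - 1L
    }
    out
  })
}

# Band-limited unit-variance oscillation: white noise filtered to [lo, hi) Hz.
band_noise <- function(n, band, fs) {
  w <- rnorm(n)
  bf <- signal::butter(4, pmin(band / (fs / 2), 0.999), type = "pass")
  x <- signal::filtfilt(bf, w)
  x / stats::sd(x)
}

# 1/f noise via spectral shaping of white noise (power ~ 1/f), unit variance.
pink_noise <- function(n) {
  w <- rnorm(n)
  f <- fft(w)
  freq <- c(1, seq_len(n - 1)) # avoid dividing DC by zero
  scale <- 1 / sqrt(pmin(freq, n - freq + 1))
  x <- Re(fft(f * scale, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Synthesize a recording from a planted label sequence
#'
#' At each sample `t` the channel vector is `a(t) * template[s_t, ] + noise`,
#' where the state amplitude `a(t)` sums gain-weighted band-limited
#' oscillations over the five canonical bands plus a 1/f component scaled by
#' `pink_frac` times the state's mean gain (so zero gains give zero signal).
#'
#' @param labels integer 0-based label sequence.
#' @param templates a `template_set`.
#' @param band_gains K x 5 nonnegative matrix of state-by-band gains
#'   (columns delta, theta, alpha, beta, gamma).
#' @param noise_sd white sensor-noise SD per channel.
#' @param fs sampling rate in Hz.
#' @param seed RNG seed.
#' @param pink_frac 1/f background amplitude as a fraction of the state's
#'   mean band gain.
#' @param subject,group metadata passed to the recording.
#' @return An [eeg_recording()].
#' @export
synthesize_recording <- function(labels, templates, band_gains, noise_sd,
                                 fs = 128, seed = 42, pink_frac = 0.5,
                                 subject = NULL, group = NULL) {
  labels <- as.integer(labels)
  K <- templates$K
  n <- length(labels)
  band_gains <- as.matrix(band_gains)
  if (nrow(band_gains) != K || ncol(band_gains) != 5)
    stopf("band_gains must be K x 5")
  if (any(band_gains < 0)) stopf("band gains must be >= 0")
  if (any(labels < 0 | labels >= K)) stopf("labels outside [0, K)")
  bands <- canonical_bands()
  with_seed(seed, {
    osc <- vapply(bands, function(b) band_noise(n, b, fs), numeric(n))
    pink <- pink_noise(n)
    # per-state amplitude time course, evaluated at the active state
    amp <- osc %*% t(band_gains) + pink %o% (pink_frac * rowMeans(band_gains))
    a <- amp[cbind(seq_len(n), labels + 1L)]
    x <- t(templates$maps[labels + 1L, , drop = FALSE] * a)
    if (noise_sd > 0)
      x <- x + matrix(rnorm(length(x), sd = noise_sd), nrow = nrow(x))
    eeg_recording(x, fs = fs, ch_names = templates$ch_names,
                  subject = subject, group = group)
  })
}

#' Synthetic cohort configuration
#'
#' Defaults emulate the study conditions the pipeline is designed for:
#' two groups of 28 subjects, 54 channels at 128 Hz, 150 s eyes-closed
#' resting state, K = 4 states with ~100 ms mean dwell. The planted group
#' contrasts are (i) a 2x state-3 delta gain and (ii) 20% shorter dwell
#' times (faster switching) in the `"ASD"` group.
#'
#' @param n_per_group subjects per group.
#' @param n_channels,fs,duration,K recording geometry.
#' @param transition per-group list of K x K row-stochastic matrices.
#' @param dwell_mean per-group list of per-state mean dwells (samples).
#' @param dwell_shape gamma shape of the dwell distribution.
#' @param band_gains per-group list of K x 5 state-by-band gain matrices.
#' @param noise_sd sensor noise SD.
#' @param pink_frac 1/f background fraction.
#' @param seed master RNG seed; all per-subject seeds derive from it.
#' @param groups group labels (first is the reference/control group).
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_per_group = 28, n_channels = 54, fs = 128,
                             duration = 150, K = 4,
                             transition = NULL, dwell_mean = NULL,
                             dwell_shape = 2, band_gains = NULL,
                             noise_sd = 1, pink_frac = 0.5, seed = 42,
                             groups = c("NT", "ASD")) {
  uni <- matrix(1 / (K - 1), K, K); diag(uni) <- 0
  transition <- transition %||% list(uni, uni)
  base_gains <- 10 * matrix(c(
    0.6, 0.5, 1.2, 0.5, 0.25,   # state 0: alpha-dominant
    0.8, 1.0, 0.6, 0.5, 0.25,   # state 1: theta-leaning
    0.7, 0.6, 0.9, 0.8, 0.30,   # state 2: mixed alpha/beta
    0.9, 0.5, 0.7, 0.6, 0.35),  # state 3: delta-leaning
    nrow = 4, byrow = TRUE)
  if (is.null(band_gains)) {
    if (K != 4) stopf("default band_gains require K = 4")
    g2 <- base_gains
    g2[4, 1] <- 2 * g2[4, 1] # planted: 2x delta gain in state 3, group 2
    band_gains <- list(base_gains, g2)
  }
  # planted: 20% shorter dwells (faster switching) in group 2
  dwell_mean <- dwell_mean %||% list(rep(13, K), rep(13 * 0.8, K))
  for (tm in transition)
    if (any(abs(rowSums(tm) - 1) > 1e-9)) stopf("transition rows must sum to 1")
  for (g in band_gains) if (any(g < 0)) stopf("gains must be >= 0")
  if (any(unlist(dwell_mean) < 1)) stopf("dwell_mean must be >= 1 sample")
  structure(list(n_per_group = n_per_group, n_channels = n_channels, fs = fs,
                 duration = duration, K = K, transition = transition,
                 dwell_mean = dwell_mean, dwell_shape = dwell_shape,
                 band_gains = band_gains, noise_sd = noise_sd,
                 pink_frac = pink_frac, seed = seed, groups = groups),
            class = "generator_config")
}

#' Generate a two-group synthetic cohort with known ground truth
#'
#' @param config a [generator_config()].
#' @return List with `recordings` (list of [eeg_recording()]),
#'   `groups` (factor, one per recording) and `ground_truth` (templates,
#'   per-subject planted label sequences, per-subject parameter records).
#' @export
generate_cohort <- function(config = generator_config()) {
  cf <- config
  n_samples <- round(cf$duration * cf$fs)
  templates <- make_templates(cf$K, cf$n_channels, seed = cf$seed)
  recordings <- list(); labels <- list(); params <- list(); groups <- character(0)
  idx <- 0
  for (g in seq_along(cf$groups)) {
    for (i in seq_len(cf$n_per_group)) {
      idx <- idx + 1
      sid <- sprintf("%s_%02d", cf$groups[g], i)
      lab_seed <- derive_seed(cf$seed, g, i, 1)
      rec_seed <- derive_seed(cf$seed, g, i, 2)
      lab <- simulate_labels(cf$transition[[g]], cf$dwell_mean[[g]],
                             cf$dwell_shape, n_samples, seed = lab_seed)
      rec <- synthesize_recording(lab, templates, cf$band_gains[[g]],
                                  cf$noise_sd, fs = cf$fs, seed = rec_seed,
                                  pink_frac = cf$pink_frac,
                                  subject = sid, group = cf$groups[g])
      recordings[[idx]] <- rec
      labels[[idx]] <- lab
      params[[idx]] <- list(subject = sid, group = cf$groups[g],
                            dwell_mean = cf$dwell_mean[[g]],
                            band_gains = cf$band_gains[[g]],
                            transition = cf$transition[[g]])
      groups[idx] <- cf$groups[g]
    }
  }
  names(recordings) <- names(labels) <- vapply(params, `[[`, "", "subject")
  list(recordings = recordings,
       groups = factor(groups, levels = cf$groups),
       ground_truth = list(templates = templates, labels = labels,
                           params = params, config = cf))
}
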