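#' @title Symbolic-sequence complexity metrics
#' @description
#' Nonlinear complexity measures of the flattened microstate label
#' sequence: sample entropy, permutation entropy, detrended fluctuation
#' analysis, Lempel-Ziv (LZ76) complexity and the rescaled-range Hurst
#' exponent, each evaluated at coarse-graining scales 1, 2 and 4 (keep
#' every s-th label) for 5 x 3 = 15 features.
#' @name complexity
NULL

#' Sample entropy
#'
#' `-ln(A/B)` where B counts pairs of length-`m` windows matching under the
#' Chebyshev metric within `r`, and A counts those whose length-`m+1`
#' extensions also match. Self-matches are excluded. Returns `NaN` with a
#' warning when A or B is zero (undefined, not an infinity sentinel).
#'
#' @param x numeric sequence (length > m + 1).
#' @param m embedding dimension.
#' @param r match tolerance; default `0.2 * sd(x)`.
#' @return Entropy in nats.
#' @export
sample_entropy <- function(x, m = 2, r = 0.2 * stats::sd(x)) {
  x <- as.numeric(x)
  if (length(x) <= m + 1) stopf("sequence too short for m = %d", m)
  ab <- sampen_count_pairs(x, m, r)
  if (ab[1] == 0 || ab[2] == 0) {
    warnf("sample entropy undefined (A = %g, B = %g)", ab[1], ab[2])
    return(NaN)
  }
  -log(ab[1] / ab[2])
}

# Template match counts (A at length m+1, B at length m). For
# integer-valued series with r < 1 the Chebyshev tolerance can only be met
# by exact equality, so matches reduce to identical m-grams, counted in
# O(N) by base-coding each window; otherwise the O(N^2) scan runs in C++.
sampen_count_pairs <- function(x, m, r) {
  nt <- length(x) - m
  if (r >= 0 && r < 1 && all(x == round(x)) && diff(range(x)) < 50) {
    sym <- as.integer(x - min(x))
    base <- max(sym) + 1L
    pair_count <- function(len) {
      code <- sym[seq_len(nt)]
      for (j in seq_len(len - 1))
        code <- code * base + sym[seq_len(nt) + j]
      cnt <- table(code)
      sum(cnt * (cnt - 1) / 2)
    }
    c(pair_count(m + 1), pair_count(m))
  } else {
    .sampen_counts(x, as.integer(m), r)
  }
}

# Ordinal pattern id of each embedding window; ties broken by the earlier
# index taking the smaller rank. A permutation is uniquely determined by
# its pairwise order relations, so the code packs the m(m-1)/2 comparisons
# (with the tie rule folded in as <=) into one integer, vectorized over
# windows.
ordinal_patterns <- function(x, m, delay) {
  n <- length(x) - (m - 1) * delay
  idx <- seq_len(n)
  code <- integer(n)
  for (p in seq_len(m - 1)) for (q in (p + 1):m) {
    xp <- x[idx + (p - 1) * delay]
    xq <- x[idx + (q - 1) * delay]
    code <- code * 2L + as.integer(xp <= xq)
  }
  code
}

#' Permutation entropy
#'
#' Shannon entropy (natural log) of the empirical distribution of ordinal
#' patterns of `m` points spaced `delay` apart; ties resolve by the earlier
#' index ranking smaller.
#'
#' @param x numeric sequence.
#' @param m embedding dimension.
#' @param delay embedding delay.
#' @return Entropy in nats.
#' @export
permutation_entropy <- function(x, m = 3, delay = 1) {
  x <- as.numeric(x)
  if (length(x) < m) stopf("sequence shorter than m")
  p <- table(ordinal_patterns(x, m, delay))
  p <- p / sum(p)
  -sum(p * log(p))
}

#' Detrended fluctuation analysis scaling exponent
#'
#' Integrates the demeaned series, removes a least-squares linear trend in
#' non-overlapping windows of each size (log-spaced from 4 to N/4, at least
#' 8 sizes), and fits the slope of log RMS fluctuation against log window
#' size. An exponent of 0.5 indicates uncorrelated noise, larger values
#' long-range correlation.
#'
#' @param x numeric sequence (length >= 64).
#' @param n_sizes number of window sizes.
#' @return Scaling exponent (slope).
#' @export
dfa_exponent <- function(x, n_sizes = 12) {
  x <- as.numeric(x)
  N <- length(x)
  if (N < 64) stopf("DFA needs at least 64 samples")
  y <- cumsum(x - mean(x))
  sizes <- unique(round(exp(seq(log(4), log(N / 4), length.out = n_sizes))))
  Fn <- vapply(sizes, function(n) {
    nseg <- N %/% n
    idx <- seq_len(nseg * n)
    seg <- matrix(y[idx], nrow = n)
    t_ <- seq_len(n)
    # per-segment linear detrend via closed-form least squares
    tb <- t_ - mean(t_)
    beta <- colSums(seg * tb) / sum(tb^2)
    alpha <- colMeans(seg)
    res <- seg - outer(tb, beta) - rep(alpha, each = n)
    sqrt(mean(res^2))
  }, numeric(1))
  ok <- Fn > 0
  if (sum(ok) < 2) {
    warnf("DFA undefined: fewer than two nonzero fluctuation sizes")
    return(NaN)
  }
  unname(coef(lm(log(Fn[ok]) ~ log(sizes[ok])))[2])
}

#' Lempel-Ziv (LZ76) complexity, normalized
#'
#' Counts the phrases of the exhaustive-history LZ76 parse of the symbol
#' sequence over its native alphabet and normalizes by `n / log2(n)`.
#'
#' @param s symbol sequence (any atomic vector; coded by value).
#' @return Normalized complexity `c(S) * log2(n) / n`.
#' @export
lz_complexity <- function(s) {
  if (!length(s)) stopf("empty sequence")
  code <- as.integer(factor(s))
  c_s <- .lz76_count(code)
  n <- length(s)
  c_s * log2(n) / n
}

#' Hurst exponent by rescaled-range analysis
#'
#' For window sizes log-spaced from 8 to N/2 the series is split into
#' non-overlapping windows; each window's range of cumulative deviations
#' from its mean is divided by its standard deviation, and the Hurst
#' exponent is the slope of log mean(R/S) against log window size.
#'
#' @param x numeric sequence.
#' @param n_sizes number of window sizes.
#' @return Hurst exponent, or `NaN` with a warning for constant input.
#' @export
hurst_exponent <- function(x, n_sizes = 10) {
  x <- as.numeric(x)
  N <- length(x)
  if (N < 32) stopf("R/S analysis needs at least 32 samples")
  if (stats::sd(x) == 0) {
    warnf("Hurst exponent undefined for constant input")
    return(NaN)
  }
  sizes <- unique(round(exp(seq(log(8), log(N / 2), length.out = n_sizes))))
  rs <- vapply(sizes, function(n) {
    nseg <- N %/% n
    vals <- vapply(seq_len(nseg), function(j) {
      w <- x[((j - 1) * n + 1):(j * n)]
      s <- stats::sd(w)
      if (s == 0) return(NA_real_)
      y <- cumsum(w - mean(w))
      (max(y) - min(y)) / s
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  ok <- is.finite(rs) & rs > 0
  if (sum(ok) < 2) {
    warnf("too few valid R/S window sizes")
    return(NaN)
  }
  unname(coef(lm(log(rs[ok]) ~ log(sizes[ok])))[2])
}

#' Multiscale complexity feature vector
#'
#' Flattens per-epoch label sequences into one continuous sequence and
#' evaluates the five complexity metrics at coarse-graining scales 1, 2
#' and 4 (scale s keeps every s-th label).
#'
#' @param labels an [ms_labels()], list of label vectors, or one vector.
#' @param scales coarse-graining scales.
#' @return Named numeric vector (`sampen_s1`, ..., `hurst_s4`; 15 values
#'   for the default scales). Cells may be `NaN` where a metric is
#'   undefined.
#' @export
complexity_vector <- function(labels, scales = c(1, 2, 4)) {
  s <- flatten_labels(labels)
  out <- numeric(0)
  for (sc in scales) {
    xs <- s[seq(1, length(s), by = sc)]
    xn <- as.numeric(xs)
    vals <- c(
      sampen = suppressWarnings(sample_entropy(xn)),
      permen = suppressWarnings(permutation_entropy(xn)),
      dfa = suppressWarnings(dfa_exponent(xn)),
      lzc = lz_complexity(xs),
      hurst = suppressWarnings(hurst_exponent(xn)))
    names(vals) <- sprintf("%s_s%d", c("sampen", "permen", "dfa", "lzc",
                                       "hurst"), sc)
    out <- c(out, vals)
  }
  out
}

#' Canonical complexity feature names
#' @param scales coarse-graining scales.
#' @return Character vector (length 15 for the default scales).
#' @export
complexity_feature_names <- function(scales = c(1, 2, 4)) {
  as.vector(vapply(scales, function(sc)
    sprintf("%s_s%d", c("sampen", "permen", "dfa", "lzc", "hurst"), sc),
    character(5)))
}
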