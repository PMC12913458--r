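#' @title Higher-order microstate sequence features
#' @description
#' Sequence-level descriptors beyond first-order temporal statistics:
#' transition entropy, mean inter-transition interval, 3-gram entropy on
#' remapped labels, an approximate phase-locking value of the symbolic
#' series, fractional-occupancy first differences, and graph-theoretical
#' properties of the transition network — the canonical 10-feature block.
#' @name higher_order
NULL

#' Transition entropy
#'
#' Sum over states of the Shannon entropy (natural log) of each row of the
#' empirical first-order transition matrix, with `0 * log(0) := 0`.
#'
#' @param seq integer label vector (length >= 2).
#' @param K number of states.
#' @return Entropy in nats.
#' @export
transition_entropy <- function(seq, K) {
  P <- transition_probabilities(seq, K)
  nz <- P > 0
  -sum(P[nz] * log(P[nz]))
}

#' Mean inter-transition interval
#'
#' Transitions are the sample indices t with `s_t != s_{t-1}`; the feature
#' is the mean difference between consecutive transition times, in samples.
#'
#' @param seq integer label vector.
#' @return Mean interval in samples, or `NaN` with a warning when fewer
#'   than two transitions occur.
#' @export
mean_iti <- function(seq) {
  seq <- as.integer(seq)
  tr <- which(diff(seq) != 0) # 0-based index of each new-state sample
  if (length(tr) < 2) {
    warnf("fewer than 2 transitions; mean ITI undefined")
    return(NaN)
  }
  mean(diff(tr))
}

#' n-gram entropy of the label sequence
#'
#' Observed labels are first remapped to contiguous integers starting at 0
#' (sorted ascending), then all length-`n` subsequences are counted and
#' their Shannon entropy (natural log) returned.
#'
#' @param seq integer label vector (length >= n).
#' @param n subsequence length.
#' @return Entropy in nats.
#' @export
ngram_entropy <- function(seq, n = 3) {
  seq <- as.integer(seq)
  if (length(seq) < n) stopf("sequence shorter than n = %d", n)
  seq <- match(seq, sort(unique(seq))) - 1L # contiguous remap
  m <- length(seq) - n + 1
  grams <- vapply(seq_len(m), function(i)
    paste(seq[i:(i + n - 1)], collapse = ","), character(1))
  p <- table(grams) / m
  -sum(p * log(p))
}

# analytic signal by the frequency-domain Hilbert transform
analytic_signal <- function(x) {
  n <- length(x)
  f <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(f * h, inverse = TRUE) / n
}

#' Approximate phase-locking value of the label series
#'
#' Demeans the numeric label series, takes the instantaneous phase of its
#' analytic signal (Hilbert transform) and returns the modulus of the mean
#' unit phasor. A constant sequence gives 1 (zero analytic signal has
#' phase 0 everywhere by convention).
#'
#' @param seq integer label vector.
#' @return Value in `[0, 1]`.
#' @export
plv_sync <- function(seq) {
  x <- as.numeric(seq) - mean(seq)
  phi <- Arg(analytic_signal(x))
  Mod(mean(exp(1i * phi)))
}

#' Fractional occupancy first differences
#'
#' Fractional occupancy `FO_k` is the fraction of samples in state k; the
#' features are the K - 1 first differences `FO_k - FO_{k-1}`.
#'
#' @param seq integer label vector.
#' @param K number of states.
#' @return Named vector `dfo_state_1 .. dfo_state_{K-1}`.
#' @export
fo_derivatives <- function(seq, K) {
  fo <- tabulate(as.integer(seq) + 1L, K) / length(seq)
  setNames(diff(fo), sprintf("dfo_state_%d", seq_len(K - 1)))
}

#' Transition-network graph features
#'
#' Builds the directed graph on K state nodes with an edge i -> j (i != j)
#' for every observed transition; reports its density `|E| / (K (K - 1))`,
#' plus average degree and mean local clustering coefficient of the simple
#' undirected projection (isolated or degree-1 nodes contribute 0 to
#' clustering).
#'
#' @param seq integer label vector (length >= 2).
#' @param K number of states.
#' @return Named vector `c(graph_density, graph_avg_degree,
#'   graph_clustering)`.
#' @export
graph_features <- function(seq, K) {
  seq <- as.integer(seq)
  if (length(seq) < 2) stopf("need at least 2 samples")
  from <- seq[-length(seq)]
  to <- seq[-1]
  keep <- from != to
  edges <- unique(cbind(from[keep], to[keep]))
  density <- nrow(edges) / (K * (K - 1))
  g <- igraph::make_empty_graph(n = K, directed = TRUE)
  if (nrow(edges))
    g <- igraph::add_edges(g, as.vector(t(edges + 1L)))
  gu <- igraph::as_undirected(igraph::simplify(g), mode = "collapse")
  avg_degree <- mean(igraph::degree(gu))
  cc <- igraph::transitivity(gu, type = "local", isolates = "zero")
  c(graph_density = density, graph_avg_degree = avg_degree,
    graph_clustering = mean(cc))
}

#' Subject-level higher-order feature vector
#'
#' The canonical 10 features on the flattened label sequence. The mock
#' cross-frequency-coupling scalars (one seeded uniform draw per state) are
#' excluded by default and appended only when `include_cfc = TRUE`.
#'
#' @param labels an [ms_labels()], list of label vectors, or one vector.
#' @param K number of states.
#' @param n n-gram length.
#' @param include_cfc append mock `cfc_state_k` features.
#' @param cfc_seed seed for the mock CFC draws.
#' @return Named numeric vector (10 canonical values).
#' @export
higher_order_vector <- function(labels, K = 4, n = 3, include_cfc = FALSE,
                                cfc_seed = 42) {
  if (inherits(labels, "ms_labels")) K <- labels$K
  s <- flatten_labels(labels)
  out <- c(transition_entropy = transition_entropy(s, K),
           mean_inter_transition_interval = suppressWarnings(mean_iti(s)),
           ngram_entropy = ngram_entropy(s, n),
           plv_sync = plv_sync(s),
           fo_derivatives(s, K),
           graph_features(s, K))
  if (include_cfc) {
    cfc <- with_seed(cfc_seed, runif(K))
    out <- c(out, setNames(cfc, sprintf("cfc_state_%d", 0:(K - 1))))
  }
  out
}

#' Canonical higher-order feature names
#' @param K number of states.
#' @return Character vector (length 10 for K = 4).
#' @export
higher_order_feature_names <- function(K = 4) {
  c("transition_entropy", "mean_inter_transition_interval", "ngram_entropy",
    "plv_sync", sprintf("dfo_state_%d", seq_len(K - 1)),
    "graph_density", "graph_avg_degree", "graph_clustering")
}
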