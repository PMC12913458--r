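#' @title Microstate segmentation: GFP peaks, K-means templates, back-fitting
#' @description
#' Global field power (GFP) is the per-timepoint spatial standard deviation
#' of the multichannel signal; its local maxima mark moments of strong,
#' stable topography. Topographies at GFP peaks are pooled across epochs
#' and subjects, normalized to unit norm, and clustered with K-means
#' (k-means++ seeding, multiple restarts) into K = 4 canonical microstate
#' templates. Back-fitting then labels every sample with the template of
#' highest spatial similarity (dot product of unit-norm vectors).
#' @name microstates
NULL

#' Microstate template container
#'
#' @param maps K x C numeric matrix; rows are normalized to unit Euclidean
#'   norm on construction.
#' @param ch_names channel names (length C).
#' @param sizes optional per-template cluster sizes.
#' @return A `template_set`.
#' @export
template_set <- function(maps, ch_names = NULL, sizes = NULL) {
  maps <- as.matrix(maps)
  nrm <- sqrt(rowSums(maps^2))
  if (any(nrm == 0)) stopf("zero-norm template row")
  maps <- maps / nrm
  if (is.null(ch_names)) ch_names <- paste0("ch", seq_len(ncol(maps)))
  structure(list(maps = maps, K = nrow(maps), ch_names = ch_names,
                 sizes = sizes),
            class = "template_set")
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("<template_set> K=%d states x %d channels\n", x$K,
              ncol(x$maps)))
  invisible(x)
}

#' Global field power curve
#'
#' GFP(t) is the population standard deviation of the channel values at
#' each time point: `sqrt(mean((V_i(t) - mean(V(t)))^2))` (divide by N,
#' not N - 1).
#'
#' @param epoch channels x samples numeric matrix (>= 2 channels).
#' @return Nonnegative numeric vector, one value per sample.
#' @export
gfp_curve <- function(epoch) {
  epoch <- as.matrix(epoch)
  n <- nrow(epoch)
  if (n < 2) stopf("GFP needs at least 2 channels")
  mu <- colMeans(epoch)
  sqrt(colMeans(sweep(epoch, 2, mu)^2))
}

# Local maxima of a curve: strictly greater than both neighbours, plateaus
# keep their leftmost sample; peaks closer than min_distance are resolved
# by keeping the higher one (greedy, height-sorted).
find_peaks <- function(g, min_distance = 2) {
  r <- rle(g)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  nr <- length(r$values)
  is_pk <- logical(nr)
  for (i in seq_len(nr)) {
    left_ok <- i > 1 && r$values[i] > r$values[i - 1]
    right_ok <- i < nr && r$values[i] > r$values[i + 1]
    is_pk[i] <- left_ok && right_ok
  }
  idx <- starts[is_pk]
  if (length(idx) == 0 || min_distance <= 1) return(idx)
  ord <- idx[order(-g[idx], idx)]
  kept <- integer(0)
  for (p in ord)
    if (!length(kept) || min(abs(kept - p)) >= min_distance)
      kept <- c(kept, p)
  sort(kept)
}

#' Extract unit-norm topographies at GFP peaks
#'
#' Computes the GFP curve of every accepted epoch, locates its local
#' maxima (at least `min_peak_distance` samples apart; on conflict the
#' higher peak wins), and returns the channel vectors at those samples,
#' each divided by its Euclidean norm.
#'
#' @param es an [eeg_epochs()].
#' @param min_peak_distance minimum distance between retained peaks, in
#'   samples.
#' @return Matrix of peak maps (rows = maps, columns = channels); zero rows
#'   if no peaks were found (with a warning).
#' @export
extract_peak_maps <- function(es, min_peak_distance = 2) {
  stopifnot(inherits(es, "eeg_epochs"))
  keep <- which(!es$rejected)
  maps <- list()
  for (i in keep) {
    ep <- es$epochs[i, , , drop = TRUE]
    g <- gfp_curve(ep)
    pk <- find_peaks(g, min_peak_distance)
    if (length(pk)) maps[[length(maps) + 1]] <- t(ep[, pk, drop = FALSE])
  }
  if (!length(maps)) {
    warnf("no GFP peaks found in any epoch")
    return(matrix(0, 0, dim(es$epochs)[2]))
  }
  m <- do.call(rbind, maps)
  nrm <- sqrt(rowSums(m^2))
  ok <- nrm > 0
  if (!all(ok)) m <- m[ok, , drop = FALSE]
  m / sqrt(rowSums(m^2))
}

# k-means++ seeding (Arthur & Vassilvitskii): first centre uniform, then
# each next centre with probability proportional to squared distance to the
# nearest chosen centre.
kmeanspp_init <- function(x, K) {
  n <- nrow(x)
  centers <- matrix(0, K, ncol(x))
  i <- sample.int(n, 1)
  centers[1, ] <- x[i, ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (k in seq_len(K - 1) + 1) {
    if (sum(d2) <= 0) i <- sample.int(n, 1)
    else i <- sample.int(n, 1, prob = d2)
    centers[k, ] <- x[i, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[k, ])^2))
  }
  centers
}

#' Learn microstate templates by K-means clustering of peak maps
#'
#' Runs K-means with k-means++ initialization and `nstart` seeded restarts,
#' keeping the solution with the lowest within-cluster sum of squares.
#' Centroids are renormalized to unit norm and ordered by descending
#' cluster size (ties by first occurrence).
#'
#' With `ignore_polarity = TRUE` the classical polarity-invariant variant
#' is used instead: maps are assigned to the template of highest absolute
#' cosine similarity and each centroid is updated as the first principal
#' component of its assigned maps, so topographies of opposite polarity
#' count as the same state (the standard convention for microstate
#' clustering of oscillatory data).
#'
#' @param maps matrix of unit-norm topographies (rows = maps).
#' @param K number of templates.
#' @param seed RNG seed.
#' @param nstart number of seeded restarts.
#' @param ignore_polarity fold map polarity before clustering.
#' @return A [template_set()] with per-template cluster sizes.
#' @export
learn_templates <- function(maps, K = 4, seed = 42, nstart = 10,
                            ignore_polarity = FALSE) {
  maps <- as.matrix(maps)
  if (nrow(maps) < K) stopf("need at least K = %d maps, got %d", K, nrow(maps))
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(nstart)) {
      km <- if (ignore_polarity) polarity_kmeans(maps, K)
        else {
          fit <- suppressWarnings(
            stats::kmeans(maps, centers = kmeanspp_init(maps, K),
                          iter.max = 100, algorithm = "Lloyd"))
          list(centers = fit$centers, cluster = fit$cluster,
               objective = fit$tot.withinss)
        }
      if (is.null(best) || km$objective < best$objective) best <- km
    }
    sizes <- tabulate(best$cluster, K)
    first_seen <- vapply(seq_len(K), function(k) {
      w <- which(best$cluster == k)
      if (length(w)) w[1] else Inf
    }, numeric(1))
    ord <- order(-sizes, first_seen)
    template_set(best$centers[ord, , drop = FALSE], sizes = sizes[ord])
  })
}

# polarity-invariant K-means on unit-norm maps: assignment by maximum
# |cosine|, centroid update toward the first principal component of the
# assigned maps (power iterations interleaved with the assignment loop, a
# final eigendecomposition at convergence); objective = sum of (1 - cos^2)
polarity_kmeans <- function(maps, K, iter_max = 100) {
  centers <- kmeanspp_init(maps, K)
  centers <- centers / sqrt(rowSums(centers^2))
  assign_prev <- rep(0L, nrow(maps))
  for (it in seq_len(iter_max)) {
    sim <- maps %*% t(centers)
    cl <- max.col(abs(sim), ties.method = "first")
    if (all(cl == assign_prev)) break
    assign_prev <- cl
    for (k in seq_len(K)) {
      rows <- cl == k
      if (!any(rows)) next # empty cluster keeps its centre
      mk <- maps[rows, , drop = FALSE]
      v <- centers[k, ]
      for (p in 1:3) { # power iterations toward the top eigenvector
        v <- crossprod(mk, mk %*% v)[, 1]
        v <- v / sqrt(sum(v^2))
      }
      centers[k, ] <- v
    }
  }
  # polish the converged centroids with the exact principal component
  for (k in seq_len(K)) {
    mk <- maps[assign_prev == k, , drop = FALSE]
    if (nrow(mk))
      centers[k, ] <- eigen(crossprod(mk), symmetric = TRUE)$vectors[, 1]
  }
  sim <- maps %*% t(centers)
  cl <- max.col(abs(sim), ties.method = "first")
  obj <- sum(1 - sim[cbind(seq_len(nrow(maps)), cl)]^2)
  list(centers = centers, cluster = cl, objective = obj)
}

#' Back-fit microstate labels to every sample
#'
#' Each sample's channel vector is normalized to unit norm and compared to
#' every template by dot product; the sample takes the label of the
#' best-matching template (highest signed dot product, or highest absolute
#' dot product with `ignore_polarity = TRUE`). Ties resolve to the lowest
#' state index; zero-norm samples carry the previous label forward (state 0
#' if the first sample has zero norm).
#'
#' @param es an [eeg_epochs()] (or a single channels x samples matrix).
#' @param templates a [template_set()].
#' @param ignore_polarity compare by absolute dot product.
#' @return An [ms_labels()] (or an integer vector for matrix input).
#' @export
assign_labels <- function(es, templates, ignore_polarity = FALSE) {
  if (is.matrix(es)) {
    return(backfit_matrix(es, templates, ignore_polarity))
  }
  stopifnot(inherits(es, "eeg_epochs"))
  if (dim(es$epochs)[2] != ncol(templates$maps))
    stopf("channel count mismatch: epochs have %d, templates %d",
          dim(es$epochs)[2], ncol(templates$maps))
  keep <- which(!es$rejected)
  seqs <- lapply(keep, function(i)
    backfit_matrix(es$epochs[i, , , drop = TRUE], templates, ignore_polarity))
  ms_labels(seqs, K = templates$K, fs = es$fs)
}

backfit_matrix <- function(x, templates, ignore_polarity) {
  if (nrow(x) != ncol(templates$maps)) stopf("channel count mismatch")
  nrm <- sqrt(colSums(x^2))
  ok <- nrm > 0
  xs <- sweep(x, 2, pmax(nrm, .Machine$double.eps), "/")
  d <- templates$maps %*% xs # K x T dot products
  if (ignore_polarity) d <- abs(d)
  lab <- max.col(t(d), ties.method = "first") - 1L
  if (!all(ok)) { # carry previous label through zero-norm samples
    prev <- 0L
    for (t in seq_along(lab)) {
      if (!ok[t]) lab[t] <- prev else prev <- lab[t]
    }
  }
  lab
}
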