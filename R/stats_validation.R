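#' @title Nonparametric feature screening
#' @description
#' Between-group screening of each feature with the Mann-Whitney U test
#' (mid-ranks for ties; exact null distribution when feasible, otherwise a
#' tie-corrected normal approximation) alongside two effect sizes: Cohen's
#' d (signed standardized mean difference, pooled variance) and Cliff's
#' delta (dominance probability difference). The sign convention is
#' group x minus group y throughout (positive = higher in x).
#' @name stats_validation
NULL

#' Mann-Whitney U test
#'
#' Computes `U = min(U1, U2)` from rank sums with mid-ranks for ties. The
#' two-sided p-value uses the exact null distribution (no ties and
#' `n1 * n2 <= exact_limit`) or a tie-corrected normal approximation with
#' continuity correction. Identical samples give `U = n1 n2 / 2`, `p = 1`.
#'
#' @param x,y numeric samples (non-empty).
#' @param exact_limit largest `n1 * n2` for the exact path.
#' @return List with `u`, `p`, and the `method` used.
#' @export
mann_whitney_u <- function(x, y, exact_limit = 400) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stopf("both samples must be non-empty")
  r <- rank(c(x, y)) # mid-ranks
  R1 <- sum(r[seq_len(n1)])
  U1 <- n1 * n2 + n1 * (n1 + 1) / 2 - R1
  U2 <- n1 * n2 - U1
  U <- min(U1, U2)
  ties <- table(r)
  has_ties <- any(ties > 1)
  if (!has_ties && n1 * n2 <= exact_limit) {
    # exact null CDF of the Mann-Whitney statistic
    p <- min(1, 2 * stats::pwilcox(U, n1, n2))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tie_term <- sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1))
    sigma2 <- n1 * n2 / 12 * ((n1 + n2 + 1) - tie_term)
    if (sigma2 <= 0) return(list(u = U, p = 1, method = "degenerate"))
    z <- (U - mu + 0.5) / sqrt(sigma2) # U <= mu by construction
    p <- min(1, 2 * stats::pnorm(z))
    method <- "normal"
  }
  list(u = U, p = p, method = method)
}

#' Cohen's d (pooled standard deviation)
#'
#' `(mean(x) - mean(y)) / s_pooled` with the pooled variance
#' `((n1-1) s_x^2 + (n2-1) s_y^2) / (n1 + n2 - 2)`. Positive values mean
#' higher values in `x`.
#'
#' @param x,y numeric samples.
#' @return Signed effect size; `NaN` with a warning when the pooled SD is
#'   zero.
#' @export
cohens_d <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (is.na(sp2) || sp2 == 0) {
    warnf("pooled SD is zero; Cohen's d undefined")
    return(NaN)
  }
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Cliff's delta
#'
#' `(#(x > y) - #(x < y)) / (n1 n2)` over all pairs; ties count neither
#' way. Ranges from -1 (complete dominance of y) to +1 (of x).
#'
#' @param x,y numeric samples (non-empty).
#' @return Effect size in `[-1, 1]`.
#' @export
cliffs_delta <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (!length(x) || !length(y)) stopf("both samples must be non-empty")
  d <- outer(x, y, `-`)
  (sum(d > 0) - sum(d < 0)) / (length(x) * length(y))
}

#' Screen every feature between two groups
#'
#' Runs the U test, Cohen's d and Cliff's delta per feature column.
#' Non-finite values are dropped pairwise per feature (dropped counts are
#' reported); the sign convention is `positive` group minus the other.
#'
#' @param table data.frame of features (numeric columns) or matrix.
#' @param groups factor/character group label per row (exactly 2 levels).
#' @param positive the group treated as `x` in the sign convention;
#'   defaults to the second factor level (e.g. the case group).
#' @param features columns to screen; default all numeric columns.
#' @param adjust p-value adjustment method (`"none"` keeps raw p-values;
#'   `"BH"` adds a `p_adj` column).
#' @return data.frame with one row per feature: `feature`, `n_x`, `n_y`,
#'   `n_dropped`, `median_x`, `median_y`, `u`, `p_value`, `cohens_d`,
#'   `cliffs_delta` (and `p_adj` if adjusted), sortable by any column.
#' @export
feature_screen <- function(table, groups, positive = NULL, features = NULL,
                           adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  table <- as.data.frame(table)
  groups <- factor(groups)
  if (nlevels(groups) != 2) stopf("exactly two groups required")
  if (any(tabulate(groups) < 2)) stopf("each group needs >= 2 observations")
  positive <- positive %||% levels(groups)[2]
  if (!positive %in% levels(groups)) stopf("unknown positive group")
  other <- setdiff(levels(groups), positive)
  if (is.null(features))
    features <- names(table)[vapply(table, is.numeric, logical(1))]
  rows <- lapply(features, function(f) {
    v <- table[[f]]
    x <- v[groups == positive]; y <- v[groups == other]
    drop <- sum(!is.finite(x)) + sum(!is.finite(y))
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 2 || length(y) < 2) {
      warnf("feature %s: fewer than 2 finite values in a group; skipped", f)
      return(data.frame(feature = f, n_x = length(x), n_y = length(y),
                        n_dropped = drop, median_x = NA_real_,
                        median_y = NA_real_, u = NA_real_,
                        p_value = NA_real_, cohens_d = NA_real_,
                        cliffs_delta = NA_real_))
    }
    mw <- mann_whitney_u(x, y)
    data.frame(feature = f, n_x = length(x), n_y = length(y),
               n_dropped = drop, median_x = median(x), median_y = median(y),
               u = mw$u, p_value = mw$p,
               cohens_d = suppressWarnings(cohens_d(x, y)),
               cliffs_delta = cliffs_delta(x, y))
  })
  out <- do.call(rbind, rows)
  if (adjust == "BH") out$p_adj <- stats::p.adjust(out$p_value, "BH")
  attr(out, "positive") <- positive
  out
}

#' Effect-size magnitude annotations
#'
#' Conventional interpretive cutoffs: Cohen's d 0.2 / 0.5 / 0.8 and
#' Cliff's delta 0.147 / 0.33 / 0.474 for small / medium / large.
#'
#' @param value effect size value(s).
#' @param type `"d"` or `"delta"`.
#' @return Character vector of magnitude labels.
#' @export
effect_magnitude <- function(value, type = c("d", "delta")) {
  type <- match.arg(type)
  cuts <- if (type == "d") c(0.2, 0.5, 0.8) else c(0.147, 0.33, 0.474)
  labs <- c("negligible", "small", "medium", "large")
  labs[findInterval(abs(value), cuts) + 1]
}
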