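#' Association measure configuration
#'
#' Settings for the B-spline mutual-information association measure: the number
#' of bins per dimension and the spline order. Six bins with a third-order
#' (quadratic) B-spline is the standard configuration of the fuzzy-binning
#' estimator; each observation then contributes probability mass to up to three
#' adjacent bins, which smooths the histogram and stabilises the estimate at
#' the cohort sizes typical of tumor expression studies.
#'
#' Knots are placed uniformly over each vector's own observed range, so the
#' measure is invariant to affine rescaling of either input.
#'
#' @param n_bins Number of B-spline basis functions (bins) per dimension.
#' @param spline_order B-spline order (1 = hard binning, 3 = quadratic).
#' @return An object of class `assoc_config`.
#' @examples
#' cfg <- assoc_config()
#' spline_mi(rnorm(100), rnorm(100), cfg)
#' @export
assoc_config <- function(n_bins = 6L, spline_order = 3L) {
  n_bins <- as.integer(n_bins)
  spline_order <- as.integer(spline_order)
  if (is.na(n_bins) || n_bins < 2L) stop("n_bins must be an integer >= 2")
  if (is.na(spline_order) || spline_order < 1L) stop("spline_order must be an integer >= 1")
  if (spline_order > n_bins) stop("spline_order must not exceed n_bins")
  structure(list(n_bins = n_bins, spline_order = spline_order), class = "assoc_config")
}

# B-spline membership weights: n x n_bins matrix whose rows sum to 1.
# Returns NULL for a constant vector (no range to bin over).
.mi_basis <- function(x, cfg) {
  r <- range(x)
  if (r[1L] == r[2L]) return(NULL)
  m <- cfg$n_bins
  k <- cfg$spline_order
  top <- m - k + 1L
  z <- (x - r[1L]) / (r[2L] - r[1L]) * top
  knots <- c(rep(0, k), seq_len(m - k), rep(top, k))
  splines::splineDesign(knots, z, ord = k)
}

# Entropy of a probability table in nats. Summands are sorted before adding so
# the result does not depend on element traversal order (this makes
# spline_mi(a, b) == spline_mi(b, a) bit-exact).
.entropy <- function(p) {
  v <- p[p > 0]
  if (!length(v)) return(0)
  -sum(sort(v * log(v)))
}

# Engine-internal entropy without the sorted summation (the engine never
# needs the transpose-exact symmetry the public API guarantees).
.entropy_raw <- function(p) {
  v <- p[p > 0]
  if (!length(v)) return(0)
  -sum(v * log(v))
}

.check_mi_input <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (length(a) < 8L) stop("need at least 8 paired observations")
  if (!all(is.finite(a)) || !all(is.finite(b))) stop("inputs must be finite")
}

#' Spline-based mutual information
#'
#' Estimates the mutual information I(A;B), in nats, between two paired sample
#' vectors with the fuzzy-binning B-spline estimator: each observation is
#' spread over adjacent bins with B-spline membership weights, marginal and
#' joint probability tables are accumulated, and I = H(A) + H(B) - H(A,B).
#' Because the joint table has exactly the marginals of the two one-dimensional
#' tables, the estimate is non-negative up to floating-point error.
#'
#' The absolute value is resolution-limited by the bin count: it estimates the
#' information retained after fuzzy discretisation, not the full differential
#' mutual information (which it approaches as `n_bins` grows). Downstream code
#' therefore works with the normalized measure ([normalized_association()]),
#' whose scale is estimator-independent.
#'
#' @param a,b Numeric vectors of equal length (>= 8), finite values.
#' @param cfg An [assoc_config()].
#' @return Estimated mutual information in nats. A constant input yields 0.
#' @export
spline_mi <- function(a, b, cfg = assoc_config()) {
  .check_mi_input(a, b)
  ba <- .mi_basis(a, cfg)
  bb <- .mi_basis(b, cfg)
  if (is.null(ba) || is.null(bb)) return(0)
  n <- length(a)
  ha <- .entropy(colSums(ba) / n)
  hb <- .entropy(colSums(bb) / n)
  hab <- .entropy(crossprod(ba, bb) / n)
  ha + hb - hab
}

#' Signed, normalized mutual-information association
#'
#' The spline MI of the pair divided by the larger of the two self-informations
#' I(A;A), I(B;B), giving a score with maximum 1 for identical (non-constant)
#' vectors and about 0 for independent ones; the score is multiplied by -1 when
#' the Pearson correlation of the pair is strictly negative, so the final value
#' lies in [-1, 1]. A constant vector carries no information and gets
#' association 0.
#'
#' @inheritParams spline_mi
#' @return A number in [-1, 1].
#' @examples
#' x <- rnorm(200)
#' normalized_association(x, x)    # exactly 1
#' normalized_association(x, -x)   # exactly -1
#' @export
normalized_association <- function(a, b, cfg = assoc_config()) {
  .check_mi_input(a, b)
  ba <- .mi_basis(a, cfg)
  bb <- .mi_basis(b, cfg)
  if (is.null(ba) || is.null(bb)) return(0)
  n <- length(a)
  ha <- .entropy(colSums(ba) / n)
  hb <- .entropy(colSums(bb) / n)
  iaa <- 2 * ha - .entropy(crossprod(ba, ba) / n)
  ibb <- 2 * hb - .entropy(crossprod(bb, bb) / n)
  den <- max(iaa, ibb)
  if (den <= 0) return(0)
  iab <- ha + hb - .entropy(crossprod(ba, bb) / n)
  val <- iab / den
  if (stats::cor(a, b) < 0) val <- -val
  max(-1, min(1, val))
}

#' Lower weighted median
#'
#' The smallest value `v` such that the total weight of observations `<= v`
#' reaches half the total weight. This "lower" convention is deterministic (no
#' interpolation between order statistics) and reduces to the usual lower
#' median under equal weights.
#'
#' @param values Numeric vector.
#' @param weights Non-negative weights, same length, positive total.
#' @return One element of `values`.
#' @examples
#' weighted_median(c(1, 2, 3), c(1, 1, 1))        # 2
#' weighted_median(c(1, 2, 3), c(0.6, 0.2, 0.2))  # 1
#' @export
weighted_median <- function(values, weights = rep(1, length(values))) {
  if (!length(values)) stop("empty input")
  if (length(values) != length(weights)) stop("values and weights must have equal length")
  if (any(!is.finite(values)) || any(!is.finite(weights))) stop("inputs must be finite")
  if (any(weights < 0)) stop("weights must be non-negative")
  tot <- sum(weights)
  if (tot <= 0) stop("total weight must be positive")
  ord <- order(values)
  cw <- cumsum(weights[ord]) / tot
  unname(values[ord][which(cw >= 0.5 - 1e-12)[1L]])
}

#' Pan-cancer association across cohorts
#'
#' Computes the normalized MI association within each cohort and aggregates
#' with the lower weighted median, weighting each cohort by its share of
#' samples. Cohorts with fewer than 8 paired samples are excluded with a
#' warning and the remaining weights renormalized.
#'
#' @param pairs A list with one element per cohort, each a list with numeric
#'   vectors `a` and `b` of equal length.
#' @param weights Per-cohort weights (proportions of samples); any positive
#'   vector is accepted and normalized.
#' @param cfg An [assoc_config()].
#' @return The weighted-median association, a number in [-1, 1].
#' @export
pan_cancer_association <- function(pairs, weights = rep(1, length(pairs)),
                                   cfg = assoc_config()) {
  if (!length(pairs)) stop("no cohorts supplied")
  if (length(weights) != length(pairs)) stop("one weight per cohort required")
  ns <- vapply(pairs, function(p) {
    if (length(p$a) != length(p$b)) stop("cohort vectors must have equal length")
    length(p$a)
  }, integer(1))
  keep <- ns >= 8L
  if (!any(keep)) stop("every cohort has fewer than 8 samples")
  if (!all(keep)) {
    warning(sprintf("excluding %d cohort(s) with fewer than 8 samples", sum(!keep)))
    pairs <- pairs[keep]
    weights <- weights[keep]
  }
  vals <- vapply(pairs, function(p) normalized_association(p$a, p$b, cfg), numeric(1))
  weighted_median(vals, weights)
}

# ---- vectorised engine -------------------------------------------------------
# The attractor iteration and the permutation test need the association of one
# vector against many genes (or many permutations) within a cohort. Both reuse
# per-gene basis matrices, so we precompute them once per cohort as a column-
# block stack: gene g occupies columns ((g-1)*m+1):(g*m).

# Build the basis stack for a genes x samples matrix. Ec holds the centered
# sample-by-gene expression used for the (sign-only) Pearson direction.
.mi_block <- function(E, cfg) {
  g <- nrow(E)
  n <- ncol(E)
  m <- cfg$n_bins
  B <- matrix(0, n, g * m)
  H <- numeric(g)
  self <- numeric(g)
  const <- logical(g)
  for (i in seq_len(g)) {
    bi <- .mi_basis(E[i, ], cfg)
    if (is.null(bi)) {
      const[i] <- TRUE
      next
    }
    cols <- ((i - 1L) * m + 1L):(i * m)
    B[, cols] <- bi
    p <- colSums(bi) / n
    H[i] <- .entropy_raw(p)
    self[i] <- 2 * H[i] - .entropy_raw(crossprod(bi, bi) / n)
  }
  Ec <- t(E) - rep(rowMeans(E), each = n)
  list(B = B, H = H, self = self, const = const, Ec = Ec, n = n, m = m, g = g)
}

# Joint entropies of one basis matrix against every m-column block of a stack.
.block_joint_entropy <- function(bm, Bstack, n, m) {
  J <- crossprod(bm, Bstack) / n
  v <- J * log(J)
  v[J <= 0] <- 0
  cs <- colSums(v)
  -colSums(matrix(cs, nrow = m))
}

# Signed normalized association of vector x against genes `idx` of a cohort
# block. The sign is the sign of the covariance (equals the Pearson sign).
.assoc_vs_block <- function(x, block, idx, cfg) {
  k <- length(idx)
  out <- numeric(k)
  bm <- .mi_basis(x, cfg)
  if (is.null(bm)) return(out)
  n <- block$n
  m <- block$m
  pm <- colSums(bm) / n
  hm <- .entropy_raw(pm)
  selfm <- 2 * hm - .entropy_raw(crossprod(bm, bm) / n)
  cols <- rep((idx - 1L) * m, each = m) + seq_len(m)
  hj <- .block_joint_entropy(bm, block$B[, cols, drop = FALSE], n, m)
  mi <- hm + block$H[idx] - hj
  den <- pmax(block$self[idx], selfm)
  val <- numeric(k)
  pos <- den > 0
  val[pos] <- mi[pos] / den[pos]
  sgn <- as.vector(crossprod(x - mean(x), block$Ec[, idx, drop = FALSE]))
  neg <- sgn < 0
  val[neg] <- -val[neg]
  val[block$const[idx]] <- 0
  pmax(-1, pmin(1, val))
}

# Row-wise lower weighted median of a matrix (rows = items, cols = cohorts),
# fully vectorised: sort within rows, cumulate the matching weights with a
# lower-triangular multiply, pick the first column reaching half weight.
.row_weighted_median <- function(M, w) {
  if (!is.matrix(M)) M <- matrix(M, ncol = length(w))
  if (ncol(M) == 1L) return(M[, 1L])
  k <- nrow(M)
  cc <- ncol(M)
  o <- order(row(M), M)
  S <- matrix(M[o], nrow = k, byrow = TRUE)
  W <- matrix(w[((o - 1L) %/% k) + 1L], nrow = k, byrow = TRUE)
  W <- W / rowSums(W)
  CW <- W %*% upper.tri(diag(cc), diag = TRUE)
  pick <- max.col(CW >= 0.5 - 1e-12, ties.method = "first")
  S[cbind(seq_len(k), pick)]
}
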