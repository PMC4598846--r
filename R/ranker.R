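# Semi-supervised manifold ranking: unlabelled drug pairs are scored by
# diffusion proximity to the labelled bait pairs on a Gaussian affinity
# graph built in the normalized feature space.

#' Gaussian affinity matrix over feature-space points
#'
#' `W_ij = exp(-||x_i - x_j||^2 / (2 sigma^2))` for i != j, zero diagonal.
#'
#' @param points Numeric matrix, one row per point.
#' @param kernelWidth Positive bandwidth sigma, or `NULL` to use the median
#'   heuristic (median of the nonzero pairwise Euclidean distances).
#' @return Symmetric affinity matrix with entries in [0, 1], zero diagonal.
#' @export
buildAffinity <- function(points, kernelWidth = NULL) {
  points <- as.matrix(points)
  stopIfNot(nrow(points) >= 2L, "need at least 2 points")
  d <- as.matrix(stats::dist(points))
  if (is.null(kernelWidth)) {
    pos <- d[upper.tri(d)]
    kernelWidth <- stats::median(pos[pos > 0])
    if (!is.finite(kernelWidth) || kernelWidth <= 0) kernelWidth <- 1
  }
  stopIfNot(kernelWidth > 0, "kernel width must be positive")
  w <- exp(-d^2 / (2 * kernelWidth^2))
  diag(w) <- 0
  dimnames(w) <- NULL
  w
}

#' Sparsify an affinity matrix to its symmetrized k nearest neighbours
#'
#' Keeps, for every point, the `k` strongest affinities, then symmetrizes
#' by the elementwise maximum. On a dense Gaussian affinity the diffusion
#' score at high `alpha` is dominated by each point's global affinity
#' degree rather than by proximity to the baits; restricting the graph to
#' nearest neighbours restores the local manifold structure the ranking
#' relies on.
#'
#' @param W Affinity matrix (zero diagonal).
#' @param k Neighbours kept per point (>= 1); values >= n-1 return `W`
#'   unchanged.
#' @return Sparsified symmetric affinity matrix.
#' @export
sparsifyAffinity <- function(W, k) {
  n <- nrow(W)
  stopIfNot(k >= 1L, "k must be >= 1")
  if (k >= n - 1L) return(W)
  keep <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    keep[i, order(-W[i, ])[seq_len(k)]] <- TRUE
  }
  W * (keep | t(keep))
}

#' Manifold ranking scores
#'
#' Solves the diffusion fixed point `f = alpha S f + (1 - alpha) y` with
#' `S = D^{-1/2} W D^{-1/2}` the symmetrically normalized affinity and `y`
#' the bait indicator. The closed-form solution
#' `f = (1 - alpha) (I - alpha S)^{-1} y` is used for systems up to
#' `directLimit` points; larger systems use fixed-point iteration to
#' `tol`. Isolated points (zero affinity degree) receive `(1 - alpha) y`.
#'
#' @param W Affinity matrix from [buildAffinity()] (or any symmetric
#'   nonnegative matrix with zero diagonal).
#' @param y Numeric indicator vector (1 = labelled bait, 0 = unlabelled).
#' @param alpha Diffusion parameter, strictly inside (0, 1); default 0.99.
#' @param method `"direct"`, `"iterative"`, or `"auto"` (direct up to
#'   `directLimit` points).
#' @param tol,maxIter Convergence control for the iterative solver.
#' @param directLimit Size cutoff for the direct solver under
#'   `method = "auto"`.
#' @return Nonnegative score vector, one per point.
#' @export
manifoldRank <- function(W, y, alpha = 0.99,
                         method = c("auto", "direct", "iterative"),
                         tol = 1e-10, maxIter = 10000L,
                         directLimit = 5000L) {
  method <- match.arg(method)
  n <- nrow(W)
  stopIfNot(length(y) == n, "y must have one entry per point")
  stopIfNot(alpha > 0 && alpha < 1, "alpha must lie strictly in (0, 1)")
  deg <- rowSums(W)
  dInv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  S <- W * tcrossprod(dInv)
  if (method == "auto") method <- if (n <= directLimit) "direct" else "iterative"
  if (method == "direct") {
    f <- (1 - alpha) * solve(diag(n) - alpha * S, y)
  } else {
    f <- (1 - alpha) * y
    for (i in seq_len(maxIter)) {
      fNew <- alpha * as.vector(S %*% f) + (1 - alpha) * y
      if (max(abs(fNew - f)) < tol) {
        f <- fNew
        break
      }
      f <- fNew
    }
  }
  unname(pmax(f, 0))
}

#' Preliminary ranking of unlabelled pairs against bait pairs
#'
#' Runs manifold ranking over the union of bait and unlabelled pairs in
#' the feature matrix, removes the baits, and returns the unlabelled pairs
#' sorted by score (descending; ties broken lexicographically by pair id,
#' so the output is deterministic and independent of input order).
#'
#' @param fm A [PairFeatureMatrix-class] (normalized) containing both
#'   labelled (bait) and unlabelled rows.
#' @param alpha Diffusion parameter, default 0.99.
#' @param kernelWidth Gaussian bandwidth; `NULL` for the median heuristic.
#' @param knn Neighbours kept per point when sparsifying the affinity
#'   graph (see [sparsifyAffinity()]); `NULL` for the dense graph.
#'   Default 7.
#' @param ... Passed on to [manifoldRank()].
#' @return A [RankedList-class] with `stage = "preliminary"`.
#' @export
preliminaryRank <- function(fm, alpha = 0.99, kernelWidth = NULL,
                            knn = 7L, ...) {
  y <- as.numeric(fm@label == "labelled")
  stopIfNot(sum(y) >= 1, "need at least one bait pair")
  if (all(y == 1)) {
    warning("no unlabelled pairs to rank", call. = FALSE)
    return(new("RankedList",
      entries = data.frame(
        drug_a = character(), drug_b = character(),
        score = numeric(), rank = integer(), flag = character()
      ),
      stage = "preliminary",
      config = list(alpha = alpha, kernelWidth = kernelWidth)
    ))
  }
  W <- buildAffinity(fm@features, kernelWidth)
  if (!is.null(knn)) W <- sparsifyAffinity(W, knn)
  f <- manifoldRank(W, y, alpha = alpha, ...)
  un <- fm@label == "unlabelled"
  newRankedList(
    fm@pairs$drug_a[un], fm@pairs$drug_b[un], f[un],
    stage = "preliminary",
    config = list(alpha = alpha, kernelWidth = kernelWidth)
  )
}
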