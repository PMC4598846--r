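# Ensemble of ranking runs over bait subsamples, top-fraction consistency
# screening, and exact Spearman-footrule consensus via minimum-cost
# bipartite assignment.

#' Ensemble specification
#'
#' @param nRuns Number of ranking runs (default 30).
#' @param baitFractions Cycle of bait subsample fractions applied across
#'   runs (run r uses fraction `baitFractions[((r-1) %% length) + 1]`);
#'   default 50%..100% in steps of 10%.
#' @param topFraction Fraction of the list counted as "top" in the
#'   consistency screen (default 0.01).
#' @param quorum Fraction of runs a pair must hit the top in to survive
#'   (default 1 = all runs).
#' @param masterSeed Integer seed; run r draws its bait subset under seed
#'   `masterSeed + r`.
#' @return A list of class `EnsembleSpec`.
#' @export
ensembleSpec <- function(nRuns = 30L,
                         baitFractions = seq(0.5, 1, by = 0.1),
                         topFraction = 0.01, quorum = 1,
                         masterSeed = 1L) {
  stopIfNot(nRuns >= 1L, "nRuns must be >= 1")
  stopIfNot(topFraction > 0 && topFraction <= 1,
    "topFraction must lie in (0, 1]")
  stopIfNot(quorum > 0 && quorum <= 1, "quorum must lie in (0, 1]")
  stopIfNot(all(baitFractions > 0 & baitFractions <= 1),
    "bait fractions must lie in (0, 1]")
  structure(
    list(
      nRuns = as.integer(nRuns), baitFractions = baitFractions,
      topFraction = topFraction, quorum = quorum,
      masterSeed = as.integer(masterSeed)
    ),
    class = "EnsembleSpec"
  )
}

# bait subset (row indices into baitIdx) for run r; deterministic in
# (masterSeed, r)
sampleBaitSubset <- function(baitIdx, spec, r) {
  frac <- spec$baitFractions[((r - 1L) %% length(spec$baitFractions)) + 1L]
  k <- max(1L, round(frac * length(baitIdx)))
  withSeed(spec$masterSeed + r, sample(baitIdx, k))
}

#' Run an ensemble of manifold-ranking runs over bait subsamples
#'
#' Each run draws a bait subset (size cycling through
#' `spec$baitFractions` of the positives, without replacement, seeded by
#' `masterSeed + run`), ranks the full unlabelled set against that subset,
#' and records the complete ordering. Held-out baits are excluded from the
#' run entirely (they are known positives, not queries).
#'
#' @param fm A normalized [PairFeatureMatrix-class] with labelled and
#'   unlabelled rows.
#' @param spec An [ensembleSpec()].
#' @param alpha,kernelWidth,knn Passed to [preliminaryRank()].
#' @return List of [RankedList-class] objects, one per run (all over the
#'   same unlabelled pair set).
#' @export
runEnsemble <- function(fm, spec = ensembleSpec(), alpha = 0.99,
                        kernelWidth = NULL, knn = 7L) {
  baitIdx <- which(fm@label == "labelled")
  stopIfNot(length(baitIdx) >= 1L, "need at least one bait pair")
  unIdx <- which(fm@label == "unlabelled")
  if (length(baitIdx) < 2L && spec$nRuns > 1L) {
    spec$nRuns <- 1L  # nothing to subsample
  }
  lapply(seq_len(spec$nRuns), function(r) {
    sub <- sampleBaitSubset(baitIdx, spec, r)
    keep <- sort(c(sub, unIdx))
    sfm <- new("PairFeatureMatrix",
      pairs = fm@pairs[keep, , drop = FALSE],
      features = fm@features[keep, , drop = FALSE],
      label = fm@label[keep], normalized = fm@normalized,
      bounds = fm@bounds
    )
    rl <- preliminaryRank(sfm, alpha = alpha, kernelWidth = kernelWidth,
      knn = knn)
    rl@config$run <- r
    rl@config$baitSubset <- pairKey(
      fm@pairs$drug_a[sub], fm@pairs$drug_b[sub]
    )
    rl
  })
}

#' Pairs consistently at the top of an ensemble of rankings
#'
#' A pair survives when it appears within the top
#' `ceil(topFraction * n)` positions of at least `quorum * nRuns` of the
#' rankings.
#'
#' @param rankings List of [RankedList-class] objects over the same pairs.
#' @param topFraction Top fraction of each list (default 0.01).
#' @param quorum Required fraction of runs (default 1 = every run).
#' @return Character vector of surviving pair keys (`"a||b"`), in the
#'   order of the first ranking.
#' @export
consistentTop <- function(rankings, topFraction = 0.01, quorum = 1) {
  stopIfNot(length(rankings) >= 1L, "need at least one ranking")
  counts <- NULL
  for (rl in rankings) {
    e <- rankedEntries(rl)
    k <- ceiling(topFraction * nrow(e))
    topKeys <- pairKey(e$drug_a[e$rank <= k], e$drug_b[e$rank <= k])
    if (is.null(counts)) {
      counts <- stats::setNames(
        integer(nrow(e)), pairKey(e$drug_a, e$drug_b)
      )
    }
    counts[topKeys] <- counts[topKeys] + 1L
  }
  need <- ceiling(quorum * length(rankings))
  names(counts)[counts >= need]
}

# exact minimum-cost square assignment (Hungarian algorithm, shortest
# augmenting path formulation); returns match[i] = column of row i
lapAssign <- function(cost) {
  n <- nrow(cost)
  stopIfNot(n == ncol(cost), "cost matrix must be square")
  if (n == 0L) return(integer(0))
  v0 <- n + 1L  # virtual column playing the role of column 0
  u <- numeric(n)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)   # p[j] = row assigned to column j (0 = free)
  way <- integer(n)
  for (i in seq_len(n)) {
    p[v0] <- i
    j0 <- v0
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) {
          if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == v0) break
    }
  }
  match <- integer(n)
  for (j in seq_len(n)) if (p[j] > 0L) match[p[j]] <- j
  match
}

#' Spearman-footrule consensus of an ensemble of rankings
#'
#' Restricts every input ranking to the surviving pairs (relative order
#' preserved, positions recompacted to 1..k) and finds the consensus
#' permutation minimizing the total footrule distance
#' `sum_runs sum_pairs |pos_consensus - pos_run|`. The minimization is
#' exact, via minimum-cost bipartite assignment of pairs to positions with
#' cost `sum_runs |position - pos_run(pair)|`; among equal-cost optima the
#' pair with the smaller mean rank (then the lexicographically smaller id)
#' takes the better position.
#'
#' @param rankings List of [RankedList-class] objects over a common pair
#'   set.
#' @param survivors Character vector of pair keys (`"a||b"`) to aggregate,
#'   e.g. from [consistentTop()]; default all pairs of the first ranking.
#' @return A [RankedList-class] with `stage = "consensus"` (score =
#'   k - position + 1).
#' @export
footruleConsensus <- function(rankings, survivors = NULL) {
  stopIfNot(length(rankings) >= 1L, "need at least one ranking")
  e1 <- rankedEntries(rankings[[1L]])
  allKeys <- pairKey(e1$drug_a, e1$drug_b)
  if (is.null(survivors)) survivors <- allKeys
  if (!length(survivors)) {
    warning("empty survivor set; empty consensus", call. = FALSE)
    return(new("RankedList",
      entries = data.frame(
        drug_a = character(), drug_b = character(),
        score = numeric(), rank = integer(), flag = character()
      ),
      stage = "consensus", config = list(nRuns = length(rankings))
    ))
  }
  # positions of survivors within each run after restriction
  posMat <- vapply(rankings, function(rl) {
    e <- rankedEntries(rl)
    keys <- pairKey(e$drug_a, e$drug_b)
    stopIfNot(all(survivors %in% keys),
      "every surviving pair must be present in every ranking")
    keep <- keys[keys %in% survivors]
    match(survivors, keep)  # compacted rank 1..k within the run
  }, integer(length(survivors)))
  posMat <- matrix(posMat, nrow = length(survivors))
  k <- length(survivors)
  cost <- matrix(0, k, k)
  for (pos in seq_len(k)) cost[, pos] <- rowSums(abs(posMat - pos))
  # deterministic tie-break among equal-cost assignments: prefer small
  # mean rank (then pair id) at top positions, via a perturbation too
  # small to alter optimality (integer costs)
  ord <- order(rowMeans(posMat), survivors)
  pref <- match(seq_len(k), ord)            # preference index per pair
  eps <- 0.5 / (as.numeric(k)^3 + 1)
  cost <- cost + eps * outer(k - pref, seq_len(k))
  assign <- lapAssign(cost)
  parts <- do.call(rbind, strsplit(survivors, "||", fixed = TRUE))
  o <- order(assign)
  newRankedList(
    parts[o, 1L], parts[o, 2L], score = as.numeric(k - seq_len(k) + 1L),
    stage = "consensus",
    config = list(nRuns = length(rankings), nSurvivors = k)
  )
}

#' Total footrule distance of a candidate ordering to an ensemble
#'
#' @param ordering Character vector of pair keys in candidate order.
#' @param posMat Integer matrix of per-run positions (pairs x runs), rows
#'   named or aligned with `ordering`'s pair set.
#' @param keys Pair keys labelling the rows of `posMat`.
#' @return Total footrule distance (numeric).
#' @export
footruleDistance <- function(ordering, posMat, keys) {
  idx <- match(ordering, keys)
  stopIfNot(!anyNA(idx), "ordering and keys must contain the same pairs")
  sum(abs(matrix(posMat[idx, ], nrow = length(idx)) - seq_along(idx)))
}
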