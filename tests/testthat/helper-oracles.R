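# Independent oracles and small fixtures used across the suite. These are
# deliberately naive re-derivations (BFS by hand, exhaustive enumeration)
# so they share no code path with the implementation they check.

# all-pairs shortest paths by breadth-first search over an edge data.frame
bfsDistances <- function(edges, nodes) {
  adj <- lapply(stats::setNames(nodes, nodes), function(v) {
    unique(c(edges[[2]][edges[[1]] == v], edges[[1]][edges[[2]] == v]))
  })
  d <- matrix(Inf, length(nodes), length(nodes),
    dimnames = list(nodes, nodes))
  for (s in nodes) {
    d[s, s] <- 0
    frontier <- s
    depth <- 0
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- setdiff(unique(unlist(adj[frontier])),
        nodes[is.finite(d[s, ])])
      d[s, nxt] <- depth
      frontier <- nxt
    }
  }
  d
}

# apply the package's unreachable-pair convention to a BFS matrix
penalizeInf <- function(d) {
  if (any(is.infinite(d))) {
    dmax <- max(d[is.finite(d)])
    d[is.infinite(d)] <- dmax + 1
  }
  d
}

# all permutations of a vector (exhaustive search oracle)
allPerms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in allPerms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# brute-force minimal assignment cost over all permutations
bruteAssignmentCost <- function(cost) {
  n <- nrow(cost)
  best <- Inf
  for (p in allPerms(seq_len(n))) {
    s <- sum(cost[cbind(seq_len(n), p)])
    if (s < best) best <- s
  }
  best
}

# two-sided Fisher p by explicit hypergeometric enumeration over all
# tables with the observed margins (probability-mass rule)
fisherEnumeration <- function(tbl) {
  a <- tbl[1, 1]
  r1 <- sum(tbl[1, ])
  c1 <- sum(tbl[, 1])
  n <- sum(tbl)
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(ks, r1, n - r1, c1)
  pObs <- stats::dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# small fixed bundle: path graph A-B-C-D with CN = {B, C, D}
pathBundle <- function() {
  networkBundle(
    data.frame(a = c("A", "B", "C"), b = c("B", "C", "D")),
    cnNodes = c("B", "C", "D")
  )
}

# tiny deterministic feature matrix: two labelled + four unlabelled rows
toyFeatureMatrix <- function() {
  pairs <- canonicalPairs(
    c("a", "a", "a", "b", "b", "c"),
    c("b", "c", "d", "c", "d", "d")
  )
  feats <- matrix(
    c(
      0.9, 0.8, # labelled cluster
      0.85, 0.75,
      0.88, 0.79, # unlabelled near the cluster
      0.2, 0.1, # far unlabelled
      0.15, 0.2,
      0.1, 0.05
    ),
    ncol = 2, byrow = TRUE, dimnames = list(NULL, c("f1", "f2"))
  )
  new("PairFeatureMatrix",
    pairs = pairs, features = feats,
    label = c("labelled", "labelled", rep("unlabelled", 4)),
    normalized = TRUE, bounds = matrix(numeric(0), 0, 0)
  )
}

# random small drug library + bundle for symmetry/property loops
randomStudy <- function(seed, nProteins = 40L, nDrugs = 8L) {
  bundle <- simulateNetworkBundle(nProteins, nCn = 12L, seed = seed)
  sim <- simulateDrugLibrary(bundle,
    nDrugs = nDrugs, nSynergyDrugs = 4L,
    nPositives = 3L, nGoTerms = 20L, nPathways = 10L, seed = seed + 1L
  )
  list(bundle = bundle, sim = sim)
}
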