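# Pair-level network/annotation features.
#
# Shortest-path conventions: an unreachable node pair contributes Dmax + 1,
# where Dmax is the largest finite shortest-path length (finite diameter) of
# the graph being measured, recomputed on the perturbed graph after node
# removal. This keeps distance means defined on disconnected graphs.

#' GO biological-process fingerprint of a target set
#'
#' Binary vector over a fixed universe of cancer-related GO BP terms;
#' element t is 1 iff at least one target belongs to term t's gene set.
#'
#' @param targets Character vector of target proteins (may be empty:
#'   all-zero fingerprint).
#' @param goTermSets Named list of character vectors, the term universe.
#' @return Named integer 0/1 vector of length `length(goTermSets)`.
#' @examples
#' goFingerprint("P1", list(go1 = c("P1", "P2"), go2 = "P3"))
#' @export
goFingerprint <- function(targets, goTermSets) {
  stopIfNot(length(goTermSets) > 0L, "GO term universe must be nonempty")
  vapply(goTermSets, function(g) as.integer(any(targets %in% g)),
    integer(1)
  )
}

#' GO-based mutual information of two fingerprints
#'
#' Pointwise mutual information of the two drugs' term memberships:
#' `P(x,y) * ln(P(x,y) / (P(x) P(y)))`, where P(x) is the fraction of terms
#' mapped by drug x's targets and P(x,y) the fraction mapped by both.
#' Natural logarithm; the 0 * ln 0 limit convention gives 0 whenever the
#' fingerprints share no term. Symmetric; can be negative when the shared
#' fraction is below the independence expectation.
#'
#' @param fpX,fpY Equal-length binary vectors.
#' @return A single numeric value.
#' @examples
#' mutualInformation(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' @export
mutualInformation <- function(fpX, fpY) {
  stopIfNot(length(fpX) > 0L && length(fpX) == length(fpY),
    "fingerprints must be nonempty and of equal length")
  px <- mean(fpX != 0)
  py <- mean(fpY != 0)
  pxy <- mean(fpX != 0 & fpY != 0)
  if (pxy == 0) return(0)
  pxy * log(pxy / (px * py))
}

# all-pairs shortest path matrix with the Dmax+1 convention for
# unreachable pairs; rows/cols restricted to `from`/`to` if given
finiteDistances <- function(g, from = igraph::V(g), to = igraph::V(g)) {
  d <- igraph::distances(g, v = from, to = to)
  if (any(is.infinite(d))) {
    dAll <- igraph::distances(g)
    dmax <- max(dAll[is.finite(dAll)])
    d[is.infinite(d)] <- dmax + 1
  }
  d
}

#' Mean shortest-path distance between two target sets
#'
#' Average over all (i, j) target pairs of the shortest-path length between
#' target i of drug x and target j of drug y in the background PPI graph.
#' Targets absent from the graph are dropped first; unreachable pairs
#' contribute Dmax + 1 (Dmax = largest finite shortest-path length).
#'
#' @param targetsX,targetsY Character vectors of target proteins.
#' @param bundle A [NetworkBundle-class].
#' @return Mean distance, or `NA_real_` (with a warning) when either set is
#'   empty after mapping onto the graph.
#' @examples
#' nb <- networkBundle(
#'   data.frame(a = c("A", "B", "C"), b = c("B", "C", "D")), cnNodes = "B"
#' )
#' avgTargetDistance("A", c("C", "D"), nb) # (2 + 3) / 2
#' @export
avgTargetDistance <- function(targetsX, targetsY, bundle) {
  g <- backgroundGraph(bundle)
  nm <- igraph::V(g)$name
  tx <- intersect(unique(targetsX), nm)
  ty <- intersect(unique(targetsY), nm)
  if (!length(tx) || !length(ty)) {
    dropWarning("pair distance", "no target maps onto the background graph")
    return(NA_real_)
  }
  mean(finiteDistances(g, from = tx, to = ty))
}

#' Mean internode distance ("information-sending efficiency") of a graph
#'
#' Arithmetic mean of the shortest-path lengths over all unordered node
#' pairs; unreachable pairs contribute Dmax + 1 of the same graph. Smaller
#' values mean a tighter, faster-communicating network.
#'
#' @param graph An igraph with at least 2 nodes (typically the CN-induced
#'   subgraph).
#' @return Mean pairwise distance.
#' @examples
#' networkEfficiency(igraph::make_ring(3)) # 1
#' @export
networkEfficiency <- function(graph) {
  n <- igraph::vcount(graph)
  stopIfNot(n >= 2L, "efficiency needs at least 2 nodes")
  d <- finiteDistances(graph)
  sum(d[upper.tri(d)]) / (n * (n - 1) / 2)
}

#' Relative efficiency change of the cancer network under target removal
#'
#' Removes the drug's targets from the CN graph, recomputes the mean
#' internode distance, and returns the relative change
#' `(E_removed - E) / E`. Returns 0 when no target lies in the CN.
#'
#' @param cnGraph The CN-induced subgraph (igraph).
#' @param targets Character vector of targets (set semantics; duplicates
#'   ignored).
#' @return Relative change, a single numeric value.
#' @export
deltaEfficiency <- function(cnGraph, targets) {
  nm <- igraph::V(cnGraph)$name
  hit <- intersect(unique(targets), nm)
  if (!length(hit)) return(0)
  stopIfNot(
    length(nm) - length(hit) >= 2L,
    "target removal leaves <2 CN nodes; use a larger CN or smaller target set"
  )
  e0 <- networkEfficiency(cnGraph)
  e1 <- networkEfficiency(igraph::delete_vertices(cnGraph, hit))
  (e1 - e0) / e0
}

#' Drug-combination interference (DCI)
#'
#' Difference between the CN efficiency change of the combined treatment
#' and the sum of the single-agent changes:
#' `DCI = dE(x u y) - dE(x) - dE(y)`. Signed and symmetric; positive when
#' the combination perturbs the cancer network more than the two drugs
#' added independently.
#'
#' @param cnGraph CN-induced subgraph.
#' @param targetsX,targetsY Target sets of the two drugs.
#' @return A single numeric value.
#' @export
dci <- function(cnGraph, targetsX, targetsY) {
  deltaEfficiency(cnGraph, union(targetsX, targetsY)) -
    deltaEfficiency(cnGraph, targetsX) -
    deltaEfficiency(cnGraph, targetsY)
}

#' Centrality weights for the efficacy features
#'
#' Normalized node weights for one centrality scheme: CN nodes are weighted
#' by their centrality on the CN-induced subgraph (normalized to sum 1 over
#' the CN), non-CN nodes by their centrality on the full background graph
#' (normalized to sum 1 over all background nodes). The two scopes reflect
#' that therapeutic value is judged within the cancer network while
#' off-target liability is judged against the whole interactome.
#'
#' @param bundle A [NetworkBundle-class].
#' @param scheme `"degree"`, `"betweenness"` or `"eigenvector"`.
#' @param lambda Penalty weight in [0, 1] for non-CN ("additional effect")
#'   hits; default 0.1.
#' @return List with elements `scheme`, `lambda`, `cn` (named weights over
#'   CN nodes) and `ncn` (named weights over non-CN nodes).
#' @export
efficacyWeights <- function(bundle,
                            scheme = c("degree", "betweenness",
                                       "eigenvector"),
                            lambda = 0.1) {
  scheme <- match.arg(scheme)
  stopIfNot(lambda >= 0 && lambda <= 1, "lambda must lie in [0, 1]")
  normalize1 <- function(w) if (sum(w) > 0) w / sum(w) else w
  wCn <- normalize1(bundle@centralities$cn[[scheme]])
  wBg <- normalize1(bundle@centralities$background[[scheme]])
  list(
    scheme = scheme, lambda = lambda,
    cn = wCn, ncn = wBg[ncnNodes(bundle)]
  )
}

#' Efficacy of a drug pair (Eff.D / Eff.B / Eff.E)
#'
#' For the union T of the two target sets,
#' `Eff = sum_{i in T n CN} W_i - lambda * sum_{i in T n NCN} W_i`:
#' reward for hitting central cancer-network nodes, penalty (scaled by
#' lambda) for hitting central nodes elsewhere in the background network.
#' The scheme (degree / betweenness / eigenvector) picks which centrality
#' defines W.
#'
#' @param targetsX,targetsY Target sets of the two drugs.
#' @param weights Output of [efficacyWeights()].
#' @return A single numeric value (0 for an empty union).
#' @export
efficacy <- function(targetsX, targetsY, weights) {
  tAll <- union(targetsX, targetsY)
  hitCn <- intersect(tAll, names(weights$cn))
  hitNcn <- intersect(tAll, names(weights$ncn))
  sum(weights$cn[hitCn]) - weights$lambda * sum(weights$ncn[hitNcn])
}

#' Fraction of unrelated pathway pairs (MP.U)
#'
#' Over all cross pairs (p, q) with p from drug x's pathways and q from
#' drug y's, the fraction whose relation is "unrelated" (not identical, not
#' cross-talking, not interacting). A pathway paired with itself is always
#' identical; pathway pairs absent from the relation table default to
#' unrelated.
#'
#' @param pathwaysX,pathwaysY Character vectors of pathway ids (both
#'   nonempty).
#' @param relations A pathway-relation table from [pathwayRelations()], or
#'   `NULL` for the empty table (everything non-identical is unrelated).
#' @return Fraction in [0, 1], or `NA_real_` with a warning if either set
#'   is empty.
#' @export
mpU <- function(pathwaysX, pathwaysY, relations = NULL) {
  px <- unique(as.character(pathwaysX))
  py <- unique(as.character(pathwaysY))
  if (!length(px) || !length(py)) {
    dropWarning("pathway feature", "empty pathway set")
    return(NA_real_)
  }
  grid <- expand.grid(p = px, q = py, stringsAsFactors = FALSE)
  rel <- pathwayRelation(relations, grid$p, grid$q)
  mean(rel == "unrelated")
}

#' Pathway-pair relation table
#'
#' Symmetric lookup of the relation between two pathways: `identical`,
#' `cross-talking`, `interacting` or `unrelated`. `(p, p)` is always
#' identical; unordered pairs missing from the table are unrelated.
#'
#' @param pathway_a,pathway_b Character vectors (one row per known pair).
#' @param relation Character vector of relations, from the four categories
#'   above.
#' @return An object of class `PathwayRelations` (keyed environment-free
#'   data.frame).
#' @examples
#' rel <- pathwayRelations(c("pw1"), c("pw2"), c("cross-talking"))
#' pathwayRelation(rel, c("pw1", "pw1"), c("pw2", "pw3"))
#' @export
pathwayRelations <- function(pathway_a = character(),
                             pathway_b = character(),
                             relation = character()) {
  ok <- c("identical", "cross-talking", "interacting", "unrelated")
  stopIfNot(all(relation %in% ok),
    paste("relations must be one of:", paste(ok, collapse = ", ")))
  key <- pairKey(as.character(pathway_a), as.character(pathway_b))
  tab <- data.frame(key = key, relation = as.character(relation),
    stringsAsFactors = FALSE)
  tab <- tab[!duplicated(tab$key), , drop = FALSE]
  structure(tab, class = c("PathwayRelations", "data.frame"))
}

#' @rdname pathwayRelations
#' @param relations A `PathwayRelations` table or `NULL`.
#' @param p,q Character vectors of pathway ids (recycled).
#' @export
pathwayRelation <- function(relations, p, q) {
  n <- max(length(p), length(q))
  p <- rep_len(as.character(p), n)
  q <- rep_len(as.character(q), n)
  out <- rep("unrelated", n)
  out[p == q] <- "identical"
  if (!is.null(relations) && nrow(relations)) {
    idx <- match(pairKey(p, q), relations$key)
    hit <- !is.na(idx) & p != q
    out[hit] <- relations$relation[idx[hit]]
  }
  out
}

#' Compute the seven-feature matrix for a set of drug pairs
#'
#' Evaluates MI, Dis, DCI, Eff.D, Eff.B, Eff.E and MP.U for each pair.
#' Pairs for which Dis or MP.U is undefined (no mappable target, empty
#' pathway set) are excluded with a warning, since rows entering the
#' ranking may not contain missing values.
#'
#' @param library A [DrugLibrary-class].
#' @param bundle A [NetworkBundle-class].
#' @param pairs data.frame with columns `drug_a`, `drug_b` (canonicalized
#'   internally).
#' @param labels Character vector (`"labelled"`/`"unlabelled"`) per pair.
#' @param relations Optional [pathwayRelations()] table.
#' @param lambda Efficacy penalty weight, default 0.1.
#' @return A [PairFeatureMatrix-class] (raw, unnormalized).
#' @export
computePairFeatures <- function(library, bundle, pairs, labels,
                                relations = NULL, lambda = 0.1) {
  stopIfNot(nrow(pairs) == length(labels),
    "labels must have one entry per pair")
  pp <- canonicalPairs(pairs$drug_a, pairs$drug_b)
  known <- pp$drug_a %in% drugIds(library) & pp$drug_b %in% drugIds(library)
  if (any(!known)) {
    dropWarning(sprintf("%d pair(s)", sum(!known)),
      "reference drugs absent from the library")
    pp <- pp[known, , drop = FALSE]
    labels <- labels[known]
  }
  cng <- cnGraph(bundle)
  fps <- goFingerprints(library)
  wts <- lapply(
    c(degree = "degree", betweenness = "betweenness",
      eigenvector = "eigenvector"),
    function(s) efficacyWeights(bundle, s, lambda)
  )
  dEcache <- new.env(parent = emptyenv())
  dE <- function(tset) {
    k <- paste(sort(tset), collapse = "|")
    if (is.null(dEcache[[k]])) dEcache[[k]] <- deltaEfficiency(cng, tset)
    dEcache[[k]]
  }

  featNames <- c("MI", "Dis", "DCI", "Eff.D", "Eff.B", "Eff.E", "MP.U")
  m <- matrix(NA_real_, nrow(pp), length(featNames),
    dimnames = list(NULL, featNames))
  for (i in seq_len(nrow(pp))) {
    x <- pp$drug_a[i]
    y <- pp$drug_b[i]
    tx <- targetsOf(library, x)
    ty <- targetsOf(library, y)
    m[i, "MI"] <- mutualInformation(fps[x, ], fps[y, ])
    m[i, "Dis"] <- suppressWarnings(avgTargetDistance(tx, ty, bundle))
    m[i, "DCI"] <- dE(union(tx, ty)) - dE(tx) - dE(ty)
    m[i, "Eff.D"] <- efficacy(tx, ty, wts$degree)
    m[i, "Eff.B"] <- efficacy(tx, ty, wts$betweenness)
    m[i, "Eff.E"] <- efficacy(tx, ty, wts$eigenvector)
    m[i, "MP.U"] <- suppressWarnings(
      mpU(pathwaysOf(library, x), pathwaysOf(library, y), relations)
    )
  }
  ok <- stats::complete.cases(m)
  if (any(!ok)) {
    bad <- paste(pp$drug_a[!ok], pp$drug_b[!ok], sep = "+")
    dropWarning(
      paste("pair(s)", paste(bad, collapse = ", ")),
      "undefined feature (unmappable targets or empty pathway set)"
    )
  }
  new("PairFeatureMatrix",
    pairs = pp[ok, , drop = FALSE], features = m[ok, , drop = FALSE],
    label = labels[ok], normalized = FALSE,
    bounds = matrix(numeric(0), 0, 0)
  )
}

#' Min-max normalize a feature matrix to [0, 1]
#'
#' Each feature is rescaled by its pooled (labelled + unlabelled) observed
#' minimum and maximum; the bounds are stored on the returned object.
#' Constant features map to 0 with a warning. Idempotent.
#'
#' @param fm A [PairFeatureMatrix-class].
#' @return The normalized [PairFeatureMatrix-class].
#' @export
minMaxNormalize <- function(fm) {
  m <- fm@features
  lo <- apply(m, 2, min)
  hi <- apply(m, 2, max)
  flat <- hi - lo <= 0
  if (any(flat)) {
    warning(sprintf(
      "constant feature(s) mapped to 0: %s",
      paste(colnames(m)[flat], collapse = ", ")
    ), call. = FALSE)
  }
  span <- ifelse(flat, 1, hi - lo)
  m2 <- sweep(sweep(m, 2, lo, "-"), 2, span, "/")
  m2[, flat] <- 0
  new("PairFeatureMatrix",
    pairs = fm@pairs, features = m2, label = fm@label, normalized = TRUE,
    bounds = rbind(min = lo, max = hi)
  )
}

#' Z-score screen for features separating bait from unlabelled pairs
#'
#' For each (normalized) feature, computes the two-sample Z statistic
#' `(mean_L - mean_U) / sqrt(s2_L/n_L + s2_U/n_U)` (Welch-style standard
#' error, since the labelled group is tiny relative to the unlabelled one)
#' and selects features with `|Z| >` the threshold. Features with zero
#' variance in both groups are dropped with a warning.
#'
#' @param fm A [PairFeatureMatrix-class] containing both labelled and
#'   unlabelled rows (>= 2 of each).
#' @param threshold Selection threshold on |Z|; default 3.
#' @return data.frame with columns `feature`, `z`, `selected`.
#' @export
zScoreScreen <- function(fm, threshold = 3) {
  lab <- fm@label == "labelled"
  stopIfNot(sum(lab) >= 2L && sum(!lab) >= 2L,
    "need >= 2 labelled and >= 2 unlabelled pairs")
  mL <- fm@features[lab, , drop = FALSE]
  mU <- fm@features[!lab, , drop = FALSE]
  se <- sqrt(apply(mL, 2, stats::var) / nrow(mL) +
    apply(mU, 2, stats::var) / nrow(mU))
  z <- (colMeans(mL) - colMeans(mU)) / se
  dead <- !is.finite(z)
  if (any(dead)) {
    warning(sprintf(
      "feature(s) with zero variance in both groups dropped: %s",
      paste(colnames(fm@features)[dead], collapse = ", ")
    ), call. = FALSE)
  }
  data.frame(
    feature = colnames(fm@features),
    z = unname(z),
    selected = ifelse(dead, FALSE, abs(z) > threshold),
    stringsAsFactors = FALSE
  )
}

#' Restrict a feature matrix to named features
#'
#' @param fm A [PairFeatureMatrix-class].
#' @param features Character vector of feature (column) names to keep.
#' @return The restricted [PairFeatureMatrix-class].
#' @export
selectFeatures <- function(fm, features) {
  stopIfNot(all(features %in% colnames(fm@features)),
    "unknown feature name(s)")
  new("PairFeatureMatrix",
    pairs = fm@pairs,
    features = fm@features[, features, drop = FALSE],
    label = fm@label, normalized = fm@normalized,
    bounds = if (length(fm@bounds)) {
      fm@bounds[, features, drop = FALSE]
    } else {
      fm@bounds
    }
  )
}
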