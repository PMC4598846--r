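#' Build a DrugLibrary from targets and annotation gene sets
#'
#' Derives each drug's GO fingerprint and pathway set by membership of its
#' targets in the supplied gene sets: fingerprint element t is 1 iff at
#' least one target belongs to term t's gene set, and a pathway is assigned
#' iff at least one target belongs to its gene set. Drugs with an empty
#' target set are excluded with a warning, since every pair-level feature
#' needs at least one target per drug.
#'
#' @param targets Named list of character vectors: protein targets per drug.
#' @param goTermSets Named list of character vectors: gene members of each
#'   cancer-related GO biological-process term. The names define the fixed
#'   fingerprint universe.
#' @param pathwaySets Named list of character vectors: gene members of each
#'   pathway.
#' @param degSets Optional named list of character vectors: per-drug DEG
#'   sets. Drugs absent from this list carry `NULL` (no expression profile).
#' @return A [DrugLibrary-class] object.
#' @examples
#' lib <- drugLibrary(
#'   targets = list(d1 = c("P1", "P2"), d2 = "P3"),
#'   goTermSets = list(go1 = c("P1", "P9"), go2 = "P3"),
#'   pathwaySets = list(pw1 = c("P2", "P3"))
#' )
#' goFingerprints(lib)
#' @export
drugLibrary <- function(targets, goTermSets, pathwaySets,
                        degSets = list()) {
  stopIfNot(length(goTermSets) > 0L, "GO term universe must be nonempty")
  stopIfNot(!is.null(names(targets)), "targets must be a named list")
  empty <- vapply(targets, function(t) length(t) == 0L, logical(1))
  if (any(empty)) {
    dropWarning(
      paste("drug(s)", paste(names(targets)[empty], collapse = ", ")),
      "empty target set"
    )
    targets <- targets[!empty]
  }
  stopIfNot(length(targets) > 0L, "no drug with a nonempty target set")
  ids <- names(targets)
  targets <- lapply(targets, function(t) unique(as.character(t)))

  fp <- t(vapply(
    targets,
    function(t) goFingerprint(t, goTermSets),
    integer(length(goTermSets))
  ))
  rownames(fp) <- ids

  pw <- lapply(targets, function(t) {
    hit <- vapply(pathwaySets, function(g) any(t %in% g), logical(1))
    names(pathwaySets)[hit]
  })
  names(pw) <- ids

  deg <- lapply(ids, function(d) {
    s <- degSets[[d]]
    if (is.null(s) || !length(s)) NULL else unique(as.character(s))
  })
  names(deg) <- ids

  new("DrugLibrary",
    drugIds = ids, targets = targets, goFingerprint = fp,
    pathways = pw, degSets = deg
  )
}

#' Build a NetworkBundle
#'
#' Simplifies the supplied graph (drops self-loops and duplicate edges),
#' records the cancer-network node subset, and precomputes the degree,
#' betweenness and eigenvector centralities used by the efficacy features,
#' on both scopes: the full background graph and the CN-induced subgraph.
#' Eigenvector centrality is computed on the largest connected component of
#' each scope; nodes outside it get weight 0.
#'
#' @param graph An [igraph::igraph] (or a 2-column edge data.frame /
#'   matrix) over named protein nodes; treated as undirected.
#' @param cnNodes Character vector of cancer-network nodes; must be a
#'   subset of the graph's nodes.
#' @return A [NetworkBundle-class] object.
#' @examples
#' edges <- data.frame(a = c("P1", "P2", "P3"), b = c("P2", "P3", "P4"))
#' nb <- networkBundle(edges, cnNodes = c("P2", "P3"))
#' ncnNodes(nb)
#' @export
networkBundle <- function(graph, cnNodes) {
  if (!igraph::is_igraph(graph)) {
    graph <- igraph::graph_from_data_frame(as.data.frame(graph),
      directed = FALSE
    )
  }
  graph <- igraph::as_undirected(graph, mode = "collapse")
  graph <- igraph::simplify(graph)
  cnNodes <- unique(as.character(cnNodes))
  missing <- setdiff(cnNodes, igraph::V(graph)$name)
  stopIfNot(
    length(missing) == 0L,
    paste("CN nodes absent from graph:", paste(missing, collapse = ", "))
  )
  cn <- igraph::induced_subgraph(graph, cnNodes)
  cents <- list(
    background = nodeCentralities(graph),
    cn = nodeCentralities(cn)
  )
  new("NetworkBundle", graph = graph, cnNodes = cnNodes,
      centralities = cents)
}

# degree/betweenness/eigenvector centralities of a named graph; eigenvector
# is computed on the largest connected component, zero elsewhere.
nodeCentralities <- function(g) {
  nm <- igraph::V(g)$name
  if (length(nm) == 0L) {
    z <- numeric(0)
    return(list(degree = z, betweenness = z, eigenvector = z))
  }
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE)
  ev <- stats::setNames(numeric(length(nm)), nm)
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  inBig <- nm[comp$membership == big]
  if (length(inBig) >= 2L) {
    sub <- igraph::induced_subgraph(g, inBig)
    ev[inBig] <- igraph::eigen_centrality(sub)$vector
  } else {
    ev[inBig] <- 1
  }
  list(degree = deg, betweenness = btw, eigenvector = ev)
}

# internal RankedList constructor from scored pairs (already canonical)
newRankedList <- function(drug_a, drug_b, score, stage,
                          flag = NULL, config = list()) {
  if (is.null(flag)) flag <- rep("", length(drug_a))
  o <- order(-score, drug_a, drug_b)
  e <- data.frame(
    drug_a = drug_a[o], drug_b = drug_b[o],
    score = score[o], rank = seq_along(o), flag = flag[o],
    stringsAsFactors = FALSE
  )
  rownames(e) <- NULL
  new("RankedList", entries = e, stage = stage, config = config)
}

## Accessors -----------------------------------------------------------------

#' @rdname DrugLibrary-class
#' @export
setMethod("drugIds", "DrugLibrary", function(x) x@drugIds)

#' @rdname DrugLibrary-class
#' @export
setMethod("targetsOf", "DrugLibrary", function(x, drug) {
  stopIfNot(drug %in% x@drugIds, paste("unknown drug:", drug))
  x@targets[[drug]]
})

#' @rdname DrugLibrary-class
#' @export
setMethod("pathwaysOf", "DrugLibrary", function(x, drug) {
  stopIfNot(drug %in% x@drugIds, paste("unknown drug:", drug))
  x@pathways[[drug]]
})

#' @rdname DrugLibrary-class
#' @export
setMethod("degSetOf", "DrugLibrary", function(x, drug) {
  stopIfNot(drug %in% x@drugIds, paste("unknown drug:", drug))
  x@degSets[[drug]]
})

#' @rdname DrugLibrary-class
#' @export
setMethod("goFingerprints", "DrugLibrary", function(x) x@goFingerprint)

#' @rdname NetworkBundle-class
#' @export
setMethod("backgroundGraph", "NetworkBundle", function(x) x@graph)

#' @rdname NetworkBundle-class
#' @export
setMethod("cnNodes", "NetworkBundle", function(x) x@cnNodes)

#' @rdname NetworkBundle-class
#' @export
setMethod("ncnNodes", "NetworkBundle", function(x) {
  setdiff(igraph::V(x@graph)$name, x@cnNodes)
})

#' @rdname NetworkBundle-class
#' @export
setMethod("cnGraph", "NetworkBundle", function(x) {
  igraph::induced_subgraph(x@graph, x@cnNodes)
})

#' @rdname PairFeatureMatrix-class
#' @export
setMethod("featureValues", "PairFeatureMatrix", function(x) x@features)

#' @rdname PairFeatureMatrix-class
#' @export
setMethod("pairLabels", "PairFeatureMatrix", function(x) x@label)

#' @rdname PairFeatureMatrix-class
#' @export
setMethod("pairIds", "PairFeatureMatrix", function(x) {
  paste(x@pairs$drug_a, x@pairs$drug_b, sep = "||")
})

#' @rdname RankedList-class
#' @export
setMethod("rankedEntries", "RankedList", function(x) x@entries)

#' @rdname RankedList-class
#' @export
setMethod("rankingStage", "RankedList", function(x) x@stage)

## show methods ---------------------------------------------------------------

setMethod("show", "DrugLibrary", function(object) {
  nDeg <- sum(!vapply(object@degSets, is.null, logical(1)))
  cat(sprintf(
    "DrugLibrary: %d drugs, %d GO terms, %d with DEG profiles\n",
    length(object@drugIds), ncol(object@goFingerprint), nDeg
  ))
})

setMethod("show", "NetworkBundle", function(object) {
  cat(sprintf(
    "NetworkBundle: %d nodes, %d edges; CN %d nodes, NCN %d nodes\n",
    igraph::vcount(object@graph), igraph::ecount(object@graph),
    length(object@cnNodes),
    igraph::vcount(object@graph) - length(object@cnNodes)
  ))
})

setMethod("show", "PairFeatureMatrix", function(object) {
  cat(sprintf(
    "PairFeatureMatrix: %d pairs (%d labelled) x %d features%s\n",
    nrow(object@pairs), sum(object@label == "labelled"),
    ncol(object@features),
    if (isTRUE(object@normalized)) " [normalized]" else ""
  ))
})

setMethod("show", "RankedList", function(object) {
  cat(sprintf(
    "RankedList (stage=%s): %d pairs\n", object@stage,
    nrow(object@entries)
  ))
  if (nrow(object@entries)) {
    print(utils::head(object@entries, 5))
    if (nrow(object@entries) > 5) cat("...\n")
  }
})
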