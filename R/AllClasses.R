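#' @import methods
NULL

#' DrugLibrary: per-drug targets and annotations
#'
#' Container for the per-drug information the ranking system consumes: the
#' target protein set, a binary fingerprint over a fixed universe of
#' cancer-related GO biological-process terms, the set of pathways hit by at
#' least one target, and (optionally) the differentially-expressed-gene set
#' induced by single-drug treatment.
#'
#' @slot drugIds Character vector of drug identifiers (unique).
#' @slot targets Named list of character vectors; protein targets per drug.
#' @slot goFingerprint Integer 0/1 matrix, drugs x GO terms. Column names
#'   are the term universe, fixed across all drugs.
#' @slot pathways Named list of character vectors; pathway ids per drug.
#' @slot degSets Named list; per-drug DEG sets, entries may be `NULL` when
#'   no expression profile is available (such drugs bypass the secondary
#'   expression filter).
#'
#' @seealso [drugLibrary()] for the constructor, [simulateDrugLibrary()]
#'   for synthetic libraries.
#' @export
setClass("DrugLibrary",
  representation(
    drugIds = "character",
    targets = "list",
    goFingerprint = "matrix",
    pathways = "list",
    degSets = "list"
  )
)

setValidity("DrugLibrary", function(object) {
  msg <- character()
  ids <- object@drugIds
  if (anyDuplicated(ids)) msg <- c(msg, "drug ids must be unique")
  for (slotName in c("targets", "pathways", "degSets")) {
    s <- slot(object, slotName)
    if (!identical(names(s), ids)) {
      msg <- c(msg, sprintf("names of @%s must equal @drugIds", slotName))
    }
  }
  fp <- object@goFingerprint
  if (nrow(fp) != length(ids) || !identical(rownames(fp), ids)) {
    msg <- c(msg, "@goFingerprint rows must match @drugIds")
  }
  if (length(fp) && !all(fp %in% c(0L, 1L))) {
    msg <- c(msg, "@goFingerprint must be binary")
  }
  if (length(msg)) msg else TRUE
})

#' NetworkBundle: background PPI graph plus cancer-network annotation
#'
#' Holds the undirected background protein-protein-interaction graph, the
#' designated cancer-network (CN) node subset, and centralities precomputed
#' on the two scopes the efficacy features use: the CN-induced subgraph for
#' CN nodes and the full background graph otherwise.
#'
#' @slot graph An [igraph::igraph] object; simple (no loops or multi-edges),
#'   undirected, nodes named by protein identifier.
#' @slot cnNodes Character vector, subset of the graph's nodes.
#' @slot centralities List with elements `background` and `cn`, each a list
#'   of named numeric vectors `degree`, `betweenness`, `eigenvector`.
#'
#' @seealso [networkBundle()], [efficacyWeights()]
#' @export
setClass("NetworkBundle",
  representation(
    graph = "ANY",
    cnNodes = "character",
    centralities = "list"
  )
)

setValidity("NetworkBundle", function(object) {
  g <- object@graph
  msg <- character()
  if (!igraph::is_igraph(g)) return("@graph must be an igraph object")
  if (igraph::is_directed(g)) msg <- c(msg, "@graph must be undirected")
  if (any(igraph::which_loop(g)) || any(igraph::which_multiple(g))) {
    msg <- c(msg, "@graph must be simple (no self-loops, no multi-edges)")
  }
  if (is.null(igraph::V(g)$name)) msg <- c(msg, "@graph nodes must be named")
  if (!all(object@cnNodes %in% igraph::V(g)$name)) {
    msg <- c(msg, "@cnNodes must be a subset of the graph's nodes")
  }
  if (anyDuplicated(object@cnNodes)) msg <- c(msg, "@cnNodes must be unique")
  if (length(msg)) msg else TRUE
})

#' PairFeatureMatrix: drug pairs by network/annotation features
#'
#' A matrix of per-pair feature values (columns MI, Dis, DCI, Eff.D, Eff.B,
#' Eff.E, MP.U by default) with a labelled/unlabelled indicator per row.
#' After min-max normalization the observed bounds are retained so the same
#' scaling can be reapplied.
#'
#' @slot pairs data.frame with columns `drug_a`, `drug_b` (canonical order).
#' @slot features Numeric matrix, one row per pair.
#' @slot label Character vector, `"labelled"` or `"unlabelled"` per row.
#' @slot normalized Logical scalar; if `TRUE` all entries lie in [0, 1].
#' @slot bounds Numeric matrix (2 x n_features, rows `min`/`max`) storing
#'   the pooled normalization bounds, or a 0 x 0 matrix before
#'   normalization.
#' @export
setClass("PairFeatureMatrix",
  representation(
    pairs = "data.frame",
    features = "matrix",
    label = "character",
    normalized = "logical",
    bounds = "matrix"
  )
)

setValidity("PairFeatureMatrix", function(object) {
  msg <- character()
  n <- nrow(object@pairs)
  if (!all(c("drug_a", "drug_b") %in% names(object@pairs))) {
    msg <- c(msg, "@pairs needs drug_a, drug_b columns")
  } else if (any(object@pairs$drug_a > object@pairs$drug_b)) {
    msg <- c(msg, "@pairs must be in canonical (lexicographic) order")
  }
  if (nrow(object@features) != n) msg <- c(msg, "feature rows != pairs")
  if (length(object@label) != n) msg <- c(msg, "label length != pairs")
  if (!all(object@label %in% c("labelled", "unlabelled"))) {
    msg <- c(msg, "labels must be 'labelled' or 'unlabelled'")
  }
  if (any(!is.finite(object@features))) {
    msg <- c(msg, "feature values must be finite")
  }
  if (isTRUE(object@normalized) && length(object@features) &&
      (min(object@features) < 0 || max(object@features) > 1)) {
    msg <- c(msg, "normalized features must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' RankedList: an ordered list of scored drug pairs
#'
#' The output of each ranking stage. Ranks run 1..n without gaps, scores are
#' non-increasing with rank, and bait (labelled) pairs have already been
#' removed.
#'
#' @slot entries data.frame with columns `drug_a`, `drug_b`, `score`,
#'   `rank`, `flag` (filter provenance: `""`, `"pass"` or
#'   `"single_profile"`).
#' @slot stage One of `"preliminary"`, `"consensus"`, `"filtered"`.
#' @slot config List snapshot of the parameters and seeds that produced the
#'   list.
#' @export
setClass("RankedList",
  representation(
    entries = "data.frame",
    stage = "character",
    config = "list"
  )
)

setValidity("RankedList", function(object) {
  msg <- character()
  e <- object@entries
  need <- c("drug_a", "drug_b", "score", "rank", "flag")
  if (!all(need %in% names(e))) {
    return(paste("entries needs columns:", paste(need, collapse = ", ")))
  }
  if (nrow(e)) {
    if (!identical(as.integer(e$rank), seq_len(nrow(e)))) {
      msg <- c(msg, "ranks must be 1..n in order")
    }
    if (is.unsorted(rev(e$score))) {
      msg <- c(msg, "scores must be non-increasing with rank")
    }
    if (any(e$drug_a > e$drug_b)) {
      msg <- c(msg, "pairs must be canonical")
    }
  }
  if (length(object@stage) != 1L ||
      !object@stage %in% c("preliminary", "consensus", "filtered")) {
    msg <- c(msg, "stage must be preliminary/consensus/filtered")
  }
  if (length(msg)) msg else TRUE
})
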