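# Secondary transcriptomic filtering: DEG overlap and cancer-pathway
# coverage with right-tailed permutation p-values.

#' Expression context for the secondary filter
#'
#' @param degSets Named list of per-drug DEG sets (character vectors);
#'   entries may be `NULL`.
#' @param geneUniverse Character vector of genes eligible for permutation
#'   draws (must contain every DEG set).
#' @param cancerPathwayGenes Nonempty character vector: the genes of the
#'   specific cancer pathway (the coverage denominator N).
#' @param nPermutations Number of permutation draws, >= 100 (default 1000).
#' @param seed Integer seed for the permutation draws.
#' @param alphaLevel Significance level for both filters (default 0.05).
#' @return A list of class `ExpressionContext`.
#' @export
expressionContext <- function(degSets, geneUniverse, cancerPathwayGenes,
                              nPermutations = 1000L, seed = 1L,
                              alphaLevel = 0.05) {
  geneUniverse <- unique(as.character(geneUniverse))
  cancerPathwayGenes <- unique(as.character(cancerPathwayGenes))
  stopIfNot(length(cancerPathwayGenes) > 0L,
    "cancer pathway gene set must be nonempty")
  stopIfNot(nPermutations >= 100L, "need at least 100 permutations")
  present <- !vapply(degSets, is.null, logical(1))
  outside <- unlist(lapply(degSets[present], setdiff, y = geneUniverse))
  stopIfNot(length(outside) == 0L,
    "every DEG set must be contained in the gene universe")
  structure(
    list(
      degSets = degSets, geneUniverse = geneUniverse,
      cancerPathwayGenes = cancerPathwayGenes,
      nPermutations = as.integer(nPermutations),
      seed = as.integer(seed), alphaLevel = alphaLevel
    ),
    class = "ExpressionContext"
  )
}

#' DEG overlap of two gene sets (Jaccard index)
#'
#' `|A n B| / |A u B|`; symmetric, in [0, 1].
#'
#' @param A,B Nonempty character vectors of genes.
#' @return A single numeric value.
#' @examples
#' degOverlap(c("g1", "g2", "g3"), c("g2", "g3", "g4"))
#' @export
degOverlap <- function(A, B) {
  A <- unique(A)
  B <- unique(B)
  stopIfNot(length(A) > 0L && length(B) > 0L,
    "DEG overlap is undefined for empty sets")
  length(intersect(A, B)) / length(union(A, B))
}

#' Cancer-pathway coverage of a drug pair's DEGs
#'
#' `|(A u B) n N| / |N|`: the fraction of the cancer pathway's genes
#' perturbed by either drug. Symmetric in A and B, in [0, 1].
#'
#' @param A,B Character vectors of genes (DEG sets of the two drugs).
#' @param N Nonempty character vector: the cancer pathway's genes.
#' @return A single numeric value.
#' @export
pathwayCoverage <- function(A, B, N) {
  N <- unique(N)
  stopIfNot(length(N) > 0L, "pathway gene set N must be nonempty")
  length(intersect(union(A, B), N)) / length(N)
}

#' Right-tailed permutation p-value for a pair statistic
#'
#' Draws `nPermutations` random gene-set pairs of the same sizes as the
#' observed sets, uniformly without replacement from the gene universe,
#' recomputes the statistic, and returns the pseudo-count corrected
#' p-value `(1 + #(null >= observed)) / (n + 1)`.
#'
#' @param observed Observed statistic value.
#' @param statistic `"deg_overlap"` or `"pathway_coverage"`.
#' @param sizeA,sizeB Sizes of the two observed gene sets.
#' @param context An [expressionContext()].
#' @param seed Seed for this call (default: the context's seed).
#' @return p-value in `[1/(n+1), 1]`.
#' @export
permutationPValue <- function(observed,
                              statistic = c("deg_overlap",
                                            "pathway_coverage"),
                              sizeA, sizeB, context,
                              seed = context$seed) {
  statistic <- match.arg(statistic)
  g <- context$geneUniverse
  stopIfNot(sizeA >= 1L && sizeB >= 1L, "set sizes must be positive")
  stopIfNot(sizeA <= length(g) && sizeB <= length(g),
    "set sizes exceed the gene universe")
  n <- context$nPermutations
  stat <- switch(statistic,
    deg_overlap = function(a, b) degOverlap(a, b),
    pathway_coverage = function(a, b) {
      pathwayCoverage(a, b, context$cancerPathwayGenes)
    }
  )
  null <- withSeed(seed, vapply(seq_len(n), function(i) {
    stat(sample(g, sizeA), sample(g, sizeB))
  }, numeric(1)))
  (1 + sum(null >= observed)) / (n + 1)
}

#' Apply the transcriptomic filters to a consensus ranking
#'
#' Pairs for which both drugs have a DEG profile are retained only when
#' the permutation p-values of both DEG overlap and cancer-pathway
#' coverage fall below `context$alphaLevel`; pairs with at most one
#' profile are retained unchanged and flagged `"single_profile"`. The
#' relative order of survivors is preserved.
#'
#' @param consensus A [RankedList-class] (any stage).
#' @param context An [expressionContext()].
#' @return A [RankedList-class] with `stage = "filtered"`; the config
#'   carries a per-pair table of statistics and p-values.
#' @export
applyExpressionFilters <- function(consensus, context) {
  e <- rankedEntries(consensus)
  stopIfNot(nrow(e) > 0L, "consensus list is empty")
  stats <- data.frame(
    drug_a = e$drug_a, drug_b = e$drug_b,
    deg_overlap = NA_real_, p_overlap = NA_real_,
    pathway_coverage = NA_real_, p_coverage = NA_real_,
    flag = "", stringsAsFactors = FALSE
  )
  keep <- logical(nrow(e))
  for (i in seq_len(nrow(e))) {
    A <- context$degSets[[e$drug_a[i]]]
    B <- context$degSets[[e$drug_b[i]]]
    if (is.null(A) || is.null(B) || !length(A) || !length(B)) {
      keep[i] <- TRUE
      stats$flag[i] <- "single_profile"
      next
    }
    ov <- degOverlap(A, B)
    cv <- pathwayCoverage(A, B, context$cancerPathwayGenes)
    pOv <- permutationPValue(ov, "deg_overlap", length(unique(A)),
      length(unique(B)), context, seed = context$seed + 2L * i)
    pCv <- permutationPValue(cv, "pathway_coverage", length(unique(A)),
      length(unique(B)), context, seed = context$seed + 2L * i + 1L)
    stats$deg_overlap[i] <- ov
    stats$p_overlap[i] <- pOv
    stats$pathway_coverage[i] <- cv
    stats$p_coverage[i] <- pCv
    keep[i] <- pOv < context$alphaLevel && pCv < context$alphaLevel
    stats$flag[i] <- if (keep[i]) "pass" else "removed"
  }
  surv <- which(keep)
  entries <- data.frame(
    drug_a = e$drug_a[surv], drug_b = e$drug_b[surv],
    score = e$score[surv], rank = seq_along(surv),
    flag = stats$flag[surv], stringsAsFactors = FALSE
  )
  cfg <- consensus@config
  cfg$filterStats <- stats
  cfg$alphaLevel <- context$alphaLevel
  cfg$nPermutations <- context$nPermutations
  new("RankedList", entries = entries, stage = "filtered", config = cfg)
}
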