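# End-to-end orchestration: config, input loading, pair enumeration, and
# the full rank -> consensus -> filter pipeline.

#' Default pipeline parameters
#'
#' Every tunable of the pipeline with its default: `lambda` (efficacy
#' penalty, 0.1), `alpha` (manifold diffusion, 0.99), `kernel_width`
#' (`NULL` = median heuristic), `z_threshold` (feature screen, 3),
#' `feature_screen` (TRUE), `n_runs` (30), `bait_fractions`
#' (50%..100%), `top_fraction` (0.01), `quorum` (1), `n_permutations`
#' (1000), `alpha_level` (0.05), `filtering` (TRUE), `seed` (1).
#'
#' @return Named list of defaults.
#' @export
racsDefaultParams <- function() {
  list(
    lambda = 0.1,
    alpha = 0.99,
    kernel_width = NULL,
    knn = 7L,
    z_threshold = 3,
    feature_screen = TRUE,
    n_runs = 30L,
    bait_fractions = seq(0.5, 1, by = 0.1),
    top_fraction = 0.01,
    quorum = 1,
    n_permutations = 1000L,
    alpha_level = 0.05,
    filtering = TRUE,
    seed = 1L
  )
}

#' Enumerate the unlabelled drug pairs
#'
#' All C(n, 2) unordered pairs of the drug universe minus the positive
#' (labelled) pairs, canonicalized and in deterministic lexicographic
#' order. Positive pairs referencing drugs outside the universe are
#' ignored with a warning.
#'
#' @param drugIds Character vector of >= 2 drug identifiers.
#' @param positivePairs data.frame with columns `drug_a`, `drug_b` (may
#'   be empty or `NULL`).
#' @return data.frame of unlabelled pairs (`drug_a`, `drug_b`).
#' @examples
#' enumerateUnlabelledPairs(c("a", "b", "c"),
#'   data.frame(drug_a = "a", drug_b = "b"))
#' @export
enumerateUnlabelledPairs <- function(drugIds, positivePairs = NULL) {
  drugIds <- unique(as.character(drugIds))
  stopIfNot(length(drugIds) >= 2L, "need at least 2 drugs")
  cmb <- utils::combn(sort(drugIds), 2L)
  all <- canonicalPairs(cmb[1L, ], cmb[2L, ])
  allKeys <- pairKey(all$drug_a, all$drug_b)
  if (!is.null(positivePairs) && nrow(positivePairs)) {
    pos <- canonicalPairs(positivePairs$drug_a, positivePairs$drug_b)
    inUniverse <- pos$drug_a %in% drugIds & pos$drug_b %in% drugIds
    if (any(!inUniverse)) {
      warning(sprintf(
        "%d positive pair(s) reference unknown drugs and are ignored",
        sum(!inUniverse)
      ), call. = FALSE)
    }
    posKeys <- pairKey(pos$drug_a[inUniverse], pos$drug_b[inUniverse])
    all <- all[!allKeys %in% posKeys, , drop = FALSE]
  }
  rownames(all) <- NULL
  all
}

#' Read a pipeline config file
#'
#' YAML with an `inputs` block of file paths (relative paths resolved
#' against the config's directory) and top-level parameters merged over
#' [racsDefaultParams()].
#'
#' @param path Config file path.
#' @return List with elements `inputs` (absolute paths) and the merged
#'   parameters.
#' @export
readRacsConfig <- function(path) {
  if (!file.exists(path)) {
    stop(paste("config file not found:", path), call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  merged <- utils::modifyList(racsDefaultParams(), cfg, keep.null = TRUE)
  base <- dirname(normalizePath(path))
  merged$inputs <- lapply(merged$inputs, function(f) {
    if (!grepl("^(/|[A-Za-z]:)", f)) file.path(base, f) else f
  })
  merged
}

#' Load and cross-link all pipeline inputs
#'
#' Reads every file named by the config, builds the [DrugLibrary-class]
#' and [NetworkBundle-class], attaches DEG sets, and warns about drugs
#' whose targets all fall outside the background graph (their distance
#' feature would be undefined). Drugs with zero targets are excluded with
#' a warning; a missing file is fatal.
#'
#' @param config A config path or the list returned by
#'   [readRacsConfig()].
#' @return List with `library`, `bundle`, `relations`, `positivePairs`,
#'   `expression` (an [expressionContext()] or `NULL`), `params`.
#' @export
loadRacsInputs <- function(config) {
  if (is.character(config)) config <- readRacsConfig(config)
  ins <- config$inputs
  stopIfNot(!is.null(ins), "config has no inputs block")
  targets <- readDrugTargets(ins$drug_targets)
  graph <- readEdgeList(ins$network)
  cn <- readNodeList(ins$cn_nodes)
  goSets <- readGmt(ins$go_terms)
  pwSets <- readGmt(ins$pathways)
  relations <- if (!is.null(ins$pathway_relations)) {
    readPathwayRelations(ins$pathway_relations)
  } else {
    NULL
  }
  positives <- readPairs(ins$positive_pairs)
  degSets <- if (!is.null(ins$deg_sets)) readGmt(ins$deg_sets) else list()

  lib <- drugLibrary(targets, goSets, pwSets, degSets)
  bundle <- networkBundle(graph, cn)

  nodes <- igraph::V(backgroundGraph(bundle))$name
  unmapped <- vapply(
    drugIds(lib),
    function(d) !any(targetsOf(lib, d) %in% nodes), logical(1)
  )
  if (any(unmapped)) {
    warning(sprintf(
      "drug(s) with no target on the background graph: %s",
      paste(drugIds(lib)[unmapped], collapse = ", ")
    ), call. = FALSE)
  }

  expression <- NULL
  if (!is.null(ins$deg_sets) && !is.null(ins$cancer_pathway)) {
    cp <- readGmt(ins$cancer_pathway)[[1L]]
    universe <- if (!is.null(ins$gene_universe)) {
      readNodeList(ins$gene_universe)
    } else {
      # fallback: the measured universe is at least everything observed
      present <- lib@degSets[!vapply(lib@degSets, is.null, logical(1))]
      unique(c(unlist(present), cp))
    }
    expression <- expressionContext(
      lib@degSets, universe, cp,
      nPermutations = config$n_permutations,
      seed = config$seed, alphaLevel = config$alpha_level
    )
  }
  list(
    library = lib, bundle = bundle, relations = relations,
    positivePairs = positives, expression = expression, params = config
  )
}

#' Run the full two-stage ranking pipeline
#'
#' Feature computation over all bait + unlabelled pairs, min-max
#' normalization, Z-score feature screen, ensemble manifold ranking over
#' bait subsamples, top-fraction consistency + footrule consensus, and
#' (when expression data are available and `filtering` is enabled) the
#' transcriptomic secondary filter. Deterministic for a fixed config and
#' seed.
#'
#' @param config A config path, a [readRacsConfig()] list, or the loaded
#'   inputs from [loadRacsInputs()].
#' @param outDir Optional directory; when given, the final ranking
#'   (`ranking.tsv`) and a run manifest (`manifest.yaml`) are written.
#' @return The final [RankedList-class] (stage `"filtered"`, or
#'   `"consensus"` when filtering is disabled or no expression data are
#'   present).
#' @export
runRacs <- function(config, outDir = NULL) {
  inp <- if (is.list(config) && !is.null(config$library)) {
    config
  } else {
    loadRacsInputs(config)
  }
  par <- inp$params
  lib <- inp$library
  pos <- canonicalPairs(inp$positivePairs$drug_a, inp$positivePairs$drug_b)
  inLib <- pos$drug_a %in% drugIds(lib) & pos$drug_b %in% drugIds(lib)
  pos <- pos[inLib, , drop = FALSE]
  un <- enumerateUnlabelledPairs(drugIds(lib), pos)
  pairs <- rbind(pos, un)
  labels <- rep(c("labelled", "unlabelled"), c(nrow(pos), nrow(un)))

  fm <- computePairFeatures(lib, inp$bundle, pairs, labels,
    relations = inp$relations, lambda = par$lambda)
  stopIfNot(sum(fm@label == "labelled") >= 1L,
    "no positive pair survives feature computation")
  fm <- minMaxNormalize(fm)

  screen <- NULL
  if (isTRUE(par$feature_screen) &&
      sum(fm@label == "labelled") >= 2L &&
      sum(fm@label == "unlabelled") >= 2L) {
    screen <- zScoreScreen(fm, threshold = par$z_threshold)
    if (any(screen$selected)) {
      fm <- selectFeatures(fm, screen$feature[screen$selected])
    } else {
      warning("no feature passed the Z-score screen; keeping all",
        call. = FALSE)
    }
  }

  spec <- ensembleSpec(
    nRuns = par$n_runs, baitFractions = par$bait_fractions,
    topFraction = par$top_fraction, quorum = par$quorum,
    masterSeed = par$seed
  )
  runs <- runEnsemble(fm, spec, alpha = par$alpha,
    kernelWidth = par$kernel_width, knn = par$knn)
  survivors <- consistentTop(runs, spec$topFraction, spec$quorum)
  consensus <- footruleConsensus(runs, survivors)

  final <- consensus
  if (isTRUE(par$filtering) && !is.null(inp$expression) &&
      nrow(rankedEntries(consensus))) {
    final <- applyExpressionFilters(consensus, inp$expression)
  }
  final@config$params <- par[setdiff(names(par), "inputs")]
  final@config$featureScreen <- screen
  final@config$nBait <- nrow(pos)
  final@config$nUnlabelled <- nrow(un)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeRanking(final, file.path(outDir, "ranking.tsv"))
    manifest <- list(
      stage = rankingStage(final),
      n_pairs = nrow(rankedEntries(final)),
      n_bait = nrow(pos),
      n_unlabelled = nrow(un),
      features_used = colnames(fm@features),
      params = lapply(
        par[setdiff(names(par), "inputs")],
        function(x) if (is.null(x)) "median-heuristic" else x
      )
    )
    yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  }
  final
}
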