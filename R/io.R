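# Readers and writers for the plain-text interchange formats: 2-column
# TSV drug-target tables, edge lists (SIF-compatible), GMT gene sets,
# pair tables, pathway-relation tables, rankings, and the YAML config.

readTsvChecked <- function(path, nCols, what) {
  if (!file.exists(path)) {
    stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < nCols)
  if (length(bad)) {
    stop(sprintf(
      "malformed %s line %d in %s: expected >= %d tab-separated fields",
      what, bad[1L], path, nCols
    ), call. = FALSE)
  }
  fields
}

#' Read a drug-target table
#'
#' 2-column TSV, one `drug_id<TAB>target_id` row per target.
#'
#' @param path File path.
#' @return Named list of character vectors (targets per drug).
#' @export
readDrugTargets <- function(path) {
  f <- readTsvChecked(path, 2L, "drug-target")
  drug <- vapply(f, `[[`, character(1), 1L)
  target <- vapply(f, `[[`, character(1), 2L)
  split(target, factor(drug, levels = unique(drug)))
}

#' Read a network edge list
#'
#' 2-column TSV edge list; 3-column SIF (`node<TAB>type<TAB>node`) is
#' accepted, with the interaction type ignored.
#'
#' @param path File path.
#' @return An undirected, simplified [igraph::igraph].
#' @export
readEdgeList <- function(path) {
  f <- readTsvChecked(path, 2L, "edge-list")
  n <- vapply(f, length, integer(1))
  a <- vapply(f, `[[`, character(1), 1L)
  b <- mapply(function(x, k) x[[if (k >= 3L) 3L else 2L]], f, n)
  igraph::simplify(igraph::graph_from_data_frame(
    data.frame(a = a, b = as.character(b)), directed = FALSE
  ))
}

#' Read a one-identifier-per-line node list
#'
#' @param path File path.
#' @return Character vector of identifiers.
#' @export
readNodeList <- function(path) {
  if (!file.exists(path)) {
    stop(paste("node-list file not found:", path), call. = FALSE)
  }
  lines <- trimws(readLines(path, warn = FALSE))
  unique(lines[nzchar(lines) & !startsWith(lines, "#")])
}

#' Read / write gene sets in GMT format
#'
#' One record per line: `set_id<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path File path.
#' @return For `readGmt`, a named list of character vectors.
#' @export
readGmt <- function(path) {
  f <- readTsvChecked(path, 3L, "GMT")
  sets <- lapply(f, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(f, `[[`, character(1), 1L)
  sets
}

#' @rdname readGmt
#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector of per-set descriptions.
#' @export
writeGmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Read / write drug-pair tables
#'
#' TSV with columns `drug_a`, `drug_b` (header optional on read); pairs
#' are canonicalized.
#'
#' @param path File path.
#' @return data.frame with columns `drug_a`, `drug_b`.
#' @export
readPairs <- function(path) {
  f <- readTsvChecked(path, 2L, "pair")
  a <- vapply(f, `[[`, character(1), 1L)
  b <- vapply(f, `[[`, character(1), 2L)
  if (length(a) && a[1L] == "drug_a") {
    a <- a[-1L]
    b <- b[-1L]
  }
  unique(canonicalPairs(a, b))
}

#' Read a pathway-relation table
#'
#' 3-column TSV `pathway_a<TAB>pathway_b<TAB>relation` with relation in
#' identical / cross-talking / interacting / unrelated.
#'
#' @param path File path.
#' @return A [pathwayRelations()] table.
#' @export
readPathwayRelations <- function(path) {
  f <- readTsvChecked(path, 3L, "pathway-relation")
  pathwayRelations(
    vapply(f, `[[`, character(1), 1L),
    vapply(f, `[[`, character(1), 2L),
    vapply(f, `[[`, character(1), 3L)
  )
}

#' Write / read a RankedList as TSV
#'
#' Columns `drug_a`, `drug_b`, `score`, `rank`, `flag`, plus a `# stage:`
#' header comment. Scores are written at full double precision so that
#' the write/read round trip reproduces the entries exactly.
#'
#' @param rl A [RankedList-class].
#' @param path File path.
#' @export
writeRanking <- function(rl, path) {
  e <- rankedEntries(rl)
  lines <- c(
    paste0("# stage: ", rankingStage(rl)),
    "drug_a\tdrug_b\tscore\trank\tflag",
    sprintf(
      "%s\t%s\t%.17g\t%d\t%s", e$drug_a, e$drug_b, e$score, e$rank,
      e$flag
    )
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeRanking
#' @export
readRanking <- function(path) {
  if (!file.exists(path)) {
    stop(paste("ranking file not found:", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  stage <- "preliminary"
  sl <- grep("^# stage: ", lines, value = TRUE)
  if (length(sl)) stage <- sub("^# stage: ", "", sl[1L])
  lines <- lines[!startsWith(lines, "#")]
  stopIfNot(length(lines) >= 1L, "empty ranking file")
  f <- strsplit(lines[-1L], "\t", fixed = TRUE)
  entries <- data.frame(
    drug_a = vapply(f, `[[`, character(1), 1L),
    drug_b = vapply(f, `[[`, character(1), 2L),
    score = as.numeric(vapply(f, `[[`, character(1), 3L)),
    rank = as.integer(vapply(f, `[[`, character(1), 4L)),
    flag = vapply(f, function(x) {
      if (length(x) >= 5L) x[[5L]] else ""
    }, character(1)),
    stringsAsFactors = FALSE
  )
  new("RankedList", entries = entries, stage = stage, config = list())
}

#' Write a full set of pipeline inputs plus config to a directory
#'
#' Materializes a simulated study (network, CN membership, drug targets,
#' GO/pathway gene sets, pathway relations, positive pairs, DEG sets,
#' cancer-pathway gene set) as the standard plain-text formats, together
#' with a `config.yaml` pointing at them — directly consumable by
#' [runRacs()].
#'
#' @param dir Output directory (created if absent).
#' @param nProteins,nCn,nDrugs,seed Passed to the simulators.
#' @param plantStrength,overlapBoost Planting strengths (see
#'   [simulateDrugLibrary()], [simulateExpressionProfiles()]).
#' @param params Named list of pipeline parameter overrides merged into
#'   the config (see [racsDefaultParams()]).
#' @return The config file path, invisibly.
#' @export
simulateRacsInputs <- function(dir, nProteins = 100L, nCn = 30L,
                               nDrugs = 18L, plantStrength = 0.9,
                               overlapBoost = 0.5, seed = 1L,
                               params = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- simulateNetworkBundle(nProteins, nCn, seed = seed)
  # cluster and bait sizes scale with the library so small studies
  # remain feasible (defaults: 8 of 18 drugs, 10 bait pairs)
  nSyn <- min(8L, max(3L, round(nDrugs * 0.45)))
  nPos <- max(1L, round(choose(nSyn, 2L) * 0.36))
  sim <- simulateDrugLibrary(bundle, nDrugs = nDrugs,
    nSynergyDrugs = nSyn, nPositives = nPos,
    plantStrength = plantStrength, seed = seed + 1L)
  lib <- sim$library
  expr <- simulateExpressionProfiles(
    drugIds(lib),
    plantedPairs = rbind(sim$positivePairs, sim$plantedUnlabelled),
    overlapBoost = overlapBoost, seed = seed + 2L
  )

  p <- function(f) file.path(dir, f)
  ed <- igraph::as_data_frame(backgroundGraph(bundle), what = "edges")
  writeLines(paste(ed$from, ed$to, sep = "\t"), p("network.tsv"))
  writeLines(cnNodes(bundle), p("cn_nodes.txt"))
  tg <- lib@targets
  writeLines(
    unlist(lapply(names(tg), function(d) paste(d, tg[[d]], sep = "\t"))),
    p("drug_targets.tsv")
  )
  writeGmt(sim$goTermSets, p("go_terms.gmt"))
  writeGmt(sim$pathwaySets, p("pathways.gmt"))
  rel <- sim$relations
  parts <- do.call(rbind, strsplit(rel$key, "||", fixed = TRUE))
  writeLines(
    paste(parts[, 1L], parts[, 2L], rel$relation, sep = "\t"),
    p("pathway_relations.tsv")
  )
  pp <- sim$positivePairs
  writeLines(
    c("drug_a\tdrug_b", paste(pp$drug_a, pp$drug_b, sep = "\t")),
    p("positive_pairs.tsv")
  )
  writeGmt(expr$degSets, p("deg_sets.gmt"))
  writeGmt(
    list(cancer_pathway = expr$cancerPathwayGenes),
    p("cancer_pathway.gmt")
  )
  writeLines(expr$geneUniverse, p("gene_universe.txt"))
  pu <- sim$plantedUnlabelled
  writeLines(
    c("drug_a\tdrug_b", paste(pu$drug_a, pu$drug_b, sep = "\t")),
    p("planted_unlabelled.tsv")
  )

  cfg <- utils::modifyList(racsDefaultParams(), params)
  cfg$inputs <- list(
    drug_targets = "drug_targets.tsv",
    network = "network.tsv",
    cn_nodes = "cn_nodes.txt",
    go_terms = "go_terms.gmt",
    pathways = "pathways.gmt",
    pathway_relations = "pathway_relations.tsv",
    positive_pairs = "positive_pairs.tsv",
    deg_sets = "deg_sets.gmt",
    cancer_pathway = "cancer_pathway.gmt",
    gene_universe = "gene_universe.txt"
  )
  yaml::write_yaml(cfg, p("config.yaml"))
  invisible(p("config.yaml"))
}
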