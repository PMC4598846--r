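# Seeded generators for every input the pipeline consumes, with plantable
# synergy structure so each stage has a known answer. Every generator is a
# pure function of its arguments plus the seed.

#' Simulate a background PPI network with an embedded cancer network
#'
#' Draws a preferential-attachment (scale-free) random graph — matching
#' the heavy-tailed degree distribution of real protein-interaction
#' networks, which matters for the betweenness/eigenvector efficacy
#' weights — and designates the cancer network as a connected
#' neighbourhood grown greedily (highest degree first) around the top
#' hub. The background graph is connected by construction.
#'
#' @param nProteins Number of proteins (>= 10); default 100.
#' @param nCn Cancer-network size (<= nProteins); default 30.
#' @param edgesPerNode Preferential-attachment edges added per node;
#'   default 2.
#' @param seed Integer seed.
#' @return A [NetworkBundle-class]; nodes are named `P1..Pn`.
#' @export
simulateNetworkBundle <- function(nProteins = 100L, nCn = 30L,
                                  edgesPerNode = 2L, seed = 1L) {
  stopIfNot(nProteins >= 10L, "need at least 10 proteins")
  stopIfNot(nCn >= 2L && nCn <= nProteins,
    "nCn must lie in 2..nProteins")
  g <- withSeed(seed, igraph::sample_pa(
    nProteins, power = 1, m = edgesPerNode, directed = FALSE
  ))
  igraph::V(g)$name <- paste0("P", seq_len(nProteins))
  if (nCn == nProteins) {
    cn <- igraph::V(g)$name
  } else {
    deg <- igraph::degree(g)
    cn <- names(which.max(deg))
    while (length(cn) < nCn) {
      adj <- igraph::adjacent_vertices(g, cn)
      nbr <- setdiff(unique(unlist(lapply(adj, names))), cn)
      cn <- c(cn, nbr[which.max(deg[nbr])])
    }
  }
  networkBundle(g, cn)
}

#' Simulate a drug library with planted synergistic pairs
#'
#' Assigns each drug a target set, GO-term gene sets, and pathway
#' memberships. A designated cluster of "synergy" drugs draws its targets
#' preferentially from cancer-network hubs and its pathways from a small
#' shared pool, so that pairs within the cluster concentrate in feature
#' space; pairs among them are declared positives (baits), the remainder
#' of the cluster pairs are recorded as planted-but-unlabelled — the known
#' answer for enrichment checks. `plantStrength = 0` turns the bias off,
#' making positives statistically indistinguishable from the rest (the
#' null fixture).
#'
#' @param bundle A [NetworkBundle-class].
#' @param nDrugs Number of drugs; default 18.
#' @param targetsPerDrug Targets per drug; default 3.
#' @param nGoTerms Size of the GO BP term universe; default 60.
#' @param nPathways Number of pathways; default 20.
#' @param nSynergyDrugs Size of the planted cluster; default 8.
#' @param nPositives Number of cluster pairs labelled positive (bait);
#'   default 10.
#' @param plantStrength Bias strength in [0, 1]; default 0.9.
#' @param seed Integer seed.
#' @return List with elements `library` ([DrugLibrary-class]),
#'   `positivePairs` (data.frame `drug_a`/`drug_b`), `plantedUnlabelled`
#'   (data.frame of cluster pairs left unlabelled), `relations`
#'   ([pathwayRelations()] table), `goTermSets`, `pathwaySets`.
#' @export
simulateDrugLibrary <- function(bundle, nDrugs = 18L, targetsPerDrug = 3L,
                                nGoTerms = 60L, nPathways = 20L,
                                nSynergyDrugs = 8L, nPositives = 10L,
                                plantStrength = 0.9, seed = 1L) {
  stopIfNot(nSynergyDrugs <= nDrugs, "cluster larger than library")
  stopIfNot(plantStrength >= 0 && plantStrength <= 1,
    "plantStrength must lie in [0, 1]")
  maxPos <- choose(nSynergyDrugs, 2L)
  stopIfNot(nPositives <= maxPos,
    "more positives requested than cluster pairs")
  withSeed(seed, {
    nodes <- igraph::V(backgroundGraph(bundle))$name
    cn <- cnNodes(bundle)
    deg <- igraph::degree(backgroundGraph(bundle))
    cnHubs <- cn[order(-deg[cn])][seq_len(max(3L, length(cn) %/% 3L))]

    drugs <- paste0("D", formatC(seq_len(nDrugs), width = 2, flag = "0"))
    synDrugs <- drugs[seq_len(nSynergyDrugs)]
    targets <- lapply(drugs, function(d) {
      if (d %in% synDrugs) {
        nBias <- stats::rbinom(1L, targetsPerDrug, plantStrength)
        c(
          sample(cnHubs, min(nBias, length(cnHubs))),
          sample(nodes, targetsPerDrug - min(nBias, length(cnHubs)))
        )
      } else {
        sample(nodes, targetsPerDrug)
      }
    })
    names(targets) <- drugs
    targets <- lapply(targets, unique)

    goTermSets <- lapply(seq_len(nGoTerms), function(i) {
      sample(nodes, max(3L, round(length(nodes) * 0.08)))
    })
    names(goTermSets) <- paste0("GO", formatC(seq_len(nGoTerms),
      width = 4, flag = "0"))

    pathwaySets <- lapply(seq_len(nPathways), function(i) {
      sample(nodes, max(3L, round(length(nodes) * 0.1)))
    })
    names(pathwaySets) <- paste0("pw", formatC(seq_len(nPathways),
      width = 2, flag = "0"))
    # the planted cluster shares a pathway core: make a few pathways
    # contain all cluster targets
    if (plantStrength > 0) {
      core <- sample(names(pathwaySets), 3L)
      clusterTargets <- unique(unlist(targets[synDrugs]))
      for (p in core) {
        pathwaySets[[p]] <- unique(c(pathwaySets[[p]], clusterTargets))
      }
    }

    # random relation table over a subset of pathway pairs
    allPw <- t(utils::combn(names(pathwaySets), 2L))
    nRel <- max(1L, nrow(allPw) %/% 4L)
    pick <- sample(nrow(allPw), nRel)
    relations <- pathwayRelations(
      allPw[pick, 1L], allPw[pick, 2L],
      sample(c("cross-talking", "interacting"), nRel, replace = TRUE)
    )

    lib <- drugLibrary(targets, goTermSets, pathwaySets)

    clusterPairs <- canonicalPairs(
      utils::combn(synDrugs, 2L)[1L, ], utils::combn(synDrugs, 2L)[2L, ]
    )
    posIdx <- sample(nrow(clusterPairs), nPositives)
    list(
      library = lib,
      positivePairs = clusterPairs[posIdx, , drop = FALSE],
      plantedUnlabelled = clusterPairs[-posIdx, , drop = FALSE],
      relations = relations,
      goTermSets = goTermSets,
      pathwaySets = pathwaySets
    )
  })
}

#' Simulate per-drug DEG sets with planted between-drug overlap
#'
#' Each drug gets a random DEG set from the gene universe. For every
#' planted pair, a fraction `overlapBoost` of both sets is replaced by a
#' common draw from the designated cancer-pathway gene set, giving the
#' pair both an elevated Jaccard overlap and joint pathway coverage.
#' `overlapBoost = 0` leaves all sets independent (null model: the mean
#' pairwise overlap then matches the hypergeometric expectation).
#'
#' @param drugIds Character vector of drug identifiers.
#' @param nGenes Gene universe size (>= 10x degSetSize); default 1000.
#' @param degSetSize DEG set size per drug; default 50.
#' @param cancerPathwaySize Size of the cancer-pathway gene set N;
#'   default 100.
#' @param plantedPairs data.frame `drug_a`/`drug_b` of pairs to boost
#'   (may be empty).
#' @param overlapBoost Fraction in [0, 1] of each planted pair's sets
#'   forced to coincide; default 0.5.
#' @param seed Integer seed.
#' @return List with `degSets` (named list), `geneUniverse`,
#'   `cancerPathwayGenes`.
#' @export
simulateExpressionProfiles <- function(drugIds, nGenes = 1000L,
                                       degSetSize = 50L,
                                       cancerPathwaySize = 100L,
                                       plantedPairs = NULL,
                                       overlapBoost = 0.5, seed = 1L) {
  stopIfNot(nGenes >= 10L * degSetSize,
    "gene universe must be >= 10x the DEG set size")
  stopIfNot(overlapBoost >= 0 && overlapBoost <= 1,
    "overlapBoost must lie in [0, 1]")
  withSeed(seed, {
    genes <- paste0("G", formatC(seq_len(nGenes), width = 5, flag = "0"))
    N <- sample(genes, cancerPathwaySize)
    degSets <- lapply(drugIds, function(d) sample(genes, degSetSize))
    names(degSets) <- drugIds
    if (!is.null(plantedPairs) && nrow(plantedPairs) && overlapBoost > 0) {
      k <- min(round(overlapBoost * degSetSize), length(N))
      # drugs linked by planted pairs share one DEG core per connected
      # cluster (a per-pair core would be overwritten when a drug sits
      # in several planted pairs); the core is drawn from the cancer
      # pathway, giving both the overlap and the joint coverage signal
      pp <- plantedPairs[
        plantedPairs$drug_a %in% drugIds & plantedPairs$drug_b %in% drugIds,
        , drop = FALSE
      ]
      if (nrow(pp) && k > 0L) {
        g <- igraph::graph_from_data_frame(pp, directed = FALSE)
        comp <- igraph::components(g)
        for (ci in seq_len(comp$no)) {
          members <- names(comp$membership)[comp$membership == ci]
          core <- sample(N, k)
          for (d in members) {
            rest <- sample(setdiff(genes, core), degSetSize - k)
            degSets[[d]] <- c(core, rest)
          }
        }
      }
    }
    list(degSets = degSets, geneUniverse = genes, cancerPathwayGenes = N)
  })
}

# Loewe-additive fraction affected of a fixed-ratio mixture at total dose
# `total`, for two median-effect agents; solved by bisection on fa.
loeweFractionAffected <- function(total, w1, w2, DmX, mX, DmY, mY) {
  ciAt <- function(fa) {
    dx <- DmX * (fa / (1 - fa))^(1 / mX)
    dy <- DmY * (fa / (1 - fa))^(1 / mY)
    total * w1 / dx + total * w2 / dy
  }
  # ciAt is decreasing in fa; find fa with ciAt(fa) = 1
  stats::uniroot(function(fa) ciAt(fa) - 1,
    interval = c(1e-9, 1 - 1e-9), tol = 1e-12)$root
}

#' Simulate single-agent and fixed-ratio combination dose-response data
#'
#' Single-agent curves follow the median-effect equation exactly.
#' Combination curves at the four standard mixing ratios are built under
#' Loewe additivity and then shifted in potency by `potencyMultiplier`:
#' the combination at total dose T responds as the additive mixture would
#' at `T * potencyMultiplier`. A multiplier of 1 is therefore additive
#' ground truth (downstream CI = 1), a multiplier of 2 plants synergy
#' with CI = 0.5 when both agents share the same slope. Optional Gaussian
#' noise is added to the fractions affected (clipped to (0, 1)).
#'
#' @param DmX,mX,DmY,mY Median-effect parameters of the two agents.
#' @param potencyMultiplier Planted potency gain of the combination
#'   (>= 0, default 1 = additive).
#' @param ratios List of length-2 mixing ratios; default the four
#'   standard ratios 4:1, 3:2, 2:3, 1:4.
#' @param nDoses Concentration gradients per curve (default 6).
#' @param dilution Serial dilution factor between gradients (default 4).
#' @param noiseSd Gaussian noise SD on the fraction affected (default 0).
#' @param seed Integer seed (used only when `noiseSd > 0`).
#' @return List with `singleX`, `singleY` (data.frames `dose`, `fa`),
#'   `combos` (one data.frame per ratio, `dose` = total dose), `ratios`.
#' @export
simulateDoseResponse <- function(DmX, mX, DmY, mY,
                                 potencyMultiplier = 1,
                                 ratios = list(c(4, 1), c(3, 2),
                                               c(2, 3), c(1, 4)),
                                 nDoses = 6L, dilution = 4,
                                 noiseSd = 0, seed = 1L) {
  stopIfNot(DmX > 0 && DmY > 0 && mX > 0 && mY > 0,
    "median-effect parameters must be positive")
  stopIfNot(potencyMultiplier > 0, "potency multiplier must be positive")
  faOf <- function(D, Dm, m) {
    r <- (D / Dm)^m
    r / (1 + r)
  }
  doseGrid <- function(top) top / dilution^(seq_len(nDoses) - 1L)
  noisy <- function(fa) {
    if (noiseSd <= 0) return(fa)
    pmin(pmax(fa + stats::rnorm(length(fa), 0, noiseSd), 1e-4), 1 - 1e-4)
  }
  withSeed(seed, {
    dX <- doseGrid(4 * DmX)
    dY <- doseGrid(4 * DmY)
    singleX <- data.frame(dose = dX, fa = noisy(faOf(dX, DmX, mX)))
    singleY <- data.frame(dose = dY, fa = noisy(faOf(dY, DmY, mY)))
    combos <- lapply(ratios, function(rt) {
      w1 <- rt[1L] / sum(rt)
      w2 <- rt[2L] / sum(rt)
      top <- 4 * (w1 * DmX + w2 * DmY)
      total <- doseGrid(top)
      fa <- vapply(
        total * potencyMultiplier,
        loeweFractionAffected, numeric(1),
        w1 = w1, w2 = w2, DmX = DmX, mX = mX, DmY = DmY, mY = mY
      )
      data.frame(dose = total, fa = noisy(fa))
    })
    list(singleX = singleX, singleY = singleY, combos = combos,
         ratios = ratios)
  })
}

#' Combination-index profile of a simulated dose-response set
#'
#' Fits the median-effect model to each curve of a
#' [simulateDoseResponse()] output (or equivalently shaped data) and
#' returns the CI at each mixing ratio.
#'
#' @param drs Output of [simulateDoseResponse()].
#' @param effectLevel Effect level for the CI; default 0.5.
#' @return Numeric vector of CI values, one per ratio.
#' @export
doseResponseCI <- function(drs, effectLevel = 0.5) {
  fx <- medianEffectFit(drs$singleX$dose, drs$singleX$fa)
  fy <- medianEffectFit(drs$singleY$dose, drs$singleY$fa)
  vapply(seq_along(drs$combos), function(i) {
    fc <- medianEffectFit(drs$combos[[i]]$dose, drs$combos[[i]]$fa)
    combinationIndex(fx, fy, fc, drs$ratios[[i]],
      effectLevel = effectLevel)
  }, numeric(1))
}
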