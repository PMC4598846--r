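# The seven pair-level features, the Z-score screen and normalization.

test_that("GO fingerprints match a naive set-membership scan", {
  terms <- list(t1 = c("P1", "P2"), t2 = "P3", t3 = c("P1", "P9"),
    t4 = "P7", t5 = c("P2", "P3"))
  expect_equal(unname(goFingerprint(character(0), terms)), rep(0L, 5))
  expect_equal(unname(goFingerprint("P1", terms)), c(1L, 0L, 1L, 0L, 0L))
  set.seed(11)
  for (i in 1:10) {
    tg <- sample(paste0("P", 1:12), sample(1:4, 1))
    naive <- vapply(terms, function(g) {
      hit <- 0L
      for (t in tg) for (m in g) if (t == m) hit <- 1L
      hit
    }, integer(1))
    expect_identical(goFingerprint(tg, terms), naive)
  }
  expect_error(goFingerprint("P1", list()), "nonempty")
})

test_that("mutual information follows the pointwise formula and is symmetric", {
  # disjoint fingerprints: shared ratio 0, limit convention
  expect_equal(mutualInformation(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
  # 10 terms, P(x)=0.4, P(y)=0.5, 3 shared
  fx <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  fy <- c(1, 1, 1, 0, 1, 1, 0, 0, 0, 0)
  expect_equal(mutualInformation(fx, fy), 0.3 * log(1.5), tolerance = 1e-12)
  expect_equal(0.3 * log(1.5), 0.12164, tolerance = 1e-4)
  # negative when overlap is below independence
  fz <- c(1, 0, 0, 0, 1, 1, 1, 1, 0, 0)
  expect_lt(mutualInformation(fx, fz), 0)
  set.seed(7)
  for (i in 1:10) {
    a <- stats::rbinom(12, 1, 0.5)
    b <- stats::rbinom(12, 1, 0.5)
    expect_equal(mutualInformation(a, b), mutualInformation(b, a))
  }
  expect_error(mutualInformation(numeric(0), numeric(0)), "nonempty")
})

test_that("mean target distance reproduces the path-graph hand computation", {
  nb <- pathBundle()
  expect_equal(avgTargetDistance("A", "A", nb), 0)
  expect_equal(avgTargetDistance("A", c("C", "D"), nb), 2.5)
  expect_equal(
    avgTargetDistance(c("C", "D"), "A", nb),
    avgTargetDistance("A", c("C", "D"), nb)
  )
  expect_warning(v <- avgTargetDistance("Zz", "A", nb), "excluded")
  expect_true(is.na(v))
})

test_that("network efficiency equals pairwise-distance enumeration", {
  expect_equal(networkEfficiency(igraph::make_ring(3)), 1)
  path3 <- igraph::graph_from_data_frame(
    data.frame(a = c("A", "B"), b = c("B", "C")), directed = FALSE)
  expect_equal(networkEfficiency(path3), 4 / 3)
  for (n in c(2, 4, 6)) {
    expect_equal(networkEfficiency(igraph::make_full_graph(n)), 1)
  }
  expect_error(networkEfficiency(igraph::make_full_graph(1)), "2 nodes")
})

test_that("efficiency change under removal matches full recomputation", {
  nb <- pathBundle()
  cng <- cnGraph(nb) # path B-C-D
  expect_equal(deltaEfficiency(cng, c("A", "Zz")), 0) # outside CN
  expect_equal(deltaEfficiency(cng, "D"), deltaEfficiency(cng, c("D", "D")))
  # remove D: B-C remains, E goes from 4/3 to 1
  expect_equal(deltaEfficiency(cng, "D"), (1 - 4 / 3) / (4 / 3))
  # disconnection handled with the Dmax+1 convention, recomputed on the
  # perturbed graph: 5-node path, remove middle node
  p5 <- igraph::graph_from_data_frame(
    data.frame(a = c("n1", "n2", "n3", "n4"), b = c("n2", "n3", "n4", "n5")),
    directed = FALSE
  )
  e0 <- networkEfficiency(p5)
  # after removing n3: components {n1,n2},{n4,n5}; finite dists: 1,1 and
  # dmax=1 so unreachable pairs contribute 2
  eAfter <- (1 + 1 + 2 * 4) / 6
  expect_equal(deltaEfficiency(p5, "n3"), (eAfter - e0) / e0)
})

test_that("combination interference is the signed difference of changes", {
  nb <- pathBundle()
  cng <- cnGraph(nb)
  expect_equal(dci(cng, "A", "Zz"), 0) # both outside CN
  expect_equal(dci(cng, "D", "D"), -deltaEfficiency(cng, "D"))
  # enumeration on a 6-node CN
  set.seed(3)
  g6 <- igraph::graph_from_data_frame(
    data.frame(a = c("x1", "x1", "x2", "x3", "x4", "x5", "x2"),
               b = c("x2", "x3", "x3", "x4", "x5", "x6", "x6")),
    directed = FALSE
  )
  dEoracle <- function(remove) {
    nodes <- paste0("x", 1:6)
    ed <- igraph::as_data_frame(g6)
    eff <- function(keep) {
      d <- penalizeInf(bfsDistances(ed[ed$from %in% keep & ed$to %in% keep, ],
        keep))
      mean(d[upper.tri(d)])
    }
    (eff(setdiff(nodes, remove)) - eff(nodes)) / eff(nodes)
  }
  tX <- c("x1", "x6")
  tY <- "x4"
  expect_equal(
    dci(g6, tX, tY),
    dEoracle(union(tX, tY)) - dEoracle(tX) - dEoracle(tY),
    tolerance = 1e-12
  )
})

test_that("efficacy sums normalized centralities with the NCN penalty", {
  st <- randomStudy(21)
  nb <- st$bundle
  for (scheme in c("degree", "betweenness", "eigenvector")) {
    w <- efficacyWeights(nb, scheme, lambda = 0.1)
    expect_equal(sum(w$cn), 1, tolerance = 1e-12)
    expect_true(all(w$cn >= 0) && all(w$ncn >= 0))
    expect_equal(efficacy(character(0), character(0), w), 0)
    # single CN target at lambda 0 returns its own weight
    w0 <- efficacyWeights(nb, scheme, lambda = 0)
    tgt <- names(w$cn)[1]
    expect_equal(efficacy(tgt, character(0), w0), unname(w0$cn[tgt]))
    # hand-summed oracle on a random pair of target sets
    set.seed(31)
    tx <- sample(igraph::V(backgroundGraph(nb))$name, 4)
    ty <- sample(igraph::V(backgroundGraph(nb))$name, 3)
    tu <- union(tx, ty)
    hand <- 0
    for (t in tu) {
      if (t %in% names(w$cn)) hand <- hand + w$cn[[t]]
      if (t %in% names(w$ncn)) hand <- hand - 0.1 * w$ncn[[t]]
    }
    expect_equal(efficacy(tx, ty, w), hand, tolerance = 1e-12)
    # monotone: adding a CN target never decreases, an NCN target never
    # increases (lambda > 0)
    extraCn <- setdiff(names(w$cn), tu)[1]
    extraNcn <- setdiff(names(w$ncn), tu)[1]
    expect_gte(efficacy(c(tx, extraCn), ty, w), efficacy(tx, ty, w))
    expect_lte(efficacy(c(tx, extraNcn), ty, w), efficacy(tx, ty, w))
  }
  expect_error(efficacyWeights(nb, "degree", lambda = 2), "lambda")
})

test_that("unrelated-pathway fraction counts cross pairs correctly", {
  expect_equal(mpU("p1", "p1", NULL), 0) # identical singleton
  expect_equal(mpU("p1", "p2", NULL), 1) # empty table: default unrelated
  rel <- pathwayRelations(
    c("p1", "p2"), c("p2", "p3"), c("cross-talking", "interacting")
  )
  # Px={p1,p2}, Py={p2,p3}: pairs (p1,p2)=ct, (p1,p3)=unrel,
  # (p2,p2)=identical, (p2,p3)=int -> 1/4
  expect_equal(mpU(c("p1", "p2"), c("p2", "p3"), rel), 1 / 4)
  expect_equal(
    mpU(c("p1", "p2"), c("p2", "p3"), rel),
    mpU(c("p2", "p3"), c("p1", "p2"), rel)
  )
  expect_warning(v <- mpU(character(0), "p1", rel), "excluded")
  expect_true(is.na(v))
  # relation lookups are symmetric and (p,p) is always identical
  expect_equal(pathwayRelation(rel, "p2", "p1"), "cross-talking")
  expect_equal(pathwayRelation(rel, "p9", "p9"), "identical")
  expect_error(pathwayRelations("a", "b", "friendly"), "relations")
})

test_that("all seven features are symmetric and match brute-force oracles", {
  # deep property: <=30-node graphs, BFS distance oracle by hand
  for (seed in c(5, 17)) {
    st <- randomStudy(seed, nProteins = 30L)
    nb <- st$bundle
    lib <- st$sim$library
    ed <- igraph::as_data_frame(backgroundGraph(nb))
    nodes <- igraph::V(backgroundGraph(nb))$name
    dOracle <- penalizeInf(bfsDistances(ed, nodes))
    ids <- drugIds(lib)
    set.seed(seed)
    for (i in 1:5) {
      xy <- sample(ids, 2)
      tx <- intersect(targetsOf(lib, xy[1]), nodes)
      ty <- intersect(targetsOf(lib, xy[2]), nodes)
      expect_equal(
        avgTargetDistance(tx, ty, nb),
        mean(dOracle[tx, ty, drop = FALSE])
      )
      expect_equal(
        avgTargetDistance(tx, ty, nb), avgTargetDistance(ty, tx, nb)
      )
      fps <- goFingerprints(lib)
      expect_equal(
        mutualInformation(fps[xy[1], ], fps[xy[2], ]),
        mutualInformation(fps[xy[2], ], fps[xy[1], ])
      )
      cng <- cnGraph(nb)
      expect_equal(dci(cng, tx, ty), dci(cng, ty, tx))
      for (scheme in c("degree", "betweenness", "eigenvector")) {
        w <- efficacyWeights(nb, scheme)
        expect_equal(efficacy(tx, ty, w), efficacy(ty, tx, w))
      }
      px <- pathwaysOf(lib, xy[1])
      py <- pathwaysOf(lib, xy[2])
      if (length(px) && length(py)) {
        expect_equal(
          mpU(px, py, st$sim$relations), mpU(py, px, st$sim$relations)
        )
        expect_true(mpU(px, py, st$sim$relations) >= 0 &&
          mpU(px, py, st$sim$relations) <= 1)
      }
    }
    # CN efficiency against the oracle on the CN subgraph
    cnN <- cnNodes(nb)
    cnD <- penalizeInf(bfsDistances(
      ed[ed$from %in% cnN & ed$to %in% cnN, ], cnN
    ))
    expect_equal(networkEfficiency(cnGraph(nb)), mean(cnD[upper.tri(cnD)]))
  }
})

test_that("min-max normalization rescales to pooled [0,1] and is idempotent", {
  pairs <- canonicalPairs(c("a", "a", "b"), c("b", "c", "c"))
  fm <- new("PairFeatureMatrix",
    pairs = pairs,
    features = matrix(c(2, 4, 6, 0, 0.5, 1), ncol = 2,
      dimnames = list(NULL, c("u", "v"))),
    label = c("labelled", "unlabelled", "unlabelled"),
    normalized = FALSE, bounds = matrix(numeric(0), 0, 0)
  )
  nm <- minMaxNormalize(fm)
  expect_equal(unname(featureValues(nm)[, "u"]), c(0, 0.5, 1))
  expect_equal(unname(featureValues(nm)[, "v"]), c(0, 0.5, 1))
  expect_equal(featureValues(minMaxNormalize(nm)), featureValues(nm))
  expect_equal(unname(nm@bounds["min", "u"]), 2)
  # constant feature maps to 0 with warning
  fm2 <- fm
  fm2@features[, "v"] <- 5
  expect_warning(nm2 <- minMaxNormalize(fm2), "constant")
  expect_equal(unname(featureValues(nm2)[, "v"]), c(0, 0, 0))
})

test_that("Z-score screen uses the Welch standard error and the |Z|>3 rule", {
  mkFm <- function(L, U) {
    nL <- nrow(L)
    nU <- nrow(U)
    drugs <- c(paste0("l", seq_len(nL)), paste0("u", seq_len(nU)))
    pairs <- canonicalPairs(drugs, paste0(drugs, "x"))
    new("PairFeatureMatrix",
      pairs = pairs, features = rbind(L, U),
      label = rep(c("labelled", "unlabelled"), c(nL, nU)),
      normalized = TRUE, bounds = matrix(numeric(0), 0, 0)
    )
  }
  # identical group means: Z = 0, not selected
  L <- matrix(c(0.2, 0.4, 0.6), ncol = 1, dimnames = list(NULL, "f"))
  U <- matrix(c(0.2, 0.4, 0.6), ncol = 1, dimnames = list(NULL, "f"))
  sc <- zScoreScreen(mkFm(L, U))
  expect_equal(sc$z, 0)
  expect_false(sc$selected)
  # separated groups with tiny jitter: |Z| large, selected
  set.seed(9)
  L <- matrix(0.9 + stats::rnorm(4, 0, 1e-4), ncol = 1,
    dimnames = list(NULL, "f"))
  U <- matrix(0.1 + stats::rnorm(4, 0, 1e-4), ncol = 1,
    dimnames = list(NULL, "f"))
  sc <- zScoreScreen(mkFm(L, U))
  expect_gt(abs(sc$z), 100)
  expect_true(sc$selected)
  # textbook Welch numerator on random data
  set.seed(10)
  L <- matrix(stats::runif(5), ncol = 1, dimnames = list(NULL, "f"))
  U <- matrix(stats::runif(40), ncol = 1, dimnames = list(NULL, "f"))
  sc <- zScoreScreen(mkFm(L, U))
  zHand <- (mean(L) - mean(U)) /
    sqrt(stats::var(as.vector(L)) / 5 + stats::var(as.vector(U)) / 40)
  expect_equal(sc$z, zHand, tolerance = 1e-12)
})

test_that("screen signs recover the direction of group separation", {
  # groups built with the reference separation pattern: labelled pairs
  # sit closer in the network (Dis lower), hit more central cancer-network
  # nodes (Eff.* higher), perturb the CN more than additively (DCI
  # higher), share fewer GO terms than independence predicts (MI lower),
  # and target more mutually unrelated pathways (MP.U higher)
  set.seed(12)
  nL <- 26L
  nU <- 500L
  mk <- function(mL, mU, s) c(stats::rnorm(nL, mL, s), stats::rnorm(nU, mU, s))
  feats <- cbind(
    Dis = mk(0.45, 0.55, 0.05),
    `MP.U` = mk(0.62, 0.5, 0.08),
    MI = mk(0.4, 0.5, 0.06),
    `Eff.D` = mk(0.23, 0.16, 0.05),
    `Eff.B` = mk(0.17, 0.12, 0.05),
    `Eff.E` = mk(0.23, 0.19, 0.05),
    DCI = mk(0.58, 0.5, 0.08)
  )
  drugs <- paste0("d", seq_len(nL + nU))
  fm <- new("PairFeatureMatrix",
    pairs = canonicalPairs(drugs, paste0(drugs, "x")),
    features = pmin(pmax(feats, 0), 1),
    label = rep(c("labelled", "unlabelled"), c(nL, nU)),
    normalized = TRUE, bounds = matrix(numeric(0), 0, 0)
  )
  sc <- zScoreScreen(fm)
  z <- stats::setNames(sc$z, sc$feature)
  expect_lt(z[["Dis"]], 0)
  expect_lt(z[["MI"]], 0)
  expect_gt(z[["MP.U"]], 0)
  expect_gt(z[["Eff.D"]], 0)
  expect_gt(z[["Eff.B"]], 0)
  expect_gt(z[["Eff.E"]], 0)
  expect_gt(z[["DCI"]], 0)
  # the clearly separated features clear the |Z| > 3 bar
  sel <- stats::setNames(sc$selected, sc$feature)
  expect_true(all(sel[c("Dis", "MP.U", "MI", "Eff.D", "Eff.B", "DCI")]))
})
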