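# DEG overlap, pathway coverage, permutation p-values, and the secondary
# filter.

test_that("DEG overlap is the Jaccard index", {
  expect_equal(degOverlap(c("a", "b"), c("a", "b")), 1)
  expect_equal(degOverlap(c("a", "b"), c("c", "d")), 0)
  expect_equal(degOverlap(c("g1", "g2", "g3"), c("g2", "g3", "g4", "g5",
    "g6", "g7", "g8")), 2 / 8)
  expect_equal(degOverlap(c("a", "b"), c("b", "c")),
    degOverlap(c("b", "c"), c("a", "b")))
  expect_error(degOverlap(character(0), "a"), "empty")
})

test_that("pathway coverage is the union's fraction of N", {
  N <- paste0("n", 1:10)
  expect_equal(pathwayCoverage(N[1:6], N[5:10], N), 1)
  expect_equal(pathwayCoverage("x", "y", N), 0)
  expect_equal(pathwayCoverage(c("n1", "n2", "x"), c("n3", "n4"), N), 0.4)
  expect_equal(pathwayCoverage(c("n1"), c("n2"), N),
    pathwayCoverage(c("n2"), c("n1"), N))
  expect_error(pathwayCoverage("a", "b", character(0)), "nonempty")
})

test_that("permutation p-values hit their bounds and match a replay", {
  ctx <- expressionContext(
    degSets = list(),
    geneUniverse = paste0("g", 1:20),
    cancerPathwayGenes = paste0("g", 1:5),
    nPermutations = 1000L, seed = 77L
  )
  # observed above every achievable null value
  expect_equal(
    permutationPValue(2, "deg_overlap", 5, 5, ctx), 1 / 1001
  )
  # observed below every null value
  expect_equal(
    permutationPValue(-1, "deg_overlap", 5, 5, ctx), 1
  )
  # monotone non-increasing in the observed statistic
  ps <- vapply(c(0, 0.1, 0.3, 0.6, 1),
    permutationPValue, numeric(1),
    statistic = "deg_overlap", sizeA = 5, sizeB = 5, context = ctx
  )
  expect_true(all(diff(ps) <= 0))
  # independent reimplementation at the same seed reproduces p exactly
  obs <- 0.25
  null <- withr::with_seed(77L, vapply(1:1000, function(i) {
    a <- sample(ctx$geneUniverse, 5)
    b <- sample(ctx$geneUniverse, 5)
    length(intersect(a, b)) / length(union(a, b))
  }, numeric(1)))
  expect_equal(
    permutationPValue(obs, "deg_overlap", 5, 5, ctx),
    (1 + sum(null >= obs)) / 1001
  )
  expect_error(
    permutationPValue(0.5, "deg_overlap", 50, 5, ctx), "exceed"
  )
  # p for deg_overlap with |A|=|B|=5 from a universe of 20 is
  # hypergeometric in the intersection size: cross-check the null CDF
  pHyper <- function(obs) {
    x <- 0:5
    jac <- x / (10 - x)
    sum(stats::dhyper(x, 5, 15, 5)[jac >= obs])
  }
  pEmp <- permutationPValue(0.25, "deg_overlap", 5, 5, ctx)
  expect_equal(pEmp, pHyper(0.25), tolerance = 0.1)
})

test_that("the filter applies the two-test AND rule and keeps order", {
  genes <- paste0("g", 1:500)
  N <- genes[1:50]
  set.seed(5)
  degSets <- list(
    d1 = c(N[1:20], genes[101:130]),  # d1,d2 share 20 cancer genes
    d2 = c(N[1:20], genes[131:160]),
    d3 = sample(genes[200:500], 50),  # unrelated profile
    d4 = NULL                          # no profile
  )
  ctx <- expressionContext(degSets, genes, N,
    nPermutations = 400L, seed = 11L)
  newRL <- getFromNamespace("newRankedList", "racs")
  cons <- newRL(
    c("d1", "d1", "d2", "d3"), c("d2", "d4", "d3", "d4"),
    score = c(4, 3, 2, 1), stage = "consensus"
  )
  filt <- applyExpressionFilters(cons, ctx)
  e <- rankedEntries(filt)
  expect_equal(rankingStage(filt), "filtered")
  # planted pair passes both tests; d2-d3 fails; single-profile pairs kept
  expect_true("pass" %in% e$flag[e$drug_a == "d1" & e$drug_b == "d2"])
  expect_false(any(e$drug_a == "d2" & e$drug_b == "d3"))
  expect_equal(e$flag[e$drug_b == "d4"], rep("single_profile", 2))
  # survivors keep their relative order and ranks are compacted
  expect_equal(e$rank, seq_len(nrow(e)))
  expect_true(all(diff(e$score) <= 0))
  st <- filt@config$filterStats
  expect_equal(st$flag[st$drug_a == "d2" & st$drug_b == "d3"], "removed")
  # a pair passing only one of the two tests is removed: give d5 strong
  # overlap with d6 but no cancer-pathway content
  degSets2 <- list(
    d5 = genes[301:350], d6 = c(genes[301:340], genes[351:360])
  )
  ctx2 <- expressionContext(degSets2, genes, N,
    nPermutations = 400L, seed = 12L)
  cons2 <- newRL("d5", "d6", score = 1, stage = "consensus")
  filt2 <- applyExpressionFilters(cons2, ctx2)
  st2 <- filt2@config$filterStats
  expect_lt(st2$p_overlap, 0.05)
  expect_gt(st2$p_coverage, 0.05)
  expect_equal(nrow(rankedEntries(filt2)), 0L)
})

test_that("null-model pairs are retained at roughly the squared level", {
  # independence approximation: both permutation tests at alpha = 0.05
  # retain ~ 0.25% of random pairs; loose +/- 3 sigma binomial band
  genes <- paste0("g", seq_len(600))
  N <- genes[1:60]
  nPairs <- 200L
  set.seed(99)
  degSets <- lapply(seq_len(2L * nPairs), function(i) sample(genes, 30))
  names(degSets) <- paste0("d", formatC(seq_len(2L * nPairs), width = 4,
    flag = "0"))
  ctx <- expressionContext(degSets, genes, N,
    nPermutations = 199L, seed = 1L)
  newRL <- getFromNamespace("newRankedList", "racs")
  cons <- newRL(
    paste0("d", formatC(seq_len(nPairs), width = 4, flag = "0")),
    paste0("d", formatC(nPairs + seq_len(nPairs), width = 4, flag = "0")),
    score = rev(seq_len(nPairs)), stage = "consensus"
  )
  filt <- applyExpressionFilters(cons, ctx)
  kept <- nrow(rankedEntries(filt))
  p0 <- 0.05^2
  sigma <- sqrt(nPairs * p0 * (1 - p0))
  expect_lte(kept, ceiling(nPairs * p0 + 3 * sigma))
})
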