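# Median-effect fitting, combination index, synergy calls, and the
# ranking evaluation metrics.

test_that("median-effect fit recovers model parameters exactly", {
  d <- c(0.25, 0.5, 1, 2, 4)
  fa <- (d / 1)^2 / (1 + (d / 1)^2) # Dm = 1, m = 2
  fit <- medianEffectFit(d, fa)
  expect_equal(fit$Dm, 1, tolerance = 1e-10)
  expect_equal(fit$m, 2, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  # fa = 0.5 exactly at D = Dm regardless of slope
  for (m in c(0.5, 1, 3)) {
    dd <- c(0.25, 0.5, 1, 2, 4) * 7
    ff <- (dd / 7)^m / (1 + (dd / 7)^m)
    f2 <- medianEffectFit(dd, ff)
    expect_equal((7 / f2$Dm)^f2$m / (1 + (7 / f2$Dm)^f2$m), 0.5,
      tolerance = 1e-8)
  }
  # saturated fractions are dropped with a warning
  expect_warning(
    f3 <- medianEffectFit(c(d, 64), c(fa, 1)), "excluded"
  )
  expect_equal(f3$n, 5L)
  expect_equal(f3$Dm, 1, tolerance = 1e-10)
  expect_error(
    suppressWarnings(medianEffectFit(c(1, 2, 4), c(0.5, 1, 1))),
    "3 distinct"
  )
})

test_that("noisy median-effect data are recovered within 10%", {
  set.seed(20)
  d <- c(0.5, 1, 2, 4, 8, 16)
  fa <- (d / 2)^1.5 / (1 + (d / 2)^1.5)
  faN <- pmin(pmax(fa + stats::rnorm(6, 0, 0.02), 0.02), 0.98)
  fit <- medianEffectFit(d, faN)
  expect_equal(fit$Dm, 2, tolerance = 0.1)
  expect_equal(fit$m, 1.5, tolerance = 0.1)
})

test_that("sham self-combinations give CI = 1 at any ratio", {
  d <- 1 / 4^(0:5) * 8
  fa <- (d / 1)^2 / (1 + (d / 1)^2)
  fit <- suppressWarnings(medianEffectFit(d, fa))
  for (ratio in list(c(4, 1), c(3, 2), c(2, 3), c(1, 4), c(1, 1))) {
    # combining a drug with itself: the combo curve is the drug's own
    expect_equal(combinationIndex(fit, fit, fit, ratio), 1,
      tolerance = 1e-8)
  }
  # two identical drugs mixed 1:1: closed-form dose arithmetic
  expect_equal(combinationIndex(fit, fit, fit, c(1, 1), 0.7), 1,
    tolerance = 1e-8)
  # CI is invariant to a common rescaling of all doses
  s <- 37
  fitS <- suppressWarnings(medianEffectFit(d * s, fa))
  expect_equal(
    combinationIndex(fitS, fitS, fitS, c(2, 3)),
    combinationIndex(fit, fit, fit, c(2, 3)),
    tolerance = 1e-8
  )
})

test_that("planted combination potency maps to the analytic CI", {
  for (mult in c(1, 2)) {
    drs <- simulateDoseResponse(1, 2, 3, 2, potencyMultiplier = mult)
    ci <- suppressWarnings(doseResponseCI(drs))
    expect_equal(ci, rep(1 / mult, 4), tolerance = 1e-6)
  }
  # unequal slopes, additive: the Loewe mixture is no longer exactly
  # median-effect, so the refitted CI only approximates 1
  drs <- simulateDoseResponse(1, 1.5, 2, 3, potencyMultiplier = 1)
  expect_equal(suppressWarnings(doseResponseCI(drs)), rep(1, 4),
    tolerance = 0.1)
})

test_that("synergy classification applies the all-four-ratio rules", {
  expect_equal(classifySynergy(c(0.2, 0.25, 0.1, 0.28))$label,
    "strong_synergy")
  expect_equal(classifySynergy(c(0.5, 0.5, 0.95, 0.5))$label, "mixed")
  expect_equal(classifySynergy(c(1.2, 1.3, 1.5, 1.11))$label,
    "antagonism")
  expect_equal(classifySynergy(c(0.5, 0.6, 0.7, 0.85))$label, "synergy")
  expect_equal(classifySynergy(c(0.95, 1.05, 1.0, 0.99))$label,
    "additive")
  expect_equal(classifySynergy(c(0.2, 0.2, 0.2, 0.95))$label, "mixed")
  expect_equal(
    classifySynergy(c(0.2, 0.5, 1.0, 1.5))$perRatio,
    c("strong_synergy", "synergy", "additive", "antagonism")
  )
  expect_error(classifySynergy(c(0.5, 0.5)), "4")
})

test_that("PC-index respects its limits and symmetry", {
  set.seed(30)
  s <- c(3, 2, 1, 0)
  # perfect prediction with vanishing noise approaches 1
  expect_equal(pcIndex(c(40, 30, 20, 10), s, rep(1e-9, 4)), 1)
  # reversal complements the index
  pred <- stats::rnorm(10)
  truth <- stats::rnorm(10)
  sd <- stats::runif(10, 0.1, 0.5)
  expect_equal(
    pcIndex(-pred, truth, sd), 1 - pcIndex(pred, truth, sd),
    tolerance = 1e-12
  )
  # invariant to strictly monotone transforms of the prediction
  expect_equal(
    pcIndex(exp(2 * pred), truth, sd), pcIndex(pred, truth, sd)
  )
  # random rankings average to 0.5
  set.seed(31)
  pcs <- replicate(400, pcIndex(sample(50), truth = stats::rnorm(50),
    truthSD = rep(0.3, 50)))
  expect_equal(mean(pcs), 0.5, tolerance = 0.02)
  expect_error(pcIndex(c(1, 2), c(0, 0), c(0, 0)), "degenerate")
})

test_that("AUC matches the concordant-pair count and pROC", {
  # positives exactly on top
  expect_equal(rocAuc(c(4, 3, 2, 1), c(1, 1, 0, 0)), 1)
  # 4-item worked case vs exhaustive concordant-pair enumeration
  pred <- c(0.9, 0.4, 0.6, 0.2)
  lab <- c(1, 0, 1, 0)
  conc <- 0
  for (i in which(lab == 1)) {
    for (j in which(lab == 0)) {
      conc <- conc + (pred[i] > pred[j]) + 0.5 * (pred[i] == pred[j])
    }
  }
  expect_equal(rocAuc(pred, lab), conc / 4)
  # ties credited half
  expect_equal(rocAuc(c(1, 1), c(1, 0)), 0.5)
  # independent implementation cross-check
  set.seed(33)
  pred <- stats::rnorm(60)
  lab <- stats::rbinom(60, 1, 0.4)
  expect_equal(
    rocAuc(pred, lab),
    as.numeric(pROC::auc(pROC::roc(lab, pred, quiet = TRUE,
      direction = "<")))
  )
  # invariant under strictly monotone transforms
  expect_equal(rocAuc(exp(pred), lab), rocAuc(pred, lab))
  expect_error(rocAuc(pred, rep(1, 60)), "classes")
})

test_that("true-positive rate counts positives in the head", {
  pred <- 10:1
  lab <- c(1, 1, 0, 1, 0, 0, 0, 0, 0, 1)
  expect_equal(truePositiveRate(pred, lab, 2), 1)
  expect_equal(truePositiveRate(pred, lab, 4), 3 / 4)
  expect_equal(truePositiveRate(pred, lab, 5), 3 / 5)
  expect_equal(truePositiveRate(pred, rep(0, 10), 5), 0)
  # reference top-20 examination: 11 positives among 20 -> 0.55
  lab78 <- c(rep(1, 11), rep(0, 9), rep(1, 5), rep(0, 53))
  expect_equal(truePositiveRate(78:1, lab78, 20), 0.55)
  expect_error(truePositiveRate(pred, lab, 0), "topK")
})

test_that("Fisher's exact p equals hypergeometric enumeration", {
  # the pick-up-rate contingency: 9/17 predicted vs 4/30 random
  expect_equal(fisherExact2x2(rbind(c(9, 8), c(4, 26))), 0.006188,
    tolerance = 5e-7 / 0.006188)
  expect_equal(fisherExact2x2(rbind(c(1, 1), c(1, 1))), 1)
  expect_equal(fisherExact2x2(rbind(c(5, 0), c(0, 5))), 2 / 252,
    tolerance = 1e-12)
  # enumeration oracle on random tables up to n = 60
  set.seed(40)
  for (i in 1:20) {
    tbl <- matrix(stats::rpois(4, 6) + 1, 2)
    expect_equal(fisherExact2x2(tbl), fisherEnumeration(tbl),
      tolerance = 1e-9)
  }
  expect_error(fisherExact2x2(rbind(c(-1, 2), c(3, 4))), "nonnegative")
})
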