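# Experimental-validation mathematics: Chou-Talalay median-effect model,
# combination index, synergy calls, and ranking evaluation metrics.

#' Fit the median-effect model to a dose-response series
#'
#' The median-effect equation `fa/fu = (D/Dm)^m` (fu = 1 - fa) is linear
#' in log space: `log(fa/(1-fa)) = m log(D) - m log(Dm)`. The fit is the
#' ordinary least-squares line of the logit of the fraction affected on
#' log dose; it recovers (Dm, m) exactly on noise-free model data.
#' Points with fa outside [0.01, 0.99] (where MTT readouts saturate and
#' the logit explodes) are dropped with a warning before fitting.
#'
#' @param doses Positive dose values (>= 3 distinct).
#' @param fractionAffected Fractions affected, same length.
#' @return List of class `medianEffectFit` with elements `Dm`, `m`, `r2`,
#'   `n`.
#' @examples
#' d <- c(0.25, 0.5, 1, 2, 4)
#' fa <- d^2 / (d^2 + 1) # Dm = 1, m = 2
#' medianEffectFit(d, fa)
#' @export
medianEffectFit <- function(doses, fractionAffected) {
  stopIfNot(length(doses) == length(fractionAffected),
    "doses and fractions must have equal length")
  stopIfNot(all(doses > 0), "doses must be positive")
  ok <- fractionAffected >= 0.01 & fractionAffected <= 0.99
  if (any(!ok)) {
    dropWarning(sprintf("%d dose point(s)", sum(!ok)),
      "fraction affected outside [0.01, 0.99]")
  }
  d <- doses[ok]
  fa <- fractionAffected[ok]
  stopIfNot(length(unique(d)) >= 3L,
    "need at least 3 distinct surviving dose points")
  fit <- stats::lm(log(fa / (1 - fa)) ~ log(d))
  m <- unname(stats::coef(fit)[2L])
  b <- unname(stats::coef(fit)[1L])
  stopIfNot(is.finite(m) && m != 0, "degenerate fit: zero slope")
  structure(
    list(Dm = exp(-b / m), m = m,
         r2 = suppressWarnings(summary(fit)$r.squared),
         n = length(d)),
    class = "medianEffectFit"
  )
}

#' @export
print.medianEffectFit <- function(x, ...) {
  cat(sprintf("median-effect fit: Dm = %.4g, m = %.4g, r2 = %.4f (n = %d)\n",
    x$Dm, x$m, x$r2, x$n))
  invisible(x)
}

# dose achieving a given fraction affected under a median-effect fit
doseAtEffect <- function(fit, effectLevel) {
  stopIfNot(effectLevel > 0 && effectLevel < 1,
    "effect level must lie in (0, 1)")
  stopIfNot(fit$Dm > 0 && fit$m > 0,
    "fit must have positive Dm and positive slope")
  fit$Dm * (effectLevel / (1 - effectLevel))^(1 / fit$m)
}

#' Chou-Talalay combination index at a fixed-ratio design
#'
#' From the combination's own median-effect fit, finds the total dose
#' achieving the effect level, splits it into the two component doses by
#' the fixed mixing ratio, and computes
#' `CI = d1/Dx1 + d2/Dx2`, where Dxi is the single-agent dose achieving
#' the same effect level. CI < 1 indicates less drug than Loewe
#' additivity demands (synergy); a sham combination of a drug with itself
#' gives CI = 1 at any ratio.
#'
#' @param fitX,fitY Single-agent `medianEffectFit` objects.
#' @param comboFit `medianEffectFit` of the fixed-ratio combination
#'   (dose = total dose).
#' @param ratio Length-2 numeric mixing ratio, e.g. `c(4, 1)`.
#' @param effectLevel Effect level at which CI is evaluated; default 0.5
#'   (IC50).
#' @return A single numeric CI value.
#' @export
combinationIndex <- function(fitX, fitY, comboFit, ratio,
                             effectLevel = 0.5) {
  stopIfNot(length(ratio) == 2L && all(ratio > 0),
    "ratio must be two positive numbers")
  total <- doseAtEffect(comboFit, effectLevel)
  d1 <- total * ratio[1L] / sum(ratio)
  d2 <- total * ratio[2L] / sum(ratio)
  d1 / doseAtEffect(fitX, effectLevel) +
    d2 / doseAtEffect(fitY, effectLevel)
}

#' Classify a pair's synergy from its four fixed-ratio CI values
#'
#' The pair-level call uses the strict all-ratio rule: synergistic only
#' when all four CI values are < 0.9; strongly synergistic when all four
#' are < 0.3; additive when all lie in (0.9, 1.1); antagonistic when all
#' are > 1.1; otherwise mixed. Per-ratio calls (for heat-map style
#' output) are returned alongside.
#'
#' @param ci Numeric vector of exactly 4 CI values (one per concentration
#'   ratio).
#' @return List with `label` (one of `strong_synergy`, `synergy`,
#'   `additive`, `antagonism`, `mixed`) and `perRatio` (per-cell calls).
#' @examples
#' classifySynergy(c(0.2, 0.25, 0.1, 0.28))$label
#' @export
classifySynergy <- function(ci) {
  stopIfNot(length(ci) == 4L && all(is.finite(ci)),
    "need exactly 4 finite CI values")
  label <- if (all(ci < 0.3)) {
    "strong_synergy"
  } else if (all(ci < 0.9)) {
    "synergy"
  } else if (all(ci > 0.9 & ci < 1.1)) {
    "additive"
  } else if (all(ci > 1.1)) {
    "antagonism"
  } else {
    "mixed"
  }
  perRatio <- ifelse(ci < 0.3, "strong_synergy",
    ifelse(ci < 0.9, "synergy",
      ifelse(ci <= 1.1, "additive", "antagonism")))
  list(label = label, perRatio = perRatio)
}

#' Probabilistic concordance index (PC-index)
#'
#' Concordance between a predicted ranking and a noisy experimental
#' synergy ordering. For every unordered pair (i, j) of items, the
#' probability that the experimental order is as observed is
#' `p_ij = Phi((s_i - s_j) / sqrt(sd_i^2 + sd_j^2))` (s = mean synergy
#' score, sd = replicate standard deviation, Gaussian replicate noise).
#' The pair contributes `p_ij` when the prediction agrees with the
#' experimental mean order and `1 - p_ij` otherwise (0.5 for a tied
#' prediction); the PC-index is the mean contribution. 0.5 is chance
#' level, 1 perfect concordance.
#'
#' @param predicted Numeric prediction scores (higher = predicted more
#'   synergistic), one per item.
#' @param truthScore Experimental mean synergy scores.
#' @param truthSD Replicate standard deviations (>= 0).
#' @return PC-index in [0, 1].
#' @export
pcIndex <- function(predicted, truthScore, truthSD) {
  n <- length(predicted)
  stopIfNot(n >= 2L, "need at least 2 items")
  stopIfNot(length(truthScore) == n && length(truthSD) == n,
    "truth vectors must match the prediction length")
  stopIfNot(all(truthSD >= 0), "replicate SDs must be nonnegative")
  ij <- utils::combn(n, 2L)
  ds <- truthScore[ij[1L, ]] - truthScore[ij[2L, ]]
  se <- sqrt(truthSD[ij[1L, ]]^2 + truthSD[ij[2L, ]]^2)
  stopIfNot(any(ds != 0 | se > 0),
    "degenerate truth: all scores equal with zero SD")
  # probability the true order matches the observed mean order
  p <- ifelse(se > 0, stats::pnorm(abs(ds) / se),
    ifelse(ds == 0, 0.5, 1))
  dp <- predicted[ij[1L, ]] - predicted[ij[2L, ]]
  agree <- sign(dp) * sign(ds)
  contrib <- ifelse(agree > 0, p, ifelse(agree < 0, 1 - p, 0.5))
  mean(contrib)
}

#' ROC AUC of prediction scores against binary labels
#'
#' Mann-Whitney formulation: the probability that a uniformly chosen
#' positive outranks a uniformly chosen negative, with ties credited 0.5.
#'
#' @param predicted Numeric scores (higher = predicted positive).
#' @param labels Logical or 0/1 vector; both classes must be present.
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(predicted, labels) {
  labels <- as.logical(labels)
  nPos <- sum(labels)
  nNeg <- sum(!labels)
  stopIfNot(nPos > 0L && nNeg > 0L, "both classes must be present")
  r <- rank(predicted)
  (sum(r[labels]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' True-positive rate among the top-k predictions
#'
#' @param predicted Numeric scores (higher = predicted positive).
#' @param labels Logical or 0/1 vector.
#' @param topK Size of the examined head of the ranking (0 < topK <= n).
#' @return Fraction of the top `topK` items that are positive.
#' @export
truePositiveRate <- function(predicted, labels, topK) {
  stopIfNot(topK >= 1L && topK <= length(predicted),
    "topK must lie in 1..n")
  labels <- as.logical(labels)
  top <- order(-predicted)[seq_len(topK)]
  sum(labels[top]) / topK
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p-value under the hypergeometric null with fixed
#' margins, by the probability-mass rule (summing the probabilities of
#' all tables no more probable than the observed one). Used for the
#' pick-up-rate comparison between predicted and randomly chosen pairs.
#'
#' @param tbl 2x2 matrix of nonnegative integer counts, e.g.
#'   `rbind(c(confirmed_pred, failed_pred), c(confirmed_rand,
#'   failed_rand))`.
#' @return Two-sided p-value.
#' @examples
#' fisherExact2x2(rbind(c(9, 8), c(4, 26)))
#' @export
fisherExact2x2 <- function(tbl) {
  tbl <- as.matrix(tbl)
  stopIfNot(all(dim(tbl) == 2L), "table must be 2x2")
  stopIfNot(all(tbl >= 0) && all(tbl == round(tbl)),
    "counts must be nonnegative integers")
  stopIfNot(all(rowSums(tbl) > 0) && all(colSums(tbl) > 0),
    "all margins must be positive")
  stats::fisher.test(tbl)$p.value
}
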