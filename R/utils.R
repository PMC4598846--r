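# Internal helpers shared across modules.

#' Canonicalize drug pairs
#'
#' Orders each pair lexicographically so that (a, b) and (b, a) refer to the
#' same unordered pair. All pair-level features are symmetric, so the
#' canonical form is the package-wide identity of a pair.
#'
#' @param a,b Character vectors of drug identifiers (recycled to common
#'   length).
#' @return A data.frame with columns `drug_a`, `drug_b` where
#'   `drug_a <= drug_b` elementwise.
#' @examples
#' canonicalPairs(c("tamoxifen", "aspirin"), c("gefitinib", "zidovudine"))
#' @export
canonicalPairs <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  swap <- a > b
  data.frame(
    drug_a = ifelse(swap, b, a),
    drug_b = ifelse(swap, a, b),
    stringsAsFactors = FALSE
  )
}

#' @rdname canonicalPairs
#' @return For `pairKey`, a character vector of `"a||b"` keys, the
#'   canonical single-string identity of each unordered pair (the form
#'   used by [consistentTop()] and [footruleConsensus()]).
#' @export
pairKey <- function(a, b) {
  p <- canonicalPairs(a, b)
  paste(p$drug_a, p$drug_b, sep = "||")
}

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  eval.parent(substitute(expr))
}

# consistent warning channel for dropped items
dropWarning <- function(what, why) {
  warning(sprintf("excluded %s: %s", what, why), call. = FALSE)
}

stopIfNot <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
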