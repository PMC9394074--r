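#' @import methods
#' @importFrom stats coef
NULL

#' PairMatrix: binary within-sample lncRNA pair features
#'
#' A \code{PairMatrix} stores, for every unordered pair of genes (in canonical
#' lexicographic orientation \code{a < b}), the per-sample indicator that the
#' first gene's expression strictly exceeds the second's. Because each
#' indicator compares two measurements taken inside the same sample, the
#' matrix is invariant to any strictly increasing per-sample transformation
#' of the expression values (library-size scaling, log transforms, ranks),
#' which is the property that makes pair features portable across platforms.
#'
#' @slot pairA character, first gene id of each pair (lexicographically
#'   smaller).
#' @slot pairB character, second gene id of each pair.
#' @slot values numeric matrix of 0/1 values, pairs in rows (named
#'   \code{"a|b"}), samples in columns.
#'
#' @seealso [buildPairMatrix()], [filterValidPairs()]
#' @export
setClass("PairMatrix",
  representation(pairA = "character", pairB = "character", values = "matrix"))

setValidity("PairMatrix", function(object) {
  v <- object@values
  msgs <- character()
  if (length(object@pairA) != nrow(v) || length(object@pairB) != nrow(v))
    msgs <- c(msgs, "pairA/pairB length must equal nrow(values)")
  if (any(object@pairA >= object@pairB))
    msgs <- c(msgs, "pairs must be in canonical orientation (pairA < pairB)")
  ids <- paste(object@pairA, object@pairB, sep = "|")
  if (anyDuplicated(ids))
    msgs <- c(msgs, "duplicated pairs")
  if (nrow(v) > 0 && !identical(rownames(v), ids))
    msgs <- c(msgs, "rownames(values) must be 'pairA|pairB'")
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    msgs <- c(msgs, "values must have unique sample column names")
  if (length(v) && (!all(is.finite(v)) || !all(v %in% c(0, 1))))
    msgs <- c(msgs, "values must be 0 or 1")
  if (length(msgs)) msgs else TRUE
})

#' SignatureModel: a fitted lncRNA-pair prognostic signature
#'
#' Holds the pairs selected by the penalized Cox procedure, their
#' coefficients on the log-hazard scale, the penalty at which the final
#' full-data fit was taken, and (once evaluation has chosen one) the
#' risk-score cutoff separating high- from low-risk patients.
#'
#' @slot pairs character vector of pair ids (\code{"a|b"}).
#' @slot betas numeric coefficients aligned with \code{pairs}; all nonzero.
#' @slot lambda numeric penalty used for the final fit.
#' @slot cutoff numeric risk-score threshold; \code{NA_real_} until set by
#'   [optimalCutoff()] / [setCutoff()].
#' @slot provenance list recording seed, cycle count, fold count and the
#'   per-pair selection frequency across cycles.
#'
#' @seealso [lassoCoxSelect()], [computeRiskScores()]
#' @export
setClass("SignatureModel",
  representation(pairs = "character", betas = "numeric", lambda = "numeric",
                 cutoff = "numeric", provenance = "list"),
  prototype(cutoff = NA_real_, provenance = list()))

setValidity("SignatureModel", function(object) {
  msgs <- character()
  if (length(object@pairs) != length(object@betas))
    msgs <- c(msgs, "pairs and betas must be the same length")
  if (anyDuplicated(object@pairs))
    msgs <- c(msgs, "duplicated pairs in signature")
  if (any(object@betas == 0) || any(!is.finite(object@betas)))
    msgs <- c(msgs, "betas must be nonzero and finite")
  if (length(object@lambda) != 1 || object@lambda < 0)
    msgs <- c(msgs, "lambda must be a single non-negative number")
  if (length(object@cutoff) != 1)
    msgs <- c(msgs, "cutoff must be length 1 (NA until set)")
  if (length(msgs)) msgs else TRUE
})

#' RiskProfile: per-sample risk scores and risk groups
#'
#' The risk score of sample \eqn{s} is the linear predictor
#' \eqn{\sum_i \beta_i P_i(s)} over the signature's pairs, where
#' \eqn{P_i(s) \in \{0,1\}} is the pair indicator. Groups are assigned by a
#' strict comparison with the cutoff: \code{high} iff score > cutoff.
#'
#' @slot score named numeric vector of risk scores (names are sample ids).
#' @slot group factor with levels \code{c("low","high")} aligned with
#'   \code{score}; may be all-NA before a cutoff is applied.
#'
#' @seealso [computeRiskScores()], [assignGroups()]
#' @export
setClass("RiskProfile",
  representation(score = "numeric", group = "factor"))

setValidity("RiskProfile", function(object) {
  msgs <- character()
  if (is.null(names(object@score)) || anyDuplicated(names(object@score)))
    msgs <- c(msgs, "score must be named with unique sample ids")
  if (any(!is.finite(object@score)))
    msgs <- c(msgs, "scores must be finite")
  if (length(object@group) != length(object@score))
    msgs <- c(msgs, "group must align with score")
  if (!identical(levels(object@group), c("low", "high")))
    msgs <- c(msgs, "group levels must be c('low','high')")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "PairMatrix", function(object) {
  cat("PairMatrix with", nrow(object@values), "pairs x",
      ncol(object@values), "samples\n")
  if (nrow(object@values)) {
    f <- rowMeans(object@values)
    cat("  1-frequency range: [", sprintf("%.3f", min(f)), ", ",
        sprintf("%.3f", max(f)), "]\n", sep = "")
  }
})

setMethod("show", "SignatureModel", function(object) {
  cat("SignatureModel:", length(object@pairs), "pairs, lambda =",
      signif(object@lambda, 4), "\n")
  cat("  cutoff:", ifelse(is.na(object@cutoff), "not set",
      signif(object@cutoff, 4)), "\n")
  if (length(object@pairs)) {
    k <- min(5L, length(object@pairs))
    for (i in seq_len(k))
      cat(sprintf("  %s  beta = %+.4f\n", object@pairs[i], object@betas[i]))
    if (length(object@pairs) > k) cat("  ...\n")
  }
})

setMethod("show", "RiskProfile", function(object) {
  cat("RiskProfile for", length(object@score), "samples\n")
  if (all(is.na(object@group))) {
    cat("  groups not assigned\n")
  } else {
    tb <- table(object@group)
    cat("  low:", tb[["low"]], " high:", tb[["high"]], "\n")
  }
})
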