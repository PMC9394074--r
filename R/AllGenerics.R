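#' Accessors for pair-signature objects
#'
#' \code{pairIds} returns the canonical \code{"a|b"} pair identifiers,
#' \code{sampleIds} the sample identifiers, \code{pairValues} the binary
#' pairs-by-samples matrix, \code{riskScores} the named risk-score vector,
#' and \code{riskGroups} the low/high factor.
#'
#' @param x a \linkS4class{PairMatrix}, \linkS4class{SignatureModel} or
#'   \linkS4class{RiskProfile}.
#' @return The corresponding slot content (copied, never by reference).
#' @name accessors
#' @examples
#' m <- rbind(A = c(1, 5), B = c(2, 2), C = c(0, 9))
#' colnames(m) <- c("s1", "s2")
#' pm <- buildPairMatrix(m)
#' pairIds(pm)
#' sampleIds(pm)
NULL

#' @rdname accessors
#' @export
setGeneric("pairIds", function(x) standardGeneric("pairIds"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("pairValues", function(x) standardGeneric("pairValues"))
#' @rdname accessors
#' @export
setGeneric("riskScores", function(x) standardGeneric("riskScores"))
#' @rdname accessors
#' @export
setGeneric("riskGroups", function(x) standardGeneric("riskGroups"))

#' @rdname accessors
#' @export
setMethod("pairIds", "PairMatrix", function(x)
  paste(x@pairA, x@pairB, sep = "|"))
#' @rdname accessors
#' @export
setMethod("pairIds", "SignatureModel", function(x) x@pairs)
#' @rdname accessors
#' @export
setMethod("sampleIds", "PairMatrix", function(x) colnames(x@values))
#' @rdname accessors
#' @export
setMethod("sampleIds", "RiskProfile", function(x) names(x@score))
#' @rdname accessors
#' @export
setMethod("pairValues", "PairMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("riskScores", "RiskProfile", function(x) x@score)
#' @rdname accessors
#' @export
setMethod("riskGroups", "RiskProfile", function(x) x@group)

#' @describeIn accessors signature coefficients, named by pair id.
#' @param object a \linkS4class{SignatureModel}.
#' @param ... ignored.
#' @export
setMethod("coef", "SignatureModel", function(object, ...)
  stats::setNames(object@betas, object@pairs))

#' Set the risk-score cutoff of a signature
#'
#' @param model a \linkS4class{SignatureModel}.
#' @param cutoff finite numeric threshold (typically from [optimalCutoff()]).
#' @return The model with its cutoff slot set.
#' @export
setCutoff <- function(model, cutoff) {
  stopifnot(is(model, "SignatureModel"),
            is.numeric(cutoff), length(cutoff) == 1, is.finite(cutoff))
  model@cutoff <- as.numeric(cutoff)
  validObject(model)
  model
}
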