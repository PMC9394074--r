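## Within-sample binary pair features: the 0-or-1 matrix and the
## validity-frequency filter.

#' Build the binary lncRNA-pair matrix
#'
#' For every unordered pair of genes (a, b) with a < b lexicographically, the
#' pair scores 1 in a sample when the expression of a strictly exceeds the
#' expression of b in that same sample, and 0 otherwise (ties score 0). Only
#' the within-sample ordering matters, so the output is unchanged by any
#' strictly increasing per-sample transform of the expression values.
#'
#' @param expr genes-by-samples matrix, typically restricted to the
#'   differentially expressed immune-related lncRNAs; k genes yield
#'   k(k-1)/2 pairs.
#' @return a \linkS4class{PairMatrix}.
#' @export
#' @examples
#' m <- rbind(A = c(5, 1), B = c(3, 3), C = c(4, 2))
#' colnames(m) <- c("s1", "s2")
#' pairValues(buildPairMatrix(m))
buildPairMatrix <- function(expr) {
  .validateExpression(expr, "pair input")
  g <- rownames(expr)
  k <- length(g)
  if (k < 2) stop("need at least 2 genes to build pairs")
  ord <- order(g)
  expr <- expr[ord, , drop = FALSE]
  g <- g[ord]
  idx <- utils::combn(k, 2)
  a <- idx[1L, ]; b <- idx[2L, ]
  values <- (expr[a, , drop = FALSE] > expr[b, , drop = FALSE]) * 1.0
  rownames(values) <- paste(g[a], g[b], sep = "|")
  pm <- new("PairMatrix", pairA = g[a], pairB = g[b], values = values)
  validObject(pm)
  pm
}

#' Filter pairs by 1-frequency (validity filter)
#'
#' A pair is kept only when its across-sample frequency of 1s lies strictly
#' between \code{low} and \code{high} (defaults 0.2 and 0.8), discarding
#' near-constant pair features that would be uninformative and unstable in a
#' survival model. Idempotent.
#'
#' @param pm a \linkS4class{PairMatrix}.
#' @param low,high strict bounds on the 1-frequency.
#' @return the filtered \linkS4class{PairMatrix}.
#' @export
filterValidPairs <- function(pm, low = 0.2, high = 0.8) {
  stopifnot(is(pm, "PairMatrix"))
  if (!is.numeric(low) || !is.numeric(high) || low >= high ||
      low < 0 || high > 1)
    stop("require 0 <= low < high <= 1")
  if (!nrow(pm@values)) stop("empty pair matrix")
  f <- rowMeans(pm@values)
  keep <- f > low & f < high
  message("pair validity filter: ", length(f), " pairs in -> ", sum(keep),
          " valid")
  new("PairMatrix", pairA = pm@pairA[keep], pairB = pm@pairB[keep],
      values = pm@values[keep, , drop = FALSE])
}

#' Subset a PairMatrix by pair id and/or sample id
#'
#' @param pm a \linkS4class{PairMatrix}.
#' @param pairs character pair ids ("a|b") to keep; NULL keeps all.
#' @param samples character sample ids to keep; NULL keeps all.
#' @return the subset \linkS4class{PairMatrix}, pairs in the requested order.
#' @export
subsetPairs <- function(pm, pairs = NULL, samples = NULL) {
  stopifnot(is(pm, "PairMatrix"))
  ids <- pairIds(pm)
  ri <- if (is.null(pairs)) seq_along(ids) else {
    miss <- setdiff(pairs, ids)
    if (length(miss))
      stop("pair(s) absent from matrix: ", paste(miss, collapse = ", "))
    match(pairs, ids)
  }
  ci <- if (is.null(samples)) seq_len(ncol(pm@values)) else {
    miss <- setdiff(samples, colnames(pm@values))
    if (length(miss))
      stop("sample(s) absent from matrix: ", paste(miss, collapse = ", "))
    match(samples, colnames(pm@values))
  }
  new("PairMatrix", pairA = pm@pairA[ri], pairB = pm@pairB[ri],
      values = pm@values[ri, ci, drop = FALSE])
}

#' Serialize / read a PairMatrix as TSV
#'
#' First column \code{pair_id} ("a|b"), remaining columns one per sample.
#'
#' @param pm a \linkS4class{PairMatrix}.
#' @param path file path.
#' @return \code{path} (write) / a \linkS4class{PairMatrix} (read).
#' @export
writePairMatrix <- function(pm, path) {
  df <- data.frame(pair_id = pairIds(pm), pm@values, check.names = FALSE)
  .writeTSV(df, path)
}

#' @rdname writePairMatrix
#' @export
readPairMatrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  ab <- strsplit(as.character(df[[1L]]), "|", fixed = TRUE)
  values <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- as.character(df[[1L]])
  new("PairMatrix",
      pairA = vapply(ab, `[`, "", 1L), pairB = vapply(ab, `[`, "", 2L),
      values = values)
}

#' Apply a random strictly increasing distortion to each sample
#'
#' Emulates per-sample platform/normalization differences: each sample's
#' expression vector is passed through one randomly chosen strictly
#' increasing map (positive affine, power, scaled log1p, or rank). Useful for
#' demonstrating that pair features - and everything downstream of them - are
#' invariant to such distortions.
#'
#' @param expr genes-by-samples matrix.
#' @param seed integer seed.
#' @return distorted matrix, same dimnames, all values non-negative.
#' @export
applyMonotoneDistortion <- function(expr, seed = 1L) {
  .withSeed(seed, {
    out <- expr
    for (j in seq_len(ncol(expr))) {
      v <- expr[, j]
      kind <- sample(c("affine", "power", "log1p", "rank"), 1L)
      out[, j] <- switch(kind,
        affine = stats::runif(1, 0.5, 5) * v + stats::runif(1, 0, 10),
        power  = v^stats::runif(1, 0.3, 3),
        log1p  = stats::runif(1, 0.5, 5) * log1p(v),
        rank   = rank(v, ties.method = "average"))
    }
    out
  })
}
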