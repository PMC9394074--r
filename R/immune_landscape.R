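## Downstream association of the risk score / risk groups with externally
## computed immune-landscape tables (deconvolution abundances, checkpoint
## gene expression, ESTIMATE scores, predicted drug IC50s). The upstream
## algorithms producing those tables are consumed as input, not recomputed.

#' Default immune-checkpoint and cytolytic gene panels
#'
#' Editable defaults for the gene panels used in checkpoint / cytolytic
#' contrasts: \code{ici} = PDCD1 (PD-1), CD274 (PD-L1), PDCD1LG2 (PD-L2),
#' CTLA4, LAG3, CD74, IDO1; \code{cytolytic} = GZMA, PRF1; HLA genes matched
#' by the prefix \code{"HLA-"}.
#'
#' @return named list with character vectors \code{ici}, \code{cytolytic}
#'   and the \code{hla_prefix} string.
#' @export
immuneGenePanels <- function() {
  list(ici = c("PDCD1", "CD274", "PDCD1LG2", "CTLA4", "LAG3", "CD74",
               "IDO1"),
       cytolytic = c("GZMA", "PRF1"),
       hla_prefix = "HLA-")
}

#' Read a samples-by-features table (immune landscape input)
#'
#' First column = sample id, remaining columns features (cell types, genes,
#' scores or drugs). Returned as samples-by-features numeric matrix.
#'
#' @param path TSV file path.
#' @return numeric matrix with sample rownames.
#' @export
readSampleFeatureTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  if (anyDuplicated(rownames(m))) stop("duplicated sample ids in table")
  m
}

#' Spearman correlation of each feature with the risk score
#'
#' @param scores a \linkS4class{RiskProfile}.
#' @param table samples-by-features numeric matrix (e.g. deconvolved
#'   immune-cell abundances).
#' @return data.frame ranked by rho: feature, rho, p, stars. Constant
#'   features are skipped with a warning.
#' @export
correlateWithRisk <- function(scores, table) {
  stopifnot(is(scores, "RiskProfile"))
  shared <- intersect(sampleIds(scores), rownames(table))
  if (length(shared) < 3) stop("need at least 3 shared samples")
  sc <- unname(riskScores(scores)[shared])
  tb <- table[shared, , drop = FALSE]
  rows <- lapply(colnames(tb), function(nm) {
    v <- tb[, nm]
    ok <- is.finite(v)
    if (sum(ok) < 3 || stats::var(v[ok]) == 0) {
      warning("feature '", nm, "' constant or too sparse; skipped")
      return(NULL)
    }
    ct <- suppressWarnings(
      stats::cor.test(sc[ok], v[ok], method = "spearman"))
    data.frame(feature = nm, rho = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(feature = character(), rho = numeric(), p = numeric())
  out$stars <- .pStars(out$p)
  out <- out[order(-out$rho), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Contrast each feature between high- and low-risk groups
#'
#' Two-sided Wilcoxon rank-sum test per feature: exact when both groups have
#' at most 10 non-missing samples (and the data are tie-free), normal
#' approximation with continuity correction otherwise. Reports per-group
#' medians and the direction of the difference.
#'
#' @param groups a \linkS4class{RiskProfile} with groups assigned.
#' @param table samples-by-features numeric matrix.
#' @return data.frame: feature, median_high, median_low, p, direction
#'   ("higher-in-high" / "higher-in-low" / "none"), stars.
#' @export
contrastGroups <- function(groups, table) {
  stopifnot(is(groups, "RiskProfile"))
  if (any(is.na(riskGroups(groups)))) stop("groups must be assigned")
  shared <- intersect(sampleIds(groups), rownames(table))
  g <- riskGroups(groups)[match(shared, sampleIds(groups))]
  tb <- table[shared, , drop = FALSE]
  rows <- lapply(colnames(tb), function(nm) {
    v <- tb[, nm]
    hi <- v[g == "high" & is.finite(v)]
    lo <- v[g == "low" & is.finite(v)]
    if (!length(hi) || !length(lo))
      stop("feature '", nm, "': a risk group is empty after NA removal")
    exact <- length(hi) <= 10 && length(lo) <= 10
    w <- suppressWarnings(
      stats::wilcox.test(hi, lo, exact = exact, correct = TRUE))
    mh <- stats::median(hi); ml <- stats::median(lo)
    data.frame(feature = nm, median_high = mh, median_low = ml,
               p = w$p.value,
               direction = if (mh > ml) "higher-in-high"
                           else if (mh < ml) "higher-in-low" else "none",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$stars <- .pStars(out$p)
  rownames(out) <- NULL
  out
}

#' Drop samples failing the deconvolution quality filter
#'
#' Deconvolution outputs (CIBERSORT-style) carry a per-sample p-value; only
#' samples with p < 0.05 are retained for downstream immune analyses.
#'
#' @param table samples-by-features matrix including a p-value column.
#' @param p_column name of the per-sample p-value column (default
#'   \code{"P.value"}; \code{"p_value"} also recognised).
#' @param p_max retention threshold (strict; default 0.05).
#' @return the filtered matrix with the p-value column removed.
#' @export
cibersortQCFilter <- function(table, p_column = NULL, p_max = 0.05) {
  if (is.null(p_column))
    p_column <- intersect(c("P.value", "p_value", "p.value"),
                          colnames(table))[1]
  if (is.na(p_column) || is.null(p_column) ||
      !p_column %in% colnames(table))
    stop("table has no per-sample deconvolution p-value column")
  keep <- table[, p_column] < p_max
  message("deconvolution QC: ", nrow(table), " samples in -> ", sum(keep),
          " at p < ", p_max)
  if (!any(keep)) warning("no samples pass the deconvolution QC filter")
  table[keep, setdiff(colnames(table), p_column), drop = FALSE]
}
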