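## Immune-related lncRNA screen: Pearson coexpression with immune mRNAs,
## then tumor/normal differential expression on the immune-related set.

#' Screen lncRNAs for coexpression with immune genes
#'
#' Computes the Pearson correlation between every lncRNA and every immune
#' mRNA across shared samples. A lncRNA is called immune-related when it has
#' at least one immune partner with \code{|r| >= r_min} and a two-sided
#' p-value (t approximation with n - 2 degrees of freedom) \code{<= p_max}.
#' The defaults |r| >= 0.4 and p <= 0.001 are the conventional thresholds for
#' this screen.
#'
#' @param lnc lncRNA expression matrix (genes x samples).
#' @param mrna mRNA expression matrix (genes x samples, same samples).
#' @param immune_genes character vector of immune gene symbols; intersected
#'   with \code{rownames(mrna)}.
#' @param r_min minimum absolute Pearson correlation (default 0.4).
#' @param p_max maximum correlation p-value (default 0.001).
#' @return list with \code{hits} (data.frame: lnc_id, immune_gene_id, r, p)
#'   and \code{irlnc_ids} (character vector of immune-related lncRNA ids).
#' @export
correlateToImmune <- function(lnc, mrna, immune_genes,
                              r_min = 0.4, p_max = 0.001) {
  shared <- intersect(colnames(lnc), colnames(mrna))
  if (length(shared) < 3) stop("need at least 3 shared samples")
  imm <- intersect(immune_genes, rownames(mrna))
  if (!length(imm)) stop("no immune genes present in the mRNA matrix")
  lx <- t(lnc[, shared, drop = FALSE])
  mx <- t(mrna[imm, shared, drop = FALSE])
  constL <- apply(lx, 2, function(v) stats::var(v) == 0)
  constM <- apply(mx, 2, function(v) stats::var(v) == 0)
  if (any(constL) || any(constM))
    warning(sum(constL) + sum(constM),
            " constant-expression gene(s) skipped in correlation screen")
  lx <- lx[, !constL, drop = FALSE]
  mx <- mx[, !constM, drop = FALSE]
  if (!ncol(lx) || !ncol(mx))
    return(list(hits = data.frame(lnc_id = character(),
                                  immune_gene_id = character(),
                                  r = numeric(), p = numeric()),
                irlnc_ids = character()))
  n <- length(shared)
  r <- stats::cor(lx, mx)                      # lnc x immune
  r[] <- pmin(1, pmax(-1, r))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(r) == 1] <- 0
  keep <- which(abs(r) >= r_min & p <= p_max, arr.ind = TRUE)
  hits <- data.frame(
    lnc_id = rownames(r)[keep[, 1]],
    immune_gene_id = colnames(r)[keep[, 2]],
    r = r[keep], p = p[keep], stringsAsFactors = FALSE)
  hits <- hits[order(hits$lnc_id, hits$immune_gene_id), , drop = FALSE]
  rownames(hits) <- NULL
  irlnc <- sort(unique(hits$lnc_id))
  message("immune-correlation screen: ", nrow(lnc), " lncRNA in -> ",
          length(irlnc), " immune-related (", nrow(hits), " hits)")
  list(hits = hits, irlnc_ids = irlnc)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' order-preserving with the input.
#'
#' @param pvals numeric vector of raw p-values in [0, 1].
#' @return adjusted p-values, same order as input.
#' @export
bhAdjust <- function(pvals) {
  if (!is.numeric(pvals) || any(!is.finite(pvals)) ||
      any(pvals < 0 | pvals > 1))
    stop("p-values must be finite and within [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Tumor/normal differential expression
#'
#' For each gene, the log2 fold change is computed from pseudocounted group
#' means, \code{log2((mean_tumor + c) / (mean_normal + c))}, and the p-value
#' from a two-sided Wilcoxon rank-sum test; FDR by Benjamini-Hochberg. A gene
#' is flagged differentially expressed when \code{|log_fc| > logfc_min} and
#' \code{fdr < fdr_max} (defaults 1 and 0.05).
#'
#' @param expr genes-by-samples matrix.
#' @param labels named character vector (sample id -> "tumor"/"normal"), or
#'   unnamed and aligned with \code{colnames(expr)}.
#' @param logfc_min minimum absolute log2 fold change (default 1).
#' @param fdr_max FDR threshold (default 0.05).
#' @param pseudocount added to group means before the ratio (default 1).
#' @return data.frame: gene_id, log_fc, p, fdr, direction ("up"/"down"),
#'   flagged (logical).
#' @export
differentialExpression <- function(expr, labels, logfc_min = 1.0,
                                   fdr_max = 0.05, pseudocount = 1.0) {
  if (!is.null(names(labels))) labels <- labels[colnames(expr)]
  labels <- as.character(labels)
  if (length(labels) != ncol(expr) || any(is.na(labels)))
    stop("labels must cover every expression sample")
  if (!all(labels %in% c("tumor", "normal")))
    stop("labels must be 'tumor' or 'normal'")
  it <- labels == "tumor"; inn <- labels == "normal"
  if (sum(it) < 2 || sum(inn) < 2)
    stop("each label needs at least 2 samples")
  mt <- rowMeans(expr[, it, drop = FALSE])
  mn <- rowMeans(expr[, inn, drop = FALSE])
  log_fc <- log2((mt + pseudocount) / (mn + pseudocount))
  p <- apply(expr, 1, function(v)
    suppressWarnings(stats::wilcox.test(v[it], v[inn])$p.value))
  p[is.na(p)] <- 1  # constant genes: no evidence
  fdr <- bhAdjust(p)
  res <- data.frame(
    gene_id = rownames(expr), log_fc = log_fc, p = p, fdr = fdr,
    direction = ifelse(log_fc > 0, "up", "down"),
    flagged = abs(log_fc) > logfc_min & fdr < fdr_max,
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  message("differential expression: ", nrow(res), " genes in -> ",
          sum(res$flagged), " flagged (",
          sum(res$flagged & res$direction == "up"), " up, ",
          sum(res$flagged & res$direction == "down"), " down)")
  res
}
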