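## Input/output and cohort plumbing: reading the expression matrix, gene
## annotation, immune gene list and clinical table, aligning samples, and
## splitting the cohort. Canonical dialect: tab-separated UTF-8, genes in
## rows, first column = gene id.

.validateExpression <- function(values, what = "expression matrix") {
  if (!is.matrix(values) || !is.numeric(values))
    stop(what, " must be a numeric matrix")
  gid <- rownames(values); sid <- colnames(values)
  if (is.null(gid) || is.null(sid))
    stop(what, " must have gene rownames and sample colnames")
  dup <- unique(gid[duplicated(gid)])
  if (length(dup))
    stop(what, ": duplicated gene ids: ", paste(dup, collapse = ", "))
  dup <- unique(sid[duplicated(sid)])
  if (length(dup))
    stop(what, ": duplicated sample ids: ", paste(dup, collapse = ", "))
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(what, ": negative or non-finite values at (gene, sample): ",
         paste(sprintf("(%s,%s)", gid[bad[, 1]], sid[bad[, 2]])[
           seq_len(min(5, nrow(bad)))], collapse = ", "))
  if (ncol(values) < 2) stop(what, " needs at least 2 samples")
  if (nrow(values) < 1) stop(what, " needs at least 1 gene")
  invisible(values)
}

#' Read a normalized expression matrix
#'
#' Reads a delimited text file (TSV by default; the delimiter is sniffed from
#' the header line) holding non-negative normalized expression values such as
#' FPKM or TPM, and returns a validated genes-by-samples numeric matrix.
#'
#' @param path file path.
#' @param orientation \code{"genes_in_rows"} (canonical: first column = gene
#'   id, header = sample ids) or \code{"samples_in_rows"} (the transpose).
#' @return numeric matrix, genes in rows, samples in columns.
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' m <- matrix(1:6, 2, 3, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' writeExpression(m, f)
#' stopifnot(identical(readExpression(f), m * 1.0))
readExpression <- function(path,
                           orientation = c("genes_in_rows",
                                           "samples_in_rows")) {
  orientation <- match.arg(orientation)
  sep <- if (grepl(",", readLines(path, n = 1L)[1])) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  ids <- as.character(df[[1L]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicated ", if (orientation == "genes_in_rows") "gene" else
         "sample", " ids: ", paste(dup, collapse = ", "))
  body <- df[, -1L, drop = FALSE]
  nonnum <- !vapply(body, is.numeric, logical(1))
  if (any(nonnum))
    stop("non-numeric expression column(s): ",
         paste(colnames(body)[nonnum], collapse = ", "))
  values <- as.matrix(body)
  rownames(values) <- ids
  if (orientation == "samples_in_rows") values <- t(values)
  .validateExpression(values)
  values
}

#' Write an expression matrix in the canonical TSV dialect
#'
#' @param expr genes-by-samples numeric matrix.
#' @param path output file path.
#' @param id_column name of the first (gene id) column.
#' @return \code{path}, invisibly.
#' @export
writeExpression <- function(expr, path, id_column = "gene_id") {
  df <- data.frame(rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene biotype annotation
#'
#' Two-column table (gene_id, biotype). Biotypes other than \code{lncRNA} and
#' \code{mRNA} are mapped to \code{other}.
#'
#' @param path file path (TSV with header).
#' @return named character vector: gene id -> biotype in
#'   \code{c("lncRNA", "mRNA", "other")}.
#' @export
readGeneAnnotation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  ann <- as.character(df[[2L]])
  ann[!ann %in% c("lncRNA", "mRNA")] <- "other"
  stats::setNames(ann, as.character(df[[1L]]))
}

#' Read an immune gene list (one symbol per line)
#'
#' @param path file path.
#' @return character vector of unique, non-empty gene symbols.
#' @export
readImmuneGeneSet <- function(path) {
  x <- trimws(readLines(path))
  x <- unique(x[nzchar(x)])
  if (!length(x)) stop("immune gene list is empty")
  x
}

#' Read and validate a clinical table
#'
#' Requires columns \code{sample_id}, \code{os_time} (days) and
#' \code{os_event} (0/1); keeps any further covariate columns (age, sex,
#' t_stage, n_stage, m_stage, stage, ...). Rows with \code{os_time <= 0}
#' cannot contribute to a partial likelihood and are dropped with a message.
#'
#' @param path file path (TSV with header).
#' @return data.frame with one row per sample, \code{sample_id} unique.
#' @export
readClinical <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  validateClinical(df)
}

#' @rdname readClinical
#' @param clin a clinical data.frame to validate in place of a file.
#' @export
validateClinical <- function(clin) {
  need <- c("sample_id", "os_time", "os_event")
  miss <- setdiff(need, colnames(clin))
  if (length(miss))
    stop("clinical table is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(clin$sample_id))
    stop("duplicated sample ids in clinical table")
  if (!all(clin$os_event %in% c(0, 1)))
    stop("os_event must be 0 or 1")
  bad <- !is.finite(clin$os_time) | clin$os_time <= 0
  if (any(bad)) {
    message(sum(bad), " clinical sample(s) dropped for os_time <= 0")
    clin <- clin[!bad, , drop = FALSE]
  }
  if (!nrow(clin)) stop("no clinical samples left after validation")
  rownames(clin) <- NULL
  clin
}

#' Align an expression matrix and a clinical table on shared samples
#'
#' Restricts both inputs to the intersection of their sample ids, in the
#' expression matrix's column order, after dropping clinical rows with
#' non-positive follow-up. Idempotent.
#'
#' @param expr genes-by-samples matrix.
#' @param clin clinical data.frame (see [readClinical()]).
#' @return list with elements \code{expr} and \code{clin}.
#' @export
alignCohort <- function(expr, clin) {
  .validateExpression(expr)
  clin <- validateClinical(clin)
  shared <- intersect(colnames(expr), clin$sample_id)
  if (!length(shared))
    stop("no shared sample ids between expression and clinical table")
  shared <- colnames(expr)[colnames(expr) %in% shared]
  message("aligned cohort: ", ncol(expr), " expression / ", nrow(clin),
          " clinical samples in -> ", length(shared), " shared")
  list(expr = expr[, shared, drop = FALSE],
       clin = clin[match(shared, clin$sample_id), , drop = FALSE])
}

#' Partition an expression matrix by gene biotype
#'
#' @param expr genes-by-samples matrix.
#' @param annotation named biotype vector from [readGeneAnnotation()].
#' @return list with matrices \code{lnc} and \code{mrna}; genes annotated
#'   \code{other} (or missing from the annotation, with a warning) are
#'   excluded from both.
#' @export
splitBiotypes <- function(expr, annotation) {
  gid <- rownames(expr)
  unknown <- setdiff(gid, names(annotation))
  if (length(unknown))
    warning(length(unknown), " gene(s) absent from annotation treated as ",
            "'other': ", paste(utils::head(unknown, 5), collapse = ", "))
  bt <- rep("other", length(gid))
  hit <- gid %in% names(annotation)
  bt[hit] <- unname(annotation[gid[hit]])
  message("biotype split: ", sum(bt == "lncRNA"), " lncRNA, ",
          sum(bt == "mRNA"), " mRNA, ", sum(bt == "other"), " other")
  list(lnc  = expr[bt == "lncRNA", , drop = FALSE],
       mrna = expr[bt == "mRNA", , drop = FALSE])
}

#' Random train/test split of a cohort
#'
#' Deterministic given \code{seed}; the training set has
#' \code{round(ratio * n)} samples.
#'
#' @param sample_ids character vector of sample ids (or a clinical
#'   data.frame, whose \code{sample_id} column is used).
#' @param ratio training fraction in (0, 1).
#' @param seed integer seed.
#' @return list with \code{train_ids}, \code{test_ids} (disjoint, exhaustive)
#'   and \code{seed}.
#' @export
splitTrainTest <- function(sample_ids, ratio = 0.5, seed = 1L) {
  if (is.data.frame(sample_ids)) sample_ids <- sample_ids$sample_id
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicated sample ids")
  n <- length(sample_ids)
  if (n < 2) stop("need at least 2 samples to split")
  if (!is.numeric(ratio) || length(ratio) != 1 || ratio <= 0 || ratio >= 1)
    stop("ratio must lie strictly within (0, 1)")
  n_train <- round(ratio * n)
  n_train <- max(1L, min(n - 1L, as.integer(n_train)))
  train_ids <- .withSeed(seed, sort(sample(sample_ids, n_train)))
  list(train_ids = train_ids,
       test_ids  = sort(setdiff(sample_ids, train_ids)),
       seed      = as.integer(seed))
}
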