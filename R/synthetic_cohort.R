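## Synthetic cohort generator: tumor/normal expression with a latent immune
## coexpression module, differential lncRNA expression, proportional-hazards
## survival driven by planted pair indicators, calibrated right censoring,
## and optional per-sample monotone platform distortion. Every stage of the
## pipeline can be validated against the planted truth it returns.

#' Specification of a synthetic cohort
#'
#' Defaults emulate a TCGA-like thyroid-carcinoma design: 500 tumor and 58
#' normal RNA-seq samples, an immune coexpression module strong enough that
#' module lncRNAs pass the |r| >= 0.4 screen, 40 differentially expressed
#' lncRNAs at four-fold effect, five planted prognostic pairs with log
#' hazard ratio 1, an exponential baseline with three-year median survival,
#' and 30 percent right censoring.
#'
#' @param n_tumor,n_normal sample counts.
#' @param n_lnc,n_immune_mrna,n_other_mrna gene counts by class; a further
#'   \code{n_other_biotype} genes carry a non-lncRNA/mRNA biotype.
#' @param n_de_lnc number of differentially expressed lncRNAs (tumor shift
#'   of \code{de_fold}-fold, half up / half down).
#' @param n_immune_lnc number of lncRNAs in the latent immune module
#'   (includes all DE lncRNAs; must be >= n_de_lnc).
#' @param immune_corr target pairwise Pearson correlation (log scale)
#'   between immune-module genes; the latent-factor loading is its square
#'   root.
#' @param sigma_log log-scale expression standard deviation.
#' @param de_fold fold change of DE lncRNAs in tumor (default 4).
#' @param n_planted,planted_beta number of planted prognostic pairs among
#'   the DE lncRNAs and their common |log hazard ratio|; or supply
#'   \code{planted_pairs} (data.frame pair_a, pair_b, beta) explicitly.
#' @param planted_pairs optional explicit planted pairs.
#' @param baseline_hazard exponential baseline hazard per day (default:
#'   median survival 3 years).
#' @param censoring target censoring fraction in (0, 1).
#' @param distortion "none" or "per_sample_monotone" (a strictly increasing
#'   per-sample measurement distortion applied after survival generation).
#' @param seed integer seed.
#' @return object of class \code{"CohortSpec"} (a validated list).
#' @export
cohortSpec <- function(n_tumor = 500L, n_normal = 58L,
                       n_lnc = 200L, n_immune_mrna = 100L,
                       n_other_mrna = 290L, n_other_biotype = 10L,
                       n_de_lnc = 40L, n_immune_lnc = 80L,
                       immune_corr = 0.6, sigma_log = 0.5, de_fold = 4,
                       n_planted = 5L, planted_beta = 1.0,
                       planted_pairs = NULL,
                       baseline_hazard = log(2) / 1095,
                       censoring = 0.3,
                       distortion = c("none", "per_sample_monotone"),
                       seed = 1L) {
  spec <- list(n_tumor = as.integer(n_tumor),
               n_normal = as.integer(n_normal),
               n_lnc = as.integer(n_lnc),
               n_immune_mrna = as.integer(n_immune_mrna),
               n_other_mrna = as.integer(n_other_mrna),
               n_other_biotype = as.integer(n_other_biotype),
               n_de_lnc = as.integer(n_de_lnc),
               n_immune_lnc = as.integer(n_immune_lnc),
               immune_corr = immune_corr, sigma_log = sigma_log,
               de_fold = de_fold, n_planted = as.integer(n_planted),
               planted_beta = planted_beta, planted_pairs = planted_pairs,
               baseline_hazard = baseline_hazard, censoring = censoring,
               distortion = match.arg(distortion),
               seed = as.integer(seed))
  with(spec, {
    stopifnot(n_tumor >= 4, n_normal >= 2, n_lnc >= 2, n_immune_mrna >= 1,
              n_de_lnc >= 2, n_de_lnc <= n_lnc,
              n_immune_lnc >= n_de_lnc, n_immune_lnc <= n_lnc,
              immune_corr > 0, immune_corr < 1, sigma_log > 0, de_fold > 1,
              baseline_hazard > 0, censoring > 0, censoring < 1)
  })
  if (!is.null(planted_pairs)) {
    stopifnot(is.data.frame(planted_pairs),
              all(c("pair_a", "pair_b", "beta") %in%
                    colnames(planted_pairs)))
    if (any(planted_pairs$pair_a == planted_pairs$pair_b))
      stop("a planted pair cannot use the same gene twice")
  } else if (2L * spec$n_planted > spec$n_de_lnc) {
    stop("not enough DE lncRNAs for ", spec$n_planted,
         " disjoint planted pairs")
  }
  structure(spec, class = "CohortSpec")
}

.geneIds <- function(prefix, n)
  sprintf("%s%03d", prefix, seq_len(n))

#' Generate a synthetic cohort with known truth
#'
#' Expression is lognormal: a gene baseline plus, for immune-module members,
#' a per-sample latent immune factor scaled by the module loading; DE
#' lncRNAs additionally shift by log(de_fold) in tumor samples (half up,
#' half down, via the sign of their module loading). Survival times for
#' tumor samples are exponential with hazard
#' \code{baseline_hazard * exp(sum(beta * pair indicator))}, the indicators
#' computed from the pre-distortion expression; censoring times are uniform
#' on (0, H) with H calibrated by bisection to the target censoring
#' fraction. Deterministic given the spec's seed.
#'
#' @param spec a \code{"CohortSpec"} from [cohortSpec()].
#' @return list: \code{expr} (genes x samples, tumor then normal),
#'   \code{annotation} (gene -> biotype), \code{immune_genes},
#'   \code{labels} (sample -> tumor/normal), \code{clin} (clinical table of
#'   tumor samples), \code{truth} (de_lnc, immune_lnc, planted_pairs,
#'   linear predictor per tumor sample, censoring horizon).
#' @export
generateCohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  .withSeed(spec$seed, {
    lnc_ids <- .geneIds("LNC", spec$n_lnc)
    imm_ids <- .geneIds("IMM", spec$n_immune_mrna)
    oth_ids <- .geneIds("MRN", spec$n_other_mrna)
    msc_ids <- .geneIds("MSC", spec$n_other_biotype)
    gene_ids <- c(lnc_ids, imm_ids, oth_ids, msc_ids)
    n_s <- spec$n_tumor + spec$n_normal
    sample_ids <- c(sprintf("TUM%04d", seq_len(spec$n_tumor)),
                    sprintf("NOR%04d", seq_len(spec$n_normal)))
    is_tumor <- c(rep(TRUE, spec$n_tumor), rep(FALSE, spec$n_normal))

    de_lnc <- lnc_ids[seq_len(spec$n_de_lnc)]
    immune_lnc <- lnc_ids[seq_len(spec$n_immune_lnc)]

    loading <- sqrt(spec$immune_corr)
    lam <- stats::setNames(rep(0, length(gene_ids)), gene_ids)
    lam[imm_ids] <- loading
    # module lncRNAs load in blocks of two with alternating sign; for DE
    # lncRNAs the sign also sets the tumor-shift direction, so consecutive
    # DE lncRNAs (the default planted pairs) shift the same way and their
    # pair indicator stays informative rather than collapsing to a constant
    sgn <- rep_len(c(1, 1, -1, -1), spec$n_immune_lnc)
    lam[immune_lnc] <- loading * sgn

    planted <- spec$planted_pairs
    if (is.null(planted)) {
      a <- de_lnc[2 * seq_len(spec$n_planted) - 1]
      b <- de_lnc[2 * seq_len(spec$n_planted)]
      swap <- a > b
      tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
      planted <- data.frame(pair_a = a, pair_b = b,
                            beta = spec$planted_beta *
                              rep_len(c(1, -1), spec$n_planted),
                            stringsAsFactors = FALSE)
    }
    bad <- !(planted$pair_a %in% gene_ids) | !(planted$pair_b %in% gene_ids)
    if (any(bad)) stop("planted pair uses unknown gene id")

    mu <- stats::setNames(stats::rnorm(length(gene_ids), 2, 0.3), gene_ids)
    # matched baselines inside each planted pair keep the indicator near
    # Bernoulli(1/2), so it survives the validity filter
    mu[planted$pair_b] <- mu[planted$pair_a]
    z <- stats::rnorm(n_s)
    eps <- matrix(stats::rnorm(length(gene_ids) * n_s), length(gene_ids),
                  n_s, dimnames = list(gene_ids, sample_ids))
    lamv <- lam[gene_ids]
    logx <- mu + spec$sigma_log *
      (outer(lamv, z) + sqrt(1 - lamv^2) * eps)
    dimnames(logx) <- list(gene_ids, sample_ids)
    shift <- log(spec$de_fold)
    de_sign <- sign(lam[de_lnc])
    logx[de_lnc, is_tumor] <- logx[de_lnc, is_tumor] + de_sign * shift
    expr <- exp(logx)

    tum <- sample_ids[is_tumor]
    ind <- vapply(seq_len(nrow(planted)), function(i)
      as.numeric(expr[planted$pair_a[i], tum] >
                   expr[planted$pair_b[i], tum]),
      numeric(length(tum)))
    linpred <- stats::setNames(as.numeric(ind %*% planted$beta), tum)

    t_event <- stats::rexp(length(tum),
                           rate = spec$baseline_hazard * exp(linpred))
    u <- stats::runif(length(tum))
    cens_frac <- function(h) mean(h * u < t_event)
    lo <- 1e-3; hi <- 1e9
    for (it in seq_len(200)) {
      mid <- sqrt(lo * hi)
      if (cens_frac(mid) > spec$censoring) lo <- mid else hi <- mid
    }
    horizon <- sqrt(lo * hi)
    c_time <- horizon * u
    os_time <- pmin(t_event, c_time)
    os_event <- as.integer(t_event <= c_time)

    clin <- data.frame(
      sample_id = tum,
      os_time = os_time, os_event = os_event,
      age = pmin(90, pmax(18, round(stats::rnorm(length(tum), 47, 15)))),
      sex = sample(c("male", "female"), length(tum), TRUE,
                   prob = c(0.27, 0.73)),
      t_stage = sample(paste0("T", 1:4), length(tum), TRUE,
                       prob = c(0.3, 0.35, 0.25, 0.1)),
      n_stage = sample(c("N0", "N1"), length(tum), TRUE,
                       prob = c(0.55, 0.45)),
      m_stage = sample(c("M0", "M1"), length(tum), TRUE,
                       prob = c(0.95, 0.05)),
      stage = sample(c("I", "II", "III", "IV"), length(tum), TRUE,
                     prob = c(0.55, 0.1, 0.2, 0.15)),
      stringsAsFactors = FALSE)

    if (spec$distortion == "per_sample_monotone")
      expr <- applyMonotoneDistortion(expr, seed = spec$seed + 1L)

    annotation <- stats::setNames(
      c(rep("lncRNA", length(lnc_ids)),
        rep("mRNA", length(imm_ids) + length(oth_ids)),
        rep("other", length(msc_ids))),
      gene_ids)

    list(expr = expr,
         annotation = annotation,
         immune_genes = imm_ids,
         labels = stats::setNames(ifelse(is_tumor, "tumor", "normal"),
                                  sample_ids),
         clin = clin,
         truth = list(de_lnc = de_lnc, immune_lnc = immune_lnc,
                      planted_pairs = planted, linpred = linpred,
                      censoring_horizon = horizon, spec = spec))
  })
}

#' Write a complete on-disk input bundle for the pipeline
#'
#' Generates a cohort (tiny: ~40 genes x 60 samples; default: ~700 genes x
#' 558 samples) and writes every input the pipeline consumes: expression,
#' annotation, immune gene list, clinical table, tumor/normal labels,
#' auxiliary immune-landscape tables (deconvolution abundances with QC
#' p-values, ESTIMATE-style scores, predicted drug IC50s), the ground truth
#' as JSON, and a ready-to-run YAML config.
#'
#' @param size "tiny" or "default".
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @return named character vector of file paths, invisibly; the cohort and
#'   truth are attached as attributes \code{"cohort"}.
#' @export
endToEndFixture <- function(size = c("tiny", "default"), dir = tempfile(),
                            seed = 1L) {
  size <- match.arg(size)
  spec <- if (size == "tiny") {
    cohortSpec(n_tumor = 40L, n_normal = 20L, n_lnc = 16L,
               n_immune_mrna = 12L, n_other_mrna = 10L,
               n_other_biotype = 2L, n_de_lnc = 8L, n_immune_lnc = 12L,
               n_planted = 2L, planted_beta = 1.5, seed = seed)
  } else {
    cohortSpec(seed = seed)
  }
  co <- generateCohort(spec)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             immune_genes = file.path(dir, "immune_genes.txt"),
             clinical = file.path(dir, "clinical.tsv"),
             labels = file.path(dir, "sample_labels.tsv"),
             infiltration = file.path(dir, "infiltration.tsv"),
             estimate = file.path(dir, "estimate_scores.tsv"),
             ic50 = file.path(dir, "drug_ic50.tsv"),
             truth = file.path(dir, "truth.json"),
             config = file.path(dir, "config.yaml"))
  writeExpression(co$expr, paths["expression"])
  .writeTSV(data.frame(gene_id = names(co$annotation),
                       biotype = unname(co$annotation)),
            paths["annotation"])
  writeLines(co$immune_genes, paths["immune_genes"])
  .writeTSV(co$clin, paths["clinical"])
  .writeTSV(data.frame(sample_id = names(co$labels),
                       label = unname(co$labels)), paths["labels"])

  tum <- co$clin$sample_id
  aux <- .withSeed(seed + 1000L, {
    lp <- co$truth$linpred[tum]
    cells <- paste0("CellType", sprintf("%02d", 1:10))
    inf <- matrix(stats::rgamma(length(tum) * 10, 2, 2),
                  length(tum), 10, dimnames = list(tum, cells))
    # two cell types track the true risk, one inversely
    inf[, 1] <- inf[, 1] + 0.5 * lp
    inf[, 2] <- inf[, 2] + 0.3 * lp
    inf[, 3] <- pmax(0, inf[, 3] - 0.4 * lp)
    inf <- inf / rowSums(inf)
    est <- cbind(StromalScore = stats::rnorm(length(tum), 0, 300),
                 ImmuneScore = stats::rnorm(length(tum), 0, 400) + 150 * lp,
                 ESTIMATEScore = NA_real_)
    est[, 3] <- est[, 1] + est[, 2]
    rownames(est) <- tum
    drugs <- paste0("Drug", LETTERS[1:5])
    ic <- matrix(stats::rnorm(length(tum) * 5, 3, 1), length(tum), 5,
                 dimnames = list(tum, drugs))
    ic[, 1] <- ic[, 1] - 0.4 * lp  # one drug more potent in high risk
    list(inf = cbind(inf, P.value = stats::runif(length(tum), 0, 0.1)),
         est = est, ic = ic)
  })
  .writeTSV(data.frame(sample_id = tum, aux$inf, check.names = FALSE),
            paths["infiltration"])
  .writeTSV(data.frame(sample_id = tum, aux$est, check.names = FALSE),
            paths["estimate"])
  .writeTSV(data.frame(sample_id = tum, aux$ic, check.names = FALSE),
            paths["ic50"])

  jsonlite::write_json(
    list(de_lnc = co$truth$de_lnc, immune_lnc = co$truth$immune_lnc,
         planted_pairs = co$truth$planted_pairs,
         censoring_horizon = co$truth$censoring_horizon,
         seed = spec$seed, size = size),
    paths["truth"], auto_unbox = TRUE, digits = NA)

  cfg <- defaultPipelineConfig(dir)
  if (size == "tiny") {
    cfg$lasso$n_cycles <- 25L
    cfg$lasso$n_folds <- 5L
    cfg$cox_p_max <- 0.2  # 40 tumor samples: keep the smoke run fed
  }
  yaml::write_yaml(cfg, paths["config"])
  attr(paths, "cohort") <- co
  invisible(paths)
}
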