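## Pipeline orchestration: a configured, logged, resumable run of
## screen -> pairs -> model -> evaluation (-> immune landscape), with a
## machine-readable manifest and checksum-based stage skipping.

#' Default pipeline configuration
#'
#' Returns the configuration list consumed by [runPipeline()], pointing at
#' the canonical file names inside \code{dir} and carrying every published
#' threshold of the method: |r| >= 0.4 and p <= 0.001 for the immune
#' coexpression screen, |logFC| > 1 and FDR < 0.05 for differential
#' expression, strict (0.2, 0.8) pair-validity bounds, p < 0.001 for the
#' univariate Cox screen, 1000 LASSO cycles with 10 folds, a 365-day primary
#' ROC horizon with 3/5/10-year extras, and a 1:1 train/test split.
#'
#' @param dir directory holding the input files.
#' @return nested configuration list (serializable as YAML).
#' @export
defaultPipelineConfig <- function(dir = ".") {
  list(
    inputs = list(
      expression = file.path(dir, "expression.tsv"),
      annotation = file.path(dir, "annotation.tsv"),
      immune_genes = file.path(dir, "immune_genes.txt"),
      clinical = file.path(dir, "clinical.tsv"),
      labels = file.path(dir, "sample_labels.tsv"),
      infiltration = file.path(dir, "infiltration.tsv"),
      estimate = file.path(dir, "estimate_scores.tsv"),
      ic50 = file.path(dir, "drug_ic50.tsv")),
    thresholds = list(r_min = 0.4, p_max_corr = 0.001, logfc_min = 1.0,
                      fdr_max = 0.05, pair_low = 0.2, pair_high = 0.8),
    cox_p_max = 0.001,
    lasso = list(n_cycles = 1000L, n_folds = 10L, seed = 1L),
    roc = list(horizon = 365, extra_horizons = c(1095, 1825, 3650),
               method = "nne"),
    split = list(ratio = 0.5, seed = 1L),
    fit_scope = "full",
    out_dir = file.path(dir, "run"))
}

.validateConfig <- function(config) {
  th <- config$thresholds
  if (is.null(th)) stop("config has no 'thresholds' block")
  if (!is.numeric(th$pair_low) || !is.numeric(th$pair_high) ||
      th$pair_low >= th$pair_high || th$pair_low < 0 || th$pair_high > 1)
    stop("config: require 0 <= pair_low < pair_high <= 1")
  if (th$r_min < 0 || th$r_min > 1) stop("config: r_min must be in [0,1]")
  for (nm in c("p_max_corr", "fdr_max"))
    if (th[[nm]] <= 0 || th[[nm]] > 1)
      stop("config: ", nm, " must be in (0,1]")
  if (config$cox_p_max <= 0 || config$cox_p_max > 1)
    stop("config: cox_p_max must be in (0,1]")
  if (any(c(config$roc$horizon, unlist(config$roc$extra_horizons)) <= 0))
    stop("config: ROC horizons must be positive")
  if (!config$fit_scope %in% c("full", "train"))
    stop("config: fit_scope must be 'full' or 'train'")
  invisible(config)
}

## md5 of an in-memory object (via a temp file; tools::md5sum is file-based)
.hashObject <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(utils::capture.output(utils::str(x, vec.len = 1e6,
                                              digits.d = 15)), f)
  unname(tools::md5sum(f))
}

.stageKey <- function(files, cfg_subset) {
  files <- files[!is.na(files) & file.exists(files)]
  .hashObject(list(files = unname(tools::md5sum(files)), cfg = cfg_subset))
}

.stageFresh <- function(run_dir, stage, key, outputs) {
  state_file <- file.path(run_dir, paste0(".state_", stage, ".json"))
  if (!file.exists(state_file)) return(FALSE)
  st <- tryCatch(jsonlite::read_json(state_file), error = function(e) NULL)
  !is.null(st) && identical(st$key, unname(key)) &&
    all(file.exists(file.path(run_dir, unlist(outputs))))
}

.stageDone <- function(run_dir, stage, key) {
  jsonlite::write_json(list(stage = stage, key = unname(key)),
                       file.path(run_dir, paste0(".state_", stage, ".json")),
                       auto_unbox = TRUE)
}

#' Run the full signature pipeline
#'
#' Executes screen -> pairs -> model -> evaluation, and the immune-landscape
#' stage when auxiliary tables are configured, writing per-stage TSV/JSON
#' artifacts plus a manifest recording seeds and in/out counts at every
#' filter. Stages whose inputs (file checksums and configuration) are
#' unchanged and whose outputs exist are skipped, making reruns cheap and
#' idempotent.
#'
#' @param config a configuration list (see [defaultPipelineConfig()]) or the
#'   path to a YAML file holding one.
#' @param force rerun all stages even if fresh.
#' @return the run directory path, invisibly.
#' @export
runPipeline <- function(config, force = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  .validateConfig(config)
  run_dir <- config$out_dir
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = config, counts = list(), stages = list())
  inp <- config$inputs
  th <- config$thresholds

  stage_wrap <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## ---- stage: screen ----------------------------------------------------
  screen_out <- list("correlation_hits.tsv", "de_results.tsv",
                     "de_irlnc.txt")
  key <- .stageKey(unlist(inp[c("expression", "annotation", "immune_genes",
                                "clinical", "labels")]),
                   list(th[c("r_min", "p_max_corr", "logfc_min",
                             "fdr_max")]))
  if (force || !.stageFresh(run_dir, "screen", key, screen_out)) {
    stage_wrap("screen", {
      expr <- readExpression(inp$expression)
      ann <- readGeneAnnotation(inp$annotation)
      immune <- readImmuneGeneSet(inp$immune_genes)
      lab_df <- utils::read.table(inp$labels, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
      labels <- stats::setNames(lab_df$label, lab_df$sample_id)
      bt <- splitBiotypes(expr, ann)
      tum <- names(labels)[labels == "tumor"]
      tum <- intersect(colnames(expr), tum)
      corr <- correlateToImmune(bt$lnc[, tum, drop = FALSE],
                                bt$mrna[, tum, drop = FALSE],
                                immune, r_min = th$r_min,
                                p_max = th$p_max_corr)
      de <- differentialExpression(
        bt$lnc[corr$irlnc_ids, , drop = FALSE], labels,
        logfc_min = th$logfc_min, fdr_max = th$fdr_max)
      .writeTSV(corr$hits, file.path(run_dir, "correlation_hits.tsv"))
      .writeTSV(de, file.path(run_dir, "de_results.tsv"))
      writeLines(de$gene_id[de$flagged],
                 file.path(run_dir, "de_irlnc.txt"))
      .stageDone(run_dir, "screen", key)
    })
  } else message("stage 'screen' fresh; skipped")

  de_irlnc <- readLines(file.path(run_dir, "de_irlnc.txt"))

  ## ---- stage: pairs -----------------------------------------------------
  pairs_out <- list("pair_matrix.tsv")
  key <- .stageKey(c(inp$expression, inp$clinical,
                     file.path(run_dir, "de_irlnc.txt")),
                   list(th[c("pair_low", "pair_high")]))
  if (force || !.stageFresh(run_dir, "pairs", key, pairs_out)) {
    stage_wrap("pairs", {
      if (length(de_irlnc) < 2)
        stop("fewer than 2 DE immune-related lncRNAs; nothing to pair")
      expr <- readExpression(inp$expression)
      clin <- readClinical(inp$clinical)
      al <- alignCohort(expr[de_irlnc, , drop = FALSE], clin)
      pm <- buildPairMatrix(al$expr)
      pm <- filterValidPairs(pm, low = th$pair_low, high = th$pair_high)
      writePairMatrix(pm, file.path(run_dir, "pair_matrix.tsv"))
      .stageDone(run_dir, "pairs", key)
    })
  } else message("stage 'pairs' fresh; skipped")

  ## ---- stage: model -----------------------------------------------------
  model_out <- list("signature.json", "cox_screen.tsv", "split.json")
  key <- .stageKey(c(inp$clinical, file.path(run_dir, "pair_matrix.tsv")),
                   list(cox_p_max = config$cox_p_max, lasso = config$lasso,
                        split = config$split,
                        fit_scope = config$fit_scope))
  if (force || !.stageFresh(run_dir, "model", key, model_out)) {
    stage_wrap("model", {
      pm <- readPairMatrix(file.path(run_dir, "pair_matrix.tsv"))
      clin <- readClinical(inp$clinical)
      split <- splitTrainTest(intersect(sampleIds(pm), clin$sample_id),
                              ratio = config$split$ratio,
                              seed = config$split$seed)
      jsonlite::write_json(split, file.path(run_dir, "split.json"),
                           auto_unbox = TRUE, digits = NA)
      fit_ids <- if (config$fit_scope == "train") split$train_ids
                 else c(split$train_ids, split$test_ids)
      pm_fit <- subsetPairs(pm, samples = intersect(sampleIds(pm), fit_ids))
      screen <- univariateCoxScreen(pm_fit, clin,
                                    p_max = config$cox_p_max)
      .writeTSV(screen, file.path(run_dir, "cox_screen.tsv"))
      kept <- screen$pair_id[screen$screened]
      if (length(kept) < 2)
        stop("fewer than 2 pairs pass the univariate Cox screen at p < ",
             config$cox_p_max, "; consider relaxing cox_p_max")
      model <- lassoCoxSelect(subsetPairs(pm_fit, pairs = kept), clin,
                              n_cycles = config$lasso$n_cycles,
                              n_folds = config$lasso$n_folds,
                              seed = config$lasso$seed)
      writeSignatureModel(model, file.path(run_dir, "signature.json"))
      .stageDone(run_dir, "model", key)
    })
  } else message("stage 'model' fresh; skipped")

  ## ---- stage: evaluation ------------------------------------------------
  eval_out <- list("risk_scores.tsv", "roc_points.tsv", "auc.tsv",
                   "signature_final.json",
                   "km_curves.tsv", "cox_independence.tsv",
                   "clinical_associations.tsv", "pca.tsv",
                   "evaluation_summary.json")
  key <- .stageKey(c(inp$clinical, file.path(run_dir, "pair_matrix.tsv"),
                     file.path(run_dir, "signature.json")),
                   list(roc = config$roc))
  if (force || !.stageFresh(run_dir, "evaluation", key, eval_out)) {
    stage_wrap("evaluation", {
      pm <- readPairMatrix(file.path(run_dir, "pair_matrix.tsv"))
      clin <- readClinical(inp$clinical)
      model <- readSignatureModel(file.path(run_dir, "signature.json"))
      split <- jsonlite::read_json(file.path(run_dir, "split.json"),
                                   simplifyVector = TRUE)
      rp <- computeRiskScores(model, pm)
      roc1 <- timeDependentROC(rp, clin, t = config$roc$horizon,
                               method = config$roc$method)
      cutoff <- optimalCutoff(roc1)
      model <- setCutoff(model, cutoff)
      writeSignatureModel(model, file.path(run_dir, "signature_final.json"))
      rp <- assignGroups(rp, cutoff)
      writeRiskProfile(rp, file.path(run_dir, "risk_scores.tsv"))
      .writeTSV(data.frame(t = roc1$t, threshold = roc1$thresholds,
                           sens = roc1$sens, spec = roc1$spec),
                file.path(run_dir, "roc_points.tsv"))
      horizons <- c(config$roc$horizon,
                    unlist(config$roc$extra_horizons))
      max_t <- max(clin$os_time)
      aucs <- lapply(horizons, function(h) {
        if (h > max_t || !any(clin$os_event == 1 & clin$os_time <= h))
          return(NULL)
        data.frame(cohort = "full", horizon = h,
                   auc = timeDependentROC(rp, clin, t = h,
                                          method = config$roc$method)$auc)
      })
      for (part in c("train", "test")) {
        ids <- intersect(split[[paste0(part, "_ids")]], names(rp@score))
        clp <- clin[clin$sample_id %in% ids, ]
        h <- config$roc$horizon
        if (length(ids) >= 3 &&
            any(clp$os_event == 1 & clp$os_time <= h)) {
          rpp <- new("RiskProfile", score = rp@score[ids],
                     group = rp@group[match(ids, names(rp@score))])
          aucs <- c(aucs, list(data.frame(
            cohort = part, horizon = h,
            auc = timeDependentROC(rpp, clp, t = h,
                                   method = config$roc$method)$auc)))
        }
      }
      auc_tab <- do.call(rbind, aucs)
      .writeTSV(auc_tab, file.path(run_dir, "auc.tsv"))
      km <- kmLogrank(rp, clin)
      .writeTSV(km$curves, file.path(run_dir, "km_curves.tsv"))
      covars <- intersect(c("age", "sex", "t_stage", "n_stage", "m_stage",
                            "stage"), colnames(clin))
      cx <- coxIndependence(rp, clin, covars)
      cx_tab <- rbind(cbind(analysis = "univariate", cx$univariate),
                      cbind(analysis = "multivariate", cx$multivariate))
      .writeTSV(cx_tab, file.path(run_dir, "cox_independence.tsv"))
      cat_covars <- setdiff(covars, "age")
      assoc <- clinicalAssociations(rp, clin, cat_covars)
      .writeTSV(assoc, file.path(run_dir, "clinical_associations.tsv"))
      pca <- pcaProjection(pm, rp)
      .writeTSV(pca$coords, file.path(run_dir, "pca.tsv"))
      jsonlite::write_json(
        list(signature_size = length(model@pairs), cutoff = cutoff,
             auc = stats::setNames(as.list(auc_tab$auc),
                                   paste0(auc_tab$cohort, "_",
                                          auc_tab$horizon, "d")),
             n_high = sum(rp@group == "high"),
             n_low = sum(rp@group == "low"),
             logrank_chisq = km$logrank_chisq,
             logrank_p = km$logrank_p,
             pca_var_explained = pca$var_explained[1:2]),
        file.path(run_dir, "evaluation_summary.json"),
        auto_unbox = TRUE, digits = NA)
      .stageDone(run_dir, "evaluation", key)
    })
  } else message("stage 'evaluation' fresh; skipped")

  ## ---- stage: immune landscape (optional) -------------------------------
  have_inf <- !is.null(inp$infiltration) && file.exists(inp$infiltration)
  have_est <- !is.null(inp$estimate) && file.exists(inp$estimate)
  have_ic <- !is.null(inp$ic50) && file.exists(inp$ic50)
  if (have_inf || have_est || have_ic) {
    imm_out <- list("immune_landscape.tsv")
    key <- .stageKey(c(unlist(inp[c("infiltration", "estimate", "ic50")]),
                       file.path(run_dir, "risk_scores.tsv")), list())
    if (force || !.stageFresh(run_dir, "immune", key, imm_out)) {
      stage_wrap("immune", {
        rs <- utils::read.table(file.path(run_dir, "risk_scores.tsv"),
                                header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
        rp <- new("RiskProfile",
                  score = stats::setNames(rs$risk_score, rs$sample_id),
                  group = factor(rs$group, levels = c("low", "high")))
        blocks <- list()
        if (have_inf) {
          tab <- cibersortQCFilter(readSampleFeatureTable(inp$infiltration))
          blocks$infiltration_corr <- cbind(
            source = "infiltration", kind = "spearman",
            correlateWithRisk(rp, tab))
          blocks$infiltration_grp <- cbind(
            source = "infiltration", kind = "contrast",
            contrastGroups(rp, tab))
        }
        if (have_est) {
          tab <- readSampleFeatureTable(inp$estimate)
          blocks$estimate_corr <- cbind(source = "estimate",
                                        kind = "spearman",
                                        correlateWithRisk(rp, tab))
          blocks$estimate_grp <- cbind(source = "estimate",
                                       kind = "contrast",
                                       contrastGroups(rp, tab))
        }
        if (have_ic) {
          tab <- readSampleFeatureTable(inp$ic50)
          blocks$ic50_grp <- cbind(source = "ic50", kind = "contrast",
                                   contrastGroups(rp, tab))
        }
        out <- do.call(rbind, lapply(blocks, function(b) {
          base <- data.frame(source = b$source, kind = b$kind,
                             feature = b$feature, p = b$p,
                             stars = b$stars, stringsAsFactors = FALSE)
          base$rho <- if ("rho" %in% colnames(b)) b$rho else NA_real_
          base$median_high <-
            if ("median_high" %in% colnames(b)) b$median_high else NA_real_
          base$median_low <-
            if ("median_low" %in% colnames(b)) b$median_low else NA_real_
          base$direction <-
            if ("direction" %in% colnames(b)) b$direction else NA_character_
          base
        }))
        rownames(out) <- NULL
        .writeTSV(out, file.path(run_dir, "immune_landscape.tsv"))
        .stageDone(run_dir, "immune", key)
      })
    } else message("stage 'immune' fresh; skipped")
  }

  jsonlite::write_json(
    list(finished = format(Sys.time(), tz = "UTC"),
         config = config,
         artifacts = sort(setdiff(list.files(run_dir),
                                  "manifest.json"))),
    file.path(run_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(run_dir)
}

#' Summarize a completed pipeline run
#'
#' @param run_dir directory written by [runPipeline()].
#' @return character vector of markdown lines (also written to
#'   \code{summary.md} in the run directory).
#' @export
reportSummary <- function(run_dir) {
  need <- c(model = "signature.json",
            evaluation = "evaluation_summary.json",
            evaluation2 = "signature_final.json",
            evaluation3 = "cox_independence.tsv")
  miss <- need[!file.exists(file.path(run_dir, need))]
  if (length(miss))
    stop("incomplete run; missing stage artifact(s): ",
         paste(unique(sub("[0-9]+$", "", names(miss))), collapse = ", "))
  ev <- jsonlite::read_json(file.path(run_dir, "evaluation_summary.json"),
                            simplifyVector = TRUE)
  model <- readSignatureModel(file.path(run_dir, "signature_final.json"))
  cx <- utils::read.table(file.path(run_dir, "cox_independence.tsv"),
                          header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  lines <- c(
    "# Pair-signature run summary", "",
    sprintf("- signature size: %d pairs", ev$signature_size),
    sprintf("- risk-score cutoff (Youden, primary horizon): %.4f",
            ev$cutoff),
    sprintf("- risk groups: %d high / %d low", ev$n_high, ev$n_low),
    sprintf("- log-rank: chisq = %.3f, p = %.3g", ev$logrank_chisq,
            ev$logrank_p), "",
    "## AUC by cohort and horizon", "")
  for (nm in names(ev$auc))
    lines <- c(lines, sprintf("- %s: %.3f", nm, ev$auc[[nm]]))
  lines <- c(lines, "", "## Signature pairs", "")
  for (i in seq_along(model@pairs))
    lines <- c(lines, sprintf("- %s: beta = %+.4f", model@pairs[i],
                              model@betas[i]))
  lines <- c(lines, "", "## Cox independence (multivariate)", "")
  mv <- cx[cx$analysis == "multivariate", ]
  for (i in seq_len(nrow(mv)))
    lines <- c(lines, sprintf("- %s: HR = %.3f [%.3f-%.3f], p = %.3g",
                              mv$covariate[i], mv$hr[i], mv$ci_low[i],
                              mv$ci_high[i], mv$p[i]))
  writeLines(lines, file.path(run_dir, "summary.md"))
  invisible(lines)
}
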