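test_that("cohort generation is deterministic given the seed", {
  sp <- cohortSpec(n_tumor = 30L, n_normal = 10L, n_lnc = 12L,
                   n_immune_mrna = 8L, n_other_mrna = 6L,
                   n_other_biotype = 2L, n_de_lnc = 6L, n_immune_lnc = 8L,
                   n_planted = 2L, seed = 5L)
  a <- suppressMessages(generateCohort(sp))
  b <- suppressMessages(generateCohort(sp))
  expect_identical(a$expr, b$expr)
  expect_identical(a$clin, b$clin)
  expect_identical(a$truth$planted_pairs, b$truth$planted_pairs)
})

test_that("invalid cohort specs are rejected", {
  expect_error(cohortSpec(censoring = 1.5))
  expect_error(cohortSpec(n_de_lnc = 4L, n_planted = 5L), "disjoint")
  expect_error(cohortSpec(planted_pairs = data.frame(
    pair_a = "LNC001", pair_b = "LNC001", beta = 1)), "same gene")
})

test_that("realized censoring tracks the target within 5 points", {
  for (target in c(0.2, 0.3, 0.5)) {
    co <- generateCohort(cohortSpec(n_tumor = 400L, n_normal = 10L,
                                    n_lnc = 20L, n_immune_mrna = 10L,
                                    n_other_mrna = 5L, n_de_lnc = 10L,
                                    n_immune_lnc = 12L, n_planted = 3L,
                                    censoring = target, seed = 17L))
    realized <- mean(co$clin$os_event == 0)
    expect_lt(abs(realized - target), 0.05)
  }
})

test_that("a Cox fit on the true linear predictor recovers slope 1", {
  co <- generateCohort(cohortSpec(n_tumor = 1000L, n_normal = 10L,
                                  n_lnc = 20L, n_immune_mrna = 10L,
                                  n_other_mrna = 5L, n_de_lnc = 10L,
                                  n_immune_lnc = 12L, n_planted = 3L,
                                  seed = 29L))
  d <- data.frame(time = co$clin$os_time, status = co$clin$os_event,
                  lp = co$truth$linpred[co$clin$sample_id])
  slope <- unname(coef(survival::coxph(
    survival::Surv(time, status) ~ lp, data = d, ties = "efron")))
  expect_lt(abs(slope - 1.0), 0.15)
})

test_that("immune-module lncRNAs pass the coexpression screen", {
  co <- generateCohort(cohortSpec(n_tumor = 200L, n_normal = 20L,
                                  n_lnc = 60L, n_immune_mrna = 30L,
                                  n_other_mrna = 10L, n_de_lnc = 20L,
                                  n_immune_lnc = 40L, n_planted = 5L,
                                  immune_corr = 0.6, seed = 37L))
  tum <- names(co$labels)[co$labels == "tumor"]
  lnc <- co$expr[grep("^LNC", rownames(co$expr)), tum]
  mrna <- co$expr[co$immune_genes, tum]
  out <- suppressMessages(correlateToImmune(lnc, mrna, co$immune_genes))
  recovered <- mean(co$truth$immune_lnc %in% out$irlnc_ids)
  expect_gte(recovered, 0.9)
})

test_that("DE lncRNAs and only few others are flagged", {
  co <- generateCohort(cohortSpec(n_tumor = 150L, n_normal = 50L,
                                  n_lnc = 60L, n_immune_mrna = 20L,
                                  n_other_mrna = 10L, n_de_lnc = 20L,
                                  n_immune_lnc = 30L, n_planted = 5L,
                                  seed = 41L))
  lnc <- co$expr[grep("^LNC", rownames(co$expr)), ]
  de <- suppressMessages(differentialExpression(lnc, co$labels))
  flagged <- de$gene_id[de$flagged]
  expect_gte(mean(co$truth$de_lnc %in% flagged), 0.9)
  expect_lte(sum(!flagged %in% co$truth$de_lnc), 3)
})

test_that("a null cohort carries no prognostic pair signal", {
  co <- generateCohort(cohortSpec(n_tumor = 300L, n_normal = 20L,
                                  n_lnc = 20L, n_immune_mrna = 10L,
                                  n_other_mrna = 5L, n_de_lnc = 10L,
                                  n_immune_lnc = 12L, n_planted = 3L,
                                  planted_beta = 0, seed = 53L))
  # any fixed risk score built from pairs concords with survival at ~0.5
  tum <- co$clin$sample_id
  pm <- buildPairMatrix(co$expr[co$truth$de_lnc, tum])
  set.seed(1)
  betas <- rnorm(nrow(pairValues(pm)))
  model <- new("SignatureModel", pairs = pairIds(pm), betas = betas,
               lambda = 0.1, cutoff = NA_real_, provenance = list())
  rp <- computeRiskScores(model, pm)
  cidx <- survival::concordance(
    survival::Surv(co$clin$os_time, co$clin$os_event) ~
      riskScores(rp)[co$clin$sample_id])$concordance
  expect_gt(cidx, 0.42); expect_lt(cidx, 0.58)
})

test_that("measurement distortion never changes the pair matrix", {
  base <- cohortSpec(n_tumor = 50L, n_normal = 10L, n_lnc = 12L,
                     n_immune_mrna = 8L, n_other_mrna = 4L,
                     n_de_lnc = 6L, n_immune_lnc = 8L, n_planted = 2L,
                     seed = 61L)
  dist <- base; dist$distortion <- "per_sample_monotone"
  a <- generateCohort(base); b <- generateCohort(dist)
  lnc <- grep("^LNC", rownames(a$expr), value = TRUE)
  expect_false(identical(a$expr, b$expr))
  expect_identical(pairValues(buildPairMatrix(a$expr[lnc, ])),
                   pairValues(buildPairMatrix(b$expr[lnc, ])))
  # survival is generated before distortion: clinical tables agree
  expect_identical(a$clin, b$clin)
})

test_that("fixture bundles are seed-stable on disk", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- suppressMessages(endToEndFixture("tiny", d1, seed = 3))
  p2 <- suppressMessages(endToEndFixture("tiny", d2, seed = 3))
  for (nm in setdiff(names(p1), "config")) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]),
                     label = paste("bundle file", nm))
  }
})
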