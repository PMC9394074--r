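pmFromValues <- function(values) {
  ids <- sprintf("P%02dA|P%02dB", seq_len(nrow(values)),
                 seq_len(nrow(values)))
  dimnames(values) <- list(ids, sprintf("S%03d", seq_len(ncol(values))))
  new("PairMatrix", pairA = sub("\\|.*", "", ids),
      pairB = sub(".*\\|", "", ids), values = values)
}

test_that("univariate Cox beta matches grid search of the Efron
           partial likelihood", {
  # deterministic 6-subject toy (groups interleaved so the partial
  # likelihood has a finite maximum)
  time <- 1:6; status <- rep(1, 6); x <- c(1, 0, 1, 0, 1, 0)
  pm <- pmFromValues(matrix(x, 1, 6))
  clin <- data.frame(sample_id = sprintf("S%03d", 1:6), os_time = time,
                     os_event = status)
  fit <- suppressMessages(univariateCoxScreen(pm, clin, p_max = 1))
  expect_equal(fit$beta, oracleCoxBeta(time, status, x), tolerance = 1e-3)
  expect_equal(fit$hr, exp(fit$beta), tolerance = 1e-12)
  expect_true(fit$ci_low <= fit$hr && fit$hr <= fit$ci_high)

  # property over random tiny instances, including ties
  set.seed(14)
  for (i in 1:15) {
    n <- sample(4:8, 1)
    time <- sample(1:5, n, replace = TRUE)
    status <- rbinom(n, 1, 0.8)
    x <- rbinom(n, 1, 0.5)
    if (sum(status) == 0 || var(x) == 0 ||
        var(x[status == 1]) == 0) next
    beta_hat <- tryCatch(
      unname(coef(survival::coxph(survival::Surv(time, status) ~ x,
                                  ties = "efron"))),
      warning = function(w) NA_real_)
    if (!is.finite(beta_hat) || abs(beta_hat) > 4) next  # separation
    pm <- pmFromValues(matrix(x, 1, n))
    clin <- data.frame(sample_id = sprintf("S%03d", 1:n), os_time = time,
                       os_event = status)
    fit <- suppressWarnings(suppressMessages(
      univariateCoxScreen(pm, clin, p_max = 1)))
    expect_equal(fit$beta, oracleCoxBeta(time, status, x),
                 tolerance = 1e-3)
  }
})

test_that("constant pairs are skipped, no-event cohorts are an error", {
  values <- rbind(rep(1, 6), c(1, 0, 1, 0, 1, 0))
  pm <- pmFromValues(values)
  clin <- data.frame(sample_id = sprintf("S%03d", 1:6), os_time = 1:6,
                     os_event = rep(1, 6))
  expect_warning(suppressMessages(univariateCoxScreen(pm, clin, 1)),
                 "constant")
  res <- suppressWarnings(suppressMessages(
    univariateCoxScreen(pm, clin, 1)))
  expect_identical(nrow(res), 1L)
  clin$os_event <- 0
  expect_error(suppressMessages(univariateCoxScreen(pm, clin, 1)),
               "no events")
})

test_that("univariate Cox recovers a planted log-hazard ratio of 1", {
  hits <- 0; seeds <- 1:50
  for (s in seeds) {
    co <- makePairCohort(500, 1, 1, 1.0, censoring = 0.3, seed = s)
    fit <- suppressWarnings(suppressMessages(
      univariateCoxScreen(co$pm, co$clin, p_max = 1)))
    if (abs(fit$beta - 1.0) <= 0.25) hits <- hits + 1
  }
  expect_gte(hits, 0.9 * length(seeds))
})

test_that("penalized fit at lambda = 0 matches unpenalized Cox", {
  co <- makePairCohort(80, 3, 1:3, c(0.8, -0.5, 0.3), censoring = 0.2,
                       seed = 77)
  b0 <- lassoCoxFit(co$pm, co$clin, lambda = 0)
  d <- as.data.frame(t(pairValues(co$pm)))
  colnames(d) <- paste0("x", 1:3)
  d$time <- co$clin$os_time; d$status <- co$clin$os_event
  ref <- coef(survival::coxph(survival::Surv(time, status) ~ x1 + x2 + x3,
                              data = d, ties = "efron"))
  expect_equal(unname(b0), unname(ref), tolerance = 1e-4)
})

test_that("nonzero-coefficient count is monotone along the penalty path", {
  co <- makePairCohort(150, 20, 1:3, c(1, -1, 1), censoring = 0.25,
                       seed = 5)
  fit <- glmnet::glmnet(t(pairValues(co$pm)),
                        survival::Surv(co$clin$os_time, co$clin$os_event),
                        family = "cox", alpha = 1)
  nz <- colSums(as.matrix(fit$beta) != 0)
  expect_true(all(diff(nz[order(fit$lambda, decreasing = TRUE)]) >= 0))
})

test_that("lassoCoxSelect is reproducible and errors on full shrinkage", {
  co <- makePairCohort(120, 8, 1:2, c(1.2, -1.2), censoring = 0.2,
                       seed = 31)
  m1 <- suppressMessages(lassoCoxSelect(co$pm, co$clin, n_cycles = 5,
                                        n_folds = 5, seed = 99))
  m2 <- suppressMessages(lassoCoxSelect(co$pm, co$clin, n_cycles = 5,
                                        n_folds = 5, seed = 99))
  expect_identical(pairIds(m1), pairIds(m2))
  expect_identical(coef(m1), coef(m2))
  expect_identical(m1@lambda, m2@lambda)
  expect_true(all(coef(m1) != 0))
  expect_true(all(pairIds(m1) %in% pairIds(co$pm)))
})

test_that("risk scores equal the brute-force linear predictor", {
  set.seed(64)
  values <- matrix(rbinom(14 * 9, 1, 0.5), 14, 9) * 1.0
  pm <- pmFromValues(values)
  betas <- round(rnorm(14), 3)
  model <- new("SignatureModel", pairs = pairIds(pm), betas = betas,
               lambda = 0.1, cutoff = NA_real_, provenance = list())
  rp <- computeRiskScores(model, pm)
  manual <- vapply(seq_len(ncol(values)), function(s)
    sum(betas * values[, s]), numeric(1))
  expect_identical(unname(riskScores(rp)), manual)

  # one-term and all-zero edge cases
  m1 <- new("SignatureModel", pairs = pairIds(pm)[1], betas = 2,
            lambda = 0, cutoff = NA_real_, provenance = list())
  rp1 <- computeRiskScores(m1, pm)
  expect_identical(unname(riskScores(rp1)), unname(2 * values[1, ]))

  bad <- new("SignatureModel", pairs = "ZZ|YY", betas = 1, lambda = 0,
             cutoff = NA_real_, provenance = list())
  expect_error(computeRiskScores(bad, pm), "ZZ\\|YY")
})

test_that("risk scores are invariant to per-sample monotone distortion", {
  set.seed(3)
  m <- matrix(exp(rnorm(10 * 30, 1)), 10, 30,
              dimnames = list(sprintf("L%02d", 1:10),
                              sprintf("s%02d", 1:30)))
  pm <- suppressMessages(filterValidPairs(buildPairMatrix(m)))
  betas <- rnorm(nrow(pairValues(pm)))
  model <- new("SignatureModel", pairs = pairIds(pm), betas = betas,
               lambda = 0.05, cutoff = NA_real_, provenance = list())
  ref <- riskScores(computeRiskScores(model, pm))
  for (d in 1:5) {
    md <- applyMonotoneDistortion(m, seed = d)
    pmd <- suppressMessages(filterValidPairs(buildPairMatrix(md)))
    expect_identical(riskScores(computeRiskScores(model, pmd)), ref)
  }
})

test_that("signature models survive a JSON round trip", {
  model <- new("SignatureModel", pairs = c("A|B", "C|D"),
               betas = c(0.5, -1.25), lambda = 0.031, cutoff = 0.868,
               provenance = list(seed = 1L, n_cycles = 10L, n_folds = 5L,
                                 selection_freq = c("A|B" = 1,
                                                    "C|D" = 0.8)))
  f <- withr::local_tempfile(fileext = ".json")
  writeSignatureModel(model, f)
  back <- readSignatureModel(f)
  expect_identical(back@pairs, model@pairs)
  expect_equal(back@betas, model@betas)
  expect_equal(back@lambda, model@lambda)
  expect_equal(back@cutoff, model@cutoff)
})
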