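rpFromScores <- function(score, group = NULL) {
  if (is.null(group))
    group <- factor(rep(NA_character_, length(score)),
                    levels = c("low", "high"))
  new("RiskProfile", score = score, group = group)
}

simClin <- function(n, seed, rate = 1 / 500, censor_at = Inf,
                    lp = rep(0, n)) {
  set.seed(seed)
  t_ev <- rexp(n, rate * exp(lp))
  data.frame(sample_id = sprintf("S%04d", 1:n),
             os_time = pmin(t_ev, censor_at),
             os_event = as.integer(t_ev <= censor_at))
}

test_that("a marker that orders event times perfectly gives AUC 1", {
  n <- 40
  clin <- simClin(n, seed = 2)
  sc <- setNames(clin$os_time * -1, clin$sample_id)  # earlier death = higher
  roc <- timeDependentROC(rpFromScores(sc), clin, t = 365, method = "km")
  expect_identical(roc$auc, 1)
})

test_that("km-method sens/spec equal uncensored counting, bit-exactly", {
  set.seed(10)
  clin <- data.frame(sample_id = sprintf("S%04d", 1:10),
                     os_time = c(30, 90, 150, 200, 400, 500, 700, 900,
                                 1000, 1200),
                     os_event = rep(1L, 10))
  sc <- setNames(rnorm(10), clin$sample_id)
  roc <- timeDependentROC(rpFromScores(sc), clin, t = 365, method = "km")
  oracle <- oracleCountingROC(unname(sc), clin$os_time, 365,
                              roc$thresholds)
  expect_identical(roc$sens, oracle$sens)
  expect_identical(roc$spec, oracle$spec)
})

test_that("an uninformative marker has AUC near one half", {
  n <- 800
  clin <- simClin(n, seed = 19)
  sc <- setNames(rnorm(n), clin$sample_id)
  for (m in c("km", "nne")) {
    roc <- timeDependentROC(rpFromScores(sc), clin, t = 365, method = m)
    expect_gt(roc$auc, 0.42)
    expect_lt(roc$auc, 0.58)
  }
})

test_that("AUC is invariant to strictly increasing marker transforms", {
  n <- 120
  clin <- simClin(n, seed = 23, censor_at = 900)
  sc <- setNames(rnorm(n), clin$sample_id)
  for (m in c("km", "nne")) {
    a1 <- timeDependentROC(rpFromScores(sc), clin, t = 365, method = m)$auc
    a2 <- timeDependentROC(rpFromScores(exp(2 * sc)), clin, t = 365,
                           method = m)$auc
    expect_equal(a1, a2, tolerance = 1e-12)
  }
  expect_error(timeDependentROC(rpFromScores(sc), clin, t = -1), "horizon")
})

test_that("Youden cutoff equals the exhaustive scan with the tie rule", {
  roc <- structure(list(t = 365, thresholds = c(1, 2, 3),
                        sens = c(1.0, 0.9, 0.4),
                        spec = c(0.2, 0.8, 0.9), auc = NA,
                        method = "km"), class = "TimedROC")
  expect_identical(optimalCutoff(roc), 2)
  flat <- structure(list(t = 365, thresholds = c(5, 7, 9),
                         sens = c(0.9, 0.8, 0.7),
                         spec = c(0.1, 0.2, 0.3), auc = NA,
                         method = "km"), class = "TimedROC")
  expect_identical(optimalCutoff(flat), 5)  # constant J: smallest wins

  set.seed(77)
  for (i in 1:30) {
    k <- sample(5:200, 1)
    roc <- structure(list(t = 1, thresholds = sort(runif(k)),
                          sens = runif(k), spec = runif(k), auc = NA,
                          method = "km"), class = "TimedROC")
    j <- roc$sens + roc$spec - 1
    best <- min(roc$thresholds[j == max(j)])
    expect_identical(optimalCutoff(roc), best)
  }
})

test_that("group assignment is strict at the cutoff", {
  sc <- setNames(c(0.5, 1.0, 1.5), c("a", "b", "c"))
  rp <- suppressMessages(assignGroups(rpFromScores(sc), 1.0))
  expect_identical(as.character(riskGroups(rp)), c("low", "low", "high"))
  rp_all_low <- suppressMessages(assignGroups(rpFromScores(sc), 99))
  expect_true(all(riskGroups(rp_all_low) == "low"))
})

test_that("log-rank statistic matches a hand tabulation and is symmetric", {
  # 8-subject toy with censoring
  clin <- data.frame(sample_id = letters[1:8],
                     os_time = c(10, 20, 30, 40, 50, 60, 70, 80),
                     os_event = c(1, 1, 0, 1, 1, 0, 1, 1))
  g <- setNames(rep(c("high", "low"), 4), letters[1:8])
  res <- kmLogrank(g, clin)
  expect_equal(res$logrank_chisq,
               oracleLogrank(clin$os_time, clin$os_event, g),
               tolerance = 1e-9)
  gs <- setNames(ifelse(g == "high", "low", "high"), names(g))
  expect_equal(kmLogrank(gs, clin)$logrank_chisq, res$logrank_chisq,
               tolerance = 1e-12)
})

test_that("identical survival in both groups gives statistic 0, p 1", {
  base <- data.frame(os_time = c(5, 10, 15, 20), os_event = c(1, 0, 1, 1))
  clin <- data.frame(sample_id = sprintf("S%02d", 1:8),
                     os_time = rep(base$os_time, 2),
                     os_event = rep(base$os_event, 2))
  g <- setNames(rep(c("high", "low"), each = 4), clin$sample_id)
  res <- kmLogrank(g, clin)
  expect_equal(res$logrank_chisq, 0, tolerance = 1e-12)
  expect_equal(res$logrank_p, 1, tolerance = 1e-12)
})

test_that("KM curves without censoring equal empirical survival", {
  clin <- simClin(60, seed = 31)
  g <- setNames(rep(c("high", "low"), 30), clin$sample_id)
  res <- kmLogrank(g, clin)
  for (lab in c("high", "low")) {
    cv <- res$curves[res$curves$group == lab, ]
    tt <- clin$os_time[g[clin$sample_id] == lab]
    emp <- vapply(cv$time, function(u) mean(tt > u), numeric(1))
    expect_equal(cv$surv, emp, tolerance = 1e-12)
  }
})

test_that("multivariate Cox equals univariate for a single covariate", {
  clin <- simClin(100, seed = 41)
  clin$age <- rnorm(100, 50, 10)
  res <- coxIndependence(NULL, clin, "age")
  expect_equal(res$univariate$beta, res$multivariate$beta,
               tolerance = 1e-10)
  expect_equal(res$univariate$p, res$multivariate$p, tolerance = 1e-10)
})

test_that("collinear covariates are rejected by name", {
  clin <- simClin(50, seed = 43)
  clin$a <- rnorm(50)
  clin$b <- 2 * clin$a
  expect_error(coxIndependence(NULL, clin, c("a", "b")), "collinear")
})

test_that("multivariate adjustment beats univariate under confounding", {
  wins <- 0; n_seeds <- 50
  for (s in seq_len(n_seeds)) {
    set.seed(s)
    n <- 300
    risk <- rnorm(n)
    conf <- 0.7 * risk + rnorm(n, sd = sqrt(1 - 0.49))
    beta_true <- 1.0
    lp <- beta_true * risk + 0.8 * conf
    t_ev <- rexp(n, (1 / 500) * exp(lp))
    clin <- data.frame(sample_id = sprintf("S%04d", 1:n),
                       os_time = pmin(t_ev, 1500),
                       os_event = as.integer(t_ev <= 1500),
                       conf = conf)
    rp <- rpFromScores(setNames(risk, clin$sample_id))
    res <- coxIndependence(rp, clin, "conf")
    b_uni <- res$univariate$beta[res$univariate$covariate == "risk_score"]
    b_multi <- res$multivariate$beta[
      res$multivariate$covariate == "risk_score"]
    if (abs(b_multi - beta_true) < abs(b_uni - beta_true))
      wins <- wins + 1
  }
  expect_gte(wins, 0.8 * n_seeds)
})

test_that("chi-square uses the closed form and rank tests behave", {
  clin <- data.frame(sample_id = sprintf("S%03d", 1:60),
                     os_time = rep(100, 60), os_event = rep(1, 60),
                     sex = rep(c("male", "female"), 30))
  set.seed(55)
  sc <- setNames(rnorm(60), clin$sample_id)
  rp <- suppressMessages(assignGroups(rpFromScores(sc), 0))
  out <- clinicalAssociations(rp, clin, "sex")
  tab <- table(riskGroups(rp), clin$sex)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(out$statistic[out$test == "chi_square"],
               sum((tab - e)^2 / e), tolerance = 1e-12)
  # score distributions identical across sexes: rank-sum p is large
  expect_gt(out$p[out$test == "wilcoxon_ranksum"], 0.05)

  clin$onelevel <- "x"
  expect_warning(clinicalAssociations(rp, clin, "onelevel"),
                 "single level")
})

test_that("PCA projection matches an eigendecomposition oracle", {
  set.seed(66)
  m <- matrix(rnorm(50), 5, 10,
              dimnames = list(paste0("f", 1:5), paste0("s", 1:10)))
  res <- pcaProjection(m)
  cv <- cov(t(m))
  eig <- eigen(cv, symmetric = TRUE)
  centered <- t(m) - rep(rowMeans(m), each = 10)
  ref1 <- centered %*% eig$vectors[, 1]
  # component scores agree up to sign
  expect_equal(abs(unname(res$coords$PC1)), abs(unname(ref1[, 1])),
               tolerance = 1e-8)
  expect_equal(res$var_explained,
               eig$values / sum(eig$values), tolerance = 1e-8)

  # rank-1 data: first component carries all variance
  r1 <- outer(c(1, 2, 3), rnorm(10))
  dimnames(r1) <- list(paste0("f", 1:3), paste0("s", 1:10))
  expect_equal(pcaProjection(r1)$var_explained[1], 1, tolerance = 1e-9)

  expect_error(pcaProjection(m[1, , drop = FALSE]), "at least 2")
})
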