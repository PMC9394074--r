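## Evaluation of a fitted signature: time-dependent ROC with Youden-optimal
## cutoff, risk-group assignment, Kaplan-Meier / log-rank, Cox independence
## testing, clinical associations, and PCA projection.

## Kaplan-Meier survival probability at horizon t (optionally weighted).
.kmAt <- function(time, status, t, w = NULL) {
  if (!length(time)) return(1)
  if (is.null(w)) w <- rep(1, length(time))
  keep <- w > 0
  time <- time[keep]; status <- status[keep]; w <- w[keep]
  if (!length(time)) return(1)
  o <- order(time)
  time <- time[o]; status <- status[o]; w <- w[o]
  ev <- status == 1 & time <= t
  if (!any(ev)) return(1)
  uu <- unique(time[ev])
  d <- vapply(split(w[ev], match(time[ev], uu)), sum, numeric(1))
  # at risk at u = total weight minus weight of subjects with time < u
  cw <- c(0, cumsum(w))
  atrisk <- sum(w) - cw[findInterval(uu, time, left.open = TRUE) + 1L]
  prod(1 - d / atrisk)
}

#' Time-dependent ROC curve for a survival marker
#'
#' Estimates sensitivity and specificity of the rule "marker > c" for the
#' cumulative-case / dynamic-control definition at horizon \code{t} (cases:
#' event by t; controls: event-free beyond t) under right censoring, using
#' the Heagerty-Lumley-Pepe estimators. \code{method = "km"} uses the
#' Kaplan-Meier plug-in (reduces exactly to empirical counting when there is
#' no censoring); \code{method = "nne"} smooths the conditional survival with
#' a nearest-neighbour kernel in marker percentile with half-width
#' \code{span} (default 0.25 * n^(-0.20)), which guarantees a monotone ROC
#' curve. AUC is the trapezoidal area over the (1 - specificity,
#' sensitivity) curve anchored at (0,0) and (1,1).
#'
#' @param scores a \linkS4class{RiskProfile} or named numeric marker vector.
#' @param clin clinical data.frame with sample_id, os_time, os_event.
#' @param t evaluation horizon in days (default 365).
#' @param method "nne" (default) or "km".
#' @param span nearest-neighbour half-width for "nne"; NULL for the default.
#' @return object of class \code{"TimedROC"}: list with t, thresholds
#'   (strictly sorted unique marker values), sens, spec, auc, method.
#' @export
timeDependentROC <- function(scores, clin, t = 365,
                             method = c("nne", "km"), span = NULL) {
  method <- match.arg(method)
  if (is(scores, "RiskProfile")) scores <- riskScores(scores)
  shared <- intersect(names(scores), clin$sample_id)
  if (length(shared) < 3) stop("need at least 3 shared samples")
  x <- unname(scores[shared])
  cl <- clin[match(shared, clin$sample_id), ]
  time <- cl$os_time; status <- cl$os_event
  if (t <= 0 || t > max(time)) stop("horizon t must lie within follow-up")
  if (!any(status == 1 & time <= t)) stop("no events by horizon t")
  cuts <- sort(unique(x))
  n <- length(x)
  if (method == "km") {
    sens <- spec <- numeric(length(cuts))
    if (!any(status == 0 & time <= t)) {
      # no censoring by t: the KM plug-in reduces exactly to counting
      # cases (event by t) and controls (still event-free past t)
      case <- time <= t
      for (k in seq_along(cuts)) {
        sens[k] <- sum(x > cuts[k] & case) / sum(case)
        spec[k] <- sum(x <= cuts[k] & !case) / sum(!case)
      }
    } else {
      s_all <- .kmAt(time, status, t)
      for (k in seq_along(cuts)) {
        hi <- x > cuts[k]
        f_c <- mean(hi)
        s_c <- if (any(hi)) .kmAt(time[hi], status[hi], t) else 1
        sens[k] <- (1 - s_c) * f_c / (1 - s_all)
        spec[k] <- 1 - s_c * f_c / max(s_all, .Machine$double.eps)
      }
    }
  } else {
    if (is.null(span)) span <- 0.25 * n^(-0.20)
    pct <- rank(x, ties.method = "average") / n
    s_cond <- vapply(seq_len(n), function(i) {
      w <- as.numeric(abs(pct - pct[i]) <= span)
      .kmAt(time, status, t, w = w)
    }, numeric(1))
    s_all <- mean(s_cond)
    sens <- spec <- numeric(length(cuts))
    for (k in seq_along(cuts)) {
      hi <- x > cuts[k]
      p_hi_surv <- mean(s_cond[hi]) * mean(hi)
      if (!any(hi)) p_hi_surv <- 0
      sens[k] <- (mean(hi) - p_hi_surv) / max(1 - s_all,
                                              .Machine$double.eps)
      spec[k] <- (s_all - p_hi_surv) / max(s_all, .Machine$double.eps)
    }
  }
  sens <- pmin(1, pmax(0, sens))
  spec <- pmin(1, pmax(0, spec))
  fpr <- 1 - spec
  o <- order(fpr, sens)
  xs <- c(0, fpr[o], 1); ys <- c(0, sens[o], 1)
  auc <- sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
  structure(list(t = t, thresholds = cuts, sens = sens, spec = spec,
                 auc = auc, method = method, n = n),
            class = "TimedROC")
}

#' @export
print.TimedROC <- function(x, ...) {
  cat("Time-dependent ROC at t =", x$t, "days (", x$method, "):",
      length(x$thresholds), "thresholds, AUC =", signif(x$auc, 4), "\n")
  invisible(x)
}

#' Youden-optimal cutoff of a time-dependent ROC curve
#'
#' Returns the threshold maximizing Youden's J = sensitivity + specificity
#' - 1; ties are broken toward the smaller threshold.
#'
#' @param roc a \code{"TimedROC"} object.
#' @return numeric cutoff.
#' @export
optimalCutoff <- function(roc) {
  stopifnot(inherits(roc, "TimedROC"), length(roc$thresholds) >= 1)
  j <- roc$sens + roc$spec - 1
  roc$thresholds[which.max(j)]  # which.max takes the first (smallest) tie
}

#' Assign high/low risk groups by a cutoff
#'
#' group = high iff risk score > cutoff (strict), else low.
#'
#' @param scores a \linkS4class{RiskProfile}.
#' @param cutoff finite numeric threshold.
#' @return the \linkS4class{RiskProfile} with groups set.
#' @export
assignGroups <- function(scores, cutoff) {
  stopifnot(is(scores, "RiskProfile"), is.finite(cutoff))
  grp <- factor(ifelse(scores@score > cutoff, "high", "low"),
                levels = c("low", "high"))
  message("risk groups: ", sum(grp == "high"), " high / ",
          sum(grp == "low"), " low at cutoff ", signif(cutoff, 4))
  new("RiskProfile", score = scores@score, group = grp)
}

#' Kaplan-Meier curves and log-rank test between risk groups
#'
#' @param groups a \linkS4class{RiskProfile} with groups assigned, or a
#'   named character/factor vector of group labels.
#' @param clin clinical data.frame.
#' @return list: \code{curves} (data.frame group/time/n_risk/n_event/surv),
#'   \code{logrank_chisq}, \code{logrank_p}.
#' @export
kmLogrank <- function(groups, clin) {
  if (is(groups, "RiskProfile")) {
    g <- stats::setNames(as.character(riskGroups(groups)),
                         sampleIds(groups))
  } else g <- stats::setNames(as.character(groups), names(groups))
  if (any(is.na(g))) stop("groups must be assigned before kmLogrank")
  shared <- intersect(names(g), clin$sample_id)
  cl <- clin[match(shared, clin$sample_id), ]
  grp <- factor(g[shared])
  if (nlevels(droplevels(grp)) < 2) stop("need two non-empty groups")
  if (sum(cl$os_event) < 1) stop("need at least one event")
  sf <- survival::survfit(survival::Surv(os_time, os_event) ~ grp,
                          data = data.frame(cl, grp = grp))
  strata_lab <- sub("^grp=", "", rep(names(sf$strata), sf$strata))
  curves <- data.frame(group = strata_lab, time = sf$time,
                       n_risk = sf$n.risk, n_event = sf$n.event,
                       surv = sf$surv, stringsAsFactors = FALSE)
  sd <- survival::survdiff(survival::Surv(os_time, os_event) ~ grp,
                           data = data.frame(cl, grp = grp), rho = 0)
  df <- length(sd$n) - 1
  list(curves = curves, logrank_chisq = unname(sd$chisq),
       logrank_p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

.encodeCovariate <- function(v, name) {
  if (is.numeric(v)) return(v)
  f <- factor(v)
  if (nlevels(f) < 2) stop("covariate '", name, "' is constant")
  if (nlevels(f) == 2) as.numeric(f) - 1 else as.numeric(f)
}

.coxFitTable <- function(fit) {
  s <- summary(fit)
  data.frame(covariate = rownames(s$coefficients),
             beta = s$coefficients[, "coef"],
             hr = s$conf.int[, "exp(coef)"],
             ci_low = s$conf.int[, "lower .95"],
             ci_high = s$conf.int[, "upper .95"],
             p = s$coefficients[, "Pr(>|z|)"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Univariate and multivariate Cox models of risk score and clinical factors
#'
#' Fits one univariate Cox model per covariate and one joint multivariate
#' model (Efron ties, Wald inference), the standard check that the risk
#' score predicts survival independently of age, sex and stage. Categorical
#' covariates are coded numerically (binary 0/1, multi-level by factor
#' order).
#'
#' @param scores a \linkS4class{RiskProfile} (its score enters as covariate
#'   \code{risk_score}), or NULL to test clinical covariates only.
#' @param clin clinical data.frame.
#' @param covariates character vector of clinical column names.
#' @return list with data.frames \code{univariate} and \code{multivariate}
#'   (covariate, beta, hr, ci_low, ci_high, p).
#' @export
coxIndependence <- function(scores, clin, covariates) {
  cl <- clin
  if (!is.null(scores)) {
    stopifnot(is(scores, "RiskProfile"))
    shared <- intersect(sampleIds(scores), clin$sample_id)
    cl <- clin[match(shared, clin$sample_id), , drop = FALSE]
    cl$risk_score <- unname(riskScores(scores)[shared])
    covariates <- unique(c(covariates, "risk_score"))
  }
  miss <- setdiff(covariates, colnames(cl))
  if (length(miss))
    stop("covariate(s) absent from clinical table: ",
         paste(miss, collapse = ", "))
  xm <- vapply(covariates, function(nm) .encodeCovariate(cl[[nm]], nm),
               numeric(nrow(cl)))
  qrx <- qr(cbind(1, scale(xm, scale = FALSE)))
  if (qrx$rank < ncol(xm) + 1) {
    drop_idx <- sort(qrx$pivot[-seq_len(qrx$rank)]) - 1L
    stop("collinear covariate set: ",
         paste(covariates[drop_idx], collapse = ", "))
  }
  y <- .survObject(cl)
  uni <- do.call(rbind, lapply(covariates, function(nm) {
    d <- data.frame(v = xm[, nm])
    tab <- .coxFitTable(survival::coxph(y ~ v, data = d, ties = "efron"))
    tab$covariate <- nm
    tab
  }))
  d <- as.data.frame(xm)
  multi <- .coxFitTable(
    survival::coxph(y ~ ., data = d, ties = "efron"))
  rownames(uni) <- rownames(multi) <- NULL
  list(univariate = uni, multivariate = multi)
}

#' Associations between risk groups and clinical features
#'
#' For each categorical feature: a Pearson chi-square test (no continuity
#' correction) of the risk-group x feature contingency table. For the risk
#' score across feature levels: a two-sided Wilcoxon rank-sum test for
#' two-level features, Kruskal-Wallis for more levels. Single-level features
#' are skipped with a warning.
#'
#' @param groups a \linkS4class{RiskProfile} with groups assigned.
#' @param clin clinical data.frame.
#' @param features character vector of categorical clinical column names.
#' @return data.frame: feature, test, statistic, p, stars.
#' @export
clinicalAssociations <- function(groups, clin, features) {
  stopifnot(is(groups, "RiskProfile"))
  shared <- intersect(sampleIds(groups), clin$sample_id)
  cl <- clin[match(shared, clin$sample_id), , drop = FALSE]
  grp <- riskGroups(groups)[match(shared, sampleIds(groups))]
  sc <- unname(riskScores(groups)[shared])
  rows <- list()
  for (nm in features) {
    f <- factor(cl[[nm]])
    f <- droplevels(f)
    if (nlevels(f) < 2) {
      warning("feature '", nm, "' has a single level; skipped")
      next
    }
    ct <- suppressWarnings(
      stats::chisq.test(table(grp, f), correct = FALSE))
    rows[[paste0(nm, ".chisq")]] <- data.frame(
      feature = nm, test = "chi_square",
      statistic = unname(ct$statistic), p = ct$p.value,
      stringsAsFactors = FALSE)
    st <- if (nlevels(f) == 2) {
      w <- suppressWarnings(
        stats::wilcox.test(sc[f == levels(f)[1]], sc[f == levels(f)[2]]))
      data.frame(feature = nm, test = "wilcoxon_ranksum",
                 statistic = unname(w$statistic), p = w$p.value,
                 stringsAsFactors = FALSE)
    } else {
      kw <- stats::kruskal.test(sc, f)
      data.frame(feature = nm, test = "kruskal_wallis",
                 statistic = unname(kw$statistic), p = kw$p.value,
                 stringsAsFactors = FALSE)
    }
    rows[[paste0(nm, ".score")]] <- st
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(feature = character(), test = character(),
                      statistic = numeric(), p = numeric())
  out$stars <- .pStars(out$p)
  rownames(out) <- NULL
  out
}

#' PCA projection of samples colored by risk group
#'
#' Centered (not scaled) principal component analysis of the samples in
#' feature space; by default the binary pair matrix, optionally any
#' features-by-samples matrix.
#'
#' @param x a \linkS4class{PairMatrix} or a features-by-samples matrix.
#' @param groups optional \linkS4class{RiskProfile} supplying group labels.
#' @return list: \code{coords} (data.frame sample_id, PC1, PC2, group),
#'   \code{var_explained} (fraction per component, all components).
#' @export
pcaProjection <- function(x, groups = NULL) {
  m <- if (is(x, "PairMatrix")) pairValues(x) else x
  if (nrow(m) < 2 || ncol(m) < 3)
    stop("PCA needs at least 2 features and 3 samples")
  pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  grp <- rep(NA_character_, ncol(m))
  if (!is.null(groups)) {
    stopifnot(is(groups, "RiskProfile"))
    grp <- as.character(riskGroups(groups))[
      match(colnames(m), sampleIds(groups))]
  }
  list(coords = data.frame(sample_id = colnames(m),
                           PC1 = pc$x[, 1], PC2 = pc$x[, 2],
                           group = grp, row.names = NULL,
                           stringsAsFactors = FALSE),
       var_explained = ve)
}
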