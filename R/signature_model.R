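## Signature construction: univariate Cox screening of pair features,
## repeated cross-validated L1-penalized Cox selection, and risk scoring
## via the linear predictor sum(beta_i * P_i).

.survObject <- function(clin) {
  survival::Surv(time = clin$os_time, event = clin$os_event)
}

.alignPairsClin <- function(pm, clin) {
  shared <- intersect(sampleIds(pm), clin$sample_id)
  if (!length(shared)) stop("no shared samples between pairs and clinical")
  list(pm = subsetPairs(pm, samples = shared),
       clin = clin[match(shared, clin$sample_id), , drop = FALSE])
}

#' Univariate Cox screening of pair features
#'
#' Fits one single-covariate Cox proportional-hazards model per pair (Efron
#' tie handling, Wald inference) against overall survival and retains pairs
#' with Wald p below \code{p_max} (default 0.001). Pairs constant across the
#' cohort carry no information and are skipped with a warning.
#'
#' @param pm a \linkS4class{PairMatrix}.
#' @param clin clinical data.frame with os_time/os_event (samples are
#'   intersected with the pair matrix).
#' @param p_max Wald p-value threshold for retention.
#' @return data.frame: pair_id, beta, hr, ci_low, ci_high, p, screened
#'   (logical; TRUE iff p < p_max).
#' @export
univariateCoxScreen <- function(pm, clin, p_max = 0.001) {
  al <- .alignPairsClin(pm, clin)
  pm <- al$pm; clin <- al$clin
  if (sum(clin$os_event) < 1) stop("no events in cohort")
  y <- .survObject(clin)
  x <- pm@values
  const <- apply(x, 1, function(v) all(v == v[1]))
  if (any(const))
    warning(sum(const), " constant pair(s) skipped in Cox screen")
  ids <- pairIds(pm)[!const]
  rows <- lapply(ids, function(id) {
    fit <- survival::coxph(y ~ v, data = data.frame(v = x[id, ]),
                           ties = "efron")
    s <- summary(fit)
    data.frame(pair_id = id,
               beta = unname(stats::coef(fit)[1]),
               hr = unname(s$conf.int[1, "exp(coef)"]),
               ci_low = unname(s$conf.int[1, "lower .95"]),
               ci_high = unname(s$conf.int[1, "upper .95"]),
               p = unname(s$coefficients[1, "Pr(>|z|)"]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    res <- data.frame(pair_id = character(), beta = numeric(),
                      hr = numeric(), ci_low = numeric(),
                      ci_high = numeric(), p = numeric())
  res$screened <- res$p < p_max
  rownames(res) <- NULL
  message("univariate Cox screen: ", nrow(x), " pairs in -> ",
          sum(res$screened), " at p < ", p_max)
  res
}

#' Select a pair signature by repeated cross-validated LASSO Cox regression
#'
#' Runs \code{n_cycles} independent k-fold cross-validations of an
#' L1-penalized Cox model over a fixed penalty path (100 log-spaced values
#' from the all-zero penalty down to 1 percent of it), each cycle with
#' freshly randomized folds, and records the partial-likelihood-optimal
#' penalty of each cycle. The final penalty is the median of those optima;
#' the signature is the set of covariates with nonzero coefficients in one
#' full-cohort fit at that penalty. Deterministic given \code{seed}.
#'
#' @param pm a \linkS4class{PairMatrix} of screened pairs.
#' @param clin clinical data.frame.
#' @param n_cycles number of repeated cross-validations (default 1000).
#' @param n_folds folds per cross-validation (default 10).
#' @param seed integer seed.
#' @return a \linkS4class{SignatureModel}; its provenance lists the seed,
#'   cycle/fold counts, the recorded per-cycle optima and the per-pair
#'   selection frequency across cycles.
#' @export
lassoCoxSelect <- function(pm, clin, n_cycles = 1000L, n_folds = 10L,
                           seed = 1L) {
  al <- .alignPairsClin(pm, clin)
  pm <- al$pm; clin <- al$clin
  if (nrow(pm@values) < 2) stop("need at least 2 screened pairs")
  if (sum(clin$os_event) < n_folds)
    stop("need at least as many events as folds")
  x <- t(pm@values)
  y <- .survObject(clin)
  path <- glmnet::glmnet(x, y, family = "cox", alpha = 1,
                         nlambda = 100, lambda.min.ratio = 0.01)
  lambda_path <- path$lambda
  .withSeed(seed, {
    lambda_min <- numeric(n_cycles)
    sel_count <- stats::setNames(numeric(ncol(x)), colnames(x))
    n <- nrow(x)
    for (cyc in seq_len(n_cycles)) {
      foldid <- sample(rep(seq_len(n_folds), length.out = n))
      cv <- glmnet::cv.glmnet(x, y, family = "cox", alpha = 1,
                              lambda = lambda_path, foldid = foldid)
      lambda_min[cyc] <- cv$lambda.min
      b <- as.numeric(stats::coef(cv, s = "lambda.min"))
      sel_count[b != 0] <- sel_count[b != 0] + 1
    }
    lambda_star <- stats::median(lambda_min)
    beta <- as.numeric(stats::coef(path, s = lambda_star, exact = TRUE,
                                   x = x, y = y))
    names(beta) <- colnames(x)
    keep <- beta != 0
    if (!any(keep))
      stop("all coefficients are zero at the selected penalty; ",
           "the pair matrix may be uninformative or the penalty too large ",
           "- consider more cycles or a smaller lambda.min.ratio")
    model <- new("SignatureModel",
                 pairs = names(beta)[keep], betas = unname(beta[keep]),
                 lambda = lambda_star, cutoff = NA_real_,
                 provenance = list(seed = as.integer(seed),
                                   n_cycles = as.integer(n_cycles),
                                   n_folds = as.integer(n_folds),
                                   lambda_min = lambda_min,
                                   selection_freq = sel_count / n_cycles))
    validObject(model)
    message("LASSO selection: ", ncol(x), " pairs in -> ",
            length(model@pairs), " selected at lambda = ",
            signif(lambda_star, 4))
    model
  })
}

#' Fit an L1-penalized Cox model at a fixed penalty
#'
#' Lower-level companion to [lassoCoxSelect()] for inspecting the solution
#' at a chosen penalty (e.g. lambda = 0 reproduces the unpenalized
#' multivariate fit).
#'
#' @param pm a \linkS4class{PairMatrix}.
#' @param clin clinical data.frame.
#' @param lambda non-negative penalty.
#' @return named numeric coefficient vector (zeros included).
#' @export
lassoCoxFit <- function(pm, clin, lambda) {
  al <- .alignPairsClin(pm, clin)
  x <- t(al$pm@values)
  y <- .survObject(al$clin)
  fit <- glmnet::glmnet(x, y, family = "cox", alpha = 1,
                        nlambda = 100, lambda.min.ratio = 0.01,
                        thresh = 1e-12)
  b <- as.numeric(stats::coef(fit, s = lambda, exact = TRUE, x = x, y = y))
  stats::setNames(b, colnames(x))
}

#' Compute per-sample risk scores from a signature
#'
#' risk(s) = sum_i beta_i * P_i(s) over the signature's pairs.
#'
#' @param model a \linkS4class{SignatureModel}.
#' @param pm a \linkS4class{PairMatrix} containing every model pair.
#' @return a \linkS4class{RiskProfile} (groups assigned if the model carries
#'   a cutoff, otherwise NA).
#' @export
computeRiskScores <- function(model, pm) {
  stopifnot(is(model, "SignatureModel"), is(pm, "PairMatrix"))
  miss <- setdiff(model@pairs, pairIds(pm))
  if (length(miss))
    stop("pair(s) missing from pair matrix: ", paste(miss, collapse = ", "))
  sub <- subsetPairs(pm, pairs = model@pairs)
  score <- colSums(sub@values * model@betas)
  names(score) <- sampleIds(pm)
  rp <- new("RiskProfile", score = score,
            group = factor(rep(NA_character_, length(score)),
                           levels = c("low", "high")))
  if (!is.na(model@cutoff)) rp <- assignGroups(rp, model@cutoff)
  rp
}

#' Serialize / read a SignatureModel as JSON
#'
#' @param model a \linkS4class{SignatureModel}.
#' @param path file path.
#' @return \code{path} (write) / a \linkS4class{SignatureModel} (read).
#' @export
writeSignatureModel <- function(model, path) {
  prov <- model@provenance
  prov$lambda_min <- NULL  # bulky diagnostics stay in-session
  jsonlite::write_json(
    list(pairs = model@pairs, betas = model@betas, lambda = model@lambda,
         cutoff = model@cutoff,
         provenance = prov[setdiff(names(prov), "selection_freq")],
         selection_freq = as.list(prov$selection_freq)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname writeSignatureModel
#' @export
readSignatureModel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("SignatureModel", pairs = j$pairs, betas = j$betas,
      lambda = j$lambda,
      cutoff = if (is.null(j$cutoff) || is.na(j$cutoff)) NA_real_
               else j$cutoff,
      provenance = c(as.list(j$provenance),
                     list(selection_freq = unlist(j$selection_freq))))
}

#' Write risk scores and groups as TSV
#'
#' @param rp a \linkS4class{RiskProfile}.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
writeRiskProfile <- function(rp, path) {
  .writeTSV(data.frame(sample_id = names(rp@score),
                       risk_score = unname(rp@score),
                       group = as.character(rp@group)), path)
}
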