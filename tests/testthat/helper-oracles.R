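# Independent brute-force oracles used across the suite. These deliberately
# take the slowest, most literal route so they share no code path with the
# implementation they check.

# naive double loop over all unordered pairs and samples
oraclePairMatrix <- function(expr) {
  g <- sort(rownames(expr))
  out <- NULL
  ids <- character()
  for (i in seq_along(g)) for (j in seq_along(g)) {
    if (i < j) {
      row <- numeric(ncol(expr))
      for (s in seq_len(ncol(expr)))
        row[s] <- if (expr[g[i], s] > expr[g[j], s]) 1 else 0
      out <- rbind(out, row)
      ids <- c(ids, paste(g[i], g[j], sep = "|"))
    }
  }
  rownames(out) <- ids
  colnames(out) <- colnames(expr)
  out
}

# literal frequency thresholding with strict bounds
oracleValidPairs <- function(values, low, high) {
  keep <- logical(nrow(values))
  for (i in seq_len(nrow(values))) {
    f <- sum(values[i, ] == 1) / ncol(values)
    keep[i] <- (f > low) && (f < high)
  }
  rownames(values)[keep]
}

# Efron partial log-likelihood for a single covariate
efronLogLik <- function(beta, time, status, x) {
  ll <- 0
  for (u in unique(time[status == 1])) {
    D <- which(time == u & status == 1)
    R <- which(time >= u)
    d <- length(D)
    sum_d <- sum(exp(beta * x[D]))
    sum_r <- sum(exp(beta * x[R]))
    ll <- ll + beta * sum(x[D])
    for (l in seq_len(d) - 1)
      ll <- ll - log(sum_r - (l / d) * sum_d)
  }
  ll
}

# dense grid-search maximizer of the Efron partial likelihood (coarse pass,
# then a fine grid around the coarse optimum; the partial likelihood is
# concave in beta so the two-stage scan finds the global maximum)
oracleCoxBeta <- function(time, status, x, lo = -5, hi = 5) {
  scan <- function(grid) {
    ll <- vapply(grid, efronLogLik, numeric(1), time = time,
                 status = status, x = x)
    grid[which.max(ll)]
  }
  b1 <- scan(seq(lo, hi, by = 0.01))
  scan(seq(b1 - 0.02, b1 + 0.02, by = 1e-5))
}

# exact two-sided rank-sum p by full enumeration of group assignments
oracleRankSumP <- function(a, b) {
  v <- c(a, b)
  n1 <- length(a)
  r <- rank(v)
  obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(v), n1)
  stats_all <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- mean(stats_all)
  mean(abs(stats_all - mu) >= abs(obs - mu) - 1e-9)
}

# step-up BH by the definition
oracleBH <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  sorted <- p[o] * n / seq_len(n)
  run <- rev(cummin(rev(sorted)))
  adj[o] <- pmin(1, run)
  adj
}

# uncensored counting sens/spec at horizon t for rule "x > c"
oracleCountingROC <- function(x, time, t, cuts) {
  case <- time <= t
  sens <- spec <- numeric(length(cuts))
  for (k in seq_along(cuts)) {
    sens[k] <- sum(x > cuts[k] & case) / sum(case)
    spec[k] <- sum(x <= cuts[k] & !case) / sum(!case)
  }
  list(sens = sens, spec = spec)
}

# two-group log-rank observed/expected/variance tabulated over event times
oracleLogrank <- function(time, status, grp) {
  ev <- sort(unique(time[status == 1]))
  o1 <- e1 <- v <- 0
  for (u in ev) {
    atrisk <- time >= u
    n <- sum(atrisk); n1 <- sum(atrisk & grp == levels(factor(grp))[1])
    d <- sum(time == u & status == 1)
    d1 <- sum(time == u & status == 1 & grp == levels(factor(grp))[1])
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o1 - e1)^2 / v
}

# simple survival cohort with binary pair-style covariates; the planted
# columns drive an exponential proportional-hazards model
makePairCohort <- function(n, n_pairs, planted_idx, beta, censoring,
                           seed, base_hazard = 1 / 1000) {
  set.seed(seed)
  p <- runif(n_pairs, 0.3, 0.7)
  x <- matrix(rbinom(n_pairs * n, 1, rep(p, times = n)),
              nrow = n_pairs, ncol = n)
  rn <- sprintf("P%03dA|P%03dB", seq_len(n_pairs), seq_len(n_pairs))
  rownames(x) <- rn
  colnames(x) <- sprintf("S%04d", seq_len(n))
  lp <- as.numeric(beta %*% x[planted_idx, , drop = FALSE])
  t_ev <- rexp(n, base_hazard * exp(lp))
  c_t <- runif(n, 0, quantile(t_ev, 1 - censoring) * 2)
  os_time <- pmin(t_ev, c_t)
  os_event <- as.integer(t_ev <= c_t)
  pm <- new("PairMatrix",
            pairA = sub("\\|.*", "", rn), pairB = sub(".*\\|", "", rn),
            values = x)
  list(pm = pm,
       clin = data.frame(sample_id = colnames(x), os_time = os_time,
                         os_event = os_event),
       lp = lp)
}
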