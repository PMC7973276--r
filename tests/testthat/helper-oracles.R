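# Independent reference implementations used as oracles. Deliberately
# written as plain enumeration/permutation code, not by calling the package.

# Exhaustive threshold search: every midpoint x both orientations, scored by
# sensitivity + specificity with the documented tie-breaks (accuracy, then
# smaller threshold, then high-is-positive).
oracle_fit_threshold <- function(values, labels) {
  sv <- sort(unique(values))
  mids <- (sv[-1] + sv[-length(sv)]) / 2
  n_pos <- sum(labels == "long")
  n_neg <- sum(labels == "short")
  best <- NULL
  for (dir in c("high_is_positive", "low_is_positive")) {
    for (t in mids) {
      pred_long <- if (dir == "high_is_positive") values >= t else values < t
      sens <- sum(pred_long & labels == "long") / n_pos
      spec <- sum(!pred_long & labels == "short") / n_neg
      youden <- 100 * (sens + spec)
      acc <- 100 * (sum(pred_long & labels == "long") +
                    sum(!pred_long & labels == "short")) / (n_pos + n_neg)
      replace <- FALSE
      if (is.null(best)) replace <- TRUE
      else if (youden > best$youden + 1e-12) replace <- TRUE
      else if (abs(youden - best$youden) <= 1e-12) {
        if (acc > best$accuracy + 1e-12) replace <- TRUE
        else if (abs(acc - best$accuracy) <= 1e-12 && t < best$threshold)
          replace <- TRUE
      }
      if (replace) best <- list(threshold = t, direction = dir,
                                youden = youden, accuracy = acc)
    }
  }
  best
}

# Full enumeration of the two-sided rank-sum p-value over all assignments of
# group membership (tie-free data): p = 2 * min tail, capped at 1.
oracle_rank_sum_p <- function(a, b) {
  n1 <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  idx <- utils::combn(length(pooled), n1)
  W <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
  obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  min(1, 2 * min(mean(W <= obs + 1e-9), mean(W >= obs - 1e-9)))
}

# Spearman rho as Pearson on ranks, p from the t reference distribution.
oracle_spearman <- function(x, y) {
  r <- stats::cor(rank(x), rank(y))
  tval <- r * sqrt((length(x) - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tval), df = length(x) - 2))
}

# Permutation p for the rank trend statistic T = sum(score * rank), centered
# at its exact permutation mean, two-sided by |T - E| exceedance.
oracle_trend_perm_p <- function(values, groups, level_order, B = 1e5,
                                seed = 1) {
  set.seed(seed)
  R <- rank(values)
  l <- match(as.character(groups), level_order)
  obs <- sum(l * R)
  E <- sum(l) * (length(values) + 1) / 2
  Tb <- vapply(seq_len(B), function(i) sum(sample(l) * R), numeric(1))
  (1 + sum(abs(Tb - E) >= abs(obs - E) - 1e-9)) / (B + 1)
}

# Plain log-rank chi-square computed from the risk tables at each event time.
oracle_logrank_chi2 <- function(time, event, in_a) {
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(time[event]))) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & in_a)
    d <- sum(time == t & event); d1 <- sum(time == t & event & in_a)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

oracle_logrank_perm_p <- function(time, event, in_a, B = 1e4, seed = 1) {
  set.seed(seed)
  obs <- oracle_logrank_chi2(time, event, in_a)
  hits <- 0
  for (i in seq_len(B)) {
    if (oracle_logrank_chi2(time, event, sample(in_a)) >= obs - 1e-9)
      hits <- hits + 1
  }
  (1 + hits) / (B + 1)
}

# Hand product-limit estimator: S(t) multiplied by (1 - d/n) at event times.
oracle_km <- function(time, event) {
  S <- 1
  out <- data.frame(time = numeric(0), surv = numeric(0))
  for (t in sort(unique(time))) {
    n <- sum(time >= t)
    d <- sum(time == t & event)
    if (d > 0) S <- S * (1 - d / n)
    out <- rbind(out, data.frame(time = t, surv = S))
  }
  out
}
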