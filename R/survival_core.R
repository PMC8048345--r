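#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over distinct event times;
#' censored-only times do not create steps but do reduce later risk sets.
#'
#' @param surv survival table (patient_id, time_days, event).
#' @return object of class `km_curve` with `event_times`, `survival`,
#'   `n_at_risk`, `n_events`.
#' @export
km_estimate <- function(surv) {
  if (!is.data.frame(surv) || nrow(surv) == 0) stop("empty survival table")
  surv <- check_survival_table(surv, require_event = FALSE)
  t <- surv$time_days; d <- surv$event
  et <- sort(unique(t[d == 1]))
  n_at_risk <- vapply(et, function(x) sum(t >= x), numeric(1))
  n_events <- vapply(et, function(x) sum(t == x & d == 1), numeric(1))
  s <- cumprod(1 - n_events / n_at_risk)
  structure(list(event_times = et, survival = s, n_at_risk = n_at_risk,
                 n_events = n_events), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve:", length(x$event_times), "event times\n")
  print(data.frame(time = x$event_times, survival = signif(x$survival, 4),
                   n_at_risk = x$n_at_risk, n_events = x$n_events),
        row.names = FALSE)
  invisible(x)
}

#' Survival probability at given times from a Kaplan-Meier curve
#' @param km a `km_curve`.
#' @param times numeric times.
#' @return right-continuous step-function values of S(t).
#' @export
km_survival_at <- function(km, times) {
  vapply(times, function(x) {
    i <- sum(km$event_times <= x)
    if (i == 0) 1 else km$survival[i]
  }, numeric(1))
}

#' Multi-group log-rank test
#'
#' Standard k-sample log-rank: observed-minus-expected event counts over
#' the pooled risk sets with hypergeometric variance, chi-square statistic
#' on `k - 1` degrees of freedom.
#'
#' @param surv survival table.
#' @param groups group label per patient (same order as `surv`).
#' @return list(statistic, df, p_value) of class `lr_test`.
#' @export
logrank_test <- function(surv, groups) {
  surv <- check_survival_table(surv)
  if (length(groups) != nrow(surv)) stop("one group label per patient")
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) == 0)) stop("empty group")
  k <- nlevels(g)
  t <- surv$time_days; d <- surv$event
  et <- sort(unique(t[d == 1]))
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (x in et) {
    at <- t >= x
    nj <- sum(at)
    ngj <- vapply(seq_len(k), function(l) sum(at & g == levels(g)[l]),
                  numeric(1))
    dj <- sum(t == x & d == 1)
    dgj <- vapply(seq_len(k), function(l)
      sum(t == x & d == 1 & g == levels(g)[l]), numeric(1))
    O <- O + dgj
    E <- E + dj * ngj / nj
    if (nj > 1) {
      f <- dj * (nj - dj) / (nj - 1)
      P <- ngj / nj
      V <- V + f * (diag(P, k) - tcrossprod(P))
    }
  }
  u <- (O - E)[-k]
  Vk <- V[-k, -k, drop = FALSE]
  stat <- tryCatch(drop(t(u) %*% solve(Vk, u)), error = function(e) {
    sv <- svd(Vk)
    pos <- sv$d > max(sv$d) * 1e-10
    drop(t(u) %*% sv$v[, pos, drop = FALSE] %*%
           ((t(sv$u[, pos, drop = FALSE]) %*% u) / sv$d[pos]))
  })
  stat <- max(stat, 0)
  df <- k - 1
  structure(list(statistic = stat, df = df,
                 p_value = pchisq(stat, df, lower.tail = FALSE)),
            class = "lr_test")
}

#' @export
print.lr_test <- function(x, ...) {
  cat(sprintf("log-rank chi-square = %.4g on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Harrell's concordance index
#'
#' Fraction of comparable pairs in which the patient with the shorter
#' event time has the higher risk score.  A pair (i, j) is comparable when
#' patient i has an observed event and `t_i < t_j` strictly; tied event
#' times are non-comparable, tied scores count 0.5.
#'
#' @param surv survival table.
#' @param risk_scores one numeric score per patient; higher = higher hazard.
#' @return concordance in `[0, 1]`.
#' @export
concordance_index <- function(surv, risk_scores) {
  surv <- check_survival_table(surv, require_event = FALSE)
  if (length(risk_scores) != nrow(surv)) stop("one score per patient")
  t <- surv$time_days; d <- surv$event; s <- risk_scores
  num <- 0; den <- 0
  for (i in which(d == 1)) {
    j <- t > t[i]
    nj <- sum(j)
    if (nj == 0) next
    den <- den + nj
    num <- num + sum(s[i] > s[j]) + 0.5 * sum(s[i] == s[j])
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

#' Negative Cox partial log-likelihood
#'
#' `-l(beta) = -sum_{i: event} [x_i' beta - log sum_{j in R(t_i)} exp(x_j' beta)]`
#' with Breslow handling of tied event times.
#'
#' @param beta coefficient vector (length `ncol(X)`).
#' @param X n x p covariate matrix.
#' @param surv survival table, rows aligned with `X`.
#' @return scalar `-l(beta)`.
#' @export
cox_neg_log_partial_likelihood <- function(beta, X, surv) {
  X <- as.matrix(X)
  surv <- check_survival_table(surv)
  if (!all(is.finite(X)) || !all(is.finite(beta)))
    stop("non-finite entries")
  if (length(beta) != ncol(X)) stop("beta length must equal ncol(X)")
  ord <- order(surv$time_days)
  eta <- drop(X %*% beta)[ord]
  st <- cox_eta_stats_cpp(surv$time_days[ord], as.integer(surv$event[ord]),
                          eta)
  -st$loglik
}

#' Breslow baseline hazard estimate
#'
#' Hazard increments `h0(t_i) = d_i / sum_{j in R(t_i)} exp(x_j' beta)` at
#' the distinct event times, with the running sum as the cumulative
#' baseline hazard.
#'
#' @inheritParams cox_neg_log_partial_likelihood
#' @return object of class `baseline_hazard` with `event_times`,
#'   `hazard`, `cumhaz`.
#' @export
breslow_baseline <- function(beta, X, surv) {
  X <- as.matrix(X)
  surv <- check_survival_table(surv)
  if (!all(is.finite(X)) || !all(is.finite(beta)))
    stop("non-finite entries")
  eta <- drop(X %*% beta)
  t <- surv$time_days; d <- surv$event
  et <- sort(unique(t[d == 1]))
  h <- vapply(et, function(x)
    sum(t == x & d == 1) / sum(exp(eta[t >= x])), numeric(1))
  structure(list(event_times = et, hazard = h, cumhaz = cumsum(h)),
            class = "baseline_hazard")
}

#' Proportional-hazards check via scaled Schoenfeld residuals
#'
#' Score test for a time-varying coefficient `beta(t) = beta + theta g(t)`
#' at the supplied fitted coefficients, with `g` the identity transform of
#' event time (centred over events).  Per-variable chi-square tests on one
#' degree of freedom and a global test on `p` degrees of freedom.
#'
#' @param beta fitted coefficient vector.
#' @param X n x p covariate matrix.
#' @param surv survival table, rows aligned with `X`.
#' @param transform function of event time used as `g` (default identity).
#' @return list with `table` (variable, chisq, df, p_value) and `global`.
#' @export
schoenfeld_ph_test <- function(beta, X, surv, transform = identity) {
  X <- as.matrix(X)
  surv <- check_survival_table(surv)
  if (sum(surv$event) < 2) stop("need at least 2 events")
  p <- ncol(X)
  ord <- order(surv$time_days)
  X <- X[ord, , drop = FALSE]
  t <- surv$time_days[ord]; d <- surv$event[ord]
  eta <- drop(X %*% beta)
  w <- exp(eta - max(eta))

  ev_idx <- which(d == 1)
  gt <- transform(t[ev_idx])
  gt <- gt - mean(gt)

  u <- numeric(p)
  I_bb <- I_bt <- I_tt <- matrix(0, p, p)
  # walk event times; risk set = {j : t_j >= t_k}
  for (m in seq_along(ev_idx)) {
    k <- ev_idx[m]
    at <- t >= t[k]
    ww <- w[at]
    sw <- sum(ww)
    xb <- colSums(X[at, , drop = FALSE] * ww) / sw
    xc <- sweep(X[at, , drop = FALSE], 2, xb)
    Vk <- crossprod(xc * sqrt(ww)) / sw
    sk <- X[k, ] - xb
    u <- u + gt[m] * sk
    I_bb <- I_bb + Vk
    I_bt <- I_bt + gt[m] * Vk
    I_tt <- I_tt + gt[m]^2 * Vk
  }
  D <- I_tt - I_bt %*% solve(I_bb, I_bt)
  global_stat <- drop(t(u) %*% solve(D, u))
  per_stat <- u^2 / diag(D)
  vars <- colnames(X)
  if (is.null(vars)) vars <- paste0("x", seq_len(p))
  list(table = data.frame(variable = vars, chisq = per_stat, df = 1,
                          p_value = pchisq(per_stat, 1, lower.tail = FALSE),
                          row.names = NULL),
       global = list(statistic = global_stat, df = p,
                     p_value = pchisq(global_stat, p, lower.tail = FALSE)))
}

#' Schoenfeld residuals at given coefficients
#'
#' One row per observed event (ordered by time): covariate of the failing
#' patient minus the risk-set weighted mean.  At the maximum partial
#' likelihood estimate these sum to zero (the score equation).
#'
#' @inheritParams schoenfeld_ph_test
#' @return matrix (events x p).
#' @export
schoenfeld_residuals <- function(beta, X, surv) {
  X <- as.matrix(X)
  surv <- check_survival_table(surv)
  ord <- order(surv$time_days)
  X <- X[ord, , drop = FALSE]
  t <- surv$time_days[ord]; d <- surv$event[ord]
  eta <- drop(X %*% beta)
  w <- exp(eta - max(eta))
  ev_idx <- which(d == 1)
  res <- matrix(0, length(ev_idx), ncol(X))
  for (m in seq_along(ev_idx)) {
    k <- ev_idx[m]
    at <- t >= t[k]
    xb <- colSums(X[at, , drop = FALSE] * w[at]) / sum(w[at])
    res[m, ] <- X[k, ] - xb
  }
  colnames(res) <- colnames(X)
  res
}
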