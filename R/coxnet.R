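#' Elastic-net penalized Cox regression
#'
#' Minimises `-l(beta)/n + lambda * (alpha * ||beta||_1 + (1 - alpha) *
#' ||beta||_2^2)` by IRLS with cyclical coordinate descent, with Breslow
#' ties.  Genes are standardized to zero mean / unit variance internally
#' (population variance, glmnet-style 1/n scaling of the likelihood, so
#' lambda is comparable across n); returned coefficients are on the
#' original covariate scale.  Convergence requires both coefficient
#' stability and the exact-gradient KKT conditions:
#' `|grad_j| <= lambda * alpha` for `beta_j = 0` and
#' `grad_j + lambda * alpha * sign(beta_j) + 2 * lambda * (1 - alpha) *
#' beta_j = 0` otherwise, in the standardized coordinates.
#'
#' @param X n x p covariate (gene expression) matrix, patients in rows.
#' @param surv survival table (patient_id, time_days, event), rows aligned
#'   with `X`.
#' @param alpha elastic-net mixing in `[0, 1]` (1 = lasso, 0 = ridge).
#' @param lambda penalty weight (>= 0).
#' @param tol convergence threshold on the weighted squared coefficient
#'   change per sweep (glmnet-style scale; default 1e-7).
#' @param max_iter cap on coordinate-descent sweeps (default 1e5).
#' @param kkt_tol tolerance for the exact KKT verification (default 1e-8).
#' @return object of class `coxnet_fit`: `beta` (original scale, named),
#'   `alpha`, `lambda`, `n_iter`, `converged`, `standardization`
#'   (`center`, `scale`, and indices of excluded zero-variance columns).
#' @export
fit_coxnet <- function(X, surv, alpha, lambda, tol = 1e-7, max_iter = 1e5,
                       kkt_tol = 1e-8) {
  coxnet_core(X, surv, alpha, lambdas = lambda, tol = tol,
              max_iter = max_iter, kkt_tol = kkt_tol,
              dev_ratio_stop = 1)$fits[[1]]
}

# Shared engine: standardize, sort by time, run the compiled path solver,
# back-transform.  Returns list(fits, lambdas).
coxnet_core <- function(X, surv, alpha, lambdas, tol = 1e-7, max_iter = 1e5,
                        kkt_tol = 1e-6, dev_ratio_stop = 0.99) {
  X <- as.matrix(X)
  surv <- check_survival_table(surv)
  if (nrow(X) != nrow(surv)) stop("rows of X must align with surv")
  if (!all(is.finite(X))) stop("X must be finite")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (any(lambdas < 0)) stop("lambda must be >= 0")
  n <- nrow(X); p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))

  ctr <- colMeans(X)
  scl <- sqrt(colMeans(sweep(X, 2, ctr)^2))
  excluded <- which(scl == 0)
  if (length(excluded)) {
    warning("excluding ", length(excluded), " zero-variance column(s)")
  }
  keep <- setdiff(seq_len(p), excluded)
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, ctr[keep]), 2, scl[keep], "/")

  ord <- order(surv$time_days)
  res <- coxnet_path_cpp(Xs[ord, , drop = FALSE], surv$time_days[ord],
                         as.integer(surv$event[ord]), alpha,
                         as.numeric(lambdas), tol, as.integer(max_iter),
                         numeric(length(keep)), kkt_tol, dev_ratio_stop)
  nf <- res$n_fitted
  fits <- lapply(seq_along(lambdas), function(l) {
    lf <- min(l, nf)   # past the saturation stop, carry the last fit
    beta <- numeric(p)
    beta[keep] <- res$beta[, lf] / scl[keep]
    names(beta) <- colnames(X)
    structure(list(beta = beta, alpha = alpha, lambda = lambdas[l],
                   n_iter = res$n_iter[lf], converged = res$converged[lf],
                   saturated = l > nf,
                   standardization = list(center = ctr, scale = scl,
                                          excluded = excluded)),
              class = "coxnet_fit")
  })
  list(fits = fits, lambdas = as.numeric(lambdas), n_fitted = nf)
}

#' @export
print.coxnet_fit <- function(x, ...) {
  nz <- sum(x$beta != 0)
  cat(sprintf(paste0("elastic-net Cox fit: alpha = %.2g, lambda = %.4g, ",
                     "%d nonzero of %d coefficients%s\n"),
              x$alpha, x$lambda, nz, length(x$beta),
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Exact KKT residuals of a fitted elastic-net Cox model
#'
#' Evaluates, in the internal standardized coordinates where the penalty
#' applies, the gradient of `-l(beta)/n` and returns per-coefficient KKT
#' residuals: `max(|grad_j| - lambda * alpha, 0)` for zero coefficients
#' and `|grad_j + lambda * alpha * sign(beta_j) + 2 * lambda * (1 - alpha)
#' * beta_j|` for active ones.
#'
#' @param fit a `coxnet_fit`.
#' @param X,surv the training data.
#' @return numeric vector of KKT residuals (one per retained column).
#' @export
coxnet_kkt <- function(fit, X, surv) {
  X <- as.matrix(X)
  surv <- check_survival_table(surv)
  st <- fit$standardization
  keep <- setdiff(seq_len(ncol(X)), st$excluded)
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, st$center[keep]), 2,
              st$scale[keep], "/")
  bs <- fit$beta[keep] * st$scale[keep]
  n <- nrow(X)
  ord <- order(surv$time_days)
  eta <- drop(Xs %*% bs)[ord]
  g <- cox_eta_stats_cpp(surv$time_days[ord], as.integer(surv$event[ord]),
                         eta)$g
  grad <- -drop(crossprod(Xs[ord, , drop = FALSE], g)) / n
  l1 <- fit$lambda * fit$alpha
  l2 <- 2 * fit$lambda * (1 - fit$alpha)
  ifelse(bs == 0, pmax(abs(grad) - l1, 0), abs(grad + l1 * sign(bs) + l2 * bs))
}

#' Penalty path for elastic-net Cox regression
#'
#' Geometric lambda sequence from `lambda_max` (the smallest penalty at
#' which all coefficients are zero, `max_j |grad_j(-l/n at 0)| / alpha`)
#' down to `lambda_max * lambda_min_ratio`, with warm starts along the
#' path.  For `alpha = 0` there is no finite all-zero penalty, so the
#' start is the gradient bound at a nominal mixing of 0.001.
#'
#' @inheritParams fit_coxnet
#' @param n_lambda path length (default 30).
#' @param lambda_min_ratio ratio of the smallest to largest lambda
#'   (default 0.05, suited to p >> n).
#' @return object of class `lambda_path`: `lambdas`, `fits`.
#' @export
lambda_path <- function(X, surv, alpha, n_lambda = 30,
                        lambda_min_ratio = 0.05, tol = 1e-7,
                        max_iter = 1e5) {
  lmax <- lambda_max(X, surv, alpha) * (1 + 1e-9)  # guard float rounding
  lambdas <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                     length.out = n_lambda))
  res <- coxnet_core(X, surv, alpha, lambdas, tol = tol,
                     max_iter = max_iter)
  structure(list(lambdas = res$lambdas, fits = res$fits, alpha = alpha),
            class = "lambda_path")
}

# Smallest lambda with an all-zero solution (alpha > 0).
lambda_max <- function(X, surv, alpha) {
  X <- as.matrix(X)
  surv <- check_survival_table(surv)
  ctr <- colMeans(X)
  scl <- sqrt(colMeans(sweep(X, 2, ctr)^2))
  keep <- scl > 0
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, ctr[keep]), 2, scl[keep], "/")
  n <- nrow(X)
  ord <- order(surv$time_days)
  g <- cox_eta_stats_cpp(surv$time_days[ord], as.integer(surv$event[ord]),
                         numeric(n))$g
  gmax <- max(abs(drop(crossprod(Xs[ord, , drop = FALSE], g)) / n))
  gmax / max(alpha, 1e-3)
}

#' Cross-validated penalty selection for elastic-net Cox regression
#'
#' K-fold cross-validation over a [lambda_path()], scoring each lambda by
#' the cross-validated partial-likelihood deviance in the
#' Verweij-van Houwelingen form, `-2 * (l_full(beta_k) - l_train(beta_k))`
#' summed over folds.  Folds are stratified by event status and
#' deterministic given `seed`; folds whose training part has no events are
#' re-randomized (bounded retries).  The final fit is on all data at the
#' selected lambda.
#'
#' @inheritParams lambda_path
#' @param n_folds number of folds (default 10).
#' @param seed integer seed for fold assignment.
#' @param rule `"min"` (default): the deviance-minimising lambda;
#'   `"1se"`: the largest lambda within one standard error of the
#'   minimum, a more conservative choice that suppresses noise genes.
#' @param max_retries re-randomizations allowed when a training fold has no
#'   events.
#' @return list of class `cv_coxnet`: `lambda_opt`, `fit`, `lambdas`,
#'   `cvm` (mean deviance per lambda), `cvse`, `alpha`, `seed`.
#' @export
cv_coxnet <- function(X, surv, alpha, n_folds = 10, seed = 1L,
                      n_lambda = 30, lambda_min_ratio = 0.05, tol = 1e-7,
                      max_iter = 1e5, rule = c("min", "1se"),
                      max_retries = 10) {
  rule <- match.arg(rule)
  X <- as.matrix(X)
  surv <- check_survival_table(surv)
  n <- nrow(X)
  if (n_folds < 2) stop("n_folds must be >= 2")
  path <- lambda_path(X, surv, alpha, n_lambda = n_lambda,
                      lambda_min_ratio = lambda_min_ratio, tol = tol,
                      max_iter = max_iter)
  lambdas <- path$lambdas

  folds <- NULL
  for (r in seq_len(max_retries)) {
    cand <- with_seed(seed + (r - 1L), make_folds(surv$event, n_folds))
    ok <- all(vapply(seq_len(n_folds), function(k)
      sum(surv$event[cand != k]) >= 1, logical(1)))
    if (ok) { folds <- cand; break }
  }
  if (is.null(folds)) stop("could not build folds with events in every ",
                           "training part")

  dev <- matrix(NA_real_, n_folds, length(lambdas))
  ord_full <- order(surv$time_days)
  for (k in seq_len(n_folds)) {
    tr <- folds != k
    fits <- coxnet_core(X[tr, , drop = FALSE], surv[tr, , drop = FALSE],
                        alpha, lambdas, tol = tol, max_iter = max_iter)$fits
    B <- vapply(fits, `[[`, numeric(ncol(X)), "beta")
    eta_full <- (X %*% B)[ord_full, , drop = FALSE]
    ll_full <- cox_loglik_path_cpp(eta_full, surv$time_days[ord_full],
                                   as.integer(surv$event[ord_full]))
    Xtr <- X[tr, , drop = FALSE]; str <- surv[tr, , drop = FALSE]
    ord_tr <- order(str$time_days)
    eta_tr <- (Xtr %*% B)[ord_tr, , drop = FALSE]
    ll_tr <- cox_loglik_path_cpp(eta_tr, str$time_days[ord_tr],
                                 as.integer(str$event[ord_tr]))
    dev[k, ] <- -2 * (ll_full - ll_tr)
  }
  cvm <- colMeans(dev)
  cvse <- apply(dev, 2, sd) / sqrt(n_folds)
  opt <- which.min(cvm)
  if (rule == "1se")
    opt <- min(which(cvm <= cvm[opt] + cvse[opt]))
  structure(list(lambda_opt = lambdas[opt], fit = path$fits[[opt]],
                 lambdas = lambdas, cvm = cvm, cvse = cvse, alpha = alpha,
                 seed = seed, rule = rule),
            class = "cv_coxnet")
}

# Stratified fold labels: events and censored split separately so every
# fold sees events whenever possible.
make_folds <- function(event, n_folds) {
  f <- integer(length(event))
  for (s in c(1, 0)) {
    idx <- which(event == s)
    f[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  f
}

#' Linear predictor (risk score) of a fitted model
#'
#' `x' beta` per patient; a higher score means a higher hazard of the
#' event — for a discharge outcome, earlier discharge.
#'
#' @param fit a `coxnet_fit` (or any object with a named `beta`).
#' @param X_new matrix with the training columns (matched by name when
#'   both are named).
#' @return numeric vector of risk scores.
#' @export
linear_predictor <- function(fit, X_new) {
  X_new <- as.matrix(X_new)
  beta <- fit$beta
  if (!is.null(names(beta)) && !is.null(colnames(X_new))) {
    if (!all(names(beta) %in% colnames(X_new)))
      stop("X_new is missing training columns")
    X_new <- X_new[, names(beta), drop = FALSE]
  } else if (ncol(X_new) != length(beta)) {
    stop("column mismatch between fit and X_new")
  }
  drop(X_new %*% beta)
}

#' Serialize a fitted elastic-net Cox model to JSON
#' @param fit a `coxnet_fit`.
#' @param path optional file path; if omitted the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
coxnet_to_json <- function(fit, path = NULL) {
  nz <- fit$beta[fit$beta != 0]
  obj <- list(alpha = fit$alpha, lambda = fit$lambda,
              converged = fit$converged,
              coefficients = as.list(nz))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
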