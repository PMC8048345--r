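#' Parameters of the triangular Global Alignment Kernel
#'
#' @param sigma Gaussian bandwidth (> 0) of the local kernel.
#' @param window_order order of the triangular integer window constraining
#'   alignments to a band around the diagonal; 0 (default) means
#'   unconstrained, appropriate for short grids.
#' @return object of class `gak_params`.
#' @export
gak_params <- function(sigma, window_order = 0) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0")
  if (window_order < 0) stop("window_order must be >= 0")
  structure(list(sigma = sigma, window_order = as.integer(window_order)),
            class = "gak_params")
}

#' Local cost matrix between two multivariate series
#'
#' Entry (q, r) is the Euclidean norm, across the shared gene dimension,
#' of the difference between the observation vectors of series i at grid
#' position q and series j at grid position r.
#'
#' @param series_i,series_j matrices (time points x genes) with the same
#'   number of genes.
#' @return non-negative matrix `length_i` x `length_j`.
#' @export
local_cost <- function(series_i, series_j) {
  series_i <- as.matrix(series_i); series_j <- as.matrix(series_j)
  if (ncol(series_i) != ncol(series_j))
    stop("series must share the gene dimension")
  d2 <- outer(rowSums(series_i^2), rowSums(series_j^2), "+") -
    2 * tcrossprod(series_i, series_j)
  sqrt(pmax(d2, 0))
}

#' Log Global Alignment Kernel of two multivariate series
#'
#' Sum over all monotone alignments of products of local kernel values,
#' computed by the dynamic program `M(q, r) = kappa(q, r) * (M(q-1, r) +
#' M(q, r-1) + M(q-1, r-1))` in log space for numerical stability.  The
#' local kernel is the normalised Gaussian term
#' `exp(-(u + log(2 - exp(-u))))` with `u = ||a - b||^2 / (2 sigma^2)`,
#' optionally times a triangular window in the index difference.
#'
#' @param series_i,series_j matrices (time points x genes).
#' @param params a [gak_params()].
#' @return `log k_GA(i, j)`; `-Inf` when the window leaves no feasible
#'   alignment, which is signalled as an error.
#' @export
gak_log_kernel <- function(series_i, series_j, params) {
  stopifnot(inherits(params, "gak_params"))
  series_i <- as.matrix(series_i); series_j <- as.matrix(series_j)
  if (ncol(series_i) != ncol(series_j))
    stop("series must share the gene dimension")
  if (nrow(series_i) == 0 || nrow(series_j) == 0) stop("empty series")
  if (!all(is.finite(series_i)) || !all(is.finite(series_j)))
    stop("series must be finite")
  lk <- gak_logk_cpp(series_i, series_j, params$sigma, params$window_order)
  if (lk == -Inf)
    stop("window_order too tight: no feasible alignment between the series")
  lk
}

#' Normalised GAK distance between two multivariate series
#'
#' `d = 1 - exp(logk(i, j) - (logk(i, i) + logk(j, j)) / 2)`.  By the
#' Cauchy-Schwarz inequality for positive-definite kernels the normalised
#' similarity is at most 1, so `d` lies in `[0, 1]` with `d(x, x) = 0`.
#' (It is not a metric: the triangle inequality need not hold.)
#'
#' @inheritParams gak_log_kernel
#' @return distance in `[0, 1]`.
#' @export
gak_distance <- function(series_i, series_j, params) {
  lij <- gak_log_kernel(series_i, series_j, params)
  lii <- gak_log_kernel(series_i, series_i, params)
  ljj <- gak_log_kernel(series_j, series_j, params)
  d <- 1 - exp(lij - 0.5 * (lii + ljj))
  min(max(d, 0), 1)
}

#' Median-based bandwidth heuristic for the GAK
#'
#' `sigma = c * median(pairwise distance between time-point observation
#' vectors) * sqrt(median series length)`, medians over a seeded
#' subsample of observations.
#'
#' @param set a complete `series_set`.
#' @param seed integer seed for the subsample.
#' @param c multiplier (default 1).
#' @param max_obs subsample cap on pooled observation vectors (default 200).
#' @return bandwidth sigma.
#' @export
sigma_heuristic <- function(set, seed = 1L, c = 1, max_obs = 200) {
  stopifnot(inherits(set, "series_set"))
  v <- set$values
  n <- dim(v)[1]; nq <- dim(v)[2]; ng <- dim(v)[3]
  obs <- matrix(aperm(v, c(2, 1, 3)), nrow = n * nq, ncol = ng)
  obs <- obs[stats::complete.cases(obs), , drop = FALSE]
  idx <- if (nrow(obs) > max_obs)
    with_seed(seed, sample.int(nrow(obs), max_obs)) else seq_len(nrow(obs))
  sub <- obs[idx, , drop = FALSE]
  dd <- as.numeric(stats::dist(sub))
  med <- median(dd)
  if (!is.finite(med) || med == 0)
    stop("degenerate data: all observations identical, sigma would be 0")
  c * med * sqrt(nq)
}

#' Cross-distance matrix of a series set under the GAK distance
#'
#' @param set a complete `series_set` (no missing cells).
#' @param params a [gak_params()].
#' @return symmetric n x n matrix of class `matrix`, zero diagonal,
#'   entries in `[0, 1]`, dimnames = patient ids.
#' @export
cross_distance_matrix <- function(set, params) {
  stopifnot(inherits(set, "series_set"))
  if (anyNA(set$values))
    stop("series set has missing cells; run split_complete_cases first")
  n <- length(set$patients)
  mats <- lapply(seq_len(n), function(i) series_matrix(set, i))
  diag_lk <- vapply(mats, function(m)
    gak_logk_cpp(m, m, params$sigma, params$window_order), numeric(1))
  dm <- matrix(0, n, n, dimnames = list(set$patients, set$patients))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      lij <- gak_logk_cpp(mats[[i]], mats[[j]], params$sigma,
                          params$window_order)
      if (lij == -Inf)
        stop("window_order too tight for patients ", set$patients[i],
             " and ", set$patients[j])
      d <- 1 - exp(lij - 0.5 * (diag_lk[i] + diag_lk[j]))
      dm[i, j] <- dm[j, i] <- min(max(d, 0), 1)
    }
  }
  dm
}

#' Partition-around-medoids clustering on a precomputed distance matrix
#'
#' Lloyd-style alternation on the distance matrix: assign each point to
#' its nearest medoid (ties to the lowest-index medoid), then move each
#' medoid to the cluster member minimising the within-cluster distance
#' sum; iterate to a fixed point.  The objective (total distance to
#' assigned medoids) is non-increasing across iterations.  Initial
#' medoids are drawn at random under `seed` unless supplied; a medoid
#' whose cluster empties is re-seeded to a random non-medoid point.
#'
#' @param dm symmetric distance matrix with zero diagonal.
#' @param k number of clusters, `2 <= k <= n` (k = n allowed: singletons).
#' @param seed integer seed for initialization.
#' @param max_iter iteration cap (default 100).
#' @param nstart random restarts; the partition with the lowest objective
#'   wins (default 10).  Ignored when `medoids_init` is given.
#' @param medoids_init optional integer vector of initial medoid indices.
#' @return object of class `pam_partition`: `labels` (named by patient),
#'   `medoids` (indices), `medoid_ids`, `objective`, `iterations`.
#' @export
pam_cluster <- function(dm, k, seed = 1L, max_iter = 100, nstart = 10,
                        medoids_init = NULL) {
  if (is.null(medoids_init) && nstart > 1) {
    runs <- lapply(seq_len(nstart), function(r)
      pam_cluster(dm, k, seed = seed + (r - 1L) * 1000L,
                  max_iter = max_iter, nstart = 1))
    objs <- vapply(runs, `[[`, numeric(1), "objective")
    return(runs[[which.min(objs)]])
  }
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (k < 1 || k > n) stop("k must lie in [1, n]")
  med <- if (is.null(medoids_init)) with_seed(seed, sample.int(n, k)) else {
    if (length(unique(medoids_init)) != k) stop("need k distinct medoids")
    as.integer(medoids_init)
  }
  reseed_pool <- with_seed(seed + 1L, sample.int(n, n))  # deterministic spares
  labels <- integer(n)
  for (it in seq_len(max_iter)) {
    labels <- apply(dm[, med, drop = FALSE], 1, which.min)
    # re-seed empty clusters
    empty <- setdiff(seq_len(k), unique(labels))
    if (length(empty)) {
      spare <- setdiff(reseed_pool, med)
      for (e in empty) {
        med[e] <- spare[1]
        spare <- spare[-1]
      }
      labels <- apply(dm[, med, drop = FALSE], 1, which.min)
    }
    new_med <- med
    for (cl in seq_len(k)) {
      members <- which(labels == cl)
      ss <- colSums(dm[members, members, drop = FALSE])
      new_med[cl] <- members[which.min(ss)]
    }
    if (identical(new_med, med)) break
    med <- new_med
  }
  labels <- apply(dm[, med, drop = FALSE], 1, which.min)
  obj <- sum(dm[cbind(seq_len(n), med[labels])])
  ids <- rownames(dm)
  structure(list(labels = setNames(labels, ids), medoids = med,
                 medoid_ids = if (!is.null(ids)) ids[med] else med,
                 objective = obj, iterations = it),
            class = "pam_partition")
}

#' @export
print.pam_partition <- function(x, ...) {
  cat(sprintf("PAM partition: k = %d, objective = %.4g, sizes: %s\n",
              length(x$medoids), x$objective,
              paste(tabulate(x$labels, length(x$medoids)), collapse = "/")))
  invisible(x)
}

#' Select the number of clusters by survival separation
#'
#' For every admissible k in `k_range` (admissible: every cluster has at
#' least `min_cluster_size` members), cluster the series with
#' [pam_cluster()] on the GAK cross-distance matrix and compare the
#' clusters' survival curves with the log-rank test (plus a Wald-test
#' companion from an unpenalized Cox fit on cluster indicators).  The
#' selected k minimises the log-rank p-value over admissible k.
#'
#' @param set a complete `series_set`.
#' @param surv survival table covering all patients in `set`.
#' @param k_range integer vector of candidate k (within `[2, n]`).
#' @param min_cluster_size smallest admissible cluster (default 2).
#' @param seed integer seed (PAM initialization).
#' @param params optional [gak_params()]; default uses
#'   [sigma_heuristic()] with `window_order = 0`.
#' @param dm optional precomputed distance matrix (skips the GAK step).
#' @return list of class `k_selection`: `k_opt`, `partition`, `table`
#'   (k, admissible, logrank_p, wald_p, min_cluster_size), `dm`.
#' @export
select_k <- function(set, surv, k_range, min_cluster_size = 2, seed = 1L,
                     params = NULL, dm = NULL) {
  stopifnot(inherits(set, "series_set"))
  surv <- check_survival_table(surv)
  if (!all(set$patients %in% surv$patient_id))
    stop("survival table must cover all patients in the series set")
  n <- length(set$patients)
  if (any(k_range < 2 | k_range > n)) stop("k_range must lie in [2, n]")
  if (is.null(dm)) {
    if (is.null(params))
      params <- gak_params(sigma_heuristic(set, seed = seed))
    dm <- cross_distance_matrix(set, params)
  }
  ssub <- surv[match(set$patients, surv$patient_id), , drop = FALSE]
  rows <- lapply(k_range, function(k) {
    part <- pam_cluster(dm, k, seed = seed)
    sizes <- tabulate(part$labels, k)
    adm <- min(sizes) >= min_cluster_size
    lr_p <- wd_p <- NA_real_
    if (adm) {
      lr <- logrank_test(ssub, part$labels)
      lr_p <- lr$p_value
      wd_p <- tryCatch({
        fit <- survival::coxph(
          survival::Surv(ssub$time_days, ssub$event) ~ factor(part$labels))
        w <- fit$wald.test
        pchisq(w, df = sum(!is.na(stats::coef(fit))), lower.tail = FALSE)
      }, error = function(e) NA_real_)
    }
    list(part = part, row = data.frame(k = k, admissible = adm,
                                       logrank_p = lr_p, wald_p = wd_p,
                                       min_size = min(sizes)))
  })
  tab <- do.call(rbind, lapply(rows, `[[`, "row"))
  adm_idx <- which(tab$admissible)
  if (length(adm_idx) == 0)
    stop("no admissible k: every candidate gives a cluster smaller than ",
         min_cluster_size)
  best <- adm_idx[which.min(tab$logrank_p[adm_idx])]
  structure(list(k_opt = tab$k[best], partition = rows[[best]]$part,
                 table = tab, dm = dm),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat("cluster-number selection by log-rank survival separation\n")
  print(x$table, row.names = FALSE)
  cat("selected k =", x$k_opt, "\n")
  invisible(x)
}
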