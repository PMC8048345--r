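#' Pipeline configuration
#'
#' Defaults mirror the motivating trauma study: supervised gene selection
#' on the snapshots of days 0, 1 and 4 taken independently, elastic-net
#' mixing tested over {0.2, 0.4, 0.6, 0.8, 1}, a 70/30 train/test split,
#' a 50% missingness threshold for the reduced time grid, a 2-day carry
#' window, complete-case horizons at days 7 and 28, and cluster counts
#' chosen by survival separation.
#'
#' @param selection_days days whose snapshots feed the per-day Cox models.
#' @param alpha_grid elastic-net mixing values to compare.
#' @param train_frac training fraction of the patient-level split.
#' @param grid_threshold per-day missingness threshold (strict) for the
#'   reduced time grid.
#' @param max_carry_days carry window for the mixed imputation.
#' @param horizons complete-case horizon days.
#' @param k_range candidate numbers of clusters.
#' @param min_cluster_size smallest admissible cluster in k selection.
#' @param n_folds folds for the cross-validated penalty.
#' @param loocv_folds folds for the penalty refits inside the
#'   leave-one-out stability stage (5 keeps the n refits affordable).
#' @param n_lambda,lambda_min_ratio penalty path shape.
#' @param seed root seed; stage streams (split, CV folds, leave-one-out
#'   fits, bandwidth subsample, PAM initialization) are derived from it.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(selection_days = c(0, 1, 4),
                            alpha_grid = c(0.2, 0.4, 0.6, 0.8, 1.0),
                            train_frac = 0.7,
                            grid_threshold = 0.5,
                            max_carry_days = 2,
                            horizons = c(7, 28),
                            k_range = 2:10,
                            min_cluster_size = 2,
                            n_folds = 10,
                            loocv_folds = 5,
                            n_lambda = 30,
                            lambda_min_ratio = 0.05,
                            seed = 1L) {
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0,1)")
  structure(list(selection_days = selection_days, alpha_grid = alpha_grid,
                 train_frac = train_frac, grid_threshold = grid_threshold,
                 max_carry_days = max_carry_days, horizons = horizons,
                 k_range = k_range, min_cluster_size = min_cluster_size,
                 n_folds = n_folds, loocv_folds = loocv_folds,
                 n_lambda = n_lambda,
                 lambda_min_ratio = lambda_min_ratio,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Per-day expression snapshot
#'
#' Patients x genes matrix of the measurements taken on one day; patients
#' without a draw on that day are excluded (they are not imputed in the
#' selection phase).
#'
#' @param expression long expression table.
#' @param day the day.
#' @param genes optional gene subset / column order.
#' @return matrix with patient ids as rownames.
#' @export
day_snapshot <- function(expression, day, genes = NULL) {
  sub <- expression[expression$day == day, , drop = FALSE]
  if (nrow(sub) == 0) stop("no measurements on day ", day)
  if (is.null(genes)) genes <- sort(unique(sub$gene_id))
  patients <- unique(sub$patient_id)
  m <- matrix(NA_real_, length(patients), length(genes),
              dimnames = list(patients, genes))
  m[cbind(match(sub$patient_id, patients), match(sub$gene_id, genes))] <-
    sub$value
  m[stats::complete.cases(m), , drop = FALSE]
}

#' Choose the elastic-net mixing by held-out concordance
#'
#' One shared patient-level train/test split; for every day and every
#' alpha, a cross-validated elastic-net Cox model is fitted on the
#' training part of that day's snapshot and scored by Harrell's c-index
#' of its linear predictor on the held-out part.  The winning alpha
#' maximises the mean c-index across days (a tie prefers the larger,
#' sparser alpha), mirroring a single mixing value shared by all days.
#'
#' @param snapshots named list (day -> patients x genes matrix).
#' @param surv survival table covering the snapshot patients.
#' @param alpha_grid mixing values to compare.
#' @param train_frac training fraction.
#' @param seed integer seed (split and CV folds).
#' @param n_folds,n_lambda,lambda_min_ratio passed to [cv_coxnet()].
#' @return list of class `alpha_selection`: `alpha_opt`, `table`
#'   (day, alpha, cindex, lambda_opt, n_selected), `fits` (per day at
#'   `alpha_opt`), `splits` (per-day train/test patient ids).
#' @export
select_alpha <- function(snapshots, surv, alpha_grid, train_frac = 0.7,
                         seed = 1L, n_folds = 10, n_lambda = 30,
                         lambda_min_ratio = 0.05) {
  surv <- check_survival_table(surv)
  if (length(alpha_grid) == 0) stop("empty alpha grid")
  all_pat <- unique(unlist(lapply(snapshots, rownames)))
  train_pool <- with_seed(seed,
    sample(all_pat, ceiling(train_frac * length(all_pat))))
  rows <- list(); fits <- list(); splits <- list()
  for (day in names(snapshots)) {
    X <- snapshots[[day]]
    tr_ids <- intersect(rownames(X), train_pool)
    te_ids <- setdiff(rownames(X), tr_ids)
    if (length(te_ids) < 2) stop("test split too small on day ", day)
    splits[[day]] <- list(train = tr_ids, test = te_ids)
    s_tr <- surv[match(tr_ids, surv$patient_id), , drop = FALSE]
    s_te <- surv[match(te_ids, surv$patient_id), , drop = FALSE]
    day_fits <- list()
    for (a in alpha_grid) {
      cvf <- cv_coxnet(X[tr_ids, , drop = FALSE], s_tr, alpha = a,
                       n_folds = n_folds, seed = seed,
                       n_lambda = n_lambda,
                       lambda_min_ratio = lambda_min_ratio)
      sc <- linear_predictor(cvf$fit, X[te_ids, , drop = FALSE])
      ci <- concordance_index(s_te, sc)
      rows[[length(rows) + 1]] <-
        data.frame(day = as.numeric(day), alpha = a, cindex = ci,
                   lambda_opt = cvf$lambda_opt,
                   n_selected = sum(cvf$fit$beta != 0))
      day_fits[[as.character(a)]] <- cvf$fit
    }
    fits[[day]] <- day_fits
  }
  tab <- do.call(rbind, rows)
  agg <- vapply(alpha_grid, function(a) mean(tab$cindex[tab$alpha == a]),
                numeric(1))
  # tie -> larger alpha (sparser model)
  best <- max(alpha_grid[agg == max(agg)])
  structure(list(alpha_opt = best, table = tab,
                 fits = lapply(fits, `[[`, as.character(best)),
                 splits = splits, seed = seed),
            class = "alpha_selection")
}

#' Stability gene selection by leave-one-out intersection
#'
#' Refits the cross-validated elastic-net Cox model on every leave-one-out
#' training set and returns the genes whose coefficients are nonzero in
#' every completed fit — the stability criterion for genes strongly
#' associated with the outcome.  Leave-one-out sets whose survival part
#' has fewer than 2 events are skipped with a warning and the
#' intersection is taken over the completed fits.
#'
#' @param X patients x genes matrix (one day's snapshot).
#' @param surv aligned survival table.
#' @param alpha elastic-net mixing (fixed).
#' @param seed integer seed (CV folds inside each refit).
#' @param n_folds,n_lambda,lambda_min_ratio passed to [cv_coxnet()].
#' @return character vector of stable gene ids, with attributes
#'   `n_fits` (completed fits) and `n_skipped`.
#' @export
loocv_intersection <- function(X, surv, alpha, seed = 1L, n_folds = 5,
                               n_lambda = 30, lambda_min_ratio = 0.05) {
  X <- as.matrix(X)
  surv <- check_survival_table(surv)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 patients")
  stable <- NULL
  n_fits <- 0L; n_skipped <- 0L
  for (i in seq_len(n)) {
    s_i <- surv[-i, , drop = FALSE]
    if (sum(s_i$event) < 2) { n_skipped <- n_skipped + 1L; next }
    cvf <- cv_coxnet(X[-i, , drop = FALSE], s_i, alpha = alpha,
                     n_folds = n_folds, seed = seed + i,
                     n_lambda = n_lambda,
                     lambda_min_ratio = lambda_min_ratio)
    supp <- names(cvf$fit$beta)[cvf$fit$beta != 0]
    stable <- if (n_fits == 0) supp else intersect(stable, supp)
    n_fits <- n_fits + 1L
    if (length(stable) == 0) stable <- character(0)
  }
  if (n_skipped > 0)
    warning(n_skipped, " leave-one-out fit(s) skipped (too few events)")
  structure(sort(stable), n_fits = n_fits, n_skipped = n_skipped)
}

#' Union signature across per-day stable gene sets
#'
#' @param per_day_sets named list (day -> character vector of genes).
#' @return sorted character vector of the union, with attribute
#'   `provenance`: data.frame (gene_id, days) recording which days
#'   selected each gene.
#' @export
build_union_signature <- function(per_day_sets) {
  if (length(per_day_sets) == 0 ||
      all(vapply(per_day_sets, length, integer(1)) == 0))
    stop("all per-day gene sets are empty")
  genes <- sort(unique(unlist(per_day_sets)))
  prov <- vapply(genes, function(g)
    paste(names(per_day_sets)[vapply(per_day_sets, function(s) g %in% s,
                                     logical(1))], collapse = ";"),
    character(1))
  structure(genes,
            provenance = data.frame(gene_id = genes, days = unname(prov)))
}

#' Split a test cohort into high/low risk and compare survival
#'
#' Patients are ranked by the fitted linear predictor and split into a
#' high-risk half (larger scores: higher hazard of discharge, i.e.
#' earlier discharge) and a low-risk half, the halves differing in size
#' by at most one; Kaplan-Meier curves are estimated per group and
#' compared by the two-group log-rank test.
#'
#' @param fit a `coxnet_fit`.
#' @param X_test test patients x genes matrix.
#' @param surv_test aligned survival table.
#' @return list of class `risk_split`: `km_high`, `km_low`, `test`,
#'   `groups` (named "high"/"low" per patient), `scores`.
#' @export
risk_stratify <- function(fit, X_test, surv_test) {
  surv_test <- check_survival_table(surv_test)
  scores <- linear_predictor(fit, X_test)
  if (length(unique(scores)) == 1)
    stop("degenerate split: all risk scores are equal")
  n <- length(scores)
  ord <- order(scores, decreasing = TRUE)
  groups <- character(n)
  groups[ord[seq_len(ceiling(n / 2))]] <- "high"
  groups[groups == ""] <- "low"
  km_h <- km_estimate(surv_test[groups == "high", , drop = FALSE])
  km_l <- km_estimate(surv_test[groups == "low", , drop = FALSE])
  lr <- logrank_test(surv_test, groups)
  list(km_high = km_h, km_low = km_l, test = lr,
       groups = setNames(groups, rownames(X_test)), scores = scores)
}

#' Run the full trajectory-survival pipeline
#'
#' Orchestrates the two-phase framework: (1) static phase — per-day
#' snapshots, shared alpha chosen by held-out concordance, per-day
#' leave-one-out stability selection, union signature, per-day high/low
#' risk stratification of the test split; (2) longitudinal phase — time
#' grid selection by missingness, mixed imputation of the signature
#' genes, complete-case horizon splits, GAK/PAM clustering with k chosen
#' by log-rank survival separation.  Fully deterministic given
#' `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @param expression long expression table (patient_id, day, gene_id,
#'   value), log-scale.
#' @param survival survival table (patient_id, time_days, event).
#' @return list of class `trajsurv_report` with elements `config`,
#'   `alpha_selection`, `stable_sets`, `signature`, `risk_splits`,
#'   `grid`, `series`, `horizon_results` (per horizon: series set,
#'   k-selection, per-cluster log-rank), `manifest`.
#' @export
run_pipeline <- function(config, expression, survival) {
  stopifnot(inherits(config, "pipeline_config"))
  survival <- check_survival_table(survival)
  seeds <- stage_seeds(config$seed, 4L)

  # --- static phase -------------------------------------------------------
  snapshots <- list()
  for (d in config$selection_days)
    snapshots[[as.character(d)]] <- day_snapshot(expression, d)
  sel <- select_alpha(snapshots, survival, config$alpha_grid,
                      train_frac = config$train_frac, seed = seeds[1],
                      n_folds = config$n_folds, n_lambda = config$n_lambda,
                      lambda_min_ratio = config$lambda_min_ratio)

  stable_sets <- list()
  for (d in names(snapshots)) {
    X <- snapshots[[d]]
    s <- survival[match(rownames(X), survival$patient_id), , drop = FALSE]
    stable_sets[[d]] <- loocv_intersection(
      X, s, alpha = sel$alpha_opt, seed = seeds[2],
      n_folds = config$loocv_folds, n_lambda = config$n_lambda,
      lambda_min_ratio = config$lambda_min_ratio)
  }
  signature <- build_union_signature(stable_sets)

  risk_splits <- lapply(names(snapshots), function(d) {
    X <- snapshots[[d]]
    te <- sel$splits[[d]]$test
    tryCatch(risk_stratify(sel$fits[[d]], X[te, , drop = FALSE],
                           survival[match(te, survival$patient_id), ,
                                    drop = FALSE]),
             error = function(e) list(error = conditionMessage(e)))
  })
  names(risk_splits) <- names(snapshots)

  # --- longitudinal phase (signature genes only) --------------------------
  expr_sig <- expression[expression$gene_id %in% signature, , drop = FALSE]
  grid <- select_time_points(expr_sig, config$grid_threshold,
                             surv = survival)
  series <- impute_mixed(expr_sig, grid,
                         max_carry_days = config$max_carry_days,
                         genes = as.character(signature))

  horizon_results <- list()
  for (h in config$horizons) {
    if (!h %in% grid$selected_days) {
      horizon_results[[as.character(h)]] <-
        list(error = paste("horizon", h, "not in selected grid"))
      next
    }
    cc <- split_complete_cases(series, h)
    res <- tryCatch({
      params <- gak_params(sigma_heuristic(cc, seed = seeds[3]))
      ks <- select_k(cc, survival, config$k_range,
                     min_cluster_size = config$min_cluster_size,
                     seed = seeds[4], params = params)
      ssub <- survival[match(cc$patients, survival$patient_id), ,
                       drop = FALSE]
      kms <- lapply(sort(unique(ks$partition$labels)), function(cl)
        km_estimate(ssub[ks$partition$labels == cl, , drop = FALSE]))
      list(series = cc, k_selection = ks, cluster_km = kms,
           logrank = logrank_test(ssub, ks$partition$labels),
           sigma = params$sigma)
    }, error = function(e) list(series = cc,
                                error = conditionMessage(e)))
    horizon_results[[as.character(h)]] <- res
  }

  manifest <- list(package_version = "0.1.0",
                   seed = config$seed,
                   stage_seeds = as.integer(seeds),
                   config_hash = config_hash(
                     jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                      digits = NA)))
  structure(list(config = config, alpha_selection = sel,
                 stable_sets = stable_sets, signature = signature,
                 risk_splits = risk_splits, grid = grid, series = series,
                 horizon_results = horizon_results, manifest = manifest),
            class = "trajsurv_report")
}
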