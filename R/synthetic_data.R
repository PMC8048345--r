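#' Configuration for a synthetic longitudinal trauma-like cohort
#'
#' Describes a cohort whose log-scale gene expression follows cluster-specific
#' smooth injury-response trajectories and whose time-to-discharge follows a
#' Weibull proportional-hazards model driven by a small planted set of active
#' genes measured at day 0.  The defaults emulate the design of a 28-day
#' prospective trauma transcriptomics study: an irregular sampling schedule
#' over `day_grid`, day-dependent missingness concentrated outside a core set
#' of well-sampled days, loss of expression follow-up after discharge, and
#' administrative censoring.
#'
#' @param n_patients number of patients.
#' @param n_genes number of genes (log2-scale expression).
#' @param n_active_genes number of genes whose day-0 expression enters the
#'   discharge hazard; must not exceed `n_genes`.
#' @param n_clusters number of planted trajectory clusters (>= 1).
#' @param day_grid ordered integer sampling days.  The default is the
#'   nominal blood-draw schedule of the motivating 28-day study.
#' @param effect_sizes log-hazard coefficients of the active genes; recycled
#'   default alternates +1/-1.
#' @param trajectory_params list with `baseline_range`, `amplitude_range`,
#'   `decay_range`: per-gene baseline level (log2 units), per-(gene, cluster)
#'   injury-response amplitude, and per-cluster exponential decay rate of the
#'   response, i.e. mean curves `b + a * exp(-r * day)`.
#' @param noise_sd log2-scale per-draw measurement noise standard deviation.
#' @param patient_sd standard deviation of persistent patient-level gene
#'   offsets (biological variation shared by all of a patient's draws);
#'   these offsets, not the draw noise, make repeated measures of one
#'   patient correlate across days.
#' @param missing_frac_by_day named numeric vector mapping day to the
#'   probability that a patient's blood draw on that day is missing.  The
#'   default keeps the core days 0, 1, 4, 7, 14, 21, 28 well sampled
#'   (30% missing) and the in-between days sparse (70% missing).
#' @param admin_censor_day administrative censoring day; must belong to
#'   `day_grid`.
#' @param weibull_shape,weibull_scale baseline hazard family for discharge
#'   times; inverse-CDF sampling gives
#'   `T = scale * (-log(U) * exp(-lp))^(1/shape)`.
#' @param severity_link when `TRUE`, clusters form an ordered severity
#'   gradient: each active gene's response amplitude is aligned with the
#'   sign of its hazard effect and scaled by an equally spaced per-cluster
#'   severity score, so cluster membership is monotonically linked to the
#'   discharge hazard (guaranteed pairwise survival separation between
#'   clusters).  When `FALSE` (default) per-(gene, cluster) response
#'   directions are balanced at random and the cluster-to-survival link is
#'   incidental.
#' @param seed root integer seed; all stage streams are derived from it.
#' @return an object of class `cohort_config`.
#' @seealso [simulate_cohort()]
#' @export
cohort_config <- function(n_patients = 168,
                          n_genes = 500,
                          n_active_genes = 10,
                          n_clusters = 3,
                          day_grid = c(0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 11, 13,
                                       14, 15, 16, 20, 21, 22, 23, 27, 28, 29),
                          effect_sizes = NULL,
                          trajectory_params = list(baseline_range = c(5, 9),
                                                   amplitude_range = c(0.3, 1),
                                                   decay_range = c(0.05, 0.3)),
                          noise_sd = 0.5,
                          patient_sd = 0.7,
                          missing_frac_by_day = NULL,
                          admin_censor_day = 28,
                          weibull_shape = 1.3,
                          weibull_scale = 18,
                          severity_link = FALSE,
                          seed = 1L) {
  if (n_active_genes > n_genes) stop("n_active_genes must be <= n_genes")
  if (n_clusters < 1) stop("n_clusters must be >= 1")
  day_grid <- sort(unique(as.integer(day_grid)))
  if (!admin_censor_day %in% day_grid)
    stop("admin_censor_day must belong to day_grid")
  if (is.null(effect_sizes))
    effect_sizes <- rep_len(c(1, -1), n_active_genes)
  if (length(effect_sizes) != n_active_genes)
    stop("effect_sizes must have length n_active_genes")
  if (is.null(missing_frac_by_day)) {
    core <- c(0, 1, 4, 7, 14, 21, 28)
    missing_frac_by_day <- setNames(ifelse(day_grid %in% core, 0.3, 0.7),
                                    day_grid)
  }
  mf <- missing_frac_by_day[as.character(day_grid)]
  mf[is.na(mf)] <- 0
  names(mf) <- day_grid
  if (any(mf < 0 | mf > 1)) stop("missing fractions must lie in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (patient_sd < 0) stop("patient_sd must be >= 0")
  if (weibull_shape <= 0 || weibull_scale <= 0)
    stop("Weibull shape and scale must be positive")
  structure(list(n_patients = n_patients, n_genes = n_genes,
                 n_active_genes = n_active_genes, n_clusters = n_clusters,
                 day_grid = day_grid, effect_sizes = effect_sizes,
                 trajectory_params = trajectory_params, noise_sd = noise_sd,
                 patient_sd = patient_sd, missing_frac_by_day = mf,
                 admin_censor_day = admin_censor_day,
                 weibull_shape = weibull_shape,
                 weibull_scale = weibull_scale,
                 severity_link = isTRUE(severity_link),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate a longitudinal expression cohort with a planted prognostic signal
#'
#' Generates log2-scale expression around cluster-specific exponential-decay
#' mean trajectories for the active genes (flat noisy baselines for inactive
#' genes), draws discharge times from a Weibull proportional-hazards model
#' whose linear predictor uses the patients' realized day-0 active-gene
#' values (centred at their cross-cluster expectation), truncates follow-up
#' at the administrative censoring day, removes expression records after
#' each patient's follow-up time (loss of follow-up after discharge), and
#' thins the remaining records by the day-specific missingness
#' probabilities.  Deterministic given `config$seed`.
#'
#' Discharge is a "good" event here: a higher linear predictor means a
#' higher hazard of discharge, i.e. earlier discharge.  Event days are
#' rounded up to whole days, matching a day-resolution length-of-stay
#' outcome (ties are therefore common, as in real data).
#'
#' @param config a [cohort_config()].
#' @param truncate_followup drop expression records after discharge
#'   (default `TRUE`; set `FALSE` to keep the full latent series, e.g. to
#'   study the clustering stage in isolation).
#' @param check_events reject configurations whose expected number of
#'   observed discharges is below 2 (the survival stages would degenerate).
#' @return list with `expression` (long data.frame: patient_id, day,
#'   gene_id, value), `survival` (patient_id, time_days, event) and `truth`
#'   (cluster_of_patient, active_genes, true_beta, true_event_times,
#'   linear_predictor).
#' @export
simulate_cohort <- function(config, truncate_followup = TRUE,
                            check_events = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  seeds <- stage_seeds(config$seed, 4L)
  n <- config$n_patients
  p <- config$n_genes
  days <- config$day_grid
  genes <- sprintf("g%04d", seq_len(p))
  patients <- sprintf("p%03d", seq_len(n))
  active <- genes[seq_len(config$n_active_genes)]
  tp <- config$trajectory_params

  # stage 1: cluster structure and mean curves
  pars <- with_seed(seeds[1], {
    cl <- sample(rep_len(seq_len(config$n_clusters), n))
    base <- runif(p, tp$baseline_range[1], tp$baseline_range[2])
    amp <- matrix(0, p, config$n_clusters)
    act <- seq_len(config$n_active_genes)
    if (config$severity_link && config$n_clusters > 1) {
      # ordered severity gradient: amplitude aligned with the hazard sign,
      # scaled by an equally spaced per-cluster severity score
      m <- seq(-1, 1, length.out = config$n_clusters)
      a0 <- runif(config$n_active_genes,
                  tp$amplitude_range[1], tp$amplitude_range[2])
      amp[act, ] <- outer(a0 * sign(config$effect_sizes), m)
    } else {
      # balanced response directions: each active gene goes up in some
      # clusters and down in others, so active genes differentiate
      # clusters (and carry comparable day-0 variance)
      signs <- matrix(nrow = config$n_active_genes, byrow = TRUE,
                      vapply(act, function(g)
                        sample(rep_len(c(-1, 1), config$n_clusters)),
                        numeric(config$n_clusters)),
                      ncol = config$n_clusters)
      amp[act, ] <- runif(config$n_active_genes * config$n_clusters,
                          tp$amplitude_range[1], tp$amplitude_range[2]) *
        signs
    }
    decay <- runif(config$n_clusters, tp$decay_range[1], tp$decay_range[2])
    list(cl = cl, base = base, amp = amp, decay = decay)
  })

  # latent mean value of gene g for patient i at day t: b_g + a_{g,c} e^{-r_c t}
  mean_curve <- function(cluster, day) {
    pars$base + pars$amp[, cluster] * exp(-pars$decay[cluster] * day)
  }

  # stage 2: persistent patient offsets + per-draw noise -> dense table
  values <- with_seed(seeds[2], {
    offset <- matrix(rnorm(n * p, sd = config$patient_sd), n, p)
    v <- array(rnorm(n * length(days) * p, sd = config$noise_sd),
               dim = c(n, length(days), p))
    for (i in seq_len(n))
      for (q in seq_along(days))
        v[i, q, ] <- v[i, q, ] + mean_curve(pars$cl[i], days[q]) + offset[i, ]
    v
  })

  # stage 3: survival via Weibull PH on realized day-0 active-gene values
  day0 <- which(days == 0)
  if (length(day0) == 0) stop("day_grid must contain day 0")
  act_idx <- seq_len(config$n_active_genes)
  # centre at the cross-cluster expectation so the baseline hazard is
  # interpretable and exp(lp) stays on a sane scale
  centre <- pars$base[act_idx] + rowMeans(pars$amp[act_idx, , drop = FALSE])
  X0 <- values[, day0, act_idx, drop = FALSE]
  dim(X0) <- c(n, config$n_active_genes)
  lp <- drop(sweep(X0, 2, centre) %*% config$effect_sizes)

  cens <- config$admin_censor_day
  if (check_events) {
    expected_events <- sum(1 - exp(-(cens / config$weibull_scale)^
                                     config$weibull_shape * exp(lp)))
    if (expected_events < 2)
      stop("configuration yields fewer than 2 expected events; ",
           "survival stages would degenerate")
  }

  tev <- with_seed(seeds[3], {
    u <- runif(n)
    config$weibull_scale * (-log(u) * exp(-lp))^(1 / config$weibull_shape)
  })
  tev_day <- pmax(1, ceiling(tev))          # day-resolution discharge
  time_days <- pmin(tev_day, cens)
  event <- as.integer(tev_day <= cens)

  survival <- data.frame(patient_id = patients, time_days = time_days,
                         event = event, stringsAsFactors = FALSE)

  expr <- data.frame(
    patient_id = rep(patients, times = length(days) * p),
    day = rep(rep(days, each = n), times = p),
    gene_id = rep(genes, each = n * length(days)),
    value = as.vector(values),
    stringsAsFactors = FALSE)

  if (truncate_followup)
    expr <- expr[expr$day <= time_days[match(expr$patient_id, patients)], ,
                 drop = FALSE]
  expr <- apply_missingness(expr, config$missing_frac_by_day, seeds[4])
  rownames(expr) <- NULL

  truth <- list(cluster_of_patient = setNames(pars$cl, patients),
                active_genes = active,
                true_beta = setNames(config$effect_sizes, active),
                true_event_times = setNames(tev, patients),
                linear_predictor = setNames(lp, patients))
  list(expression = expr, survival = survival, truth = truth)
}

#' Thin a long expression table by day-specific draw-level missingness
#'
#' Each (patient, day) block — one blood draw — is dropped independently
#' with the probability given for that day; all genes of a draw move
#' together, mirroring draw-level missingness in the study design.
#'
#' @param table long expression data.frame (patient_id, day, gene_id, value).
#' @param missing_frac_by_day named numeric vector, day -> drop probability.
#' @param seed integer seed.
#' @return the thinned table.
#' @export
apply_missingness <- function(table, missing_frac_by_day, seed = 1L) {
  if (any(missing_frac_by_day < 0 | missing_frac_by_day > 1))
    stop("missing fractions must lie in [0, 1]")
  key <- paste(table$patient_id, table$day, sep = "\r")
  blocks <- unique(key)
  bday <- as.character(table$day[match(blocks, key)])
  frac <- missing_frac_by_day[bday]
  frac[is.na(frac)] <- 0
  drop <- with_seed(seed, runif(length(blocks)) < frac)
  out <- table[!key %in% blocks[drop], , drop = FALSE]
  rownames(out) <- NULL
  out
}
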