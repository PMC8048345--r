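#' Select a reduced time grid by per-day missingness
#'
#' Keeps the days whose fraction of patients without any measurement is
#' strictly below `max_missing_frac`.  When a survival table is supplied
#' the denominator counts only patients still under follow-up at that day
#' (`time_days >= day`); otherwise all patients in the table.  The strict
#' inequality matches a "less than 50% missing" selection rule.
#'
#' @param table long expression data.frame (patient_id, day, gene_id, value).
#' @param max_missing_frac threshold in (0, 1].
#' @param surv optional survival table used for the follow-up denominator.
#' @param days candidate days (default: the days present in the table).
#' @return object of class `time_grid` (list with `selected_days`,
#'   `missing_frac`).
#' @export
select_time_points <- function(table, max_missing_frac = 0.5, surv = NULL,
                               days = NULL) {
  if (nrow(table) == 0) stop("empty expression table")
  if (max_missing_frac <= 0 || max_missing_frac > 1)
    stop("max_missing_frac must lie in (0, 1]")
  if (is.null(days)) days <- sort(unique(table$day))
  patients <- unique(table$patient_id)
  obs <- unique(table[, c("patient_id", "day")])
  frac <- vapply(days, function(d) {
    if (!is.null(surv)) {
      at_risk <- surv$patient_id[surv$time_days >= d]
      at_risk <- intersect(at_risk, patients)
    } else {
      at_risk <- patients
    }
    if (length(at_risk) == 0) return(1)
    seen <- obs$patient_id[obs$day == d]
    1 - length(intersect(at_risk, seen)) / length(at_risk)
  }, numeric(1))
  sel <- days[frac < max_missing_frac]
  if (length(sel) == 0) stop("no day passes the missingness threshold")
  structure(list(selected_days = sel,
                 missing_frac = setNames(frac, days)),
            class = "time_grid")
}

#' Mixed carry / interpolation imputation onto a reduced time grid
#'
#' For every required (patient, day in grid) cell: keep an observed draw;
#' otherwise carry the nearest draw within `max_carry_days` (past ->
#' carried_forward, future -> carried_backward, nearest wins, equidistant
#' ties prefer the past); otherwise linearly interpolate between the
#' closest past and future draws; cells with neither bracketing side stay
#' missing and are resolved later by [split_complete_cases()].  Carrying
#' moves whole per-day draw vectors — all genes of one blood draw travel
#' together — because missingness is draw-level in the study design.  No
#' extrapolation is performed beyond a patient's last observation.
#'
#' @param table long expression data.frame (patient_id, day, gene_id, value).
#' @param grid a `time_grid` or integer vector of required days.
#' @param max_carry_days carry window in days (default 2).
#' @param genes gene set / column order (default: all genes in the table,
#'   sorted).
#' @param tie_prefer `"past"` (default) or `"future"`: side carried when
#'   past and future draws are equidistant within the window.
#' @return object of class `series_set`: `values` array (patients x days x
#'   genes), `provenance` array of the same shape with entries in
#'   `observed`, `carried_forward`, `carried_backward`, `interpolated`,
#'   `missing`, plus `grid`, `patients`, `genes`.
#' @export
impute_mixed <- function(table, grid, max_carry_days = 2, genes = NULL,
                         tie_prefer = c("past", "future")) {
  tie_prefer <- match.arg(tie_prefer)
  if (inherits(grid, "time_grid")) grid <- grid$selected_days
  grid <- sort(unique(as.numeric(grid)))
  if (max_carry_days < 0) stop("max_carry_days must be >= 0")
  if (length(grid) == 0 || any(!is.finite(grid))) stop("invalid grid")
  if (is.null(genes)) genes <- sort(unique(table$gene_id))
  patients <- unique(table$patient_id)
  nq <- length(grid); np <- length(patients); ng <- length(genes)

  values <- array(NA_real_, dim = c(np, nq, ng),
                  dimnames = list(patients, grid, genes))
  prov <- array("missing", dim = c(np, nq, ng),
                dimnames = list(patients, grid, genes))

  split_idx <- split(seq_len(nrow(table)), table$patient_id)
  for (i in seq_len(np)) {
    rows <- split_idx[[patients[i]]]
    sub <- table[rows, , drop = FALSE]
    obs_days <- sort(unique(sub$day))
    # per-patient day x gene matrix of observed draws
    m <- matrix(NA_real_, length(obs_days), ng,
                dimnames = list(obs_days, genes))
    m[cbind(match(sub$day, obs_days), match(sub$gene_id, genes))] <- sub$value
    for (q in seq_len(nq)) {
      d <- grid[q]
      if (d %in% obs_days) {
        values[i, q, ] <- m[as.character(d), ]
        prov[i, q, ] <- "observed"
        next
      }
      past <- obs_days[obs_days < d]
      futr <- obs_days[obs_days > d]
      dp <- if (length(past)) d - max(past) else Inf
      df <- if (length(futr)) min(futr) - d else Inf
      use_past <- if (dp == df) tie_prefer == "past" else dp < df
      if (min(dp, df) <= max_carry_days) {
        src <- if (use_past) max(past) else min(futr)
        values[i, q, ] <- m[as.character(src), ]
        prov[i, q, ] <- if (use_past) "carried_forward" else
          "carried_backward"
      } else if (is.finite(dp) && is.finite(df)) {
        a <- max(past); b <- min(futr)
        va <- m[as.character(a), ]; vb <- m[as.character(b), ]
        values[i, q, ] <- va + (vb - va) * (d - a) / (b - a)
        prov[i, q, ] <- "interpolated"
      }  # else: stays missing
    }
  }
  structure(list(values = values, provenance = prov, grid = grid,
                 patients = patients, genes = genes),
            class = "series_set")
}

#' @export
print.series_set <- function(x, ...) {
  nmiss <- sum(is.na(x$values))
  cat(sprintf(paste0("series set: %d patients x %d days (%s) x %d genes",
                     ", %d missing cells\n"),
              length(x$patients), length(x$grid),
              paste(x$grid, collapse = ","), length(x$genes), nmiss))
  invisible(x)
}

#' Restrict a series set to complete cases up to a horizon day
#'
#' Retains the patients whose cells are fully resolved at every grid day
#' up to and including `horizon_day`, and truncates the grid there.  This
#' is how trailing unresolved cells after early discharge are handled:
#' rather than extrapolating post-discharge expression, the cohort is
#' split into complete-case datasets at different horizons.
#'
#' @param set a `series_set`.
#' @param horizon_day a day in `set$grid`.
#' @return a complete (no missing cells) `series_set` on the truncated grid.
#' @export
split_complete_cases <- function(set, horizon_day) {
  stopifnot(inherits(set, "series_set"))
  if (!horizon_day %in% set$grid) stop("horizon_day must be in the grid")
  qkeep <- which(set$grid <= horizon_day)
  v <- set$values[, qkeep, , drop = FALSE]
  ok <- apply(!is.na(v), 1, all)
  structure(list(values = v[ok, , , drop = FALSE],
                 provenance = set$provenance[ok, qkeep, , drop = FALSE],
                 grid = set$grid[qkeep],
                 patients = set$patients[ok],
                 genes = set$genes),
            class = "series_set")
}

# Matrix (days x genes) of one patient's series.
series_matrix <- function(set, i) {
  m <- set$values[i, , , drop = FALSE]
  dim(m) <- c(length(set$grid), length(set$genes))
  dimnames(m) <- list(set$grid, set$genes)
  m
}
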