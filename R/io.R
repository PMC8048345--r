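#' Read / write long expression tables and survival tables as CSV
#'
#' Expression CSV columns: patient_id, day, gene_id, value.
#' Survival CSV columns: patient_id, time_days, event.
#'
#' @param path file path.
#' @return the data.frame read.
#' @export
read_expression <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "day", "gene_id", "value")
  if (!all(need %in% names(x)))
    stop("expression CSV must have columns: ", paste(need, collapse = ", "))
  x
}

#' @rdname read_expression
#' @param table the table to write.
#' @export
write_expression <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_expression
#' @export
read_survival <- function(path) {
  check_survival_table(read.csv(path, stringsAsFactors = FALSE),
                       require_event = FALSE)
}

#' @rdname read_expression
#' @export
write_survival <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Export a Kaplan-Meier curve as CSV (time, survival, at_risk, events)
#' @param km a `km_curve`.
#' @param path file path.
#' @export
write_km_curve <- function(km, path) {
  write.csv(data.frame(time = km$event_times, survival = km$survival,
                       at_risk = km$n_at_risk, events = km$n_events),
            path, row.names = FALSE)
  invisible(path)
}

#' Write a pipeline report bundle to a directory
#'
#' Deterministic text artifacts: the selection report (JSON), the union
#' signature with per-day provenance (CSV), the imputed series and cell
#' provenance (long CSV), per-horizon partitions (CSV: patient_id,
#' cluster, is_medoid) and k-selection tables (CSV), and the run
#' manifest (JSON).  Re-running the pipeline with an identical
#' configuration and inputs reproduces the bundle byte for byte.
#'
#' @param report a `trajsurv_report` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(report, dir) {
  stopifnot(inherits(report, "trajsurv_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jw <- function(x, f)
    jsonlite::write_json(x, file.path(dir, f), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)

  sel <- report$alpha_selection
  jw(list(alpha_opt = sel$alpha_opt,
          cindex_table = sel$table,
          splits = sel$splits,
          stable_sets = lapply(report$stable_sets, as.character),
          logrank_by_day = lapply(report$risk_splits, function(r)
            if (!is.null(r$error)) r$error else r$test$p_value)),
     "selection_report.json")

  write.csv(attr(report$signature, "provenance"),
            file.path(dir, "signature.csv"), row.names = FALSE)

  write_series_csv(report$series, file.path(dir, "series.csv"))

  for (h in names(report$horizon_results)) {
    res <- report$horizon_results[[h]]
    if (!is.null(res$error)) next
    part <- res$k_selection$partition
    write.csv(data.frame(patient_id = names(part$labels),
                         cluster = unname(part$labels),
                         is_medoid = names(part$labels) %in%
                           part$medoid_ids),
              file.path(dir, paste0("partition_h", h, ".csv")),
              row.names = FALSE)
    write.csv(res$k_selection$table,
              file.path(dir, paste0("k_selection_h", h, ".csv")),
              row.names = FALSE)
  }
  jw(report$manifest, "manifest.json")
  invisible(dir)
}

# Long CSV of a series set: patient_id, day, gene_id, value, provenance.
write_series_csv <- function(set, path) {
  idx <- expand.grid(patient = set$patients, day = set$grid,
                     gene = set$genes, stringsAsFactors = FALSE)
  write.csv(data.frame(patient_id = idx$patient, day = idx$day,
                       gene_id = idx$gene,
                       value = as.vector(set$values),
                       provenance = as.vector(set$provenance)),
            path, row.names = FALSE)
  invisible(path)
}

#' Export a distance matrix as CSV
#' @param dm symmetric distance matrix.
#' @param path file path.
#' @export
write_distance_matrix <- function(dm, path) {
  write.csv(as.data.frame(dm), path, row.names = TRUE)
  invisible(path)
}
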