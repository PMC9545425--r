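#' QC stage records and reports
#'
#' Each filtering stage produces one record (stage name, unit filtered,
#' counts before/removed/after, parameters used); a `qc_report` chains them
#' and guarantees the bookkeeping arithmetic: for every stage
#' `before - removed = after`, and consecutive stages telescope (the `after`
#' of one stage is the `before` of the next stage acting on the same unit).
#'
#' @param stage stage name
#' @param unit `"variant"` or `"sample"`
#' @param n_before count before the stage
#' @param n_removed count removed by the stage
#' @param params named list of stage parameters (stored as a compact string)
#' @return `qc_stage()`: a one-row data.frame record.
#' @export
qc_stage <- function(stage, unit = c("variant", "sample"),
                     n_before, n_removed, params = list()) {
  unit <- match.arg(unit)
  stopifnot(n_removed >= 0, n_removed <= n_before)
  data.frame(stage = stage, unit = unit,
             n_before = as.integer(n_before),
             n_removed = as.integer(n_removed),
             n_after = as.integer(n_before - n_removed),
             params = paste(names(params), unlist(params),
                            sep = "=", collapse = ";"),
             stringsAsFactors = FALSE)
}

#' @param stages list of stage records (or a pre-bound data.frame)
#' @rdname qc_stage
#' @return `qc_report()`: object of class `qc_report` (a data.frame of stages).
#' @export
qc_report <- function(stages) {
  rep <- if (is.data.frame(stages)) stages else do.call(rbind, stages)
  stopifnot(all(rep$n_before - rep$n_removed == rep$n_after))
  for (u in unique(rep$unit)) {
    r <- rep[rep$unit == u, ]
    if (nrow(r) > 1 && !all(r$n_before[-1] == r$n_after[-nrow(r)]))
      stop("qc_report stages do not telescope for unit ", u)
  }
  class(rep) <- c("qc_report", "data.frame")
  rep
}

#' Initial and final counts of a QC report
#'
#' Telescopes the stage chain per unit: the final count equals the initial
#' count minus all removals.
#'
#' @param rep a `qc_report`
#' @return data.frame with one row per unit: `unit`, `n_initial`, `n_removed`,
#'   `n_final`.
#' @export
qc_report_totals <- function(rep) {
  do.call(rbind, lapply(split(as.data.frame(rep), rep$unit), function(r) {
    data.frame(unit = r$unit[1], n_initial = r$n_before[1],
               n_removed = sum(r$n_removed), n_after = r$n_after[nrow(r)])
  }))
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Write a QC report as TSV and JSON
#' @param rep a `qc_report`
#' @param prefix output path prefix (writes `<prefix>.tsv` and `<prefix>.json`)
#' @export
write_qc_report <- function(rep, prefix) {
  utils::write.table(as.data.frame(rep), paste0(prefix, ".tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.data.frame(rep), paste0(prefix, ".json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(prefix)
}
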