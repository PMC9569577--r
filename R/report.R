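# Structured-text (JSON) reports: every result type the pipeline emits can be
# written to disk and read back to an equal object, so bundles round-trip.

report_type <- function(x) {
  for (cl in c("venn_partition", "enrichment_results", "shortlist_decisions",
               "correlation_profile", "purity_summary", "direction_summary",
               "threshold_grid", "protein_table"))
    if (inherits(x, cl)) return(cl)
  abort_parameter("no report serialization for class: %s",
                  paste(class(x), collapse = "/"))
}

#' Write a result object as a structured report
#'
#' Serializes any pipeline result (Venn partition, enrichment table,
#' shortlist decisions, correlation profile, purity summary, direction
#' summary, threshold grid, protein table) to JSON with a type tag;
#' [read_report()] reconstructs the object. An empty result is a valid
#' report, not an error.
#'
#' @param x a result object.
#' @param path destination file.
#' @export
write_report <- function(x, path) {
  type <- report_type(x)
  payload <- if (is.data.frame(x)) {
    list(columns = lapply(as.data.frame(x), identity))
  } else {
    unclass(x)
  }
  obj <- list(type = type, data = payload)
  if (!is.null(attr(x, "groups"))) obj$groups <- attr(x, "groups")
  ok <- tryCatch({
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) abort_format("cannot write report to %s", path)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) abort_format("no such report: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  type <- obj$type
  d <- obj$data
  rebuild_df <- function(cols, cls) {
    cols <- lapply(cols, function(v) if (is.null(v)) logical(0) else v)
    df <- as.data.frame(cols, stringsAsFactors = FALSE, check.names = FALSE)
    structure(df, class = c(cls, "data.frame"))
  }
  out <- switch(type,
    venn_partition = {
      regions <- lapply(d$regions, function(v) as.character(unlist(v)))
      new_venn_partition(regions, as.character(unlist(d$groups)))
    },
    purity_summary = structure(list(
      counts = unlist(d$counts),
      n_classified = d$n_classified, n_unclassified = d$n_unclassified,
      verdict = d$verdict), class = "purity_summary"),
    protein_table = protein_table(rebuild_df(d$columns, character(0)),
                                  groups = unlist(obj$groups)),
    rebuild_df(d$columns, type)
  )
  out
}
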