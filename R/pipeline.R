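#' Run the full analysis pipeline
#'
#' Executes the stages in fixed order — MISEV QC, differential alteration
#' calling, Venn outcome taxonomy, correlation profiling, concept
#' enrichment, prognostic shortlist — on either a real protein table or a
#' synthetic cohort, and returns one result object carrying every stage's
#' report plus a run manifest (configuration hash, seed, versions, and
#' per-stage record counts so the count trail can be audited on any
#' input). No stage reads another's internal state except through the
#' declared result types.
#'
#' @param records a `protein_table`; omit when simulating.
#' @param spec a [cohort_spec()]; when given, the cohort is simulated and
#'   its records and annotations are used.
#' @param annotations an `annotation_map` (required for enrichment and the
#'   shortlist's relevance rule unless `spec` provides one).
#' @param catalog a `marker_catalog` for the QC stage.
#' @param config an [analysis_config()].
#' @param sev_records optional second `protein_table` (small-vesicle
#'   fraction) enabling the cross-fraction stage.
#' @return object of class `laci_run` with elements `qc`, `differential`
#'   (sets, direction summary), `taxonomy`, `correlation`, `enrichment`,
#'   `shortlist`, `cross_fraction` (or NULL), `truth` (synthetic runs
#'   only), `manifest`.
#' @export
run_pipeline <- function(records = NULL, spec = NULL, annotations = NULL,
                         catalog = builtin_marker_catalog(),
                         config = analysis_config(), sev_records = NULL) {
  truth <- NULL
  seed <- NA_integer_
  if (!is.null(spec)) {
    coh <- simulate_cohort(spec)
    records <- coh$records
    if (is.null(annotations)) annotations <- coh$annotations
    truth <- coh$truth
    seed <- spec$seed
  }
  if (is.null(records))
    abort_parameter("run_pipeline needs records or a cohort spec")

  stages <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  qc <- run_stage("qc", purity_summary(records, catalog))
  stages$qc <- c(n_in = nrow(records), n_out = qc$n_classified)

  sets <- run_stage("differential", altered_sets(records, config))
  dirsum <- run_stage("differential", direction_summary(records, config))
  stages$differential <- c(n_in = nrow(records),
                           n_out = length(sets$union))

  part <- run_stage("taxonomy",
                    venn_partition(sets$NAO, sets$RVE, sets$CD))
  stages$taxonomy <- c(n_in = length(sets$union),
                       n_out = sum(part$counts))

  correl <- run_stage("correlation", list(
    all = group_correlation_profile(records, "all", config = config),
    altered_union = group_correlation_profile(
      records, "altered_union", partition = part, config = config),
    normality = lapply(stats::setNames(nm = contrast_groups(records)),
      function(g) normality_check(records[[paste0("log2_", g, "_HC")]],
                                  alpha = config$alpha))))
  stages$correlation <- c(n_in = nrow(records),
                          n_out = nrow(correl$all))

  enr <- if (!is.null(annotations)) {
    run_stage("enrichment",
              run_enrichment(records, annotations, sets$union,
                             config = config))
  }
  stages$enrichment <- c(n_in = length(sets$union),
                         n_out = if (is.null(enr)) 0L else nrow(enr))

  sl <- run_stage("shortlist",
                  apply_shortlist(records, partition = part,
                                  annotations = annotations,
                                  config = config))
  stages$shortlist <- c(n_in = length(sets$union),
                        n_out = sum(sl$retained))

  xf <- if (!is.null(sev_records)) {
    run_stage("cross_fraction", {
      ov <- cross_fraction_overlap(records, sev_records)
      cors <- lapply(stats::setNames(nm = contrast_groups(records)),
        function(g) cross_fraction_correlation(records, sev_records, g,
                                               config))
      list(overlap = ov, correlations = cors)
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("laciMEV")),
    r_version = R.version.string,
    seed = seed,
    config = unclass(config),
    config_hash = config_hash(config),
    synthetic = !is.null(truth),
    stages = stages
  )

  structure(list(records = records, qc = qc,
                 differential = list(sets = sets, direction = dirsum),
                 taxonomy = part, correlation = correl, enrichment = enr,
                 shortlist = sl, cross_fraction = xf, truth = truth,
                 manifest = manifest),
            class = "laci_run")
}

# md5 of the canonical JSON form of the configuration
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

#' @export
print.laci_run <- function(x, ...) {
  cat("iTRAQ MEV analysis run\n")
  st <- x$manifest$stages
  for (s in names(st))
    cat(sprintf("  %-13s in %4d  out %4d\n", s, st[[s]][["n_in"]],
                st[[s]][["n_out"]]))
  cat(sprintf("  QC verdict: %s\n", x$qc$verdict))
  cat(sprintf("  altered proteome: %d of %d (%d%%)\n",
              length(x$differential$sets$union), nrow(x$records),
              round_half_up(100 * length(x$differential$sets$union) /
                              nrow(x$records))))
  cat(sprintf("  shortlist: %d candidates\n", sum(x$shortlist$retained)))
  invisible(x)
}

#' @export
summary.laci_run <- function(object, ...) {
  print(object)
  cat("\nDirection of change:\n")
  print(as.data.frame(object$differential$direction), row.names = FALSE)
  cat("\nVenn regions:\n")
  print(object$taxonomy$counts)
  cat("\nProteome-wide correlations:\n")
  print(as.data.frame(object$correlation$all), row.names = FALSE)
  if (!is.null(object$enrichment)) {
    cat("\nConcept enrichment:\n")
    print(as.data.frame(object$enrichment)[
      c("concept", "a", "b", "c", "d", "chi2", "p", "enriched")],
      row.names = FALSE, digits = 3)
  }
  invisible(object)
}

#' Write a run bundle to a directory
#'
#' One JSON report per stage plus `manifest.json`; every report
#' round-trips through [read_report()]. If any write fails, already
#' written files are kept and a `FAILED` marker file names the stage.
#' Bundles are byte-identical across repeated runs of the same seeded
#' input.
#'
#' @param run a `laci_run`.
#' @param dir destination directory (created if needed).
#' @export
write_run_bundle <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(obj, file) {
    tryCatch(write_report(obj, file.path(dir, file)),
             error = function(e) {
               writeLines(sprintf("FAILED at %s: %s", file,
                                  conditionMessage(e)),
                          file.path(dir, "FAILED"))
               stop(e)
             })
  }
  emit(run$records, "records.json")
  emit(run$qc, "qc.json")
  emit(run$differential$direction, "direction_summary.json")
  emit(run$taxonomy, "taxonomy.json")
  emit(run$correlation$all, "correlation_all.json")
  emit(run$correlation$altered_union, "correlation_altered.json")
  if (!is.null(run$enrichment)) emit(run$enrichment, "enrichment.json")
  emit(run$shortlist, "shortlist.json")
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
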