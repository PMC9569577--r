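#' Prognostic-candidate shortlist rule engine
#'
#' Filters the altered proteome through five rules, recording per protein
#' every rule fired and the evidence behind it:
#' \describe{
#'   \item{R1 (disqualify)}{altered in all three groups with a uniform
#'     direction of change: a generic stroke signature with no outcome
#'     contrast.}
#'   \item{R2 (favor)}{altered exclusively in NAO, or exclusively in one or
#'     both adverse-outcome groups (the group-specific and
#'     outcome-dependent Venn regions).}
#'   \item{R3 (favor)}{annotated with a disease-relevant concept:
#'     oxygen-glucose deprivation/hypoxia, oxidative stress, vesicle
#'     compartments, or vasculature/endothelium.}
#'   \item{R4 (favor)}{significantly altered in opposite directions in NAO
#'     versus at least one adverse group: a direct prognosis
#'     discriminator.}
#'   \item{R5 (disqualify)}{same direction \emph{and} similar magnitude of
#'     change between NAO and an adverse group irrespective of
#'     significance, operationalized as same sign with
#'     \eqn{|\Delta \log_2| \le} `config$r5_delta` (default 0.30): such a
#'     protein cannot separate outcomes.}
#' }
#' A protein is retained iff at least one favoring rule fires and no
#' disqualifying rule fires: favoring criteria are sufficient when
#' unblocked, not jointly required.
#'
#' @param records a `protein_table`.
#' @param partition a [venn_partition()] of the per-group altered sets;
#'   computed from `records` when missing.
#' @param annotations an `annotation_map` (may be empty; then R3 never
#'   fires).
#' @param config an [analysis_config()].
#' @param relevance_concepts concepts whose match fires R3.
#' @return data.frame of class `shortlist_decisions`: one row per altered
#'   protein with columns `accession`, `gene`, logical `R1`..`R5`,
#'   `retained`, and `fired_rules` / `evidence` provenance strings.
#' @export
apply_shortlist <- function(records, partition = NULL, annotations = NULL,
                            config = analysis_config(),
                            relevance_concepts = builtin_concepts()[
                              c("ogd_hypoxia", "oxidative_stress",
                                "vesicle", "vasculature")]) {
  sets <- altered_sets(records, config)
  if (is.null(partition))
    partition <- venn_partition(sets$NAO, sets$RVE, sets$CD)
  lab <- alteration_labels(records, config)
  groups <- contrast_groups(records)
  adverse <- setdiff(groups, "NAO")
  eligible <- records$accession %in% sets$union

  miss_contrast <- vapply(groups, function(g) {
    any(!is.finite(records[[paste0("log2_", g, "_HC")]][eligible]))
  }, logical(1))
  if (any(miss_contrast))
    abort_format("record(s) lack contrasts for group(s): %s",
                 paste(groups[miss_contrast], collapse = ", "))

  concept_hits <- if (is.null(annotations)) {
    stats::setNames(rep(list(rep(FALSE, nrow(records))),
                        length(relevance_concepts)),
                    vapply(relevance_concepts, `[[`, "", "name"))
  } else {
    out <- lapply(relevance_concepts,
                  function(cn) match_concept(records$accession, annotations, cn))
    names(out) <- vapply(relevance_concepts, `[[`, "", "name")
    out
  }

  rows <- lapply(which(eligible), function(i) {
    acc <- records$accession[i]
    li <- lab[i, ]
    l2 <- vapply(groups, function(g)
      records[[paste0("log2_", g, "_HC")]][i], numeric(1))

    altered_in <- names(li)[li != "unchanged"]
    ev <- character(0)

    # R1: pan-group alteration with uniform direction
    r1 <- length(altered_in) == length(groups) &&
      length(unique(li[altered_in])) == 1L
    if (r1) ev <- c(ev, sprintf("R1(disfavor): %s in all groups",
                                li[[1]]))

    # R2: exclusive to NAO, or confined to adverse groups
    r2 <- identical(altered_in, "NAO") ||
      (length(altered_in) > 0 && all(altered_in %in% adverse))
    if (r2) ev <- c(ev, sprintf("R2(favor): altered only in %s",
                                paste(altered_in, collapse = "+")))

    # R3: relevant annotation concept
    hit_names <- names(concept_hits)[vapply(concept_hits, `[[`, FALSE, i)]
    r3 <- length(hit_names) > 0
    if (r3) ev <- c(ev, sprintf("R3(favor): concept %s",
                                paste(hit_names, collapse = ",")))

    # R4: opposite significant direction NAO vs adverse
    r4 <- FALSE
    if (li[["NAO"]] != "unchanged") {
      for (g in adverse) {
        if (li[[g]] != "unchanged" && li[[g]] != li[["NAO"]]) {
          r4 <- TRUE
          ev <- c(ev, sprintf("R4(favor): NAO %s vs %s %s",
                              li[["NAO"]], g, li[[g]]))
        }
      }
    }

    # R5: same sign and similar magnitude NAO vs an adverse group,
    # irrespective of significance
    r5 <- FALSE
    for (g in adverse) {
      if (sign(l2[["NAO"]]) * sign(l2[[g]]) > 0 &&
          abs(l2[["NAO"]] - l2[[g]]) <= config$r5_delta) {
        r5 <- TRUE
        ev <- c(ev, sprintf("R5(disfavor): NAO %.2f ~ %s %.2f",
                            l2[["NAO"]], g, l2[[g]]))
      }
    }

    retained <- (r2 || r3 || r4) && !r1 && !r5
    fired <- c("R1", "R2", "R3", "R4", "R5")[c(r1, r2, r3, r4, r5)]
    data.frame(accession = acc, gene = records$gene[i],
               R1 = r1, R2 = r2, R3 = r3, R4 = r4, R5 = r5,
               retained = retained,
               fired_rules = paste(fired, collapse = ","),
               evidence = paste(ev, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
         else data.frame(accession = character(0), gene = character(0),
                         R1 = logical(0), R2 = logical(0), R3 = logical(0),
                         R4 = logical(0), R5 = logical(0),
                         retained = logical(0),
                         fired_rules = character(0), evidence = character(0),
                         stringsAsFactors = FALSE)
  structure(out, class = c("shortlist_decisions", "data.frame"))
}
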