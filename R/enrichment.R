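#' Define a GO string-match concept
#'
#' A concept is a named set of substrings matched case-insensitively
#' against GO term names of one ontology aspect. A protein matches the
#' concept when any of its terms in that aspect contains any of the
#' substrings. Matching runs over term names only, never term IDs or
#' definitions.
#'
#' @param name concept label.
#' @param aspect `"BP"`, `"CC"` or `"MF"`.
#' @param match_strings non-empty character vector of substrings.
#' @return list of class `concept_definition`.
#' @export
concept_definition <- function(name, aspect, match_strings) {
  if (!aspect %in% c("BP", "CC", "MF"))
    abort_parameter("aspect must be one of BP/CC/MF")
  if (!length(match_strings) || any(!nzchar(match_strings)))
    abort_parameter("match_strings must be non-empty")
  structure(list(name = name, aspect = aspect,
                 match_strings = tolower(match_strings)),
            class = "concept_definition")
}

#' Built-in concept library
#'
#' The concepts profiled against the altered proteome: inflammation/immune
#' response, vesicle compartments, coagulation/fibrinolysis, vasculature/
#' endothelium, oxygen-glucose deprivation and hypoxia, amyloid (an
#' age-related specificity control), brain localization, and oxidative
#' stress (used by the shortlist's relevance rule).
#'
#' @return named list of [concept_definition()]s.
#' @export
builtin_concepts <- function() {
  list(
    inflammation = concept_definition("inflammation", "BP",
      c("inflammation", "inflammatory", "immune", "immuno")),
    vesicle = concept_definition("vesicle", "CC",
      c("vesicle", "endosome", "lysosome", "autophagosome",
        "secretory granule")),
    coagulation = concept_definition("coagulation", "BP",
      c("coagulation", "fibrin", "clot", "fibrinolysis", "aggregation")),
    vasculature = concept_definition("vasculature", "BP",
      c("vasculature", "vascular", "endothelial")),
    ogd_hypoxia = concept_definition("ogd_hypoxia", "BP",
      c("ogd", "hypoxia")),
    amyloid = concept_definition("amyloid", "BP", "amyloid"),
    brain = concept_definition("brain", "CC", "brain"),
    oxidative_stress = concept_definition("oxidative_stress", "BP",
      "oxidative stress")
  )
}

#' Match proteins against a concept
#'
#' @param accessions accession(s) to test.
#' @param annotations an `annotation_map`.
#' @param concept a [concept_definition()].
#' @return logical vector, one element per accession.
#' @export
match_concept <- function(accessions, annotations, concept) {
  ann <- annotations[annotations$aspect == concept$aspect, , drop = FALSE]
  terms <- tolower(ann$term)
  hit <- rep(FALSE, length(terms))
  for (s in concept$match_strings)
    hit <- hit | grepl(s, terms, fixed = TRUE)
  matched_acc <- unique(ann$accession[hit])
  accessions %in% matched_acc
}

#' Pearson chi-square test of independence on a 2x2 table
#'
#' The uncorrected statistic \eqn{\sum (O-E)^2/E} with 1 degree of freedom
#' and an upper-tail p-value. No Yates continuity correction by default:
#' the uncorrected statistic is the convention this enrichment reproduces;
#' the corrected form is available behind `correct = TRUE`.
#'
#' @param a,b,c,d cell counts: altered-and-matched, altered-and-unmatched,
#'   unaltered-and-matched, unaltered-and-unmatched.
#' @param correct apply the Yates continuity correction.
#' @return list: `chi2`, `p`, `table`.
#' @export
#' @examples
#' chi_square_2x2(21, 125, 31, 392)$p  # ~0.011
chi_square_2x2 <- function(a, b, c, d, correct = FALSE) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != floor(cells)))
    abort_parameter("cell counts must be non-negative integers")
  m <- matrix(cells, 2, 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    abort_degenerate("degenerate 2x2 table: zero margin")
  n <- sum(m)
  expected <- outer(rowSums(m), colSums(m)) / n
  dev <- abs(m - expected)
  if (correct) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / expected)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       table = m)
}

#' Concept enrichment of the altered proteome
#'
#' For each concept, cross-tabulates altered vs unaltered proteins against
#' concept match vs no match and tests independence with the uncorrected
#' chi-square. A concept matching no protein (or matched by all) yields a
#' degenerate table and is reported as a skipped row with the reason rather
#' than aborting the batch.
#'
#' @param records a `protein_table`.
#' @param annotations an `annotation_map`.
#' @param altered_set accessions of the altered proteome (e.g.
#'   `altered_sets(records, config)$union`).
#' @param concepts list of [concept_definition()]s; defaults to
#'   [builtin_concepts()].
#' @param config an [analysis_config()]; `alpha` flags enrichment.
#' @param n_unaltered override for the unaltered total, for reproduction
#'   runs against published marginals; by default `nrow(records) -
#'   length(altered_set)`.
#' @return data.frame of class `enrichment_results`: one row per concept
#'   with cells `a`..`d`, proportions, `chi2`, `p`, `enriched`, `note`.
#' @export
run_enrichment <- function(records, annotations, altered_set,
                           concepts = builtin_concepts(),
                           config = analysis_config(),
                           n_unaltered = NULL) {
  altered_set <- intersect(altered_set, records$accession)
  unaltered <- setdiff(records$accession, altered_set)
  rows <- lapply(concepts, function(cn) {
    m_alt <- match_concept(altered_set, annotations, cn)
    m_un <- match_concept(unaltered, annotations, cn)
    a <- sum(m_alt); b <- length(altered_set) - a
    c_ <- sum(m_un)
    d <- (n_unaltered %||% length(unaltered)) - c_
    res <- tryCatch(chi_square_2x2(a, b, c_, d),
                    laci_degenerate_error = function(e) NULL)
    data.frame(
      concept = cn$name, aspect = cn$aspect,
      a = a, b = b, c = c_, d = d,
      prop_altered = if (a + b > 0) a / (a + b) else NA_real_,
      prop_unaltered = if (c_ + d > 0) c_ / (c_ + d) else NA_real_,
      chi2 = if (is.null(res)) NA_real_ else res$chi2,
      p = if (is.null(res)) NA_real_ else res$p,
      enriched = !is.null(res) && res$p < config$alpha &&
        a / (a + b) > c_ / (c_ + d),
      note = if (is.null(res)) "skipped: degenerate table" else "",
      stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, c(rows, make.row.names = FALSE)),
            class = c("enrichment_results", "data.frame"))
}
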