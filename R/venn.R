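#' Seven-region Venn partition of per-group altered sets
#'
#' Decomposes the three per-group altered-protein sets into the seven
#' disjoint Venn regions and derives the outcome-taxonomy classes defined on
#' them: \emph{LACI-related} (altered in all three groups),
#' \emph{outcome-dependent} (altered in both adverse-outcome groups and not
#' in NAO), and \emph{group-specific} (altered in exactly one group). The
#' classes are defined on the partition itself, never recomputed from raw
#' calls, so region counts and class-based filters can never disagree.
#'
#' @param set_nao,set_rve,set_cd character vectors of accessions altered in
#'   the NAO, RVE and CD groups respectively.
#' @return A `venn_partition`: regions (accession sets and counts) named
#'   `NAO_only`, `RVE_only`, `CD_only`, `NAO_RVE`, `NAO_CD`, `RVE_CD`,
#'   `all_three`, plus the derived classes and input marginals.
#' @export
#' @examples
#' vp <- venn_partition(c("a", "b"), c("b", "c"), c("b", "d"))
#' vp$counts
venn_partition <- function(set_nao, set_rve, set_cd) {
  a <- unique(as.character(set_nao))
  b <- unique(as.character(set_rve))
  d <- unique(as.character(set_cd))
  u <- unique(c(a, b, d))
  in_a <- u %in% a; in_b <- u %in% b; in_d <- u %in% d
  regions <- list(
    NAO_only  = u[ in_a & !in_b & !in_d],
    RVE_only  = u[!in_a &  in_b & !in_d],
    CD_only   = u[!in_a & !in_b &  in_d],
    NAO_RVE   = u[ in_a &  in_b & !in_d],
    NAO_CD    = u[ in_a & !in_b &  in_d],
    RVE_CD    = u[!in_a &  in_b &  in_d],
    all_three = u[ in_a &  in_b &  in_d]
  )
  new_venn_partition(regions, c("NAO", "RVE", "CD"))
}

# internal constructor shared with report deserialization
new_venn_partition <- function(regions, groups) {
  counts <- vapply(regions, length, integer(1))
  structure(list(
    regions = regions,
    counts = counts,
    groups = groups,
    marginals = c(
      NAO = counts[["NAO_only"]] + counts[["NAO_RVE"]] +
            counts[["NAO_CD"]] + counts[["all_three"]],
      RVE = counts[["RVE_only"]] + counts[["NAO_RVE"]] +
            counts[["RVE_CD"]] + counts[["all_three"]],
      CD  = counts[["CD_only"]] + counts[["NAO_CD"]] +
            counts[["RVE_CD"]] + counts[["all_three"]]),
    classes = list(
      laci_related = regions$all_three,
      outcome_dependent = regions$RVE_CD,
      group_specific = regions[c("NAO_only", "RVE_only", "CD_only")],
      adverse_predictor = unique(c(regions$RVE_CD, regions$RVE_only,
                                   regions$CD_only))
    )
  ), class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("Venn partition of altered-protein sets\n")
  cat(sprintf("  union: %d proteins\n", sum(x$counts)))
  for (r in names(x$counts))
    cat(sprintf("  %-10s %d\n", r, x$counts[[r]]))
  cat(sprintf("  adverse-predictor class: %d\n",
              length(x$classes$adverse_predictor)))
  invisible(x)
}

#' Adverse-outcome predictor set
#'
#' The union of the outcome-dependent region with the RVE-only and CD-only
#' regions: proteins altered in an adverse-outcome group but never in NAO
#' alone, the class proposed as most useful for predicting an adverse
#' outcome. Its size is exactly the sum of the three region sizes since the
#' regions are disjoint.
#'
#' @param partition a [venn_partition()].
#' @return character vector of accessions.
#' @export
adverse_predictor_set <- function(partition) {
  stopifnot(inherits(partition, "venn_partition"))
  partition$classes$adverse_predictor
}
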