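#' Volcano-style alteration calling
#'
#' A contrast is called `increased` when its log2 ratio exceeds the positive
#' cutoff and the significance criterion holds, `decreased` when it falls
#' below the negative cutoff with the criterion holding, else `unchanged`.
#' Both inequalities are strict, exactly as the dual criterion is stated:
#' \eqn{|\log_2(\mathrm{ratio})| > 0.58} and \eqn{-\log_{10}(p) > 1.30} at
#' the defaults, so a contrast sitting exactly on a boundary is unchanged.
#'
#' The significance criterion is `-log10(p) > neglog10p_cutoff` when a
#' numeric p is available; when p is missing, a logical significance flag
#' (the bold-mark convention of published tables) is accepted in its place;
#' with neither, the contrast can only be unchanged.
#'
#' @param log2_ratio numeric vector of log2 group/HC ratios.
#' @param p numeric vector of p-values (NA allowed).
#' @param sig optional logical vector of significance flags used where `p`
#'   is NA.
#' @param config an [analysis_config()].
#' @return character vector over `{increased, decreased, unchanged}`.
#' @export
#' @examples
#' classify_alteration(c(1.05, -0.58, 2.0), c(0.01, 0.01, 0.2))
classify_alteration <- function(log2_ratio, p, sig = NULL,
                                config = analysis_config()) {
  n <- length(log2_ratio)
  p <- rep_len(as.numeric(p), n)
  sig <- if (is.null(sig)) rep(NA, n) else rep_len(as.logical(sig), n)
  signif_ok <- ifelse(!is.na(p), -log10(p) > config$neglog10p_cutoff,
                      !is.na(sig) & sig)
  out <- rep("unchanged", n)
  out[signif_ok & log2_ratio >  config$log2_cutoff] <- "increased"
  out[signif_ok & log2_ratio < -config$log2_cutoff] <- "decreased"
  out
}

# per-group label matrix for a protein table; applies optional BH adjustment
alteration_labels <- function(records, config = analysis_config()) {
  groups <- contrast_groups(records)
  cols <- lapply(groups, function(g) {
    p <- records[[paste0("p_", g, "_HC")]]
    if (isTRUE(config$fdr_correct)) p <- stats::p.adjust(p, method = "BH")
    sc <- paste0("sig_", g, "_HC")
    classify_alteration(records[[paste0("log2_", g, "_HC")]], p,
                        sig = if (sc %in% names(records)) records[[sc]],
                        config = config)
  })
  matrix(unlist(cols), nrow = nrow(records),
         dimnames = list(records$accession, groups))
}

#' Per-group altered-protein sets
#'
#' @param records a `protein_table`.
#' @param config an [analysis_config()].
#' @return list with one accession set per contrast group plus `union`, the
#'   altered proteome (proteins altered in at least one group).
#' @export
altered_sets <- function(records, config = analysis_config()) {
  lab <- alteration_labels(records, config)
  sets <- lapply(colnames(lab),
                 function(g) records$accession[lab[, g] != "unchanged"])
  names(sets) <- colnames(lab)
  sets$union <- unique(unlist(sets, use.names = FALSE))
  sets
}

# round half-up to whole percent, the reporting convention for count tables
round_half_up <- function(x) floor(x + 0.5)

#' Direction-of-change summary per group
#'
#' Counts increased and decreased proteins per contrast group and the
#' percentage decreased among altered; raw counts are always retained
#' alongside the rounded percentage.
#'
#' @inheritParams altered_sets
#' @return data.frame of class `direction_summary` with columns `group`,
#'   `n_altered`, `n_decreased`, `n_increased`, `pct_decreased`.
#' @export
direction_summary <- function(records, config = analysis_config()) {
  lab <- alteration_labels(records, config)
  rows <- lapply(colnames(lab), function(g) {
    dn <- sum(lab[, g] == "decreased")
    up <- sum(lab[, g] == "increased")
    data.frame(group = g, n_altered = dn + up, n_decreased = dn,
               n_increased = up,
               pct_decreased = if (dn + up > 0)
                 round_half_up(100 * dn / (dn + up)) else 0,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("direction_summary", "data.frame"))
}

#' Threshold-sensitivity grid
#'
#' Recomputes per-group altered counts over a full factorial grid of
#' p-value cutoffs and linear fold-change cutoffs (converted to log2
#' internally), to check that group ordering of alteration burden is stable
#' under stricter filtering. Counts are monotone non-increasing along both
#' axes.
#'
#' @inheritParams altered_sets
#' @param p_grid p-value cutoffs (e.g. `c(0.05, 0.025, 0.01, 0.005)`).
#' @param fc_grid linear fold-change cutoffs, all > 1 (e.g. `c(1.5, 2, 2.5)`).
#' @return data.frame of class `threshold_grid` with columns `p_cutoff`,
#'   `fc_cutoff`, one count column per group.
#' @export
threshold_sensitivity <- function(records, p_grid, fc_grid,
                                  config = analysis_config()) {
  if (any(!is.finite(fc_grid)) || any(fc_grid <= 0))
    abort_parameter("fold-change cutoffs must be positive")
  if (any(!is.finite(p_grid)) || any(p_grid <= 0 | p_grid > 1))
    abort_parameter("p-value cutoffs must lie in (0, 1]")
  groups <- contrast_groups(records)
  grid <- expand.grid(p_cutoff = p_grid, fc_cutoff = fc_grid,
                      KEEP.OUT.ATTRS = FALSE)
  counts <- matrix(0L, nrow(grid), length(groups),
                   dimnames = list(NULL, groups))
  for (i in seq_len(nrow(grid))) {
    cfg <- analysis_config(
      log2_cutoff = log2(grid$fc_cutoff[i]),
      neglog10p_cutoff = -log10(grid$p_cutoff[i]),
      alpha = config$alpha, rho_bounds = config$rho_bounds,
      group_labels = config$group_labels, channel_map = config$channel_map,
      r5_delta = config$r5_delta, fdr_correct = config$fdr_correct)
    lab <- alteration_labels(records, cfg)
    counts[i, ] <- colSums(lab != "unchanged")
  }
  structure(cbind(grid, as.data.frame(counts)),
            class = c("threshold_grid", "data.frame"))
}
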