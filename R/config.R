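#' Analysis configuration
#'
#' All thresholds of the pipeline live in one object: the volcano cutoffs on
#' the log2 ratio and on \eqn{-\log_{10}(p)}, the significance level, the
#' Spearman-rho strength boundaries, the ordered outcome-group labels and
#' their iTRAQ reporter channels, and the magnitude-similarity window used by
#' the shortlist's exclusion rule.
#'
#' Defaults encode the study conventions: \eqn{|\log_2(\mathrm{ratio})| >
#' 0.58} with \eqn{-\log_{10}(p) > 1.30} (a 1.5-fold change at p < 0.05,
#' both strict inequalities), rho categories at 0.20 / 0.40 / 0.70, groups
#' NAO, RVE, CD against the healthy-control channel 114.
#'
#' @param log2_cutoff positive log2-ratio cutoff (strict `>`).
#' @param neglog10p_cutoff positive cutoff on \eqn{-\log_{10}(p)} (strict `>`).
#' @param alpha significance level for enrichment and correlation flags.
#' @param rho_bounds three strictly ascending values in (0,1) separating
#'   none / weak / moderate / strong correlation.
#' @param group_labels ordered outcome-group labels.
#' @param channel_map named integer vector mapping group label to iTRAQ
#'   reporter ion; must cover `"HC"` and every entry of `group_labels`.
#' @param r5_delta maximum |difference of log2 ratios| still counted as a
#'   "similar magnitude" by the shortlist exclusion rule.
#' @param fdr_correct apply Benjamini-Hochberg adjustment to contrast
#'   p-values before alteration calling. Off by default; the study design
#'   uses raw per-contrast p-values, this switch is an extension.
#'
#' @return An object of class `analysis_config`.
#' @export
#' @examples
#' cfg <- analysis_config()
#' cfg$log2_cutoff
analysis_config <- function(log2_cutoff = 0.58,
                            neglog10p_cutoff = 1.30,
                            alpha = 0.05,
                            rho_bounds = c(0.20, 0.40, 0.70),
                            group_labels = c("NAO", "RVE", "CD"),
                            channel_map = c(HC = 114L, NAO = 115L,
                                            RVE = 116L, CD = 117L),
                            r5_delta = 0.30,
                            fdr_correct = FALSE) {
  if (!is.numeric(log2_cutoff) || length(log2_cutoff) != 1L || log2_cutoff <= 0)
    abort_parameter("log2_cutoff must be a single positive number")
  if (!is.numeric(neglog10p_cutoff) || length(neglog10p_cutoff) != 1L ||
      neglog10p_cutoff <= 0)
    abort_parameter("neglog10p_cutoff must be a single positive number")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    abort_parameter("alpha must lie strictly between 0 and 1")
  if (length(rho_bounds) != 3L || any(!is.finite(rho_bounds)) ||
      any(diff(rho_bounds) <= 0) || any(rho_bounds <= 0) || any(rho_bounds >= 1))
    abort_parameter("rho_bounds must be three strictly ascending values in (0,1)")
  if (length(group_labels) < 1L || anyDuplicated(group_labels))
    abort_parameter("group_labels must be distinct, non-empty labels")
  missing_ch <- setdiff(c("HC", group_labels), names(channel_map))
  if (length(missing_ch))
    abort_parameter("channel_map lacks entries for: %s",
                    paste(missing_ch, collapse = ", "))
  if (!is.numeric(r5_delta) || r5_delta < 0)
    abort_parameter("r5_delta must be non-negative")

  structure(list(
    log2_cutoff = log2_cutoff,
    neglog10p_cutoff = neglog10p_cutoff,
    alpha = alpha,
    rho_bounds = rho_bounds,
    group_labels = group_labels,
    channel_map = channel_map,
    r5_delta = r5_delta,
    fdr_correct = fdr_correct
  ), class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("iTRAQ analysis configuration\n")
  cat(sprintf("  alteration: |log2 ratio| > %.3g and -log10(p) > %.3g%s\n",
              x$log2_cutoff, x$neglog10p_cutoff,
              if (isTRUE(x$fdr_correct)) " (BH-adjusted p)" else ""))
  cat(sprintf("  alpha: %.3g\n", x$alpha))
  cat(sprintf("  rho strength bounds: %s\n",
              paste(x$rho_bounds, collapse = " / ")))
  cat(sprintf("  groups vs HC: %s\n", paste(x$group_labels, collapse = ", ")))
  chans <- paste(sprintf("%s=%d", names(x$channel_map), x$channel_map),
                 collapse = ", ")
  cat(sprintf("  channels: %s\n", chans))
  invisible(x)
}
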