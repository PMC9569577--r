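#' Spearman rank correlation with tie handling
#'
#' Computes rho as the Pearson correlation of mid-ranks (average ranks for
#' ties). The two-tailed p-value uses the t approximation with n - 2
#' degrees of freedom for n > 8 and full permutation enumeration of all n!
#' orderings for n <= 8, where the approximation is poor.
#'
#' A constant input vector leaves the correlation undefined: the result
#' carries `defined = FALSE` and `rho = NA` rather than a number.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list of class `spearman_test`: `rho`, `p`, `n`, `method`,
#'   `defined`.
#' @export
#' @examples
#' spearman_rho(1:10, (1:10)^2)$rho  # 1: monotone transform invariance
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort_parameter("x and y differ in length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3)
    return(structure(list(rho = NA_real_, p = NA_real_, n = n,
                          method = "none", defined = FALSE),
                     class = "spearman_test"))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(list(rho = NA_real_, p = NA_real_, n = n,
                          method = "none", defined = FALSE),
                     class = "spearman_test"))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n > 8) {
    # guard rho = +/-1, where the t statistic is infinite
    if (abs(rho) >= 1) {
      p <- .Machine$double.xmin
    } else {
      tt <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tt), df = n - 2)
    }
    method <- "t-approximation"
  } else {
    pm <- permutations(n)
    # rho under permutation is affine in sum(rx[perm] * ry): enumerate that
    mrx <- mean(rx); mry <- mean(ry)
    ssx <- sqrt(sum((rx - mrx)^2)); ssy <- sqrt(sum((ry - mry)^2))
    cross <- as.vector(matrix(rx[pm], nrow(pm)) %*% ry)
    rho_all <- (cross - n * mrx * mry) / (ssx * ssy)
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    method <- "exact-permutation"
  }
  structure(list(rho = rho, p = min(max(p, .Machine$double.xmin), 1), n = n,
                 method = method, defined = TRUE),
            class = "spearman_test")
}

# all permutations of 1..n as an n! x n matrix (n <= 8 in practice)
permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub))
  }
  out
}

#' @export
print.spearman_test <- function(x, ...) {
  if (!x$defined) {
    cat(sprintf("Spearman correlation undefined (n = %d)\n", x$n))
  } else {
    cat(sprintf("Spearman rho = %.3f, p = %.3g (n = %d, %s)\n",
                x$rho, x$p, x$n, x$method))
  }
  invisible(x)
}

#' Correlation-strength category
#'
#' Buckets |rho| into none / weak / moderate / strong using the configured
#' bounds (defaults 0.20 / 0.40 / 0.70). Boundaries are lower-inclusive for
#' weak and moderate; `strong` requires strictly exceeding the upper bound,
#' so rho = 0.70 is moderate. Sign is deliberately not part of the label
#' (a rho of -0.60 is "moderate" with negative sign reported separately).
#'
#' @param rho numeric vector of correlation coefficients.
#' @param config an [analysis_config()].
#' @return character vector over `{none, weak, moderate, strong}` (NA for
#'   undefined rho).
#' @export
categorize_rho <- function(rho, config = analysis_config()) {
  b <- config$rho_bounds
  a <- abs(rho)
  out <- rep(NA_character_, length(rho))
  out[a < b[1]] <- "none"
  out[a >= b[1] & a < b[2]] <- "weak"
  out[a >= b[2] & a <= b[3]] <- "moderate"
  out[a > b[3]] <- "strong"
  out
}

# subset selection shared by the profile functions
select_subset <- function(records, subset, group = NULL, partition = NULL,
                          config = analysis_config()) {
  if (subset == "all") return(records$accession)
  sets <- altered_sets(records, config)
  if (is.null(partition))
    partition <- venn_partition(sets$NAO, sets$RVE, sets$CD)
  switch(subset,
    altered_union = sets$union,
    laci_related = partition$classes$laci_related,
    outcome_dependent = partition$classes$outcome_dependent,
    group_specific = {
      if (is.null(group))
        abort_parameter("subset 'group_specific' needs a group label")
      partition$regions[[paste0(group, "_only")]]
    },
    abort_parameter("unknown subset selector: %s", subset))
}

#' Pairwise group correlation profile
#'
#' Spearman correlations of log2 ratios between every pair of outcome
#' groups, over a chosen protein subset: the complete proteome, the altered
#' union, a Venn taxonomy class, or one group's specific proteins.
#' Significance is flagged two-tailed at p < 0.01, the reporting convention
#' for correlation analyses here.
#'
#' @param records a `protein_table`.
#' @param subset one of `"all"`, `"altered_union"`, `"laci_related"`,
#'   `"outcome_dependent"`, `"group_specific"`.
#' @param group group label whose specific proteins to use when
#'   `subset = "group_specific"`.
#' @param partition optional precomputed [venn_partition()]; derived from
#'   `records` when missing.
#' @param config an [analysis_config()].
#' @param sig_level two-tailed significance level for the flag (0.01).
#' @return data.frame of class `correlation_profile`: one row per group
#'   pair with `n`, `rho`, `p`, `strength`, `sign`, `significant`.
#' @export
group_correlation_profile <- function(records, subset = "all", group = NULL,
                                      partition = NULL,
                                      config = analysis_config(),
                                      sig_level = 0.01) {
  acc <- select_subset(records, subset, group, partition, config)
  sel <- records[records$accession %in% acc, , drop = FALSE]
  groups <- contrast_groups(records)
  pairs <- utils::combn(groups, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    st <- spearman_rho(sel[[paste0("log2_", g1, "_HC")]],
                       sel[[paste0("log2_", g2, "_HC")]])
    data.frame(pair = paste(g1, g2, sep = "-"), n = st$n, rho = st$rho,
               p = st$p,
               strength = if (st$defined) categorize_rho(st$rho, config)
                          else NA_character_,
               sign = if (st$defined && !is.na(st$rho))
                 c("negative", "zero", "positive")[sign(st$rho) + 2]
                 else NA_character_,
               significant = isTRUE(st$p < sig_level),
               defined = st$defined, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("correlation_profile", "data.frame"))
}

#' Cross-fraction correlation between vesicle preparations
#'
#' Correlates one group's log2 ratios over the proteins quantified in both
#' a medium-vesicle and a small-vesicle table. The common set is matched on
#' isoform-stripped accessions (P63010-2 matches P63010), since the two
#' searches may report different isoform entries of the same gene.
#'
#' @param records_mev,records_sev two `protein_table`s.
#' @param group contrast label to correlate.
#' @param config an [analysis_config()].
#' @return list of class `cross_fraction_cor`: `n_common`, `rho`, `p`,
#'   `strength`, `defined`.
#' @export
cross_fraction_correlation <- function(records_mev, records_sev, group,
                                       config = analysis_config()) {
  base_a <- strip_isoform(records_mev$accession)
  base_b <- strip_isoform(records_sev$accession)
  common <- intersect(base_a, base_b)
  if (!length(common))
    return(structure(list(n_common = 0L, rho = NA_real_, p = NA_real_,
                          strength = NA_character_, defined = FALSE),
                     class = "cross_fraction_cor"))
  ia <- match(common, base_a); ib <- match(common, base_b)
  col <- paste0("log2_", group, "_HC")
  st <- spearman_rho(records_mev[[col]][ia], records_sev[[col]][ib])
  structure(list(n_common = length(common), rho = st$rho, p = st$p,
                 strength = if (st$defined) categorize_rho(st$rho, config)
                            else NA_character_,
                 defined = st$defined),
            class = "cross_fraction_cor")
}

#' Normality pre-check of log-transformed ratios
#'
#' One-sample Kolmogorov-Smirnov goodness-of-fit test of the log2 ratios
#' against a normal distribution with the sample mean and standard
#' deviation. Estimating the parameters from the same sample makes the
#' classical KS p-value conservative (the Lilliefors caveat); the check is
#' kept in this classical form as a screening step that motivates
#' rank-based correlation, not as a calibrated test.
#'
#' @param x numeric vector of log2 ratios (n >= 5).
#' @param alpha verdict level; `p < alpha` gives verdict "non-normal".
#' @return list of class `normality_check`: `statistic`, `p`, `verdict`,
#'   `n`.
#' @export
normality_check <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 5)
    return(structure(list(statistic = NA_real_, p = NA_real_,
                          verdict = "insufficient-data", n = length(x)),
                     class = "normality_check"))
  ks <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  structure(list(statistic = unname(ks$statistic), p = ks$p.value,
                 verdict = if (ks$p.value < alpha) "non-normal" else "normal",
                 n = length(x)),
            class = "normality_check")
}
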