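#' Parameter set defining a synthetic iTRAQ cohort
#'
#' Describes a 4-channel iTRAQ experiment with planted structure: a fixed
#' fraction of proteins carries a latent per-group log2 effect (zero for
#' the rest), effects are correlated across outcome groups, alterations are
#' predominantly decreases, peptide-level ratios scatter around the latent
#' effect, and annotation concepts are planted at chosen odds ratios in the
#' altered stratum. Defaults mirror the study scale: 573 proteins, 25%
#' altered, decrease shares of 74/89/78% in NAO/RVE/CD, a strong (0.85)
#' RVE-CD effect correlation and a moderate (0.60) NAO-adverse one.
#'
#' Latent effects for altered proteins are drawn from a correlated
#' trivariate normal whose per-group mean is shifted to
#' \eqn{-\sigma\,\Phi^{-1}(q_g)} so that the probability of a negative
#' effect equals the requested decreased share \eqn{q_g} while the
#' cross-group correlation is preserved (independent per-group sign flips
#' would destroy it). `effect_size_mean` sets \eqn{\sigma}, the log2 scale
#' of the planted effects.
#'
#' @param n_proteins number of quantified proteins.
#' @param altered_fraction fraction of proteins carrying a true effect.
#' @param decreased_share named per-group probabilities that a true effect
#'   is negative.
#' @param effect_corr_rve_cd latent effect correlation between the two
#'   adverse groups.
#' @param effect_corr_nao_adverse latent effect correlation between NAO
#'   and each adverse group.
#' @param peptides_per_protein list with `min` and `mean`: peptide counts
#'   are `min` plus a geometric draw with the matching mean.
#' @param peptide_noise_sd log2 standard deviation of peptide-level scatter
#'   around the latent effect.
#' @param effect_size_mean log2 scale of planted effects (see Details).
#' @param concept_plants list of planted annotation concepts, each a list
#'   with `name` (the term string generated), `aspect`,
#'   `annotated_fraction` (overall prevalence) and `odds_ratio` (odds of
#'   annotation in altered vs unaltered proteins).
#' @param seed integer RNG seed; a fixed seed reproduces the cohort
#'   bit-identically.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_proteins = 573,
                        altered_fraction = 0.25,
                        decreased_share = c(NAO = 0.74, RVE = 0.89,
                                            CD = 0.78),
                        effect_corr_rve_cd = 0.85,
                        effect_corr_nao_adverse = 0.60,
                        peptides_per_protein = list(min = 1, mean = 8),
                        peptide_noise_sd = 0.4,
                        effect_size_mean = 1.2,
                        concept_plants = default_concept_plants(),
                        seed = 1L) {
  if (n_proteins < 1) abort_parameter("n_proteins must be positive")
  if (altered_fraction <= 0 || altered_fraction >= 1)
    abort_parameter("altered_fraction must lie in (0,1)")
  if (any(decreased_share <= 0) || any(decreased_share >= 1))
    abort_parameter("decreased_share values must lie in (0,1)")
  if (length(decreased_share) != 3)
    abort_parameter("decreased_share needs one value per group")
  if (is.null(names(decreased_share)))
    names(decreased_share) <- c("NAO", "RVE", "CD")
  if (abs(effect_corr_rve_cd) >= 1 || abs(effect_corr_nao_adverse) >= 1)
    abort_parameter("effect correlations must lie in (-1,1)")
  if (peptide_noise_sd < 0) abort_parameter("peptide_noise_sd must be >= 0")
  if (effect_size_mean <= 0) abort_parameter("effect_size_mean must be > 0")
  if (peptides_per_protein$min < 1 ||
      peptides_per_protein$mean < peptides_per_protein$min)
    abort_parameter("peptides_per_protein needs min >= 1 and mean >= min")
  sigma <- effect_sigma(effect_corr_nao_adverse, effect_corr_rve_cd)
  if (min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    abort_parameter(
      "infeasible correlation pair: (nao_adverse=%.2f, rve_cd=%.2f) is not positive semidefinite",
      effect_corr_nao_adverse, effect_corr_rve_cd)
  structure(list(
    n_proteins = as.integer(n_proteins),
    altered_fraction = altered_fraction,
    decreased_share = decreased_share,
    effect_corr_rve_cd = effect_corr_rve_cd,
    effect_corr_nao_adverse = effect_corr_nao_adverse,
    peptides_per_protein = peptides_per_protein,
    peptide_noise_sd = peptide_noise_sd,
    effect_size_mean = effect_size_mean,
    concept_plants = concept_plants,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

# 3x3 latent-effect correlation matrix over (NAO, RVE, CD)
effect_sigma <- function(r_nao_adverse, r_rve_cd) {
  m <- diag(3)
  m[1, 2] <- m[2, 1] <- r_nao_adverse
  m[1, 3] <- m[3, 1] <- r_nao_adverse
  m[2, 3] <- m[3, 2] <- r_rve_cd
  m
}

#' @rdname cohort_spec
#' @export
default_concept_plants <- function() {
  list(
    list(name = "cellular response to hypoxia", aspect = "BP",
         annotated_fraction = 0.046, odds_ratio = 3.1),
    list(name = "blood coagulation", aspect = "BP",
         annotated_fraction = 0.13, odds_ratio = 3.3),
    list(name = "amyloid fibril formation", aspect = "BP",
         annotated_fraction = 0.026, odds_ratio = 1.0)
  )
}

# solve per-stratum annotation probabilities from overall prevalence f and
# odds ratio in the altered stratum
plant_probs <- function(f, odds_ratio, altered_fraction) {
  if (odds_ratio == 1) return(c(p_alt = f, p_un = f))
  g <- function(p0) {
    p1 <- odds_ratio * p0 / (1 - p0 + odds_ratio * p0)
    altered_fraction * p1 + (1 - altered_fraction) * p0 - f
  }
  p0 <- stats::uniroot(g, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  p1 <- odds_ratio * p0 / (1 - p0 + odds_ratio * p0)
  c(p_alt = p1, p_un = p0)
}

#' Roll peptide-level log2 ratios up to one protein contrast
#'
#' The protein log2 ratio is the arithmetic mean of its unique peptides'
#' log2 ratios. With at least two peptides the p-value is a two-sided
#' one-sample t test of the peptide ratios against zero (the transparent
#' stand-in for a search engine's proprietary ratio-significance
#' calculation); a single-peptide protein has no dispersion estimate and
#' receives the missing-p sentinel (`NA`). A zero-variance peptide vector
#' degenerates: p is 1 at mean zero and the smallest positive double
#' otherwise (the limit of the t test).
#'
#' @param peptide_log2_ratios numeric vector of finite peptide log2
#'   ratios, length >= 1.
#' @return list: `log2_ratio`, `p_value`, `n_peptides`.
#' @export
#' @examples
#' rollup_protein_contrast(c(0.9, 1.1, 1.0, 1.2))
rollup_protein_contrast <- function(peptide_log2_ratios) {
  x <- peptide_log2_ratios
  if (!length(x) || any(!is.finite(x)))
    abort_parameter("need at least one finite peptide log2 ratio")
  n <- length(x)
  m <- mean(x)
  if (n == 1)
    return(list(log2_ratio = m, p_value = NA_real_, n_peptides = 1L))
  s <- stats::sd(x)
  p <- if (s == 0) {
    if (m == 0) 1 else .Machine$double.xmin
  } else {
    tt <- m / (s / sqrt(n))
    2 * stats::pt(-abs(tt), df = n - 1)
  }
  list(log2_ratio = m, p_value = p, n_peptides = as.integer(n))
}

# vectorized rollup across proteins: x peptide ratios, idx protein index
rollup_by_protein <- function(x, idx, n_proteins) {
  n <- tabulate(idx, n_proteins)
  sums <- rowsum(x, idx, reorder = TRUE)[, 1]
  m <- sums / n
  ss <- rowsum((x - m[idx])^2, idx, reorder = TRUE)[, 1]
  s <- sqrt(ss / pmax(n - 1, 1))
  p <- rep(NA_real_, n_proteins)
  multi <- n >= 2
  zerovar <- multi & s == 0
  p[zerovar & m == 0] <- 1
  p[zerovar & m != 0] <- .Machine$double.xmin
  ok <- multi & s > 0
  tt <- m[ok] / (s[ok] / sqrt(n[ok]))
  p[ok] <- 2 * stats::pt(-abs(tt), df = n[ok] - 1)
  list(log2_ratio = m, p_value = p, n_peptides = n)
}

#' Simulate a synthetic iTRAQ cohort
#'
#' Generates a `protein_table` (via peptide-level ratios rolled up with
#' [rollup_protein_contrast()] semantics), an `annotation_map` with the
#' planted concepts, and a truth table recording each protein's latent
#' status for leak-proof recovery testing. The truth table is shipped
#' alongside the data and is never consumed by any analysis function.
#'
#' @param spec a [cohort_spec()].
#' @return list of class `synthetic_cohort`: `records`, `annotations`,
#'   `truth`, `spec`.
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_spec(n_proteins = 50, seed = 7))
#' nrow(coh$records)
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_proteins
  groups <- c("NAO", "RVE", "CD")

  accession <- sprintf("SYN%05d", seq_len(n))
  gene <- sprintf("G%05d", seq_len(n))

  n_alt <- round(n * spec$altered_fraction)
  altered <- rep(FALSE, n)
  altered[sample.int(n, n_alt)] <- TRUE

  sig <- effect_sigma(spec$effect_corr_nao_adverse, spec$effect_corr_rve_cd)
  effects <- matrix(0, n, 3, dimnames = list(NULL, groups))
  if (n_alt > 0) {
    z <- matrix(stats::rnorm(n_alt * 3), n_alt, 3) %*% chol(sig)
    mu <- -spec$effect_size_mean *
      stats::qnorm(spec$decreased_share[groups])
    effects[altered, ] <- sweep(spec$effect_size_mean * z, 2, mu, `+`)
  }

  pp <- spec$peptides_per_protein
  extra_mean <- pp$mean - pp$min
  n_pep <- pp$min + if (extra_mean > 0)
    stats::rgeom(n, prob = 1 / (extra_mean + 1)) else 0L
  idx <- rep(seq_len(n), n_pep)

  df <- data.frame(accession = accession, gene = gene,
                   protein_score = round(exp(stats::rnorm(n, 3, 1)), 1),
                   coverage_pct = round(stats::runif(n, 1, 90), 1),
                   peptides_95 = n_pep, stringsAsFactors = FALSE)
  for (g in groups) {
    pep <- effects[idx, g] +
      stats::rnorm(length(idx), 0, spec$peptide_noise_sd)
    r <- rollup_by_protein(pep, idx, n)
    df[[paste0("log2_", g, "_HC")]] <- r$log2_ratio
    df[[paste0("p_", g, "_HC")]] <- r$p_value
  }
  records <- protein_table(df, groups = groups)

  ann_rows <- list(data.frame(accession = accession, aspect = "MF",
                              term = "protein binding",
                              stringsAsFactors = FALSE))
  planted <- matrix(FALSE, n, length(spec$concept_plants))
  for (k in seq_along(spec$concept_plants)) {
    pl <- spec$concept_plants[[k]]
    pr <- plant_probs(pl$annotated_fraction, pl$odds_ratio,
                      spec$altered_fraction)
    prob <- ifelse(altered, pr["p_alt"], pr["p_un"])
    hit <- stats::runif(n) < prob
    planted[, k] <- hit
    if (any(hit))
      ann_rows[[length(ann_rows) + 1L]] <-
        data.frame(accession = accession[hit],
                   aspect = pl$aspect %||% "BP", term = pl$name,
                   stringsAsFactors = FALSE)
  }
  annotations <- annotation_map(do.call(rbind, ann_rows))

  truth <- data.frame(accession = accession, altered = altered,
                      e_NAO = effects[, "NAO"], e_RVE = effects[, "RVE"],
                      e_CD = effects[, "CD"], n_peptides = n_pep,
                      stringsAsFactors = FALSE)
  for (k in seq_along(spec$concept_plants))
    truth[[paste0("plant_", k)]] <- planted[, k]

  structure(list(records = records, annotations = annotations,
                 truth = truth, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic iTRAQ cohort: %d proteins (%d truly altered), seed %d\n",
    nrow(x$records), sum(x$truth$altered), x$spec$seed))
  invisible(x)
}
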