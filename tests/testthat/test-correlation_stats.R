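test_that("rho hits the exact endpoints and stays within [-1, 1]", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5, 3.5, 8, 9.7)
  expect_equal(spearman_rho(x, x)$rho, 1)
  expect_equal(spearman_rho(x, -x)$rho, -1)
  # invariant under strictly monotone transforms of either vector
  y <- rnorm(10)
  set.seed(31); x2 <- rnorm(10)
  expect_equal(spearman_rho(exp(x2), y)$rho, spearman_rho(x2, y)$rho)
  expect_equal(spearman_rho(x2, y^3 + 5 * y)$rho,
               spearman_rho(x2, sign(y) * abs(y))$rho)
  # symmetry
  expect_equal(spearman_rho(x2, y)$rho, spearman_rho(y, x2)$rho)
  # a constant vector leaves the correlation undefined
  expect_false(spearman_rho(rep(1, 6), 1:6)$defined)
  expect_false(spearman_rho(1:2, 2:1)$defined)
})

test_that("tied 6-point fixture matches mid-rank and enumeration oracles", {
  x <- c(1, 2, 2, 3, 4, 4)
  y <- c(2.0, 1.0, 3.5, 3.5, 6.0, 5.0)
  st <- spearman_rho(x, y)
  # mid-rank Pearson oracle, computed directly
  rho_hand <- cor(rank(x, ties.method = "average"),
                  rank(y, ties.method = "average"))
  expect_equal(st$rho, rho_hand)
  expect_equal(st$rho, cor(x, y, method = "spearman"))
  expect_equal(st$method, "exact-permutation")
  # full 720-permutation enumeration with an independent generator
  pm <- perms_by_insertion(6)
  rx <- rank(x); ry <- rank(y)
  rho_all <- apply(pm, 1, function(p) cor(rx, ry[p]))
  p_hand <- mean(abs(rho_all) >= abs(rho_hand) - 1e-12)
  expect_equal(st$p, p_hand)
})

test_that("large-n p-values use the t approximation", {
  set.seed(5)
  x <- rnorm(60); y <- 0.5 * x + rnorm(60)
  st <- spearman_rho(x, y)
  expect_equal(st$method, "t-approximation")
  r <- st$rho
  expect_equal(st$p, 2 * pt(-abs(r * sqrt(58 / (1 - r^2))), df = 58))
  # sanity against the standard implementation (same approximation family)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(st$rho, unname(ct$estimate))
})

test_that("strength categories honor the documented boundary handling", {
  cfg <- analysis_config()
  expect_equal(categorize_rho(c(0.86, 0.26, 0.10), cfg),
               c("strong", "weak", "none"))
  # knots: lower-inclusive weak/moderate; 0.70 exactly is moderate
  expect_equal(categorize_rho(c(0.20, 0.40, 0.70, 0.701), cfg),
               c("weak", "moderate", "moderate", "strong"))
  # sign is reported separately from strength
  expect_equal(categorize_rho(-0.60, cfg), "moderate")
})

test_that("profiles recover planted correlation and ignore record order", {
  spec <- cohort_spec(n_proteins = 1200, effect_size_mean = 2.5,
                      peptides_per_protein = list(min = 3, mean = 8),
                      seed = 21)
  coh <- simulate_cohort(spec)
  prof <- group_correlation_profile(coh$records, "altered_union")
  rc <- prof[prof$pair == "RVE-CD", ]
  expect_lt(abs(rc$rho - 0.85), 0.10)
  expect_equal(rc$strength, "strong")

  shuf <- protein_table(as.data.frame(coh$records)[
    sample(nrow(coh$records)), ])
  prof2 <- group_correlation_profile(shuf, "all")
  prof1 <- group_correlation_profile(coh$records, "all")
  expect_equal(prof1$rho, prof2$rho)

  # undefined-correlation guard propagates on tiny subsets
  two <- make_records(list(
    list(nao = c(1, 0.01), rve = c(1, 0.01), cd = c(1, 0.01)),
    list(nao = c(-1, 0.01), rve = c(-1, 0.01), cd = c(-1, 0.01))))
  p2 <- group_correlation_profile(two, "altered_union")
  expect_true(all(!p2$defined))
})

test_that("cross-fraction correlation matches isoform-stripped accessions", {
  mev <- random_records(40, seed = 2)
  # identical ratios -> rho 1 in every group
  sev <- mev
  for (g in c("NAO", "RVE", "CD")) {
    r <- cross_fraction_correlation(mev, sev, g)
    expect_equal(r$rho, 1)
    expect_equal(r$n_common, 40)
  }
  # disjoint accessions -> undefined signal
  sev2 <- as.data.frame(mev)
  sev2$accession <- paste0("ZZ", sev2$accession)
  r0 <- cross_fraction_correlation(mev, protein_table(sev2), "NAO")
  expect_equal(r0$n_common, 0)
  expect_false(r0$defined)
  # isoform suffixes are stripped before matching
  sev3 <- as.data.frame(mev)[1:10, ]
  sev3$accession <- paste0(sev3$accession, "-2")
  r3 <- cross_fraction_correlation(mev, protein_table(sev3), "NAO")
  expect_equal(r3$n_common, 10)

  ov <- cross_fraction_overlap(mev, protein_table(sev3))
  expect_equal(ov$n_common, 10)
  expect_lte(ov$n_common, min(ov$n_a, ov$n_b))
  ov_sym <- cross_fraction_overlap(protein_table(sev3), mev)
  expect_equal(ov_sym$n_common, ov$n_common)
})

test_that("independent fractions stay under the null correlation bound", {
  n <- 83
  below <- logical(100)
  bound <- qnorm(0.975) / sqrt(n - 1)
  for (i in 1:100) {
    mev <- random_records(n, seed = 1000 + i)
    sev <- as.data.frame(random_records(n, seed = 2000 + i))
    sev$accession <- mev$accession
    r <- cross_fraction_correlation(mev, protein_table(sev), "NAO")
    below[i] <- abs(r$rho) < bound
  }
  expect_gte(mean(below), 0.90)
})

test_that("normality check flags heavy tails and guards tiny samples", {
  expect_equal(normality_check(rnorm(3))$verdict, "insufficient-data")
  verdicts <- vapply(1:100, function(i) {
    set.seed(300 + i)
    normality_check(rnorm(1000))$verdict
  }, character(1))
  expect_gte(mean(verdicts == "normal"), 0.95)
  heavy <- vapply(1:20, function(i) {
    set.seed(400 + i)
    x <- c(rnorm(900), rnorm(100, 0, 8))
    normality_check(x)$verdict
  }, character(1))
  expect_gte(mean(heavy == "non-normal"), 0.95)
})
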