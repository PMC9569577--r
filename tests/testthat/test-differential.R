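test_that("alteration calling applies both criteria with strict bounds", {
  cfg <- analysis_config()
  # printed examples: SLC4A1 NAO 1.05 significant; SLC2A1 RVE -2.75
  expect_equal(classify_alteration(1.05, 0.01, config = cfg), "increased")
  expect_equal(classify_alteration(-2.75, 0.001, config = cfg), "decreased")
  # boundary is strict: |log2| = 0.58 exactly stays unchanged (FLII, NAO)
  expect_equal(classify_alteration(-0.58, 0.01, config = cfg), "unchanged")
  expect_equal(classify_alteration(0.58, 0.001, config = cfg), "unchanged")
  # large fold change with weak p fails the dual criterion
  expect_equal(classify_alteration(2.0, 0.2, config = cfg), "unchanged")
  # the printed cutoff is 1.30 on the -log10 scale, taken literally:
  # p = 0.05 (-log10 = 1.30103) passes, p = 10^-1.3 sits on the boundary
  expect_equal(classify_alteration(2.0, 0.05, config = cfg), "increased")
  expect_equal(classify_alteration(2.0, 10^-1.3, config = cfg), "unchanged")
  expect_equal(classify_alteration(2.0, 0.051, config = cfg), "unchanged")
  # missing p without a flag can only be unchanged; a flag substitutes
  expect_equal(classify_alteration(2.0, NA, config = cfg), "unchanged")
  expect_equal(classify_alteration(2.0, NA, sig = TRUE, config = cfg),
               "increased")
})

test_that("per-group sets match a hand classification on a small fixture", {
  recs <- make_records(list(
    list(accession = "up_all",  nao = c(1.0, 0.01), rve = c(1.2, 0.01),
         cd = c(1.1, 0.01)),
    list(accession = "dn_rve",  nao = c(-0.2, 0.5), rve = c(-2.0, 0.001),
         cd = c(-0.3, 0.4)),
    list(accession = "ns_big",  nao = c(2.5, 0.2),  rve = c(2.5, 0.9),
         cd = c(2.5, 0.06)),
    list(accession = "edge",    nao = c(0.58, 0.01), rve = c(-0.58, 0.01),
         cd = c(0.59, 0.049)),
    list(accession = "null",    nao = c(0.05, 0.9), rve = c(-0.1, 0.8),
         cd = c(0.0, 1.0))))
  sets <- altered_sets(recs)
  expect_setequal(sets$NAO, "up_all")
  expect_setequal(sets$RVE, c("up_all", "dn_rve"))
  expect_setequal(sets$CD, c("up_all", "edge"))
  expect_setequal(sets$union, c("up_all", "dn_rve", "edge"))

  # labels partition the record set for every group
  lab <- laciMEV:::alteration_labels(recs)
  for (g in colnames(lab))
    expect_equal(sum(lab[, g] %in% c("increased", "decreased", "unchanged")),
                 nrow(recs))

  # membership is invariant under record order
  shuf <- protein_table(as.data.frame(recs)[c(3, 1, 5, 2, 4), ])
  sets2 <- altered_sets(shuf)
  expect_setequal(sets2$union, sets$union)
})

test_that("direction summaries report the printed rounding convention", {
  # 109 decreased of 122 altered -> 89%; 87 of 112 -> 78%
  mk <- function(n_dn, n_up) {
    rows <- c(replicate(n_dn, list(nao = c(-1, 0.01), rve = c(0, 1),
                                   cd = c(0, 1)), simplify = FALSE),
              replicate(n_up, list(nao = c(1, 0.01), rve = c(0, 1),
                                   cd = c(0, 1)), simplify = FALSE))
    make_records(rows)
  }
  expect_equal(direction_summary(mk(109, 13))$pct_decreased[1], 89)
  expect_equal(direction_summary(mk(87, 25))$pct_decreased[1], 78)
  expect_equal(direction_summary(mk(0, 5))$pct_decreased[1], 0)
  # raw counts retained alongside the rounded percentage
  ds <- direction_summary(mk(52, 17))
  expect_equal(ds$n_decreased[1], 52)
  expect_equal(ds$n_altered[1], 69)
  expect_equal(ds$pct_decreased[1], 75)  # exact arithmetic 75.4 -> 75
})

test_that("threshold grid matches brute-force refiltering and is monotone", {
  recs <- random_records(300, seed = 42)
  p_grid <- c(0.05, 0.025, 0.01, 0.005)
  fc_grid <- c(1.5, 2, 2.5)
  grid <- threshold_sensitivity(recs, p_grid, fc_grid)

  # brute-force oracle: direct strict filtering per cell
  for (i in seq_len(nrow(grid))) {
    for (g in c("NAO", "RVE", "CD")) {
      l2 <- recs[[paste0("log2_", g, "_HC")]]
      p <- recs[[paste0("p_", g, "_HC")]]
      want <- sum(abs(l2) > log2(grid$fc_cutoff[i]) & p < grid$p_cutoff[i])
      expect_equal(grid[[g]][i], want)
    }
  }

  # counts monotone non-increasing along both threshold axes
  for (g in c("NAO", "RVE", "CD")) {
    for (fc in fc_grid) {
      sub <- grid[grid$fc_cutoff == fc, ]
      expect_true(all(diff(sub[[g]][order(-sub$p_cutoff)]) <= 0))
    }
    for (p in p_grid) {
      sub <- grid[grid$p_cutoff == p, ]
      expect_true(all(diff(sub[[g]][order(sub$fc_cutoff)]) <= 0))
    }
  }

  expect_error(threshold_sensitivity(recs, 0.05, c(-1, 2)),
               class = "laci_parameter_error")
})

test_that("a fold change of 1.5 is the stated log2 cutoff equivalence", {
  recs <- random_records(200, seed = 9)
  grid <- threshold_sensitivity(recs, 0.05, 1.5)
  cfg585 <- analysis_config(log2_cutoff = log2(1.5))
  sets <- altered_sets(recs, cfg585)
  for (g in c("NAO", "RVE", "CD")) {
    lab <- laciMEV:::alteration_labels(recs, cfg585)
    expect_equal(grid[[g]][1], sum(lab[, g] != "unchanged"))
  }
  expect_equal(log2(1.5), 0.585, tolerance = 5e-4)
})
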