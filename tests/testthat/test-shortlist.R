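test_that("opposite-regulation candidates are retained via the reversal rule", {
  recs <- make_records(list(
    # FCGBP-like: significant decrease in NAO, significant increases in
    # both adverse groups
    list(accession = "FCGBP", gene = "FCGBP",
         nao = c(-1.37, 0.01), rve = c(1.37, 0.01), cd = c(2.48, 0.01)),
    # SLC4A1-like: up in NAO, down in both adverse groups
    list(accession = "SLC4A1", gene = "SLC4A1",
         nao = c(1.05, 0.01), rve = c(-3.16, 0.001), cd = c(-1.05, 0.01))))
  sl <- apply_shortlist(recs)
  expect_true(all(sl$retained))
  expect_true(all(sl$R4))
  expect_false(any(sl$R1 | sl$R5))
  # every fired rule names its evidence
  expect_true(all(nzchar(sl$evidence[sl$fired_rules != ""])))
})

test_that("uniform pan-group and similar-magnitude proteins are excluded", {
  recs <- make_records(list(
    # altered in all three groups, all decreased -> R1 disqualifies
    list(accession = "UNIF", nao = c(-1.2, 0.01), rve = c(-1.5, 0.01),
         cd = c(-1.1, 0.01)),
    # AHNAK-class: same direction and similar magnitude NAO vs RVE,
    # irrespective of significance -> R5 disqualifies
    list(accession = "SIMI", nao = c(1.0, 0.01), rve = c(1.0, 0.2),
         cd = c(0.1, 0.9)),
    # similar but with a gap above delta: not an R5 case
    list(accession = "GAP", nao = c(1.0, 0.01), rve = c(1.8, 0.2),
         cd = c(0.1, 0.9))))
  sl <- apply_shortlist(recs)
  expect_false(sl$retained[sl$accession == "UNIF"])
  expect_true(sl$R1[sl$accession == "UNIF"])
  expect_false(sl$retained[sl$accession == "SIMI"])
  expect_true(sl$R5[sl$accession == "SIMI"])
  expect_false(sl$R5[sl$accession == "GAP"])
  expect_true(sl$retained[sl$accession == "GAP"])  # NAO-only: R2
})

test_that("only altered-union members are evaluated and R3 is monotone", {
  recs <- make_records(list(
    list(accession = "ALT", nao = c(0, 1), rve = c(-2, 0.01),
         cd = c(0.2, 0.5)),
    list(accession = "NULL1", nao = c(0.1, 0.9), rve = c(0.2, 0.8),
         cd = c(0, 1))))
  ann <- annotation_map(data.frame(accession = "ALT", aspect = "BP",
                                   term = "cellular response to hypoxia"))
  sl <- apply_shortlist(recs, annotations = ann)
  expect_equal(sl$accession, "ALT")  # shortlist subset of altered union
  expect_true(sl$R3)
  # removing the annotation can remove R3 firing but never add retention
  sl0 <- apply_shortlist(recs, annotations = NULL)
  expect_false(sl0$R3)
  expect_true(all(sl0$retained <= sl$retained |
                    !(sl0$fired_rules == sl$fired_rules)))
  expect_lte(sum(sl0$retained), sum(sl$retained))
})

test_that("decisions replay through independent predicate evaluation", {
  spec <- cohort_spec(n_proteins = 400, seed = 13)
  coh <- simulate_cohort(spec)
  cfg <- analysis_config()
  sl <- apply_shortlist(coh$records, annotations = coh$annotations,
                        config = cfg)

  # independent oracle: recompute each rule from the raw table
  rec <- as.data.frame(coh$records)
  rec <- rec[match(sl$accession, rec$accession), ]
  lab <- function(l2, p) ifelse(!is.na(p) & p < 0.05 & l2 > 0.58,
                                "up",
                         ifelse(!is.na(p) & p < 0.05 & l2 < -0.58,
                                "down", "none"))
  ln <- lab(rec$log2_NAO_HC, rec$p_NAO_HC)
  lr <- lab(rec$log2_RVE_HC, rec$p_RVE_HC)
  lc <- lab(rec$log2_CD_HC, rec$p_CD_HC)
  r1 <- ln != "none" & ln == lr & lr == lc
  r2 <- (ln != "none" & lr == "none" & lc == "none") |
    (ln == "none" & (lr != "none" | lc != "none"))
  concepts <- builtin_concepts()[c("ogd_hypoxia", "oxidative_stress",
                                   "vesicle", "vasculature")]
  r3 <- Reduce(`|`, lapply(concepts, function(cn)
    match_concept(rec$accession, coh$annotations, cn)))
  r4 <- ln != "none" & ((lr != "none" & lr != ln) |
                          (lc != "none" & lc != ln))
  near <- function(a, b) sign(a) * sign(b) > 0 & abs(a - b) <= 0.30
  r5 <- near(rec$log2_NAO_HC, rec$log2_RVE_HC) |
    near(rec$log2_NAO_HC, rec$log2_CD_HC)
  retained <- (r2 | r3 | r4) & !r1 & !r5

  expect_equal(sl$R1, unname(r1))
  expect_equal(sl$R2, unname(r2))
  expect_equal(sl$R3, unname(r3))
  expect_equal(sl$R4, unname(r4))
  expect_equal(sl$R5, unname(r5))
  expect_equal(sl$retained, unname(retained))
  # retained implies a favoring rule and no disqualifier
  expect_true(all(!sl$retained | ((sl$R2 | sl$R3 | sl$R4) &
                                    !sl$R1 & !sl$R5)))
})
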