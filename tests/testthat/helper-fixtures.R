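# Builders for small in-code fixtures shared across test files.

table1_path <- function() {
  system.file("extdata", "shortlist_table1.tsv", package = "laciMEV")
}

# hand-rolled protein table: one row per entry of `rows`, each a list with
# gene, per-group log2 and p (NA allowed)
make_records <- function(rows) {
  df <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.frame(accession = r$accession %||% sprintf("ACC%03d", i),
               gene = r$gene %||% sprintf("GENE%03d", i),
               protein_score = 10, coverage_pct = 20, peptides_95 = 3,
               log2_NAO_HC = r$nao[1], p_NAO_HC = r$nao[2],
               log2_RVE_HC = r$rve[1], p_RVE_HC = r$rve[2],
               log2_CD_HC = r$cd[1], p_CD_HC = r$cd[2],
               stringsAsFactors = FALSE)
  }))
  protein_table(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random valid protein table for property-style tests
random_records <- function(n, seed) {
  set.seed(seed)
  df <- data.frame(accession = sprintf("R%04d", seq_len(n)),
                   gene = sprintf("RG%04d", seq_len(n)),
                   protein_score = runif(n, 1, 50),
                   coverage_pct = runif(n, 1, 90),
                   peptides_95 = sample(2:20, n, replace = TRUE),
                   stringsAsFactors = FALSE)
  for (g in c("NAO", "RVE", "CD")) {
    df[[paste0("log2_", g, "_HC")]] <- rnorm(n, 0, 1.2)
    df[[paste0("p_", g, "_HC")]] <- runif(n)
  }
  protein_table(df)
}

# independent permutation generator (insertion method) for the Spearman
# enumeration oracle; deliberately a different algorithm from the package's
perms_by_insertion <- function(n) {
  out <- list(1L)
  for (k in 2:n) {
    nxt <- list()
    for (p in out)
      for (pos in 0:(k - 1))
        nxt[[length(nxt) + 1L]] <- append(p, k, after = pos)
    out <- nxt
  }
  do.call(rbind, out)
}
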