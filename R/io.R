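#' Read a protein quantitation table
#'
#' Parses the delimited table produced downstream of database searching: one
#' row per quantified protein with identification metadata (accession, gene
#' symbol, search-engine protein score, percent sequence coverage, number of
#' unique peptides at >= 95% confidence) and, per outcome group G, a
#' group-vs-control ratio column and its p-value column `p_<G>_HC`.
#'
#' The ratio dialect is mandatory and never sniffed: with `dialect = "log2"`
#' ratio columns are named `log2_<G>_HC` and taken as is (the convention of
#' published shortlist tables); with `dialect = "linear"` they are named
#' `ratio_<G>_HC`, hold linear reporter-ion ratios (the search-engine export
#' convention) and are log2-transformed on read. Guessing between the two
#' would silently double or halve every effect size.
#'
#' p-values may be absent for a contrast (stored as `NA`); a logical
#' `sig_<G>_HC` column may carry a plain significance flag instead, the form
#' in which published tables mark significance in bold. Records whose only
#' evidence is a missing p and no flag are classifiable only as unchanged.
#'
#' @param path file to read.
#' @param dialect `"log2"` or `"linear"`; see Details.
#' @param sep field delimiter, tab by default; pass `","` for CSV.
#' @return A `protein_table`: a data.frame with one row per protein,
#'   attribute `groups` listing the contrast labels found.
#' @export
read_protein_table <- function(path, dialect = c("log2", "linear"),
                               sep = "\t") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort_format("no such file: %s", path)
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE)
  mandatory <- c("accession", "gene", "protein_score", "coverage_pct",
                 "peptides_95")
  miss <- setdiff(mandatory, names(df))
  if (length(miss))
    abort_format("missing mandatory column(s): %s", paste(miss, collapse = ", "))

  prefix <- if (dialect == "log2") "log2_" else "ratio_"
  ratio_cols <- grep(paste0("^", prefix, ".+_HC$"), names(df), value = TRUE)
  if (!length(ratio_cols))
    abort_format("missing mandatory column: no %s<group>_HC ratio columns found",
                 prefix)
  groups <- sub("_HC$", "", sub(paste0("^", prefix), "", ratio_cols))

  dup <- unique(df$accession[duplicated(df$accession)])
  if (length(dup))
    abort_format("duplicate accession(s): %s", paste(dup, collapse = ", "))

  for (g in groups) {
    rc <- paste0(prefix, g, "_HC")
    v <- df[[rc]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & nzchar(trimws(v)))
      if (length(bad))
        abort_format("non-numeric ratio in column %s at line %d ('%s')",
                     rc, bad[1] + 1L, v[bad[1]])
      v <- num
    }
    if (dialect == "linear") {
      if (any(v <= 0, na.rm = TRUE))
        abort_format("linear ratio column %s holds non-positive values", rc)
      df[[paste0("log2_", g, "_HC")]] <- log2(v)
      df[[rc]] <- NULL
    } else {
      df[[rc]] <- v
    }
    pc <- paste0("p_", g, "_HC")
    if (!pc %in% names(df)) df[[pc]] <- NA_real_
    p <- suppressWarnings(as.numeric(df[[pc]]))
    if (any(!is.na(p) & (p <= 0 | p > 1)))
      abort_format("p-values in column %s outside (0, 1]", pc)
    df[[pc]] <- p
    sc <- paste0("sig_", g, "_HC")
    if (sc %in% names(df)) df[[sc]] <- as.logical(df[[sc]])
  }
  if (any(df$peptides_95 < 1))
    abort_format("quantified records must have peptides_95 >= 1")
  protein_table(df, groups = groups)
}

#' Construct a protein table from a data.frame
#'
#' Validates invariants (unique accessions, identical contrast set on every
#' record, at least one confident peptide) and tags the object.
#'
#' @param df data.frame holding the columns described in
#'   [read_protein_table()], ratios already on the log2 scale.
#' @param groups contrast labels; inferred from `log2_<G>_HC` columns when
#'   omitted.
#' @return A `protein_table`.
#' @export
protein_table <- function(df, groups = NULL) {
  if (is.null(groups)) {
    rc <- grep("^log2_.+_HC$", names(df), value = TRUE)
    groups <- sub("_HC$", "", sub("^log2_", "", rc))
  }
  if (!length(groups)) abort_format("no contrast columns present")
  for (g in groups) {
    for (col in paste0(c("log2_", "p_"), g, "_HC"))
      if (!col %in% names(df)) abort_format("missing column: %s", col)
    if (any(!is.finite(df[[paste0("log2_", g, "_HC")]])))
      abort_format("non-finite log2 ratio in contrast %s", g)
  }
  if (anyDuplicated(df$accession))
    abort_format("duplicate accession(s): %s",
                 paste(unique(df$accession[duplicated(df$accession)]),
                       collapse = ", "))
  structure(df, groups = groups,
            class = c("protein_table", "data.frame"))
}

#' List the contrast labels of a protein table
#' @param x a `protein_table`.
#' @export
contrast_groups <- function(x) attr(x, "groups")

#' Write a protein table
#'
#' Inverse of [read_protein_table()]: `dialect = "linear"` back-transforms
#' log2 ratios to linear before writing.
#'
#' @inheritParams read_protein_table
#' @param x a `protein_table`.
#' @export
write_protein_table <- function(x, path, dialect = c("log2", "linear"),
                                sep = "\t") {
  dialect <- match.arg(dialect)
  df <- as.data.frame(x)
  if (dialect == "linear") {
    for (g in contrast_groups(x)) {
      lc <- paste0("log2_", g, "_HC")
      df[[paste0("ratio_", g, "_HC")]] <- 2 ^ df[[lc]]
      df[[lc]] <- NULL
    }
  }
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GO annotation map
#'
#' Flat three-column table `accession`, `aspect`, `term` (one term per row;
#' an accession may repeat), aspects restricted to BP / CC / MF.
#'
#' @param path TSV file.
#' @return An `annotation_map` data.frame.
#' @export
read_annotation_map <- function(path, sep = "\t") {
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  miss <- setdiff(c("accession", "aspect", "term"), names(df))
  if (length(miss))
    abort_format("annotation map lacks column(s): %s",
                 paste(miss, collapse = ", "))
  annotation_map(df)
}

#' @rdname read_annotation_map
#' @param df data.frame with columns accession / aspect / term.
#' @export
annotation_map <- function(df) {
  bad <- setdiff(unique(df$aspect), c("BP", "CC", "MF"))
  if (length(bad))
    abort_format("annotation aspect(s) outside BP/CC/MF: %s",
                 paste(bad, collapse = ", "))
  if (any(!nzchar(df$term)))
    abort_format("annotation map holds empty term strings")
  structure(df, class = c("annotation_map", "data.frame"))
}

#' @rdname read_annotation_map
#' @param x an `annotation_map`.
#' @export
write_annotation_map <- function(x, path, sep = "\t") {
  utils::write.table(as.data.frame(x), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a MISEV marker catalog
#'
#' Two-column-plus table `gene`, `category` (one of 1a, 1b, 2, 3, 4, 5) and
#' an optional free-text `note` (e.g. the tissue of a category-1b marker).
#'
#' @param path TSV file.
#' @export
read_marker_catalog <- function(path, sep = "\t") {
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  miss <- setdiff(c("gene", "category"), names(df))
  if (length(miss))
    abort_format("marker catalog lacks column(s): %s",
                 paste(miss, collapse = ", "))
  marker_catalog(df)
}

#' @rdname read_marker_catalog
#' @param df data.frame with columns gene / category / (note).
#' @export
marker_catalog <- function(df) {
  allowed <- c("1a", "1b", "2", "3", "4", "5")
  bad <- setdiff(unique(as.character(df$category)), allowed)
  if (length(bad))
    abort_format("marker category label(s) outside {%s}: %s",
                 paste(allowed, collapse = ", "), paste(bad, collapse = ", "))
  if (anyDuplicated(df$gene))
    abort_format("marker catalog assigns multiple categories to: %s",
                 paste(unique(df$gene[duplicated(df$gene)]), collapse = ", "))
  df$category <- as.character(df$category)
  if (!"note" %in% names(df)) df$note <- ""
  structure(df, class = c("marker_catalog", "data.frame"))
}
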