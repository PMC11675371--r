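# Readers for the variant-table dialects and writers for curves/regions.
#
# Dialects:
#   generic_csv     — columns: gene, hgvs_p, significance, het, hom, hemi, sex
#                     (only gene + hgvs_p required)
#   clinvar_summary — variant_summary-style TSV: Name, GeneSymbol,
#                     ClinicalSignificance; the p.(...) term is taken from
#                     Name
#   gnomad_export   — gnomAD CSV export: "Protein Consequence" plus
#                     "Allele Count" / "Homozygote Count" /
#                     "Hemizygote Count" where present
# Unknown columns are ignored: database exports vary by release.

.required_columns <- list(
  generic_csv = c("hgvs_p"),
  clinvar_summary = c("Name"),
  gnomad_export = c("Protein Consequence")
)

#' Read a variant table from a database export
#'
#' Parses, classifies and deduplicates protein-level variants from one of
#' the supported dialects.  Rows whose HGVS term cannot be parsed are
#' skipped with a summary warning; by default no clinical-significance
#' filter is applied (all records feed the clinical curve), with an optional
#' allow-list override.
#'
#' @param path file path (CSV or TSV; the delimiter is sniffed from the
#'   header line).
#' @param dialect `"generic_csv"`, `"clinvar_summary"` or `"gnomad_export"`.
#' @param gene gene symbol; when the file carries a gene column, records for
#'   other genes are dropped.
#' @param source `"clinical"` or `"population"`.
#' @param significance_allow optional character vector: keep only records
#'   whose significance matches (substring, case-insensitive).
#' @return a `variant_table`: a `protein_variant` data.frame with attributes
#'   `source` and `provenance`.
#' @export
read_variant_table <- function(path,
                               dialect = c("generic_csv", "clinvar_summary",
                                           "gnomad_export"),
                               gene = NA_character_,
                               source = c("clinical", "population"),
                               significance_allow = NULL) {
  dialect <- match.arg(dialect)
  source <- match.arg(source)
  if (!file.exists(path)) {
    stop(errorCondition(sprintf("file not found: %s", path),
                        class = c("senscan_io_error", "senscan_error")))
  }
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- .required_columns[[dialect]]
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(errorCondition(
      sprintf("dialect %s requires missing column(s): %s", dialect,
              paste(missing_cols, collapse = ", ")),
      class = c("senscan_schema_error", "senscan_error")))
  }

  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(df)) return(df[[nm]])
    rep(NA, nrow(df))
  }
  if (dialect == "generic_csv") {
    hgvs <- as.character(df$hgvs_p)
    gene_col <- as.character(pick("gene"))
    sig <- as.character(pick("significance"))
    het <- suppressWarnings(as.integer(pick("het")))
    hom <- suppressWarnings(as.integer(pick("hom")))
    hemi <- suppressWarnings(as.integer(pick("hemi")))
    sex <- tolower(as.character(pick("sex")))
  } else if (dialect == "clinvar_summary") {
    # e.g. "NM_014932.4(NLGN1):c.73C>T (p.Leu25Ter)"
    nm <- as.character(df$Name)
    hgvs <- ifelse(grepl("\\(p\\.[^)]+\\)", nm),
                   sub(".*\\((p\\.[^)]+)\\).*", "\\1", nm),
                   NA_character_)
    gene_col <- as.character(pick("GeneSymbol"))
    sig <- as.character(pick("ClinicalSignificance"))
    het <- hom <- hemi <- rep(NA_integer_, nrow(df))
    sex <- rep(NA_character_, nrow(df))
  } else {
    hgvs <- as.character(df[["Protein Consequence"]])
    gene_col <- as.character(pick("Gene", "gene"))
    sig <- as.character(pick("ClinVar Clinical Significance"))
    ac <- suppressWarnings(as.integer(pick("Allele Count")))
    hom <- suppressWarnings(as.integer(pick("Homozygote Count")))
    hemi <- suppressWarnings(as.integer(pick("Hemizygote Count")))
    het <- ac - 2L * ifelse(is.na(hom), 0L, hom) - ifelse(is.na(hemi), 0L, hemi)
    sex <- rep(NA_character_, nrow(df))
  }

  if (!is.na(gene) && any(!is.na(gene_col))) {
    keep <- is.na(gene_col) | gene_col == gene
    hgvs <- hgvs[keep]; gene_col <- gene_col[keep]; sig <- sig[keep]
    het <- het[keep]; hom <- hom[keep]; hemi <- hemi[keep]; sex <- sex[keep]
  }

  n_in <- length(hgvs)
  rows <- vector("list", n_in)
  n_bad <- 0L
  for (k in seq_len(n_in)) {
    row_gene <- if (!is.na(gene_col[k]) && nzchar(gene_col[k]))
      gene_col[k] else gene
    pv <- tryCatch(parse_hgvs_p(hgvs[k], gene = row_gene, source = source,
                                significance = sig[k]),
                   senscan_error = function(e) NULL,
                   error = function(e) NULL)
    if (is.null(pv)) { n_bad <- n_bad + 1L; next }
    pv$het <- het[k]; pv$hom <- hom[k]; pv$hemi <- hemi[k]
    if (!is.na(sex[k]) && nzchar(sex[k])) {
      pv$n_female <- as.integer(sex[k] %in% c("f", "female"))
      pv$n_male <- as.integer(sex[k] %in% c("m", "male"))
    }
    rows[[k]] <- pv
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else
    parse_hgvs_p(character(0), gene = gene, source = source)
  if (n_bad > 0L) {
    warning(sprintf("%d of %d rows failed HGVS parsing and were skipped",
                    n_bad, n_in))
  }
  if (nrow(out) == 0L && n_in >= 0L) {
    warning(sprintf("no parseable variant rows in %s", path))
  }
  if (!is.null(significance_allow) && nrow(out) > 0L) {
    pat <- paste(tolower(significance_allow), collapse = "|")
    out <- out[!is.na(out$significance) &
                 grepl(pat, tolower(out$significance)), , drop = FALSE]
  }
  out <- dedupe_variants(out)
  class(out) <- c("variant_table", "protein_variant", "data.frame")
  attr(out, "source") <- source
  attr(out, "provenance") <- sprintf("%s (%s dialect)", path, dialect)
  out
}

#' Write sensitive regions as BED
#'
#' Residue intervals are 1-based closed internally; BED is 0-based
#' half-open, so a region `[start, end]` becomes `start-1 .. end`.
#'
#' @param regions data.frame with `start`, `end` (and optionally
#'   `mean_delta`, used for the BED score column).
#' @param protein_length protein length; regions must lie inside
#'   `[1, protein_length]`.
#' @param path output file.
#' @param gene chrom-column label.
#' @param comment optional character vector written as leading `#` lines.
#' @export
write_regions_bed <- function(regions, protein_length, path,
                              gene = "protein", comment = NULL) {
  if (nrow(regions) > 0L &&
      (any(regions$start < 1L) || any(regions$end > protein_length) ||
       any(regions$start > regions$end))) {
    stop(errorCondition(
      sprintf("region outside [1, %d]", protein_length),
      class = c("senscan_range_error", "senscan_error")))
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines("#chrom\tstart\tend\tname\tscore\tstrand", con)
  if (nrow(regions) > 0L) {
    score <- if ("mean_delta" %in% names(regions))
      sprintf("%.6g", regions$mean_delta) else rep("0", nrow(regions))
    writeLines(sprintf("%s\t%d\t%d\tsensitive_region_%d\t%s\t+",
                       gene, regions$start - 1L, regions$end,
                       seq_len(nrow(regions)), score), con)
  }
  invisible(path)
}

#' Read a regions BED file back into 1-based closed residue intervals
#'
#' @param path BED file written by [write_regions_bed()].
#' @return data.frame with `start`, `end` (1-based closed) and `name`.
#' @export
read_regions_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(start = integer(0), end = integer(0),
                      name = character(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    start = vapply(parts, function(p) as.integer(p[2]), integer(1)) + 1L,
    end = vapply(parts, function(p) as.integer(p[3]), integer(1)),
    name = vapply(parts, function(p) p[4], character(1))
  )
}

#' Write the per-residue curve table as TSV
#'
#' @param profile a `tolerance_profile`.
#' @param path output file.
#' @param comment optional character vector written as leading `#` lines.
#' @export
write_curve_tsv <- function(profile, path, comment = NULL) {
  df <- as.data.frame(profile)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
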