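# HGVS protein-notation grammar and variant bookkeeping.
#
# Variants are represented as plain data.frames (one row per variant) with
# columns: gene, position, ref_aa, alt_aa, consequence, source, significance,
# het, hom, hemi, n_female, n_male, raw_hgvs.  One-letter amino-acid codes are
# canonical internally; three-letter codes (ClinVar dialect) are accepted on
# input.

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
         Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
         L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
         S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val")

CONSEQUENCE_CLASSES <- c("missense", "nonsense", "frameshift",
                         "synonymous", "other")

# Map one token (1- or 3-letter code, "*", "Ter", "X", "=", "?") to its
# canonical one-letter form, or NA when it is not an amino-acid token.
.aa_canonical <- function(tok) {
  if (is.na(tok) || !nzchar(tok)) return(NA_character_)
  if (tok %in% c("*", "X")) return("*")
  if (tok == "=") return("=")
  if (tok == "?") return("?")
  if (nchar(tok) == 1L && toupper(tok) %in% AA1) return(toupper(tok))
  if (nchar(tok) == 3L) {
    if (tolower(tok) == "ter") return("*")
    hit <- match(tolower(tok), tolower(AA3))
    if (!is.na(hit)) return(names(AA3)[hit])
  }
  NA_character_
}

.hgvs_error <- function(notation, token, what = "token") {
  stop(errorCondition(
    sprintf("cannot parse HGVS notation %s: offending %s %s",
            dQuote(notation, FALSE), what, dQuote(token, FALSE)),
    class = c("senscan_parse_error", "senscan_error"),
    notation = notation, token = token))
}

.parse_hgvs_one <- function(notation) {
  if (is.na(notation) || !nzchar(trimws(notation))) {
    .hgvs_error(if (is.na(notation)) "NA" else notation, "<empty>")
  }
  x <- trimws(notation)
  x <- sub("^p\\.", "", x)
  x <- sub("^\\((.*)\\)$", "\\1", x)
  m <- regexec("^([A-Za-z]{3}|[A-Za-z?])([0-9]+)(.*)$", x)[[1]]
  if (m[1] == -1L) .hgvs_error(notation, x)
  parts <- regmatches(x, list(regexec("^([A-Za-z]{3}|[A-Za-z?])([0-9]+)(.*)$", x)[[1]]))[[1]]
  ref_tok <- parts[2]
  pos <- suppressWarnings(as.integer(parts[3]))
  tail <- parts[4]

  ref <- .aa_canonical(ref_tok)
  if (is.na(ref) || ref %in% c("*", "=")) .hgvs_error(notation, ref_tok, "reference residue")
  if (is.na(pos) || pos < 1L) {
    stop(errorCondition(
      sprintf("HGVS notation %s: residue position must be >= 1", dQuote(notation, FALSE)),
      class = c("senscan_range_error", "senscan_error"), notation = notation))
  }

  alt <- NA_character_
  fs <- FALSE
  if (grepl("fs", tail, ignore.case = TRUE)) {
    # "fs", "Lysfs*17", "Kfs*17", "fsTer12": keep first-affected residue only
    fs <- TRUE
    alt_tok <- sub("[Ff][Ss].*$", "", tail)
    if (nzchar(alt_tok) && is.na(.aa_canonical(alt_tok))) {
      .hgvs_error(notation, alt_tok, "alternate residue")
    }
    alt <- ""
  } else if (!nzchar(tail)) {
    .hgvs_error(notation, x, "missing alternate residue in")
  } else {
    alt <- .aa_canonical(tail)
    if (is.na(alt)) .hgvs_error(notation, tail, "alternate residue")
    if (alt == "=") alt <- ref  # "Thr90=" synonymous form
  }

  consequence <-
    if (fs) "frameshift"
    else if (alt == "*") "nonsense"
    else if (ref == alt) "synonymous"
    else if (ref %in% AA1 && alt %in% AA1) "missense"
    else "other"

  list(position = pos, ref_aa = ref, alt_aa = alt, consequence = consequence)
}

#' Parse HGVS protein notation
#'
#' Parses one or more HGVS protein-level notations into a variant table.
#' Accepted forms (with or without the `"p."` prefix, with one- or
#' three-letter amino-acid codes): substitutions (`"p.R451C"`,
#' `"p.Arg451Cys"`), nonsense (`"p.L25*"`, `"p.Leu25Ter"`), frameshifts
#' (`"p.T271fs"`, `"p.T271Kfs*17"`), and synonymous (`"p.T90T"`,
#' `"p.Thr90="`).  Three-letter codes are canonicalized to one-letter so that
#' `format()` of the result is stable under re-parsing.
#'
#' @param notation character vector of HGVS protein notations.
#' @param gene gene symbol to attach (recycled).
#' @param source `"clinical"` or `"population"` (recycled).
#' @param significance optional clinical-significance strings (recycled).
#' @return a `protein_variant` data.frame with one row per notation and
#'   columns `gene`, `position`, `ref_aa`, `alt_aa`, `consequence`, `source`,
#'   `significance`, `het`, `hom`, `hemi`, `n_female`, `n_male`, `raw_hgvs`.
#' @examples
#' parse_hgvs_p(c("p.R451C", "p.L25*", "p.T271fs"), gene = "NLGN1")
#' @export
parse_hgvs_p <- function(notation, gene = NA_character_,
                         source = NA_character_,
                         significance = NA_character_) {
  stopifnot(is.character(notation))
  parsed <- lapply(notation, .parse_hgvs_one)
  out <- data.frame(
    gene = rep_len(gene, length(notation)),
    position = vapply(parsed, `[[`, integer(1), "position"),
    ref_aa = vapply(parsed, `[[`, character(1), "ref_aa"),
    alt_aa = vapply(parsed, `[[`, character(1), "alt_aa"),
    consequence = vapply(parsed, `[[`, character(1), "consequence"),
    source = rep_len(source, length(notation)),
    significance = rep_len(significance, length(notation)),
    het = rep(NA_integer_, length(notation)),
    hom = rep(NA_integer_, length(notation)),
    hemi = rep(NA_integer_, length(notation)),
    n_female = rep(NA_integer_, length(notation)),
    n_male = rep(NA_integer_, length(notation)),
    raw_hgvs = notation,
    stringsAsFactors = FALSE
  )
  class(out) <- c("protein_variant", "data.frame")
  out
}

#' Format variants back to canonical HGVS notation
#'
#' @param x a `protein_variant` data.frame.
#' @param ... ignored.
#' @return character vector of canonical one-letter notations, e.g.
#'   `"p.R451C"`, `"p.L25*"`, `"p.T271fs"`.
#' @export
format.protein_variant <- function(x, ...) {
  suffix <- ifelse(x$consequence == "frameshift", "fs", x$alt_aa)
  paste0("p.", x$ref_aa, x$position, suffix)
}

#' Classify variant consequence
#'
#' Assigns exactly one consequence class per variant: `missense` (single
#' substitution between two standard amino acids), `nonsense` (alternate
#' `"*"`), `frameshift` (notation carries `fs`), `synonymous` (reference
#' equals alternate), otherwise `other`.
#'
#' @param variants a `protein_variant` data.frame (or any data.frame with
#'   `ref_aa`, `alt_aa`, `raw_hgvs` columns).
#' @return character vector of consequence classes, one per row.
#' @export
classify_consequence <- function(variants) {
  ref <- variants$ref_aa
  alt <- variants$alt_aa
  fs <- grepl("fs", variants$raw_hgvs, ignore.case = TRUE)
  ifelse(fs, "frameshift",
    ifelse(alt == "*", "nonsense",
      ifelse(ref == alt & ref %in% AA1, "synonymous",
        ifelse(ref %in% AA1 & alt %in% AA1 & ref != alt,
               "missense", "other"))))
}

#' Collapse duplicate variant records
#'
#' Keeps one record per distinct protein-level event, identified by
#' `(gene, position, ref_aa, alt_aa, consequence)`.  Distinct substitutions
#' at the same residue are retained separately; submission or genotype counts
#' never weight the result (each distinct event counts once).  Output order
#' is stable by `(position, alt_aa)`.
#'
#' @param variants a `protein_variant` data.frame.
#' @return the deduplicated data.frame.
#' @export
dedupe_variants <- function(variants) {
  if (nrow(variants) == 0L) return(variants)
  key <- paste(variants$gene, variants$position, variants$ref_aa,
               variants$alt_aa, variants$consequence, sep = "\r")
  out <- variants[!duplicated(key), , drop = FALSE]
  out <- out[order(out$position, out$alt_aa), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count deduplicated variants of one class in a residue interval
#'
#' @param variants a `protein_variant` data.frame (deduplicated internally).
#' @param start,end 1-based closed residue interval.
#' @param consequence consequence class to count (default `"missense"`).
#' @return integer count.
#' @examples
#' v <- parse_hgvs_p(c("p.T625I", "p.T625N", "p.W633R"))
#' count_region_variants(v, 620, 633)
#' @export
count_region_variants <- function(variants, start, end,
                                  consequence = "missense") {
  stopifnot(length(start) == 1L, length(end) == 1L)
  if (start > end) {
    stop(errorCondition(
      sprintf("inverted residue interval [%d, %d]", start, end),
      class = c("senscan_range_error", "senscan_error")))
  }
  consequence <- match.arg(consequence, CONSEQUENCE_CLASSES)
  v <- dedupe_variants(variants)
  sum(v$consequence == consequence & v$position >= start & v$position <= end)
}
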