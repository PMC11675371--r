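# Transcript exon/CDS model.
#
# A `transcript_model` stores the exon structure of a single (MANE-style)
# transcript and the per-exon coding lengths, normalized so that exon 1 is
# the 5'-most coding exon regardless of genomic strand.  The protein length
# excludes the stop codon: protein_length = CDS codons - 1.

#' Construct a transcript model
#'
#' @param gene gene symbol.
#' @param exons data.frame with `start`, `end` genomic coordinates (1-based
#'   closed), in genomic order.
#' @param cds_start,cds_end genomic coordinates of the CDS span (including
#'   the stop codon).
#' @param strand `"+"` or `"-"`.
#' @return a `transcript_model`: list with `gene`, `strand`, `exons` (ordered
#'   5' to 3'), `cds_exon_lengths` (coding nucleotides per exon, 5' to 3'),
#'   `cds_length`, `n_exons`, `protein_length`.
#' @export
transcript_model <- function(gene, exons, cds_start, cds_end, strand = "+") {
  stopifnot(is.data.frame(exons), all(c("start", "end") %in% names(exons)),
            strand %in% c("+", "-"))
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  if (nrow(exons) == 0L) {
    stop(errorCondition("transcript has no exons",
                        class = c("senscan_validation_error", "senscan_error")))
  }
  if (any(exons$end < exons$start)) {
    stop(errorCondition("exon with end < start",
                        class = c("senscan_validation_error", "senscan_error")))
  }
  if (nrow(exons) > 1L && any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    stop(errorCondition("exons overlap or are out of order",
                        class = c("senscan_validation_error", "senscan_error")))
  }
  if (cds_start > cds_end) stop(errorCondition(
    "cds_start > cds_end", class = c("senscan_validation_error", "senscan_error")))
  # coding nucleotides contributed by each exon (genomic order)
  lo <- pmax(exons$start, cds_start)
  hi <- pmin(exons$end, cds_end)
  cds_len <- pmax(hi - lo + 1L, 0L)
  in_exon <- function(x) any(x >= exons$start & x <= exons$end)
  if (!in_exon(cds_start) || !in_exon(cds_end)) {
    stop(errorCondition("CDS extends outside the exons",
                        class = c("senscan_validation_error", "senscan_error")))
  }
  if (strand == "-") {
    exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
    cds_len <- rev(cds_len)
  }
  rownames(exons) <- NULL
  total <- sum(cds_len)
  if (total %% 3L != 0L) {
    stop(errorCondition(
      sprintf("CDS length %d is not a multiple of 3", total),
      class = c("senscan_validation_error", "senscan_error")))
  }
  structure(list(
    gene = gene, strand = strand, exons = exons,
    cds_exon_lengths = as.integer(cds_len),
    cds_length = as.integer(total),
    n_exons = nrow(exons),
    protein_length = as.integer(total %/% 3L - 1L)
  ), class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("Transcript model: %s (%s strand)\n", x$gene, x$strand))
  cat(sprintf("  %d exons, CDS %d nt, protein %d aa\n",
              x$n_exons, x$cds_length, x$protein_length))
  invisible(x)
}

#' Read a transcript model from GFF3 or an exon-table JSON
#'
#' The JSON schema is `{gene, strand, cds_start, cds_end, exons: [{start,
#' end}, ...]}` with 1-based closed genomic coordinates.  GFF3 input must
#' describe a single transcript; `exon` and `CDS` features are used and the
#' CDS span is taken as the range of the CDS features.
#'
#' @param path file path.
#' @param format `"exon_json"` or `"gff3"` (guessed from the extension when
#'   omitted).
#' @return a [transcript_model()].
#' @export
read_transcript <- function(path, format = c("auto", "exon_json", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gff3?|gtf)$", path, ignore.case = TRUE))
      "gff3" else "exon_json"
  }
  if (format == "exon_json") {
    j <- jsonlite::fromJSON(path)
    exons <- as.data.frame(j$exons)
    transcript_model(gene = j$gene %||% "unknown", exons = exons,
                     cds_start = j$cds_start, cds_end = j$cds_end,
                     strand = j$strand %||% "+")
  } else {
    gr <- as.data.frame(rtracklayer::import(path))
    ex <- gr[gr$type == "exon", , drop = FALSE]
    cds <- gr[gr$type == "CDS", , drop = FALSE]
    if (nrow(ex) == 0L) ex <- cds
    if (nrow(cds) == 0L) {
      stop(errorCondition("GFF3 has no CDS features",
                          class = c("senscan_validation_error", "senscan_error")))
    }
    strand <- as.character(ex$strand[1])
    if (!strand %in% c("+", "-")) strand <- "+"
    gene <- ex$gene_id[1] %||% ex$Name[1] %||% "unknown"
    if (is.null(gene) || is.na(gene)) gene <- "unknown"
    transcript_model(gene = gene,
                     exons = data.frame(start = ex$start, end = ex$end),
                     cds_start = min(cds$start), cds_end = max(cds$end),
                     strand = strand)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Map a CDS nucleotide position to its exon index
#'
#' @param transcript a [transcript_model()].
#' @param nt 1-based CDS nucleotide index (vectorized).
#' @return integer exon indices (1 = 5'-most exon).
#' @export
cds_to_exon <- function(transcript, nt) {
  stopifnot(inherits(transcript, "transcript_model"))
  if (any(nt < 1L | nt > transcript$cds_length)) {
    stop(errorCondition(
      sprintf("CDS position outside [1, %d]", transcript$cds_length),
      class = c("senscan_range_error", "senscan_error")))
  }
  bounds <- cumsum(transcript$cds_exon_lengths)
  # skip exons that contribute no coding sequence
  idx <- findInterval(nt - 1L, c(0L, bounds), rightmost.closed = FALSE)
  as.integer(idx)
}
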