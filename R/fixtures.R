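# Worked-example datasets for the four NLGN genes.
#
# The published truncation analyses report per-gene COUNTS (how many early
# truncations per source, their exon class and carrier sex), not the variant
# positions themselves.  The tables returned here are therefore synthetic
# reconstructions: deterministic variant sets laid out on toy transcripts so
# that every reported count is reproduced exactly.  They exercise the
# truncation/NMD/haploinsufficiency machinery end to end; they are not the
# database records.

# evenly spaced codon positions whose first codon nucleotide falls in the
# requested exon range of the transcript
.codons_in_exons <- function(transcript, exon_from, exon_to, n) {
  if (n == 0L) return(integer(0))
  bounds <- c(0L, cumsum(transcript$cds_exon_lengths))
  nt_lo <- bounds[exon_from] + 1L
  nt_hi <- bounds[exon_to + 1L]
  codon_lo <- (nt_lo - 1L) %/% 3L + 1L
  codon_hi <- (nt_hi - 1L) %/% 3L + 1L
  # keep codons whose first nucleotide is inside the range, and off the stop
  codon_hi <- min(codon_hi, transcript$protein_length)
  while (3L * (codon_lo - 1L) + 1L < nt_lo) codon_lo <- codon_lo + 1L
  pos <- unique(as.integer(round(seq(codon_lo, codon_hi, length.out = n))))
  k <- codon_lo
  while (length(pos) < n) {      # collisions at tiny ranges: fill linearly
    if (!(k %in% pos)) pos <- c(pos, k)
    k <- k + 1L
  }
  sort(pos[seq_len(n)])
}

.nonsense_at <- function(transcript, positions, gene, source,
                         sex = NULL, het = 1L) {
  if (length(positions) == 0L) {
    return(parse_hgvs_p(character(0), gene = gene, source = source))
  }
  refs <- rep_len(c("R", "Q", "W", "E", "K", "L", "S", "G"),
                  length(positions))
  out <- parse_hgvs_p(paste0("p.", refs, positions, "*"),
                      gene = gene, source = source)
  if (length(positions)) {
    out$het <- het
    if (!is.null(sex)) {
      out$n_female <- as.integer(sex == "F")
      out$n_male <- as.integer(sex == "M")
    }
  }
  out
}

#' Reconstructed NLGN truncation examples
#'
#' Deterministic, synthetic variant tables and toy transcripts reproducing
#' the reported early-truncation counts for the four NLGN genes: NLGN1 (53
#' population early truncations, all heterozygous, vs 3 clinical, all before
#' the last exon), NLGN2 (64 vs 2), NLGN3 (20 population truncations, 11
#' before the last exon with a single male carrier, 9 in the last exon, vs 3
#' clinical of which 2 before the last exon), and NLGN4X (5 population
#' truncations, 4 before the last exon in heterozygous females, vs 6
#' clinical).  Variant positions are evenly spaced inventions; only the
#' counts, exon classes and carrier-sex tallies are faithful.
#'
#' @param gene `"NLGN1"`, `"NLGN2"`, `"NLGN3"` or `"NLGN4X"`.
#' @return list with `clinical`, `population` (`protein_variant`
#'   data.frames) and `transcript` (a [transcript_model()]).
#' @examples
#' fx <- nlgn_truncation_example("NLGN4X")
#' haploinsufficiency_report(fx$clinical, fx$population, fx$transcript)
#' @export
nlgn_truncation_example <- function(gene = c("NLGN1", "NLGN2", "NLGN3",
                                             "NLGN4X")) {
  gene <- match.arg(gene)
  if (gene == "NLGN1") {
    tr <- generate_transcript(c(400L, 400L, 400L, 400L, 400L, 523L),
                              gene = gene)
    po <- .nonsense_at(tr, .codons_in_exons(tr, 1L, 5L, 53L), gene,
                       "population")
    cl <- .nonsense_at(tr, .codons_in_exons(tr, 1L, 5L, 3L), gene,
                       "clinical")
  } else if (gene == "NLGN2") {
    tr <- generate_transcript(rep(418L, 6L), gene = gene)
    po <- .nonsense_at(tr, .codons_in_exons(tr, 1L, 5L, 64L), gene,
                       "population")
    cl <- .nonsense_at(tr, .codons_in_exons(tr, 1L, 5L, 2L), gene,
                       "clinical")
  } else if (gene == "NLGN3") {
    tr <- generate_transcript(c(500L, 500L, 500L, 500L, 547L), gene = gene)
    before <- .nonsense_at(tr, .codons_in_exons(tr, 1L, 4L, 11L), gene,
                           "population",
                           sex = c("M", rep("F", 10L)))
    last <- .nonsense_at(tr, .codons_in_exons(tr, 5L, 5L, 9L), gene,
                         "population",
                         sex = c("M", rep("F", 8L)))
    po <- rbind(before, last)
    cl <- rbind(
      .nonsense_at(tr, .codons_in_exons(tr, 1L, 4L, 2L), gene, "clinical"),
      .nonsense_at(tr, .codons_in_exons(tr, 5L, 5L, 1L), gene, "clinical"))
  } else {
    tr <- generate_transcript(c(500L, 500L, 500L, 500L, 451L), gene = gene)
    before <- .nonsense_at(tr, .codons_in_exons(tr, 1L, 4L, 4L), gene,
                           "population", sex = rep("F", 4L))
    last <- .nonsense_at(tr, .codons_in_exons(tr, 5L, 5L, 1L), gene,
                         "population", sex = "F")
    po <- rbind(before, last)
    cl <- .nonsense_at(tr, .codons_in_exons(tr, 1L, 4L, 6L), gene,
                       "clinical")
  }
  list(clinical = cl, population = po, transcript = tr)
}
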