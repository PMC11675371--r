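# Independent brute-force oracle for the smoothed density curve: direct
# O(L * W) summation, kept loop-based and separate from the package's
# convolution path.
oracle_density <- function(positions, L, window = 31L,
                           sigma = (window - 1) / 6) {
  k <- gaussian_window_kernel(window, sigma)
  h <- (window - 1L) %/% 2L
  raw <- numeric(L)
  for (p in positions) {
    for (d in -h:h) {
      i <- p + d
      if (i >= 1L && i <= L) raw[i] <- raw[i] + k[d + h + 1L]
    }
  }
  m <- vapply(seq_len(L), function(i) {
    taps <- max(1L, i - h):min(L, i + h)
    sum(k[taps - i + h + 1L])
  }, numeric(1))
  list(raw = raw, corrected = raw / m)
}

# missense variant table at given residue positions (alternating alts keep
# duplicates at one residue distinct)
missense_at <- function(positions, gene = "GENE") {
  if (length(positions) == 0L) {
    return(parse_hgvs_p(character(0), gene = gene))
  }
  alts <- rep_len(c("V", "I", "L", "M"), length(positions))
  refs <- rep_len("A", length(positions))
  parse_hgvs_p(paste0("p.", refs, positions, alts), gene = gene)
}

# toy 3-exon transcript: 300 + 300 + 402 coding nt -> 333-residue protein
toy_transcript <- function() generate_transcript(c(300L, 300L, 402L),
                                                 gene = "TOY")

write_toy_exon_json <- function(path, strand = "+") {
  exons <- list(list(start = 101, end = 400),
                list(start = 601, end = 900),
                list(start = 1101, end = 1502))
  jsonlite::write_json(
    list(gene = "TOY", strand = strand, cds_start = 101, cds_end = 1502,
         exons = exons),
    path, auto_unbox = TRUE)
  path
}

write_toy_gff3 <- function(path, strand = "+") {
  lines <- c(
    "##gff-version 3",
    sprintf("chr1\ttest\tmRNA\t101\t1502\t.\t%s\t.\tID=toy.t1;gene_id=TOY", strand),
    sprintf("chr1\ttest\texon\t101\t400\t.\t%s\t.\tParent=toy.t1;gene_id=TOY", strand),
    sprintf("chr1\ttest\texon\t601\t900\t.\t%s\t.\tParent=toy.t1;gene_id=TOY", strand),
    sprintf("chr1\ttest\texon\t1101\t1502\t.\t%s\t.\tParent=toy.t1;gene_id=TOY", strand),
    sprintf("chr1\ttest\tCDS\t101\t400\t.\t%s\t0\tParent=toy.t1;gene_id=TOY", strand),
    sprintf("chr1\ttest\tCDS\t601\t900\t.\t%s\t0\tParent=toy.t1;gene_id=TOY", strand),
    sprintf("chr1\ttest\tCDS\t1101\t1502\t.\t%s\t0\tParent=toy.t1;gene_id=TOY", strand))
  writeLines(lines, path)
  path
}

extdata <- function(file) system.file("extdata", file, package = "senscan")
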