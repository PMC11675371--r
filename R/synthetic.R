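# Seeded synthetic variant and transcript generators.
#
# The generator emulates the qualitative structure the real data exhibit:
# clustered clinical missense variants over a diffuse population background
# with optional locally depleted windows.  Positions only — no mutational
# signature or codon-usage realism.

#' Specification for the synthetic variant generator
#'
#' @param protein_length protein length in residues.
#' @param background_rate expected population variants per residue (Poisson).
#' @param clusters data.frame with columns `center`, `sd`, `n`, `source`
#'   (`"clinical"` or `"population"`); may have zero rows.
#' @param depleted_windows optional data.frame of `start`, `end` intervals
#'   with zero background.
#' @param seed integer seed; one seed governs every draw.
#' @return a validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(protein_length, background_rate = 0.05,
                           clusters = NULL, depleted_windows = NULL,
                           seed = 1L) {
  if (is.null(clusters)) {
    clusters <- data.frame(center = numeric(0), sd = numeric(0),
                           n = integer(0), source = character(0))
  }
  clusters <- as.data.frame(clusters)
  if (background_rate < 0) {
    stop(errorCondition("background_rate must be >= 0",
                        class = c("senscan_spec_error", "senscan_error")))
  }
  if (nrow(clusters) > 0L) {
    if (any(clusters$n > 0L & clusters$sd <= 0)) {
      stop(errorCondition("cluster with n > 0 requires sd > 0",
                          class = c("senscan_spec_error", "senscan_error")))
    }
    if (any(clusters$center < 1 | clusters$center > protein_length)) {
      stop(errorCondition("cluster center outside [1, protein_length]",
                          class = c("senscan_spec_error", "senscan_error")))
    }
  }
  structure(list(protein_length = as.integer(protein_length),
                 background_rate = background_rate,
                 clusters = clusters,
                 depleted_windows = depleted_windows,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# random missense records at given residue positions; multiple draws at the
# same residue get distinct alternate residues so deduplication keeps them
.variants_at <- function(positions, gene, source) {
  n <- length(positions)
  if (n == 0L) {
    return(parse_hgvs_p(character(0), gene = gene, source = source))
  }
  ref <- character(n); alt <- character(n)
  for (k in seq_len(n)) {
    same <- which(positions[seq_len(k - 1L)] == positions[k])
    if (length(same)) {
      ref[k] <- ref[same[1]]
      pool <- setdiff(AA1, c(ref[k], alt[same]))
      if (!length(pool)) pool <- setdiff(AA1, ref[k])
      alt[k] <- sample(pool, 1L)
    } else {
      ref[k] <- sample(AA1, 1L)
      alt[k] <- sample(setdiff(AA1, ref[k]), 1L)
    }
  }
  out <- parse_hgvs_p(paste0("p.", ref, positions, alt),
                      gene = gene, source = source)
  out
}

#' Generate seeded synthetic variant tables with known ground truth
#'
#' Population background counts are drawn per residue from a Poisson with
#' mean `background_rate` (zero inside depleted windows); cluster positions
#' are drawn from a rounded Gaussian and clipped (not rejected) to
#' `[1, protein_length]`, so each cluster contributes exactly `n` records.
#'
#' @param spec a [synthetic_spec()].
#' @param gene gene label for the generated records.
#' @return list with `clinical` and `population` `protein_variant`
#'   data.frames and `truth`, a data.frame of the implanted cluster spans
#'   (`center`, `start`, `end` = center +/- 2 sd, clipped).
#' @export
generate_variants <- function(spec, gene = "SYN1") {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  L <- spec$protein_length

  lambda <- rep(spec$background_rate, L)
  dep <- .interval_flags(spec$depleted_windows, L)
  lambda[dep] <- 0
  k_bg <- stats::rpois(L, lambda)
  bg_positions <- rep(seq_len(L), k_bg)

  cl_positions <- integer(0)
  po_cluster_positions <- integer(0)
  truth <- data.frame(center = numeric(0), start = integer(0),
                      end = integer(0), source = character(0))
  for (j in seq_len(nrow(spec$clusters))) {
    cc <- spec$clusters[j, ]
    pos <- pmin(pmax(round(stats::rnorm(cc$n, cc$center, cc$sd)), 1L), L)
    if (identical(cc$source, "clinical")) {
      cl_positions <- c(cl_positions, pos)
    } else {
      po_cluster_positions <- c(po_cluster_positions, pos)
    }
    truth <- rbind(truth, data.frame(
      center = cc$center,
      start = max(1L, as.integer(round(cc$center - 2 * cc$sd))),
      end = min(L, as.integer(round(cc$center + 2 * cc$sd))),
      source = cc$source))
  }

  clinical <- .variants_at(sort(cl_positions), gene, "clinical")
  population <- .variants_at(sort(c(bg_positions, po_cluster_positions)),
                             gene, "population")
  list(clinical = clinical, population = population, truth = truth)
}

#' Generate a toy transcript from per-exon coding lengths
#'
#' Builds a plus-strand transcript whose exons carry exactly the given
#' coding lengths, separated by fixed-size introns.
#'
#' @param exon_lengths integer vector of coding nucleotides per exon; the
#'   sum must be a multiple of 3.
#' @param gene gene label.
#' @param intron_length intron size in nucleotides (default 200).
#' @return a [transcript_model()].
#' @export
generate_transcript <- function(exon_lengths, gene = "SYN1",
                                intron_length = 200L) {
  if (length(exon_lengths) == 0L || any(exon_lengths < 1L)) {
    stop(errorCondition("exon_lengths must be a non-empty positive vector",
                        class = c("senscan_spec_error", "senscan_error")))
  }
  if (sum(exon_lengths) %% 3L != 0L) {
    stop(errorCondition("total CDS length must be a multiple of 3",
                        class = c("senscan_spec_error", "senscan_error")))
  }
  starts <- integer(length(exon_lengths))
  ends <- integer(length(exon_lengths))
  pos <- 1L
  for (k in seq_along(exon_lengths)) {
    starts[k] <- pos
    ends[k] <- pos + exon_lengths[k] - 1L
    pos <- ends[k] + intron_length + 1L
  }
  transcript_model(gene = gene,
                   exons = data.frame(start = starts, end = ends),
                   cds_start = starts[1], cds_end = ends[length(ends)],
                   strand = "+")
}
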