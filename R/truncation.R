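# Early-truncation classification and the haploinsufficiency report.
#
# Nonsense and frameshift variants are marked at a single CDS nucleotide —
# the mutated stop position (nonsense) or the first inserted/deleted
# nucleotide (frameshift) — and a transcript is predicted to undergo
# nonsense-mediated decay exactly when that nucleotide falls before the
# transcript's last exon.  Only this last-exon rule is implemented; the
# 50-nt-from-last-junction refinement is deliberately out of scope.

#' Mark the CDS nucleotide of a truncating variant
#'
#' When no nucleotide-level coordinate is supplied, the first nucleotide of
#' the affected codon is used: `3 * (position - 1) + 1`.
#'
#' @param variant one-row `protein_variant` data.frame (nonsense or
#'   frameshift).
#' @param transcript a [transcript_model()].
#' @param cds_hint optional explicit 1-based CDS nucleotide index.
#' @return 1-based CDS nucleotide index.
#' @export
mark_truncation_site <- function(variant, transcript, cds_hint = NULL) {
  if (!variant$consequence[1] %in% c("nonsense", "frameshift")) {
    stop(errorCondition(
      sprintf("variant %s is %s, not truncating",
              variant$raw_hgvs[1], variant$consequence[1]),
      class = c("senscan_consequence_error", "senscan_error")))
  }
  nt <- if (!is.null(cds_hint) && !is.na(cds_hint)) as.integer(cds_hint)
        else 3L * (variant$position[1] - 1L) + 1L
  if (nt < 1L || nt > transcript$cds_length) {
    stop(errorCondition(
      sprintf("CDS position %d outside [1, %d]", nt, transcript$cds_length),
      class = c("senscan_range_error", "senscan_error")))
  }
  nt
}

#' Classify a truncating variant by the last-exon rule
#'
#' @inheritParams mark_truncation_site
#' @return a `truncation_call`: list with `variant` (the input row),
#'   `cds_position`, `exon_index`, `is_last_exon`, `predicted_nmd`.
#'   `predicted_nmd` is `TRUE` exactly when the marked nucleotide falls
#'   before the last exon; a site at the first nucleotide of the last exon
#'   belongs to the last exon and escapes.
#' @export
classify_truncation <- function(variant, transcript, cds_hint = NULL) {
  nt <- mark_truncation_site(variant, transcript, cds_hint)
  exon <- cds_to_exon(transcript, nt)
  is_last <- exon == transcript$n_exons
  structure(list(
    variant = variant[1, , drop = FALSE],
    cds_position = nt,
    exon_index = exon,
    is_last_exon = is_last,
    predicted_nmd = !is_last
  ), class = "truncation_call")
}

#' @export
print.truncation_call <- function(x, ...) {
  cat(sprintf("%s: CDS nt %d, exon %d, %s\n",
              x$variant$raw_hgvs, x$cds_position, x$exon_index,
              if (x$predicted_nmd) "predicted NMD" else "last exon (NMD escape)"))
  invisible(x)
}

.truncating <- function(variants) {
  v <- dedupe_variants(variants)
  v[v$consequence %in% c("nonsense", "frameshift"), , drop = FALSE]
}

.count_truncations <- function(variants, transcript) {
  v <- .truncating(variants)
  n <- nrow(v)
  before <- 0L; last <- 0L
  het <- 0L; hom <- 0L; hemi <- 0L; fem <- 0L; mal <- 0L
  fem_before <- 0L; mal_before <- 0L
  for (k in seq_len(n)) {
    call <- classify_truncation(v[k, , drop = FALSE], transcript)
    b <- call$predicted_nmd
    if (b) before <- before + 1L else last <- last + 1L
    het <- het + max(v$het[k], 0L, na.rm = TRUE)
    hom <- hom + max(v$hom[k], 0L, na.rm = TRUE)
    hemi <- hemi + max(v$hemi[k], 0L, na.rm = TRUE)
    f <- isTRUE(v$n_female[k] > 0L); m <- isTRUE(v$n_male[k] > 0L)
    fem <- fem + f; mal <- mal + m
    if (b) { fem_before <- fem_before + f; mal_before <- mal_before + m }
  }
  list(total = n, before_last_exon = before, last_exon = last,
       het = het, hom = hom, hemi = hemi,
       n_female = fem, n_male = mal,
       n_female_before = fem_before, n_male_before = mal_before)
}

#' Haploinsufficiency-tolerance report
#'
#' Counts deduplicated early-truncating (nonsense/frameshift) variants per
#' source, split by the last-exon rule, and applies a configurable
#' count-ratio heuristic: `tolerant` when the population shows at least
#' `t_pop` before-last-exon truncations and at least `ratio` times the
#' clinical before-last-exon count; `intolerant` when the population shows
#' at most `t_intolerant` before-last-exon truncations while at least one
#' clinical truncation exists; otherwise `indeterminate`.  A female-carrier
#' bias in the population truncations (few or no male/hemizygous carriers on
#' an X-linked gene) is reported in the rationale only, never as an
#' automatic call.
#'
#' @param clinical,population `protein_variant` data.frames (any
#'   consequences; truncating records are selected internally).
#' @param transcript a [transcript_model()].
#' @param t_pop tolerant threshold on population before-last-exon
#'   truncations (default 10).
#' @param ratio tolerant threshold on the population:clinical
#'   before-last-exon count ratio (default 3).
#' @param t_intolerant intolerant threshold on population before-last-exon
#'   truncations (default 5).
#' @return a `haploinsufficiency_report`: list with `gene`, `clinical` and
#'   `population` count lists (`total`, `before_last_exon`, `last_exon`,
#'   zygosity/sex tallies), `tolerance_call` and `rationale`.
#' @export
haploinsufficiency_report <- function(clinical, population, transcript,
                                      t_pop = 10L, ratio = 3,
                                      t_intolerant = 5L) {
  cl <- .count_truncations(clinical, transcript)
  po <- .count_truncations(population, transcript)

  call <- "indeterminate"
  why <- character(0)
  if (po$before_last_exon >= t_pop &&
      po$before_last_exon >= ratio * cl$before_last_exon) {
    call <- "tolerant"
    why <- sprintf(paste0("%d population early truncations before the last ",
                          "exon vs %d clinical: loss of one allele appears ",
                          "tolerated"),
                   po$before_last_exon, cl$before_last_exon)
  } else if (po$before_last_exon <= t_intolerant && cl$total >= 1L) {
    call <- "intolerant"
    why <- sprintf(paste0("only %d population early truncation(s) before ",
                          "the last exon against %d clinical truncation(s): ",
                          "haploinsufficiency appears not tolerated"),
                   po$before_last_exon, cl$total)
  } else if (cl$total == 0L && po$total == 0L) {
    why <- "no truncating variants in either source"
  } else {
    why <- sprintf("counts (population %d before last exon, clinical %d) match neither rule",
                   po$before_last_exon, cl$total)
  }
  # sex-linked pattern: population truncations carried almost only by females
  sexed <- po$n_female_before + po$n_male_before
  if (sexed > 0L && po$n_male_before / sexed <= 0.2) {
    why <- paste0(why, sprintf(
      "; female-carrier bias: %d of %d sexed before-last-exon population truncations are male, suggesting intolerance in hemizygous males",
      po$n_male_before, sexed))
  }

  structure(list(
    gene = transcript$gene,
    clinical = cl, population = po,
    thresholds = list(t_pop = t_pop, ratio = ratio,
                      t_intolerant = t_intolerant),
    tolerance_call = call,
    rationale = why
  ), class = "haploinsufficiency_report")
}

#' @export
print.haploinsufficiency_report <- function(x, ...) {
  cat(sprintf("Haploinsufficiency report: %s\n", x$gene))
  cat(sprintf("  clinical truncations:   %d (%d before last exon, %d last exon)\n",
              x$clinical$total, x$clinical$before_last_exon,
              x$clinical$last_exon))
  cat(sprintf("  population truncations: %d (%d before last exon, %d last exon)\n",
              x$population$total, x$population$before_last_exon,
              x$population$last_exon))
  cat(sprintf("  call: %s\n  rationale: %s\n", x$tolerance_call, x$rationale))
  invisible(x)
}
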