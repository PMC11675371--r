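# Per-residue missense-tolerance curves.
#
# The procedure, gene by gene:
#   1. deduplicated missense variant positions from each source are smoothed
#      with a truncated, unit-sum Gaussian window (default 31 residues);
#   2. values near the termini are divided by the kernel mass that falls
#      inside [1, L], so a uniform variant density yields a flat curve right
#      up to both ends;
#   3. both curves are rescaled so their maxima coincide at 1;
#   4. delta = population - clinical; maximal runs of strictly negative
#      delta are called sensitive regions.

#' Gaussian window kernel
#'
#' Discrete Gaussian weights over an odd window, truncated at the window and
#' renormalized to unit sum.  The default `sigma = (window - 1) / 6` places
#' the window edges at three standard deviations, so essentially the full
#' mass of the untruncated Gaussian is retained.
#'
#' @param window odd window width in residues (default 31).
#' @param sigma kernel standard deviation in residues.
#' @return numeric weight vector of length `window`, symmetric, maximal at
#'   the center, summing to 1.
#' @export
gaussian_window_kernel <- function(window = 31L, sigma = (window - 1) / 6) {
  if (length(window) != 1L || window < 1L || window %% 2L == 0L) {
    stop(errorCondition("window must be a single odd integer >= 1",
                        class = c("senscan_config_error", "senscan_error")))
  }
  if (window == 1L) return(1.0)
  if (!is.finite(sigma) || sigma <= 0) {
    stop(errorCondition("sigma must be > 0",
                        class = c("senscan_config_error", "senscan_error")))
  }
  half <- (window - 1L) / 2L
  w <- stats::dnorm(seq.int(-half, half), sd = sigma)
  w / sum(w)
}

# Residues covered by a set of closed intervals; intervals is NULL or a
# data.frame with start/end (and optionally a source column, filtered by the
# caller before this point).
.interval_flags <- function(intervals, protein_length) {
  flags <- logical(protein_length)
  if (is.null(intervals) || nrow(intervals) == 0L) return(flags)
  for (k in seq_len(nrow(intervals))) {
    s <- max(1L, as.integer(intervals$start[k]))
    e <- min(protein_length, as.integer(intervals$end[k]))
    if (s <= e) flags[s:e] <- TRUE
  }
  flags
}

#' Smoothed per-residue variant-density curve
#'
#' Computes the raw smoothed density (each variant contributes the kernel
#' weight for its offset from the focal residue) and the edge-corrected
#' tolerance values (raw divided by the in-range kernel mass).  Variants in
#' masked intervals are dropped and the masked residues flagged; variants
#' beyond the protein length are dropped with a warning.
#'
#' @param variants a `protein_variant` data.frame, already missense-filtered
#'   and deduplicated (both are enforced here for safety).
#' @param protein_length protein length in residues.
#' @param window,sigma kernel parameters, see [gaussian_window_kernel()].
#' @param mask optional data.frame of closed residue intervals
#'   (`start`, `end`) whose variants are excluded and whose residues are
#'   flagged.
#' @param source curve label, `"clinical"` or `"population"`.
#' @return a `tolerance_curve`: list with `gene`, `source`, `values`
#'   (edge-corrected), `raw`, `edge_flag`, `masked`, `positions` (the
#'   contributing variant positions), `window`, `sigma`.
#' @export
density_curve <- function(variants, protein_length, window = 31L,
                          sigma = (window - 1) / 6, mask = NULL,
                          source = NA_character_) {
  stopifnot(protein_length >= 1L)
  kernel <- gaussian_window_kernel(window, sigma)
  half <- (window - 1L) %/% 2L
  L <- as.integer(protein_length)

  v <- dedupe_variants(variants)
  v <- v[v$consequence == "missense", , drop = FALSE]
  out_of_range <- v$position > L | v$position < 1L
  if (any(out_of_range)) {
    warning(sprintf("%d variant(s) outside [1, %d] excluded: %s",
                    sum(out_of_range), L,
                    paste(v$raw_hgvs[out_of_range], collapse = ", ")))
    v <- v[!out_of_range, , drop = FALSE]
  }
  masked_flag <- .interval_flags(mask, L)
  keep <- !masked_flag[v$position]
  v <- v[keep, , drop = FALSE]

  counts <- tabulate(v$position, nbins = L)
  if (window == 1L) {
    raw <- as.numeric(counts)
  } else {
    full <- stats::convolve(counts, rev(kernel), type = "open")
    raw <- full[(half + 1L):(half + L)]
  }
  raw[abs(raw) < 1e-15] <- 0  # FFT convolution noise on empty stretches

  # in-range kernel mass at each residue (1 for interior residues)
  ck <- c(0, cumsum(kernel))
  i <- seq_len(L)
  lo <- pmax(1L - i, -half)       # most negative in-range tap offset
  hi <- pmin(L - i, half)
  m <- ck[hi + half + 2L] - ck[lo + half + 1L]
  values <- raw / m

  structure(list(
    gene = if (nrow(v)) v$gene[1] else NA_character_,
    source = source,
    values = values, raw = raw,
    edge_flag = i <= half | i > L - half,
    masked = masked_flag,
    positions = v$position,
    n_variants = nrow(v),
    window = as.integer(window), sigma = sigma
  ), class = "tolerance_curve")
}

#' Normalize a clinical/population curve pair to a common maximum
#'
#' Each curve with a positive maximum is rescaled so its maximum equals 1.
#' An all-zero curve (no variants) is returned unchanged.
#'
#' @param clinical,population `tolerance_curve` objects of equal length.
#' @return list with `clinical` and `population` curves, values rescaled.
#' @export
normalize_pair <- function(clinical, population) {
  if (length(clinical$values) != length(population$values)) {
    stop(errorCondition("curve length mismatch",
                        class = c("senscan_shape_error", "senscan_error")))
  }
  rescale <- function(cv) {
    mx <- max(cv$values)
    if (mx > 0) cv$values <- cv$values / mx
    cv
  }
  list(clinical = rescale(clinical), population = rescale(population))
}

#' Delta of normalized population and clinical curves
#'
#' `delta[i] = population[i] - clinical[i]`, so negative values mark residues
#' where clinically reported missense density exceeds population density.
#'
#' @param clinical_norm,population_norm normalized `tolerance_curve` objects
#'   (or bare numeric vectors) of equal length.
#' @return numeric delta vector.
#' @export
delta_profile <- function(clinical_norm, population_norm) {
  cl <- if (inherits(clinical_norm, "tolerance_curve"))
    clinical_norm$values else clinical_norm
  po <- if (inherits(population_norm, "tolerance_curve"))
    population_norm$values else population_norm
  if (length(cl) != length(po)) {
    stop(errorCondition("curve length mismatch",
                        class = c("senscan_shape_error", "senscan_error")))
  }
  po - cl
}

#' Call sensitive regions from a delta profile
#'
#' A sensitive region is a maximal run of strictly negative delta of at
#' least `min_length` residues.  Regions are never removed for lying near
#' the termini; when `ignore_edges` is set, regions that lie entirely in
#' edge-flagged residues are annotated `low_confidence`.
#'
#' @param delta numeric delta vector, or a `tolerance_profile`.
#' @param min_length minimum region length in residues.
#' @param ignore_edges annotate edge-confined regions as low confidence.
#' @param edge_flag,clinical_positions,population_positions optional vectors
#'   used to fill the per-region annotations when `delta` is a bare vector.
#' @return data.frame with columns `start`, `end`, `min_delta`, `mean_delta`,
#'   `n_clinical`, `n_population`, `low_confidence`, sorted by `start`.
#' @export
call_sensitive_regions <- function(delta, min_length = 1L,
                                   ignore_edges = FALSE,
                                   edge_flag = NULL,
                                   clinical_positions = integer(0),
                                   population_positions = integer(0)) {
  if (inherits(delta, "tolerance_profile")) {
    p <- delta
    delta <- p$delta
    edge_flag <- p$edge_flag
    clinical_positions <- p$curves$clinical$positions
    population_positions <- p$curves$population$positions
  }
  if (is.null(edge_flag)) edge_flag <- logical(length(delta))
  neg <- delta < 0
  r <- rle(neg)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_length
  starts <- starts[keep]; ends <- ends[keep]
  out <- data.frame(
    start = as.integer(starts), end = as.integer(ends),
    min_delta = numeric(length(starts)), mean_delta = numeric(length(starts)),
    n_clinical = integer(length(starts)),
    n_population = integer(length(starts)),
    low_confidence = logical(length(starts))
  )
  for (k in seq_along(starts)) {
    span <- starts[k]:ends[k]
    out$min_delta[k] <- min(delta[span])
    out$mean_delta[k] <- mean(delta[span])
    out$n_clinical[k] <- sum(clinical_positions %in% span)
    out$n_population[k] <- sum(population_positions %in% span)
    out$low_confidence[k] <- ignore_edges && all(edge_flag[span])
  }
  out[order(out$start), , drop = FALSE]
}

#' Missense-tolerance profile of a gene
#'
#' The main entry point: composes [density_curve()] for both sources,
#' [normalize_pair()], [delta_profile()] and [call_sensitive_regions()] into
#' a single classed result.
#'
#' @param clinical,population `protein_variant` data.frames (any consequence
#'   mix; missense records are selected and deduplicated internally).
#' @param protein_length protein length in residues.
#' @param window,sigma kernel parameters, see [gaussian_window_kernel()].
#' @param mask optional data.frame of masked intervals with columns `start`,
#'   `end` and optionally `source` (`"clinical"`, `"population"` or
#'   `"both"`, default both): variants inside are dropped from the stated
#'   curve(s) and the residues flagged.
#' @param min_region_length minimum sensitive-region length.
#' @param gene gene symbol for labeling (taken from the tables when omitted).
#' @return a `tolerance_profile` object; see [print.tolerance_profile()],
#'   [summary.tolerance_profile()], [plot.tolerance_profile()],
#'   [as.data.frame.tolerance_profile()].
#' @examples
#' cl <- parse_hgvs_p(c("p.A87S", "p.P89L", "p.T90R"), gene = "NLGN1")
#' po <- parse_hgvs_p(c("p.V300I", "p.T305A"), gene = "NLGN1")
#' prof <- tolerance_profile(cl, po, protein_length = 840)
#' prof
#' @export
tolerance_profile <- function(clinical, population, protein_length,
                              window = 31L, sigma = (window - 1) / 6,
                              mask = NULL, min_region_length = 1L,
                              gene = NULL) {
  split_mask <- function(which) {
    if (is.null(mask)) return(NULL)
    m <- as.data.frame(mask)
    if (!"source" %in% names(m)) m$source <- "both"
    m[m$source %in% c(which, "both"), c("start", "end"), drop = FALSE]
  }
  cl <- density_curve(clinical, protein_length, window, sigma,
                      mask = split_mask("clinical"), source = "clinical")
  po <- density_curve(population, protein_length, window, sigma,
                      mask = split_mask("population"), source = "population")
  if (is.null(gene)) {
    gene <- c(cl$gene, po$gene, NA_character_)
    gene <- gene[!is.na(gene)][1]
  }
  norm <- normalize_pair(cl, po)
  delta <- delta_profile(norm$clinical, norm$population)
  obj <- structure(list(
    gene = gene,
    protein_length = as.integer(protein_length),
    window = as.integer(window), sigma = sigma,
    curves = list(clinical = cl, population = po),
    clinical_norm = norm$clinical$values,
    population_norm = norm$population$values,
    delta = delta,
    edge_flag = cl$edge_flag,
    masked = cl$masked | po$masked,
    min_region_length = as.integer(min_region_length)
  ), class = "tolerance_profile")
  obj$regions <- call_sensitive_regions(
    delta, min_length = min_region_length, ignore_edges = TRUE,
    edge_flag = obj$edge_flag,
    clinical_positions = cl$positions,
    population_positions = po$positions)
  obj
}

#' @export
print.tolerance_profile <- function(x, ...) {
  cat(sprintf("Missense tolerance profile: %s (%d aa, window %d, sigma %.2f)\n",
              x$gene, x$protein_length, x$window, x$sigma))
  cat(sprintf("  clinical variants: %d   population variants: %d\n",
              x$curves$clinical$n_variants, x$curves$population$n_variants))
  cat(sprintf("  sensitive regions: %d\n", nrow(x$regions)))
  invisible(x)
}

#' Summarize a tolerance profile
#'
#' @param object a `tolerance_profile`.
#' @param ... ignored.
#' @return the profile's sensitive-region table, invisibly, after printing a
#'   short report.
#' @export
summary.tolerance_profile <- function(object, ...) {
  print(object)
  if (nrow(object$regions)) {
    cat("\nSensitive regions (delta < 0):\n")
    print(format(object$regions, digits = 3), row.names = FALSE)
  } else {
    cat("\nNo sensitive regions called.\n")
  }
  invisible(object$regions)
}

#' Per-residue curve table of a tolerance profile
#'
#' @param x a `tolerance_profile`.
#' @param ... ignored.
#' @return data.frame with columns `residue`, `clinical_raw`,
#'   `population_raw`, `clinical_norm`, `population_norm`, `delta`,
#'   `edge_flag`, `masked_flag`.
#' @export
as.data.frame.tolerance_profile <- function(x, ...) {
  data.frame(
    residue = seq_len(x$protein_length),
    clinical_raw = x$curves$clinical$values,
    population_raw = x$curves$population$values,
    clinical_norm = x$clinical_norm,
    population_norm = x$population_norm,
    delta = x$delta,
    edge_flag = x$edge_flag,
    masked_flag = x$masked
  )
}
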