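# Figure rendering: tolerance-curve overlays with a delta panel, and exon
# maps with truncation lollipops.  All coordinate arithmetic lives in pure
# layout functions so it can be unit-tested without a graphics device;
# drawing is side-effect-only.  Color conventions: clinical red, population
# blue (curves) / black (exon-map marks), masked intervals pink, sensitive
# regions shaded red.

.open_device <- function(path, width, height) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = grDevices::png(path, width = width, height = height,
                         units = "in", res = 150),
    svg = grDevices::svg(path, width = width, height = height),
    pdf = grDevices::pdf(path, width = width, height = height),
    stop(errorCondition(sprintf("unsupported figure extension .%s", ext),
                        class = c("senscan_io_error", "senscan_error"))))
}

#' Plot a tolerance profile
#'
#' Two stacked panels: the normalized clinical (red) and population (blue)
#' curves, and the delta curve with sensitive regions shaded; masked
#' intervals are shaded pink in both panels.  An optional domain track
#' (`label`, `start`, `end`, `color`) is drawn beneath.
#'
#' @param profile a `tolerance_profile`.
#' @param track optional domain-track data.frame.
#' @param path output file (`.png`, `.svg` or `.pdf`); `NULL` draws on the
#'   current device.
#' @param width,height device size in inches.
#' @return the path, invisibly.
#' @export
plot_profile <- function(profile, track = NULL, path = NULL,
                         width = 9, height = 6) {
  if (!is.null(path)) {
    .open_device(path, width, height)
    on.exit(grDevices::dev.off())
  }
  L <- profile$protein_length
  n_panels <- if (is.null(track)) 2L else 3L
  heights <- if (n_panels == 2L) c(2, 2) else c(2, 2, 0.6)
  old <- graphics::par(mfrow = c(n_panels, 1),
                       mar = c(2.5, 4, 1.5, 1), mgp = c(2.2, 0.7, 0))
  on.exit(graphics::par(old), add = TRUE)

  shade_mask <- function(ylim) {
    if (!any(profile$masked)) return(invisible())
    r <- rle(profile$masked)
    e <- cumsum(r$lengths); s <- e - r$lengths + 1L
    for (k in which(r$values)) {
      graphics::rect(s[k], ylim[1], e[k], ylim[2],
                     col = grDevices::adjustcolor("hotpink", 0.25),
                     border = NA)
    }
  }

  # panel 1: normalized curve overlay
  ymax <- max(profile$clinical_norm, profile$population_norm, 1e-9)
  graphics::plot(NA, xlim = c(1, L), ylim = c(0, ymax * 1.05),
                 xlab = "", ylab = "normalized tolerance value",
                 main = sprintf("%s missense tolerance (window %d)",
                                profile$gene, profile$window))
  shade_mask(c(0, ymax * 1.05))
  graphics::lines(seq_len(L), profile$clinical_norm, col = "red", lwd = 1.5)
  graphics::lines(seq_len(L), profile$population_norm, col = "blue",
                  lwd = 1.5)
  graphics::legend("topright", c("clinical", "population"),
                   col = c("red", "blue"), lwd = 1.5, bty = "n", cex = 0.8)

  # panel 2: delta with sensitive-region shading
  yl <- range(profile$delta, 0)
  graphics::plot(NA, xlim = c(1, L), ylim = yl,
                 xlab = "residue", ylab = "delta (population - clinical)")
  if (nrow(profile$regions)) {
    for (k in seq_len(nrow(profile$regions))) {
      graphics::rect(profile$regions$start[k], yl[1],
                     profile$regions$end[k], 0,
                     col = grDevices::adjustcolor("red", 0.15), border = NA)
    }
  }
  shade_mask(yl)
  graphics::abline(h = 0, col = "grey60")
  graphics::lines(seq_len(L), profile$delta, col = "grey20", lwd = 1.5)

  if (!is.null(track)) {
    graphics::plot(NA, xlim = c(1, L), ylim = c(0, 1), axes = FALSE,
                   xlab = "", ylab = "")
    for (k in seq_len(nrow(track))) {
      graphics::rect(track$start[k], 0.2, track$end[k], 0.8,
                     col = as.character(track$color[k]), border = "grey30")
      graphics::text((track$start[k] + track$end[k]) / 2, 0.5,
                     track$label[k], cex = 0.6)
    }
  }
  invisible(path)
}

#' @rdname plot_profile
#' @param x a `tolerance_profile`.
#' @param ... passed to [plot_profile()].
#' @export
plot.tolerance_profile <- function(x, ...) plot_profile(x, ...)

#' Exon-map layout coordinates
#'
#' Pure placement logic for [plot_exon_map()]: exon boxes keep their true
#' coding width while every intron is divided by `intron_scale` (one ratio
#' per gene, as in published maps).  Truncation marks are placed at their
#' CDS nucleotide.
#'
#' @param transcript a [transcript_model()].
#' @param intron_scale divisor applied to intron widths (1 = true scale).
#' @return list with `exons` (data.frame `x0`, `x1`, per-exon plot spans)
#'   and `nt_to_x`, a function mapping CDS nucleotide to plot coordinate.
#' @export
exon_map_layout <- function(transcript, intron_scale = 1) {
  if (intron_scale <= 0) {
    stop(errorCondition("intron_scale must be > 0",
                        class = c("senscan_config_error", "senscan_error")))
  }
  widths <- transcript$cds_exon_lengths
  gaps <- numeric(transcript$n_exons)
  if (transcript$n_exons > 1L) {
    ex <- transcript$exons   # already ordered 5' -> 3'
    g <- if (transcript$strand == "+")
      ex$start[-1] - ex$end[-transcript$n_exons] - 1L
    else
      ex$start[-transcript$n_exons] - ex$end[-1] - 1L
    gaps[-1] <- pmax(g, 0) / intron_scale
  }
  x0 <- numeric(transcript$n_exons)
  x1 <- numeric(transcript$n_exons)
  cur <- 0
  for (k in seq_len(transcript$n_exons)) {
    cur <- cur + gaps[k]
    x0[k] <- cur
    x1[k] <- cur + widths[k]
    cur <- x1[k]
  }
  bounds <- c(0L, cumsum(widths))
  nt_to_x <- function(nt) {
    ex <- cds_to_exon(transcript, nt)
    x0[ex] + (nt - bounds[ex] - 1L) + 0.5
  }
  list(exons = data.frame(exon = seq_len(transcript$n_exons),
                          x0 = x0, x1 = x1),
       nt_to_x = nt_to_x)
}

#' Plot an exon map with truncation lollipops
#'
#' Exon boxes to coding scale with introns shrunk by `intron_scale`;
#' population truncation marks above the boxes in black, clinical below in
#' red.  Marks sharing a nucleotide position are jittered vertically.
#'
#' @param transcript a [transcript_model()].
#' @param calls list of `truncation_call` objects (see
#'   [classify_truncation()]).
#' @param intron_scale per-gene intron shrink ratio (> 0).
#' @param path output file (`.png`, `.svg`, `.pdf`); `NULL` draws on the
#'   current device.
#' @param width,height device size in inches.
#' @return the path, invisibly.
#' @export
plot_exon_map <- function(transcript, calls = list(), intron_scale = 1,
                          path = NULL, width = 9, height = 3) {
  layout <- exon_map_layout(transcript, intron_scale)
  if (!is.null(path)) {
    .open_device(path, width, height)
    on.exit(grDevices::dev.off())
  }
  xmax <- max(layout$exons$x1)
  graphics::plot(NA, xlim = c(0, xmax), ylim = c(-1.6, 1.6), axes = FALSE,
                 xlab = "", ylab = "",
                 main = sprintf("%s exon map (introns 1:%g)",
                                transcript$gene, intron_scale))
  graphics::rect(layout$exons$x0, -0.35, layout$exons$x1, 0.35,
                 col = "lightsteelblue", border = "grey30")
  graphics::text((layout$exons$x0 + layout$exons$x1) / 2, 0,
                 layout$exons$exon, cex = 0.7)
  if (length(calls)) {
    xs <- vapply(calls, function(cl) layout$nt_to_x(cl$cds_position),
                 numeric(1))
    src <- vapply(calls, function(cl) {
      s <- cl$variant$source
      if (is.na(s)) "population" else s
    }, character(1))
    for (side in c("population", "clinical")) {
      sel <- which(src == side)
      if (!length(sel)) next
      sgn <- if (side == "population") 1 else -1
      col <- if (side == "population") "black" else "red"
      # vertical jitter for stacked marks at the same position
      lev <- stats::ave(seq_along(sel), xs[sel], FUN = seq_along)
      y <- sgn * (0.6 + 0.25 * (lev - 1))
      graphics::segments(xs[sel], sgn * 0.35, xs[sel], y, col = col)
      graphics::points(xs[sel], y, pch = 19, col = col, cex = 0.6)
    }
  }
  invisible(path)
}
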