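#' Render a pseudo-colored differential overlay
#'
#' Min-max scales the overlay to \eqn{[0, 1]} and maps it through a
#' perceptually uniform colormap, producing the familiar pseudo-colored
#' differential image in which bright regions are the moving (contractile)
#' parts of the field. An all-constant overlay maps to the colormap floor.
#'
#' @param overlay H x W numeric matrix (e.g. from [movement_index()]).
#' @param out_path Output PNG path.
#' @param colormap Palette name accepted by [grDevices::hcl.colors()]
#'   (default `"viridis"`).
#' @return `out_path`, invisibly.
#' @export
render_pseudocolor <- function(overlay, out_path, colormap = "viridis") {
  if (!is.matrix(overlay) || !all(is.finite(overlay))) {
    stop_classed("parameter_error", "`overlay` must be a finite numeric matrix")
  }
  rng <- range(overlay)
  scaled <- if (rng[2] > rng[1]) (overlay - rng[1]) / (rng[2] - rng[1])
            else matrix(0, nrow(overlay), ncol(overlay))
  n_colors <- 256L
  pal <- grDevices::hcl.colors(n_colors, palette = colormap)
  idx <- pmin(n_colors, 1L + floor(scaled * (n_colors - 1L) + 0.5))
  rgb <- grDevices::col2rgb(pal[idx]) / 255
  img <- array(0, dim = c(nrow(overlay), ncol(overlay), 3))
  img[, , 1] <- matrix(rgb[1, ], nrow(overlay))
  img[, , 2] <- matrix(rgb[2, ], nrow(overlay))
  img[, , 3] <- matrix(rgb[3, ], nrow(overlay))
  ok <- tryCatch({
    png::writePNG(img, out_path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_classed("io_error", "could not write PNG to %s", out_path)
  invisible(out_path)
}
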