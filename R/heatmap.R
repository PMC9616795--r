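# Density heatmaps of cell positions: per-grid-point kernel counts within a
# fixed sampling radius, a capped display layer, and proportional
# extrapolation to cells/mm^2.

#' Kernel count grid over a cell field
#'
#' Places a regular grid (spacing `spacing_um`) over `extent` and, at each
#' grid point, counts the cells within `radius_um` (uniform disk kernel,
#' the default) or accumulates quartic (biweight) kernel weights.  The raw
#' count layer is always preserved; a display layer capped at `cap` mirrors
#' the color scaling of the source workflow (with a 150 um radius and cap 4,
#' a saturated pixel means at least 4 cells within a pi * 0.15^2 mm^2 disk).
#' No boundary correction is applied.
#'
#' @param cells cell table (or any data.frame with `x_um`, `y_um`).
#' @param extent numeric `c(xmin, xmax, ymin, ymax)` in micrometres; default
#'   the bounding box of the cells expanded by the radius.
#' @param radius_um sampling radius, default 150.
#' @param spacing_um grid spacing, default 10.
#' @param cap display cap in count units, default 4.
#' @param kernel `"uniform"` (disk counting) or `"quartic"` (visual parity
#'   only; not extrapolatable to densities).
#' @param marker optional marker flag name to restrict the counted cells.
#' @return object of class `heat_grid`: list with `x_um`, `y_um` (grid axes),
#'   `count` (matrix, rows = x, cols = y), `count_capped`, and the
#'   parameters.
#' @export
compute_heat_grid <- function(cells, extent = NULL, radius_um = 150,
                              spacing_um = 10, cap = 4,
                              kernel = c("uniform", "quartic"),
                              marker = NULL) {
  kernel <- match.arg(kernel)
  if (radius_um <= 0 || spacing_um <= 0)
    stop("radius_um and spacing_um must be > 0")
  if (!is.null(marker)) cells <- cells[cells[[marker]] == 1, , drop = FALSE]
  if (is.null(extent)) {
    if (nrow(cells) == 0) extent <- c(0, radius_um, 0, radius_um)
    else extent <- c(min(cells$x_um) - radius_um, max(cells$x_um) + radius_um,
                     min(cells$y_um) - radius_um, max(cells$y_um) + radius_um)
  }
  gx <- seq(extent[1], extent[2], by = spacing_um)
  gy <- seq(extent[3], extent[4], by = spacing_um)
  cnt <- matrix(0, nrow = length(gx), ncol = length(gy))
  if (nrow(cells) > 0) {
    rg <- ceiling(radius_um / spacing_um)
    for (i in seq_len(nrow(cells))) {
      cx <- cells$x_um[i]; cy <- cells$y_um[i]
      ix <- which(abs(gx - cx) <= radius_um)
      iy <- which(abs(gy - cy) <= radius_um)
      if (!length(ix) || !length(iy)) next
      d2 <- outer((gx[ix] - cx)^2, (gy[iy] - cy)^2, `+`)
      if (kernel == "uniform") {
        cnt[ix, iy] <- cnt[ix, iy] + (d2 <= radius_um^2)
      } else {
        u2 <- pmin(d2 / radius_um^2, 1)
        cnt[ix, iy] <- cnt[ix, iy] + 3 / pi * (1 - u2)^2 * (d2 <= radius_um^2)
      }
    }
  }
  out <- list(x_um = gx, y_um = gy, count = cnt,
              count_capped = pmin(cnt, cap), radius_um = radius_um,
              spacing_um = spacing_um, cap = cap, kernel = kernel,
              extent = extent)
  class(out) <- "heat_grid"
  out
}

#' Print a `heat_grid` object
#' @param x the object
#' @param ... ignored
#' @return `x`, invisibly
#' @exportS3Method base::print
print.heat_grid <- function(x, ...) {
  cat("heat_grid:", length(x$x_um), "x", length(x$y_um), "points,",
      x$kernel, "kernel, radius", x$radius_um, "um, spacing", x$spacing_um,
      "um, cap", x$cap, "\n")
  invisible(x)
}

#' Extrapolate kernel counts to densities
#'
#' With the uniform disk kernel, a count of `k` cells within radius `r`
#' (in mm) extrapolates proportionally to `k / (pi r^2)` cells/mm^2.  The
#' uncapped count layer is used: extrapolating capped values would bias
#' densities downward.  Quartic-kernel grids cannot be extrapolated.
#'
#' @param grid a `heat_grid` from [compute_heat_grid()].
#' @return matrix of densities in cells/mm^2 (same shape as `grid$count`).
#' @export
extrapolate_density <- function(grid) {
  stopifnot(inherits(grid, "heat_grid"))
  if (grid$kernel != "uniform")
    stop("density extrapolation requires the uniform kernel")
  r_mm <- grid$radius_um / 1000
  grid$count / (pi * r_mm^2)
}

#' Export a heat grid with layer-boundary annotation
#'
#' Writes (or returns) the grid as a long table
#' `x_um, y_um, count, count_capped, density_per_mm2` plus one boundary row
#' per layer in an attached annotation table, for overlay on the stained
#' section.
#'
#' @param grid a `heat_grid` (uniform kernel).
#' @param layers optional [layer_annotation()]; boundary depths are exported
#'   alongside.
#' @param path optional base path; writes `<path>.tsv` and, with layers,
#'   `<path>_boundaries.tsv`.
#' @return list with `grid` (long data.frame) and `boundaries` (data.frame
#'   or `NULL`), invisibly when `path` is given.
#' @export
export_overlay <- function(grid, layers = NULL, path = NULL) {
  stopifnot(inherits(grid, "heat_grid"))
  dens <- if (grid$kernel == "uniform") extrapolate_density(grid) else
    matrix(NA_real_, nrow = length(grid$x_um), ncol = length(grid$y_um))
  long <- data.frame(
    x_um = rep(grid$x_um, times = length(grid$y_um)),
    y_um = rep(grid$y_um, each = length(grid$x_um)),
    count = as.vector(grid$count),
    count_capped = as.vector(grid$count_capped),
    density_per_mm2 = as.vector(dens))
  bounds <- NULL
  if (!is.null(layers) && nrow(layers))
    bounds <- data.frame(layer = layers$layer,
                         boundary_top_um = layers$depth_top_um,
                         boundary_bottom_um = layers$depth_bottom_um)
  if (!is.null(path)) {
    write.table(long, paste0(path, ".tsv"), sep = "\t", row.names = FALSE,
                quote = FALSE)
    if (!is.null(bounds))
      write.table(bounds, paste0(path, "_boundaries.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
    return(invisible(list(grid = long, boundaries = bounds)))
  }
  list(grid = long, boundaries = bounds)
}

#' Plot a heat grid
#'
#' Displays the capped count layer with layer boundaries as horizontal
#' lines, pial surface at the top.
#'
#' @param x a `heat_grid`.
#' @param layers optional [layer_annotation()].
#' @param ... passed to [graphics::image()].
#' @return the grid, invisibly.
#' @export
plot.heat_grid <- function(x, layers = NULL, ...) {
  graphics::image(x$x_um, x$y_um, x$count_capped, ylim = rev(range(x$y_um)),
                  xlab = "x (um)", ylab = "depth from pial surface (um)",
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  if (!is.null(layers))
    graphics::abline(h = c(layers$depth_top_um, max(layers$depth_bottom_um)),
                     lty = 3)
  invisible(x)
}
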