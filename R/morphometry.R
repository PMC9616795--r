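# Shape-based classification of microglia: migratory vs non-migratory by
# circularity, radial vs tangential by major-axis orientation.

#' Circularity of a cell outline
#'
#' The standard Fiji shape descriptor `4 * pi * area / perimeter^2`: 1 for a
#' perfect circle, smaller for elongated or convoluted outlines.  Values
#' above 1 (possible with discretised perimeters) are clamped to 1.
#'
#' @param area_um2 outline area in square micrometres (> 0).
#' @param perimeter_um outline perimeter in micrometres (> 0).
#' @return circularity in (0, 1].
#' @examples
#' circularity(pi * 10^2, 2 * pi * 10)  # circle: 1
#' circularity(4, 8)                    # unit square: pi/4
#' @export
circularity <- function(area_um2, perimeter_um) {
  if (any(area_um2 <= 0) || any(perimeter_um <= 0))
    stop("area and perimeter must be > 0")
  pmin(4 * pi * area_um2 / perimeter_um^2, 1)
}

#' Classify the migratory phenotype from circularity
#'
#' Cells with circularity below the cutoff (default 0.3) are labelled
#' `migratory`, others `non_migratory`.  A cell exactly at the cutoff is
#' non-migratory (documented tie rule; the defining inequalities are strict).
#' The label is a morphometric phenotype, not a measurement of displacement.
#'
#' @param circ circularity values in (0, 1].
#' @param cutoff circularity threshold, default 0.3.
#' @return factor with levels `migratory`, `non_migratory`.
#' @export
classify_migratory <- function(circ, cutoff = 0.3) {
  factor(ifelse(circ < cutoff, "migratory", "non_migratory"),
         levels = c("migratory", "non_migratory"))
}

#' Acute angle between the cell major axis and the layer plane
#'
#' Orientations are axial (a major axis at theta and theta + 180 is the same
#' axis), so the angle to the layer-tangential direction is folded to
#' [0, 90]:  `min(d, 180 - d)` where `d` is the absolute direction
#' difference modulo 180.
#'
#' @param theta_deg major-axis orientation in degrees (any real).
#' @param layer_tangent_deg tangential direction of the layer plane
#'   (default 0: columns are extracted normal to the pial surface, so the
#'   x-axis is tangential).
#' @return folded angle in [0, 90].
#' @export
orientation_angle <- function(theta_deg, layer_tangent_deg = 0) {
  d <- (theta_deg - layer_tangent_deg) %% 180
  pmin(d, 180 - d)
}

#' Classify the direction of migration from the folded angle
#'
#' Angles below 45 degrees are `tangential` (movement along the layer
#' plane), above 45 degrees `radial` (along the radial glia scaffold).
#' Exactly 45 degrees resolves to `radial` (documented tie rule).
#'
#' @param angle_deg folded angle in [0, 90] (see [orientation_angle()]).
#' @param cutoff angle threshold in degrees, default 45.
#' @return factor with levels `tangential`, `radial`.
#' @export
classify_direction <- function(angle_deg, cutoff = 45) {
  if (any(angle_deg < 0 | angle_deg > 90))
    stop("angle_deg must lie in [0, 90]; fold with orientation_angle() first")
  factor(ifelse(angle_deg < cutoff, "tangential", "radial"),
         levels = c("tangential", "radial"))
}

#' Per-layer migration profile
#'
#' Computes, for each annotated layer, the fraction of cells with the
#' migratory phenotype and the split of migratory cells into radial and
#' tangential movers.  Layers containing no cells are reported as `NA`
#' fractions rather than zero.  Cells outside the annotated depth span are
#' excluded (they appear in the `unassigned` attribute count).
#'
#' @param cells cell table (see [read_cell_table()]).
#' @param layers a [layer_annotation()].
#' @param circularity_cutoff,angle_cutoff_deg classification thresholds.
#' @return data.frame with columns `layer`, `n_cells`, `fraction_migratory`,
#'   `fraction_radial_of_migratory`, `fraction_tangential_of_migratory`.
#' @export
migration_summary <- function(cells, layers, circularity_cutoff = 0.3,
                              angle_cutoff_deg = 45) {
  validate_cells(cells)
  lay <- assign_layer(cells$y_um, layers)
  circ <- circularity(cells$area_um2, cells$perimeter_um)
  migr <- classify_migratory(circ, circularity_cutoff) == "migratory"
  ang <- orientation_angle(cells$theta_deg)
  radial <- classify_direction(ang, angle_cutoff_deg) == "radial"
  out <- lapply(layers$layer, function(ln) {
    sel <- !is.na(lay) & lay == ln
    n <- sum(sel)
    if (n == 0)
      return(data.frame(layer = ln, n_cells = 0L, fraction_migratory = NA_real_,
                        fraction_radial_of_migratory = NA_real_,
                        fraction_tangential_of_migratory = NA_real_))
    nm <- sum(migr[sel])
    data.frame(layer = ln, n_cells = n, fraction_migratory = nm / n,
               fraction_radial_of_migratory =
                 if (nm > 0) sum(radial[sel] & migr[sel]) / nm else NA_real_,
               fraction_tangential_of_migratory =
                 if (nm > 0) 1 - sum(radial[sel] & migr[sel]) / nm else NA_real_)
  })
  out <- do.call(rbind, out)
  attr(out, "unassigned") <- sum(is.na(lay))
  out
}
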