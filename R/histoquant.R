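# Core histological statistics: density, proliferative/apoptotic indices,
# marker ratios, growth-fold-change correction, per-layer quantification.

#' Assign cells to layers by depth
#'
#' Half-open rule: a cell belongs to layer `[top, bottom)`; a cell exactly at
#' a boundary depth belongs to the deeper interval's start.
#'
#' @param y_um depths from the pial surface in micrometres.
#' @param layers a [layer_annotation()].
#' @return character vector of layer names; `NA` when outside all layers.
#' @export
assign_layer <- function(y_um, layers) {
  idx <- findInterval(y_um, c(layers$depth_top_um, layers$depth_bottom_um[nrow(layers)]),
                      rightmost.closed = FALSE, left.open = FALSE)
  out <- rep(NA_character_, length(y_um))
  inside <- idx >= 1 & idx <= nrow(layers) &
    y_um < layers$depth_bottom_um[nrow(layers)]
  out[inside] <- layers$layer[idx[inside]]
  out
}

#' Marker count summary for one analysed region
#'
#' Holds the numerators and denominators behind the density and index
#' formulas: total IBA1+ cells, IBA1+Ki67+ and IBA1+Casp3+ double positives,
#' TMEM119+ cells, and the analysed area.
#'
#' @param cells cell table, or `NULL` to pass counts directly.
#' @param area_mm2 analysed area in square millimetres (> 0).
#' @param n_total_iba1,n_double_ki67,n_double_casp3,n_tmem119 direct counts
#'   (used when `cells` is `NULL`).
#' @return list of class `count_summary`.
#' @export
count_summary <- function(cells = NULL, area_mm2, n_total_iba1 = 0,
                          n_double_ki67 = 0, n_double_casp3 = 0,
                          n_tmem119 = 0) {
  if (area_mm2 <= 0) stop("area_mm2 must be > 0")
  if (!is.null(cells)) {
    validate_cells(cells)
    n_total_iba1 <- sum(cells$iba1 == 1)
    n_double_ki67 <- sum(cells$iba1 == 1 & cells$ki67 == 1)
    n_double_casp3 <- sum(cells$iba1 == 1 & cells$casp3 == 1)
    n_tmem119 <- sum(cells$tmem119 == 1)
  }
  if (n_double_ki67 > n_total_iba1 || n_double_casp3 > n_total_iba1)
    stop("double-positive counts cannot exceed the total IBA1 count")
  out <- list(n_total_iba1 = n_total_iba1, n_double_ki67 = n_double_ki67,
              n_double_casp3 = n_double_casp3, n_tmem119 = n_tmem119,
              analysed_area_mm2 = area_mm2)
  class(out) <- "count_summary"
  out
}

#' Cell density per square millimetre
#'
#' `N_D = number of marker-positive cells / area (mm^2)`.
#'
#' @param cells cell table.
#' @param area_mm2 analysed area in square millimetres (> 0).
#' @param marker which marker flag to count (default `"iba1"`).
#' @return density in cells per mm^2.
#' @export
compute_density <- function(cells, area_mm2, marker = "iba1") {
  if (area_mm2 <= 0) stop("area_mm2 must be > 0")
  if (!marker %in% c("iba1", "ki67", "casp3", "tmem119"))
    stop("unknown marker: ", marker)
  sum(cells[[marker]] == 1) / area_mm2
}

#' Proliferative index
#'
#' `I = 100 * (IBA1+Ki67+ double positives) / (total IBA1+ cells)`, in
#' percent.  Undefined (an error, never silently zero) when no IBA1+ cells
#' were counted, to avoid biasing cohort means.
#'
#' @param summary a [count_summary()].
#' @return percentage in [0, 100].
#' @export
proliferative_index <- function(summary) {
  if (summary$n_total_iba1 == 0)
    stop("proliferative index undefined: no IBA1+ cells counted")
  100 * summary$n_double_ki67 / summary$n_total_iba1
}

#' Apoptotic index
#'
#' Percentage of IBA1+ cells double positive for cleaved caspase-3, with the
#' same contract as [proliferative_index()].
#'
#' @param summary a [count_summary()].
#' @return percentage in [0, 100].
#' @export
apoptotic_index <- function(summary) {
  if (summary$n_total_iba1 == 0)
    stop("apoptotic index undefined: no IBA1+ cells counted")
  100 * summary$n_double_casp3 / summary$n_total_iba1
}

#' Ratio of TMEM119+ to IBA1+ densities
#'
#' Percentage of the IBA1-labelled population also labelled by the
#' homeostatic marker TMEM119.  May exceed 100 (a warning, not an error),
#' e.g. when sampling noise inverts the densities.
#'
#' @param density_tmem119,density_iba1 densities in cells per mm^2.
#' @return percentage.
#' @export
marker_ratio <- function(density_tmem119, density_iba1) {
  if (density_iba1 <= 0)
    stop("marker ratio undefined: IBA1 density is zero")
  r <- 100 * density_tmem119 / density_iba1
  if (r > 100)
    warning("TMEM119/IBA1 ratio exceeds 100%")
  r
}

#' Growth series of brain size measures
#'
#' Ordered (canonical age, size) pairs: cortical wall thickness (um)
#' prenatally or brain weight (g) postnatally.  Interpolated
#' piecewise-linearly in canonical age when correcting densities.
#'
#' @param canonical_age_days strictly increasing ages.
#' @param size_measure positive sizes.
#' @return data.frame of class `growth_series`.
#' @export
growth_series <- function(canonical_age_days, size_measure) {
  if (any(diff(canonical_age_days) <= 0))
    stop("ages must be strictly increasing")
  if (any(size_measure <= 0)) stop("size measures must be > 0")
  out <- data.frame(canonical_age_days = canonical_age_days,
                    size_measure = size_measure)
  class(out) <- c("growth_series", "data.frame")
  out
}

#' Correct densities for brain growth
#'
#' Raw densities are diluted as the cortical wall (prenatally) or whole
#' brain (postnatally) grows; to recover population change, each raw density
#' is multiplied by the cumulative size fold-change relative to a reference
#' age: `corrected(t) = raw(t) * size(t) / size(reference_age)`.  The
#' cumulative fold change equals the product of the fold changes between
#' subsequent ages, so correcting against the previous age and chaining is
#' identical to correcting against the reference directly.  The direction is
#' configurable (`"divide"` interprets the correction the opposite way);
#' the proliferative index needs no correction (it is a ratio of counts,
#' independent of growth).
#'
#' @param cohort a cohort table with `canonical_age_days` and
#'   `density_per_mm2` columns (see [generate_cohort()]).
#' @param growth a [growth_series()] spanning the cohort ages.
#' @param reference_age canonical age (days) whose size defines the unit.
#' @param direction `"multiply"` (default) or `"divide"`.
#' @param allow_extrapolate if `FALSE` (default), ages outside the growth
#'   series span are an error.
#' @return the cohort with `corrected_density_per_mm2` filled in.
#' @export
growth_corrected_density <- function(cohort, growth, reference_age,
                                     direction = c("multiply", "divide"),
                                     allow_extrapolate = FALSE) {
  direction <- match.arg(direction)
  ages <- cohort$canonical_age_days
  rng <- range(growth$canonical_age_days)
  if (!allow_extrapolate &&
      (any(ages < rng[1] - 1e-9) || any(ages > rng[2] + 1e-9) ||
       reference_age < rng[1] - 1e-9 || reference_age > rng[2] + 1e-9))
    stop("age outside the growth-series span; set allow_extrapolate = TRUE ",
         "to extrapolate with the boundary size")
  size_at <- function(t) approx(growth$canonical_age_days, growth$size_measure,
                                xout = t, rule = 2)$y
  fold <- size_at(ages) / size_at(reference_age)
  cohort$corrected_density_per_mm2 <- if (direction == "multiply")
    cohort$density_per_mm2 * fold else cohort$density_per_mm2 / fold
  cohort
}

#' Per-layer cell density
#'
#' Assigns cells to annotated layers by the half-open depth rule and reports
#' the marker-positive count, layer area (thickness x column width) and
#' density for every layer.  Cells outside all layers are counted in an
#' `"unassigned"` row (with `NA` area/density), never silently dropped.
#'
#' @param cells cell table.
#' @param layers a [layer_annotation()].
#' @param marker marker flag to count (default `"iba1"`).
#' @return data.frame with columns `layer`, `count`, `area_mm2`, `density`.
#' @export
per_layer_density <- function(cells, layers, marker = "iba1") {
  validate_cells(cells)
  width_mm <- attr(layers, "column_width_um") / 1000
  lay <- assign_layer(cells$y_um, layers)
  pos <- cells[[marker]] == 1
  rows <- lapply(seq_len(nrow(layers)), function(i) {
    area <- (layers$depth_bottom_um[i] - layers$depth_top_um[i]) / 1000 * width_mm
    cnt <- sum(pos & !is.na(lay) & lay == layers$layer[i])
    data.frame(layer = layers$layer[i], count = cnt, area_mm2 = area,
               density = cnt / area)
  })
  out <- do.call(rbind, rows)
  rbind(out, data.frame(layer = "unassigned",
                        count = sum(pos & is.na(lay)),
                        area_mm2 = NA_real_, density = NA_real_))
}
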