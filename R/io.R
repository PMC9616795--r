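# Typed readers/writers for the tabular formats shared by every stage,
# canonical age handling, configuration and validation.

CELL_COLUMNS <- c("cell_id", "x_um", "y_um", "area_um2", "perimeter_um",
                  "major_um", "minor_um", "theta_deg",
                  "iba1", "ki67", "casp3", "tmem119")

#' Days per postnatal year and month
#'
#' Documented constants used by [canonical_age()]: a year is 365.25 days and
#' a month 30.44 days.  Term is fixed at 266 days post-conception (38 pcw),
#' so prenatal and postnatal ages live on one continuous axis.
#' @name age-constants
#' @keywords internal
DAYS_PER_YEAR <- 365.25
DAYS_PER_MONTH <- 30.44
TERM_DAYS <- 266

#' Convert an age to canonical days post-conception
#'
#' All lifespan analyses run on a single canonical age axis measured in days
#' since conception.  Prenatal ages in postconceptional weeks (pcw) map to
#' `7 * pcw`; postnatal ages map to `266 + age-in-days`, with term fixed at
#' 266 days (38 pcw), so the axis is continuous at birth.
#'
#' @param age_value numeric vector of positive ages.
#' @param age_unit one of `"pcw"`, `"postnatal_days"`, `"postnatal_months"`,
#'   `"postnatal_years"` (recycled against `age_value`).
#' @return numeric vector of days post-conception.
#' @examples
#' canonical_age(10, "pcw")            # 70
#' canonical_age(1, "postnatal_years") # 631.25
#' @export
canonical_age <- function(age_value, age_unit) {
  units <- c("pcw", "postnatal_days", "postnatal_months", "postnatal_years")
  age_unit <- rep_len(as.character(age_unit), length(age_value))
  bad <- !age_unit %in% units
  if (any(bad))
    stop("unknown age_unit: ", paste(unique(age_unit[bad]), collapse = ", "))
  if (any(!is.finite(age_value) | age_value < 0) ||
      any(age_value == 0 & age_unit == "pcw"))
    stop("age_value must be positive (postnatal age 0 = birth is allowed)")
  days <- ifelse(age_unit == "pcw", 7 * age_value,
          ifelse(age_unit == "postnatal_days", TERM_DAYS + age_value,
          ifelse(age_unit == "postnatal_months", TERM_DAYS + DAYS_PER_MONTH * age_value,
                 TERM_DAYS + DAYS_PER_YEAR * age_value)))
  as.numeric(days)
}

#' Convert canonical days back to postconceptional weeks
#' @param days numeric vector of days post-conception.
#' @return numeric vector of pcw.
#' @export
days_to_pcw <- function(days) days / 7

#' Convert canonical days to postnatal years (negative before term)
#' @param days numeric vector of days post-conception.
#' @return numeric vector of years since birth.
#' @export
days_to_postnatal_years <- function(days) (days - TERM_DAYS) / DAYS_PER_YEAR

validate_cells <- function(cells) {
  missing <- setdiff(CELL_COLUMNS, names(cells))
  if (length(missing))
    stop("cell table is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(cells) == 0) return(invisible(cells))
  num_cols <- c("x_um", "y_um", "area_um2", "perimeter_um", "major_um",
                "minor_um", "theta_deg")
  for (cn in num_cols) {
    v <- cells[[cn]]
    if (!is.numeric(v) || anyNA(v)) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(v))))
      stop("non-numeric value in column '", cn, "' at row(s) ",
           paste(head(bad, 5), collapse = ", "))
    }
  }
  chk <- function(cond, msg) {
    if (any(!cond)) stop(msg, " (row ", which(!cond)[1], ")")
  }
  chk(cells$area_um2 > 0, "area_um2 must be > 0")
  chk(cells$perimeter_um > 0, "perimeter_um must be > 0")
  chk(cells$minor_um > 0, "minor_um must be > 0")
  chk(cells$major_um >= cells$minor_um, "major_um must be >= minor_um")
  chk(cells$theta_deg >= 0 & cells$theta_deg < 180,
      "theta_deg must lie in [0, 180)")
  chk(cells$y_um >= 0, "y_um (depth from pial surface) must be >= 0")
  for (cn in c("iba1", "ki67", "casp3", "tmem119"))
    chk(cells[[cn]] %in% c(0L, 1L), paste0(cn, " must be 0/1"))
  invisible(cells)
}

#' Read a per-cell table
#'
#' Reads a CSV of detected cells with positions (micrometres; `y_um` is depth
#' from the pial surface), fitted-ellipse shape descriptors, binary marker
#' flags (IBA1, Ki67, cleaved caspase-3, TMEM119) and an optional layer
#' label.  Unknown columns are preserved; row order is stable.
#'
#' @param path path to a CSV file with a header.
#' @return a validated `data.frame` of cells.
#' @seealso [write_cell_table()]
#' @export
read_cell_table <- function(path) {
  cells <- read.csv(path, stringsAsFactors = FALSE)
  for (cn in c("iba1", "ki67", "casp3", "tmem119"))
    if (cn %in% names(cells)) cells[[cn]] <- as.integer(cells[[cn]])
  validate_cells(cells)
  cells
}

#' Write a per-cell table
#' @param cells data.frame as returned by [read_cell_table()].
#' @param path output CSV path.
#' @export
write_cell_table <- function(cells, path) {
  validate_cells(cells)
  write.csv(cells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a layer annotation
#'
#' An ordered set of contiguous, non-overlapping, half-open depth intervals
#' `[top, bottom)` partitioning a cortical column, e.g. the transient zones
#' MZ, CP, PSP/SP, IZ, SVZ, VZ.  Columns are `column_width_um` wide
#' (default 450).
#'
#' @param layer character vector of layer names (pial side first).
#' @param depth_top_um,depth_bottom_um numeric interval bounds in micrometres.
#' @param column_width_um lateral column width in micrometres.
#' @return a `data.frame` of class `layer_annotation`.
#' @export
layer_annotation <- function(layer, depth_top_um, depth_bottom_um,
                             column_width_um = 450) {
  if (length(layer) == 0) stop("at least one layer is required")
  if (column_width_um <= 0) stop("column_width_um must be > 0")
  ord <- order(depth_top_um)
  layer <- as.character(layer[ord])
  depth_top_um <- depth_top_um[ord]
  depth_bottom_um <- depth_bottom_um[ord]
  if (any(depth_bottom_um <= depth_top_um))
    stop("each layer must have depth_bottom_um > depth_top_um")
  if (length(layer) > 1 &&
      any(abs(depth_top_um[-1] - depth_bottom_um[-length(layer)]) > 1e-9))
    stop("layer intervals must be contiguous")
  out <- data.frame(layer = layer, depth_top_um = depth_top_um,
                    depth_bottom_um = depth_bottom_um,
                    stringsAsFactors = FALSE)
  attr(out, "column_width_um") <- column_width_um
  class(out) <- c("layer_annotation", "data.frame")
  out
}

#' Read a layer annotation from CSV
#' @param path CSV with columns `layer,depth_top_um,depth_bottom_um`.
#' @param column_width_um lateral column width in micrometres.
#' @return a `layer_annotation`.
#' @export
read_layer_annotation <- function(path, column_width_um = 450) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("layer", "depth_top_um", "depth_bottom_um")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("layer table is missing column(s): ", paste(missing, collapse = ", "))
  layer_annotation(d$layer, d$depth_top_um, d$depth_bottom_um,
                   column_width_um = column_width_um)
}

#' Write a layer annotation to CSV
#' @param layers a `layer_annotation`.
#' @param path output CSV path.
#' @export
write_layer_annotation <- function(layers, path) {
  write.csv(as.data.frame(layers)[c("layer", "depth_top_um", "depth_bottom_um")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read case metadata
#'
#' Per-case age (+ unit), sex, region and optional growth measures (wall
#' thickness in micrometres prenatally, brain weight in grams postnatally).
#' Adds a `canonical_age_days` column via [canonical_age()].
#'
#' @param path CSV with columns
#'   `case_id,age_value,age_unit,sex,region[,wall_thickness_um,brain_weight_g]`.
#' @return a `data.frame` with `canonical_age_days` appended.
#' @export
read_case_metadata <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "age_value", "age_unit", "sex", "region")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "))
  if (!all(d$sex %in% c("F", "M", "unknown")))
    stop("sex must be one of F, M, unknown")
  d$canonical_age_days <- canonical_age(d$age_value, d$age_unit)
  d
}

#' Read an expression matrix (TPM)
#'
#' Accepts either a TSV (`gene_id` column plus one column per sample) or a
#' MatrixMarket `.mtx` triplet with `genes.tsv` / `samples.tsv` sidecars in
#' the same directory (one identifier per line).  Sample metadata
#' (`sample_id`, `timepoint_pcw`, optional `region`) is joined from
#' `sample_meta`, a data.frame or the path of a TSV.
#'
#' @param path path to the TSV or `.mtx` file.
#' @param sample_meta sample metadata with columns `sample_id` and
#'   `timepoint_pcw` (and optionally `region`).
#' @return an object of class `expression_matrix`: a list with `tpm`
#'   (genes x samples matrix) and `samples` (metadata data.frame).
#' @export
read_expression_matrix <- function(path, sample_meta) {
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    dir <- dirname(path)
    genes <- readLines(file.path(dir, "genes.tsv"))
    samples <- readLines(file.path(dir, "samples.tsv"))
    if (nrow(m) != length(genes) || ncol(m) != length(samples))
      stop("mtx dimensions do not match genes.tsv/samples.tsv sidecars")
    rownames(m) <- genes
    colnames(m) <- samples
  } else {
    d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (!"gene_id" %in% names(d)) stop("TSV must have a gene_id column")
    m <- as.matrix(d[setdiff(names(d), "gene_id")])
    rownames(m) <- d$gene_id
  }
  expression_matrix(m, sample_meta)
}

#' Construct and validate an expression matrix object
#' @param tpm numeric genes x samples matrix of TPM values.
#' @param sample_meta data.frame (or TSV path) with `sample_id`,
#'   `timepoint_pcw`, optional `region`.
#' @return an `expression_matrix`.
#' @export
expression_matrix <- function(tpm, sample_meta) {
  if (is.character(sample_meta))
    sample_meta <- read.delim(sample_meta, stringsAsFactors = FALSE)
  dup <- duplicated(rownames(tpm))
  if (any(dup))
    stop("duplicate gene id(s): ",
         paste(unique(rownames(tpm)[dup]), collapse = ", "))
  if (any(tpm < 0)) stop("TPM values must be nonnegative")
  if (!all(c("sample_id", "timepoint_pcw") %in% names(sample_meta)))
    stop("sample metadata needs sample_id and timepoint_pcw columns")
  idx <- match(colnames(tpm), sample_meta$sample_id)
  if (anyNA(idx) || anyNA(sample_meta$timepoint_pcw[idx]))
    stop("every sample must have a timepoint: missing for ",
         paste(colnames(tpm)[is.na(idx)], collapse = ", "))
  out <- list(tpm = tpm, samples = sample_meta[idx, , drop = FALSE])
  class(out) <- "expression_matrix"
  out
}

#' Print a `expression_matrix` object
#' @param x the object
#' @param ... ignored
#' @return `x`, invisibly
#' @exportS3Method base::print
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$tpm), "genes x", ncol(x$tpm), "samples;",
      length(unique(x$samples$timepoint_pcw)), "timepoints\n")
  invisible(x)
}

#' Analysis configuration
#'
#' Aggregates the thresholds and parameters used across the pipeline, with
#' the field's published defaults: circularity cutoff 0.3 and angle cutoff
#' 45 degrees for migration phenotyping, TPM cutoff 2 with sample fraction
#' 0.8 for constitutive expression, MAD multiplier 3 for single-cell QC,
#' minimum 50 cells per age for cycling fractions, heatmap sampling radius
#' 150 um with display cap 4 and 10 um grid, and B = 100 bootstrap replicas
#' at alpha 0.05 for the excess-mass test.
#'
#' @param ... overrides for any default field.
#' @return a named list of class `microdyn_config`.
#' @export
microdyn_config <- function(...) {
  cfg <- list(
    circularity_cutoff = 0.3, angle_cutoff_deg = 45,
    tpm_cutoff = 2, sample_fraction = 0.8,
    mad_k = 3, min_cells_per_age = 50,
    heatmap = list(radius_um = 150, cap = 4, grid_um = 10),
    stats = list(B = 100, alpha = 0.05),
    growth_correction = "multiply",
    rng_seed = 1L
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  stopifnot(cfg$circularity_cutoff > 0, cfg$angle_cutoff_deg > 0,
            cfg$tpm_cutoff > 0, cfg$sample_fraction > 0,
            cfg$sample_fraction < 1, cfg$mad_k > 0,
            cfg$heatmap$radius_um > 0, cfg$heatmap$grid_um > 0,
            cfg$stats$B >= 1, cfg$stats$alpha > 0, cfg$stats$alpha < 1)
  class(cfg) <- "microdyn_config"
  cfg
}

#' Read a configuration file
#' @param path YAML file mirroring the [microdyn_config()] fields.
#' @return a `microdyn_config`.
#' @export
read_config <- function(path) {
  do.call(microdyn_config, yaml::read_yaml(path))
}

#' Write a configuration file
#' @param config a `microdyn_config`.
#' @param path output YAML path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
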