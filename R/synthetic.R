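# Synthetic-data generators: cortical-column point patterns, lifespan
# cohorts with planted proliferation/density waves, and TPM matrices with
# known gene classes.  Every generator is deterministic given (spec, seed)
# and returns the ground truth alongside the data.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

fold_theta <- function(theta) ((theta %% 180) + 180) %% 180

#' Specification of a synthetic cortical column
#'
#' Layers are filled with homogeneous Poisson point patterns of IBA1+ cells;
#' marker flags are Bernoulli with per-layer fractions.  A per-layer
#' migratory fraction of cells receives elongated shapes (aspect ratio drawn
#' from `migratory_aspect`, circularity from `migratory_circ`, below the
#' 0.3 phenotype cutoff by construction: microglial outlines are convoluted,
#' so the perimeter is set from the target circularity rather than from a
#' smooth ellipse).  Non-migratory cells are amoeboid (aspect ratio about
#' 1:1, high circularity).  Migratory cells are oriented radially (major
#' axis near 90 degrees to the layer plane) or tangentially (near 0) per the
#' `radial_fraction`.
#'
#' @param layers named numeric vector of layer thicknesses in micrometres
#'   (pial side first).
#' @param lambda_per_mm2 per-layer IBA1+ intensity (recycled).
#' @param ki67_fraction,casp3_fraction,tmem119_fraction per-layer marker
#'   fractions (recycled).
#' @param migratory_fraction per-layer fraction of migratory cells (recycled).
#' @param radial_fraction fraction of migratory cells oriented radially.
#' @param column_width_um lateral column width, default 450.
#' @param migratory_aspect,amoeboid_aspect aspect-ratio ranges.
#' @param migratory_circ,amoeboid_circ circularity ranges.
#' @param orientation_sd_deg angular noise around the radial/tangential axes.
#' @return list of class `column_spec`.
#' @export
column_spec <- function(layers = c(MZ = 150, CP = 400, SP = 500, IZ = 700,
                                   SVZ = 400, VZ = 250),
                        lambda_per_mm2 = 150,
                        ki67_fraction = 0.1, casp3_fraction = 0.02,
                        tmem119_fraction = 0.5,
                        migratory_fraction = 0.3, radial_fraction = 0.5,
                        column_width_um = 450,
                        migratory_aspect = c(3, 8),
                        amoeboid_aspect = c(1, 1.2),
                        migratory_circ = c(0.08, 0.28),
                        amoeboid_circ = c(0.6, 1),
                        orientation_sd_deg = 8) {
  if (any(layers <= 0)) stop("zero-thickness layer in spec")
  n <- length(layers)
  spec <- list(layers = layers,
               lambda_per_mm2 = rep_len(lambda_per_mm2, n),
               ki67_fraction = rep_len(ki67_fraction, n),
               casp3_fraction = rep_len(casp3_fraction, n),
               tmem119_fraction = rep_len(tmem119_fraction, n),
               migratory_fraction = rep_len(migratory_fraction, n),
               radial_fraction = radial_fraction,
               column_width_um = column_width_um,
               migratory_aspect = migratory_aspect,
               amoeboid_aspect = amoeboid_aspect,
               migratory_circ = migratory_circ,
               amoeboid_circ = amoeboid_circ,
               orientation_sd_deg = orientation_sd_deg)
  stopifnot(all(unlist(spec[c("ki67_fraction", "casp3_fraction",
                              "tmem119_fraction", "migratory_fraction")]) >= 0),
            all(unlist(spec[c("ki67_fraction", "casp3_fraction",
                              "tmem119_fraction", "migratory_fraction")]) <= 1),
            all(spec$lambda_per_mm2 >= 0), column_width_um > 0)
  class(spec) <- "column_spec"
  spec
}

#' Generate a cortical-column point pattern with known phenotypes
#'
#' @param spec a [column_spec()].
#' @param seed integer RNG seed.
#' @return list with `cells` (cell table), `layers` (a [layer_annotation()])
#'   and `truth` (per-cell layer, migratory flag and direction).
#' @export
generate_column <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "column_spec"))
  with_seed(seed, {
    tops <- cumsum(c(0, unname(spec$layers)))
    layers <- layer_annotation(names(spec$layers), tops[-length(tops)],
                               tops[-1], spec$column_width_um)
    width_mm <- spec$column_width_um / 1000
    cells <- list(); truth <- list(); id0 <- 0L
    for (i in seq_along(spec$layers)) {
      area_mm2 <- spec$layers[[i]] / 1000 * width_mm
      n <- rpois(1, spec$lambda_per_mm2[i] * area_mm2)
      if (n == 0) next
      migr <- runif(n) < spec$migratory_fraction[i]
      radial <- migr & runif(n) < spec$radial_fraction
      aspect <- ifelse(migr,
                       runif(n, spec$migratory_aspect[1], spec$migratory_aspect[2]),
                       runif(n, spec$amoeboid_aspect[1], spec$amoeboid_aspect[2]))
      circ <- ifelse(migr,
                     runif(n, spec$migratory_circ[1], spec$migratory_circ[2]),
                     runif(n, spec$amoeboid_circ[1], spec$amoeboid_circ[2]))
      area <- exp(rnorm(n, log(60), 0.3))           # cell body area, um^2
      minor <- 2 * sqrt(area / (pi * aspect))
      major <- aspect * minor
      perim <- sqrt(4 * pi * area / circ)
      theta <- ifelse(!migr, runif(n, 0, 180),
                      ifelse(radial, rnorm(n, 90, spec$orientation_sd_deg),
                             rnorm(n, 0, spec$orientation_sd_deg)))
      cells[[i]] <- data.frame(
        cell_id = sprintf("c%05d", id0 + seq_len(n)),
        x_um = runif(n, 0, spec$column_width_um),
        y_um = runif(n, tops[i], tops[i + 1]),
        area_um2 = area, perimeter_um = perim,
        major_um = major, minor_um = minor,
        theta_deg = fold_theta(theta),
        iba1 = 1L,
        ki67 = as.integer(runif(n) < spec$ki67_fraction[i]),
        casp3 = as.integer(runif(n) < spec$casp3_fraction[i]),
        tmem119 = as.integer(runif(n) < spec$tmem119_fraction[i]),
        layer = names(spec$layers)[i],
        stringsAsFactors = FALSE)
      truth[[i]] <- data.frame(
        cell_id = cells[[i]]$cell_id,
        layer = names(spec$layers)[i],
        migratory = migr,
        direction = ifelse(!migr, NA_character_,
                           ifelse(radial, "radial", "tangential")),
        stringsAsFactors = FALSE)
      id0 <- id0 + n
    }
    cells <- if (length(cells)) do.call(rbind, cells) else
      stats::setNames(data.frame(matrix(ncol = 13, nrow = 0)),
                      c(CELL_COLUMNS, "layer"))
    validate_cells(cells)
    list(cells = cells, layers = layers,
         truth = if (length(truth)) do.call(rbind, truth) else NULL)
  })
}

#' Specification of lifespan waves of proliferation and density
#'
#' The latent trajectories are Gaussian bumps on a baseline:
#' `P(t) = P0 + sum_j A_j exp(-(t - tau_j)^2 / (2 sigma_j^2))` (percent) and
#' `D(t) = D0 + sum_j B_j exp(-(t - tau_j - L_j)^2 / (2 sigma_j^2))`
#' (cells/mm^2), so each proliferation wave is followed, after a lag `L_j`,
#' by a density wave.  The apoptotic index tracks refinement phases:
#' `a(t) = 100 * gamma * max(0, -D'(t)) / D(t)` (percent, per-day relative
#' loss scaled by the free gain `gamma`).  Defaults plant proliferation
#' waves at 9 and 18 postconceptional weeks with a 1.5-week density lag,
#' baseline density 90 cells/mm^2 and baseline proliferation 2%, peaking
#' near 490 and 340 cells/mm^2.  Density noise is lognormal; index noise is
#' beta-binomial on counts (so indices stay in [0, 100]); overdispersion 0
#' means noise-free indices.
#'
#' @param centers_pcw proliferation wave centers, pcw.
#' @param sigma_days wave widths (days, recycled).
#' @param prolif_amplitude,density_amplitude wave amplitudes (% and
#'   cells/mm^2, recycled).
#' @param lag_days proliferation-to-density lag (days, recycled).
#' @param baseline_density,baseline_prolif baselines (cells/mm^2 and %).
#' @param gamma apoptosis response gain.
#' @param density_lognorm_sd lognormal sigma for observed density.
#' @param index_overdispersion beta-binomial overdispersion rho in [0, 1).
#' @param area_mm2 analysed area per case (sets index count denominators).
#' @return list of class `wave_spec` with a `curves` element of functions
#'   `P`, `D`, `dD`, `A` evaluating the latent trajectories.
#' @export
wave_spec <- function(centers_pcw = c(9, 18), sigma_days = 10.5,
                      prolif_amplitude = c(20, 12),
                      density_amplitude = c(400, 250),
                      lag_days = 10.5,
                      baseline_density = 90, baseline_prolif = 2,
                      gamma = 1, density_lognorm_sd = 0.12,
                      index_overdispersion = 0.02, area_mm2 = 2) {
  k <- length(centers_pcw)
  tau <- 7 * centers_pcw
  sigma <- rep_len(sigma_days, k)
  A <- rep_len(prolif_amplitude, k)
  B <- rep_len(density_amplitude, k)
  L <- rep_len(lag_days, k)
  stopifnot(all(sigma > 0), all(A >= 0), all(B >= 0),
            baseline_density > 0, baseline_prolif >= 0,
            baseline_prolif <= 100,
            index_overdispersion >= 0, index_overdispersion < 1)
  P <- function(t) baseline_prolif +
    Reduce(`+`, lapply(seq_len(k), function(j)
      A[j] * exp(-(t - tau[j])^2 / (2 * sigma[j]^2))))
  D <- function(t) baseline_density +
    Reduce(`+`, lapply(seq_len(k), function(j)
      B[j] * exp(-(t - tau[j] - L[j])^2 / (2 * sigma[j]^2))))
  dD <- function(t) Reduce(`+`, lapply(seq_len(k), function(j)
    B[j] * exp(-(t - tau[j] - L[j])^2 / (2 * sigma[j]^2)) *
      (-(t - tau[j] - L[j]) / sigma[j]^2)))
  Afun <- function(t) pmin(100, 100 * gamma * pmax(0, -dD(t)) / D(t))
  spec <- list(tau_days = tau, sigma_days = sigma, prolif_amplitude = A,
               density_amplitude = B, lag_days = L,
               baseline_density = baseline_density,
               baseline_prolif = baseline_prolif, gamma = gamma,
               density_lognorm_sd = density_lognorm_sd,
               index_overdispersion = index_overdispersion,
               area_mm2 = area_mm2,
               curves = list(P = P, D = D, dD = dD, A = Afun))
  class(spec) <- "wave_spec"
  spec
}

#' Default lifespan sampling design of a synthetic cohort
#'
#' Canonical ages (days post-conception) emulating the sampling design of a
#' real lifespan tissue cohort: dense coverage of the two fetal wave
#' windows (several cases per age around the density peaks), weekly
#' coverage of the remaining prenatal span, and a long thin baseline tail
#' through infancy and adulthood.
#'
#' @return numeric vector of canonical ages in days.
#' @export
lifespan_age_design <- function() {
  c(rep(c(67, 70, 73, 77, 80, 133, 136, 140), each = 3),
    seq(28, 56, 7), seq(91, 119, 7), seq(147, 196, 7),
    TERM_DAYS + c(0, 30, 91, 182, 365, 730),
    TERM_DAYS + DAYS_PER_YEAR * c(18, 25, 35, 45, 55, 65, 75))
}

#' Generate a lifespan cohort with planted waves
#'
#' Draws `n_cases` cases on `age_grid` (cycled), with per-case observed
#' density, proliferative index and apoptotic index around the latent
#' trajectories of the [wave_spec()].
#'
#' @param spec a [wave_spec()].
#' @param n_cases number of cases (>= 1); default the size of the sampling
#'   design.
#' @param age_grid canonical ages in days; default [lifespan_age_design()].
#' @param seed integer RNG seed.
#' @return list with `cohort` (per-case table) and `truth` (wave centers,
#'   density peak ages, and the latent curves).
#' @export
generate_cohort <- function(spec, n_cases = NULL,
                            age_grid = lifespan_age_design(), seed = 1L) {
  if (is.null(n_cases)) n_cases <- length(age_grid)
  stopifnot(inherits(spec, "wave_spec"), n_cases >= 1)
  if (any(age_grid <= 0))
    stop("age_grid outside model support (ages must be positive days)")
  with_seed(seed, {
    t <- rep_len(age_grid, n_cases)
    Dt <- spec$curves$D(t); Pt <- spec$curves$P(t); At <- spec$curves$A(t)
    d_obs <- Dt * exp(rnorm(n_cases, 0, spec$density_lognorm_sd))
    n_counted <- pmax(1L, round(d_obs * spec$area_mm2))
    draw_index <- function(p_pct, n) {
      p <- pmin(pmax(p_pct / 100, 0), 1)
      rho <- spec$index_overdispersion
      if (rho == 0) return(100 * p)
      M <- 1 / rho - 1
      pi_i <- rbeta(length(n), pmax(p * M, 1e-8), pmax((1 - p) * M, 1e-8))
      100 * rbinom(length(n), n, pi_i) / n
    }
    cohort <- data.frame(
      case_id = sprintf("case%03d", seq_len(n_cases)),
      canonical_age_days = t,
      sex = sample(c("F", "M"), n_cases, replace = TRUE),
      region = "frontal",
      density_per_mm2 = d_obs,
      corrected_density_per_mm2 = NA_real_,
      proliferative_index_pct = draw_index(Pt, n_counted),
      apoptotic_index_pct = draw_index(At, n_counted),
      stringsAsFactors = FALSE)
    truth <- list(prolif_peak_days = spec$tau_days,
                  density_peak_days = spec$tau_days + spec$lag_days,
                  lag_days = spec$lag_days,
                  curves = spec$curves)
    list(cohort = cohort, truth = truth)
  })
}

#' Specification of a synthetic TPM matrix with known gene classes
#'
#' Three planted classes: `On` genes exceed the TPM cutoff in every sample
#' at every timepoint; `Off` genes are zero everywhere; `Other` genes are
#' expressed at a random proper, nonempty subset of timepoints (sporadic
#' expression).  An optional differential-expression spike multiplies the
#' above-cutoff excess of selected On genes at one timepoint, so spiked
#' genes remain constitutively expressed.
#'
#' @param n_on,n_off,n_other class sizes.
#' @param timepoints_pcw timepoints (pcw).
#' @param samples_per_timepoint samples per timepoint (>= 1).
#' @param tpm_cutoff expression threshold (default 2).
#' @param on_meanlog,on_sdlog lognormal parameters of the above-cutoff
#'   excess of expressed values.
#' @param de_timepoint,de_n_up,de_n_down,de_lfc DE spike: timepoint, number
#'   of up/down genes, log2 fold change.
#' @return list of class `expr_spec`.
#' @export
expr_spec <- function(n_on = 100, n_off = 50, n_other = 25,
                      timepoints_pcw = c(9, 12, 16, 20),
                      samples_per_timepoint = 6, tpm_cutoff = 2,
                      on_meanlog = log(30), on_sdlog = 0.3,
                      de_timepoint = 16, de_n_up = 10, de_n_down = 10,
                      de_lfc = 2) {
  stopifnot(n_on >= 0, n_off >= 0, n_other >= 0,
            samples_per_timepoint >= 1,
            de_n_up + de_n_down <= n_on)
  spec <- as.list(environment())
  class(spec) <- "expr_spec"
  spec
}

#' Generate an expression matrix with known classes and DE gene sets
#'
#' @param spec an [expr_spec()].
#' @param seed integer RNG seed.
#' @return list with `expr` (an [expression_matrix()]), `classes` (named
#'   character vector of truth classes) and `de_truth` (up/down gene sets
#'   and the spiked timepoint).
#' @export
generate_expression <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "expr_spec"))
  if (spec$samples_per_timepoint < 1) stop("zero samples per timepoint")
  with_seed(seed, {
    tp <- spec$timepoints_pcw
    nt <- length(tp); ns <- spec$samples_per_timepoint
    genes <- c(sprintf("ON%04d", seq_len(spec$n_on)),
               sprintf("OFF%04d", seq_len(spec$n_off)),
               sprintf("OTH%04d", seq_len(spec$n_other)))
    classes <- stats::setNames(rep(c("On", "Off", "Other"),
                                   c(spec$n_on, spec$n_off, spec$n_other)), genes)
    sample_id <- paste0("s_", rep(tp, each = ns), "pcw_", rep(seq_len(ns), nt))
    m <- matrix(0, nrow = length(genes), ncol = nt * ns,
                dimnames = list(genes, sample_id))
    tp_of <- rep(tp, each = ns)
    rexc <- function(n) spec$tpm_cutoff +
      exp(rnorm(n, spec$on_meanlog, spec$on_sdlog))
    on_rows <- which(classes == "On")
    if (length(on_rows))
      m[on_rows, ] <- rexc(length(on_rows) * nt * ns)
    oth_rows <- which(classes == "Other")
    for (g in oth_rows) {
      k <- sample(seq_len(nt - 1), 1)              # proper, nonempty subset
      expressed <- sample(tp, k)
      cols <- tp_of %in% expressed
      m[g, cols] <- rexc(sum(cols))
    }
    de_up <- de_down <- character(0)
    if (spec$de_n_up + spec$de_n_down > 0 && length(on_rows)) {
      pick <- sample(on_rows, spec$de_n_up + spec$de_n_down)
      up <- pick[seq_len(spec$de_n_up)]
      down <- setdiff(pick, up)
      cols <- tp_of == spec$de_timepoint
      m[up, cols] <- spec$tpm_cutoff +
        (m[up, cols] - spec$tpm_cutoff) * 2^spec$de_lfc
      m[down, cols] <- spec$tpm_cutoff +
        (m[down, cols] - spec$tpm_cutoff) / 2^spec$de_lfc
      de_up <- genes[up]; de_down <- genes[down]
    }
    meta <- data.frame(sample_id = sample_id, timepoint_pcw = tp_of,
                       region = "telencephalon", stringsAsFactors = FALSE)
    list(expr = expression_matrix(m, meta), classes = classes,
         de_truth = list(up = de_up, down = de_down,
                         timepoint = spec$de_timepoint))
  })
}

#' Generate single-cell QC metrics with planted outliers
#'
#' Clean metric values are uniform (compact support, so no clean cell ever
#' strays beyond the MAD fence), and a fraction of cells is displaced to
#' `median +/- displace * MAD` on one random metric.
#'
#' @param n_cells number of cells.
#' @param metrics metric names.
#' @param outlier_fraction fraction of planted outliers.
#' @param displace displacement in (unscaled) MAD units, default 8.
#' @param seed integer RNG seed.
#' @return list with `metrics` (data.frame, `cell_id` first) and
#'   `truth_outlier` (logical vector).
#' @export
generate_qc_metrics <- function(n_cells = 500,
                                metrics = c("nCount", "nFeature",
                                            "percent_mt", "percent_rb"),
                                outlier_fraction = 0.05, displace = 8,
                                seed = 1L) {
  with_seed(seed, {
    centers <- stats::setNames(c(5000, 2000, 5, 20)[seq_along(metrics)], metrics)
    half <- centers * 0.4
    d <- data.frame(cell_id = sprintf("cell%05d", seq_len(n_cells)))
    for (mn in metrics)
      d[[mn]] <- runif(n_cells, centers[mn] - half[mn], centers[mn] + half[mn])
    n_out <- round(outlier_fraction * n_cells)
    out_idx <- sample(n_cells, n_out)
    for (i in out_idx) {
      mn <- sample(metrics, 1)
      med <- median(d[[mn]]); madu <- median(abs(d[[mn]] - med))
      d[[mn]][i] <- med + sample(c(-1, 1), 1) * displace * madu
    }
    list(metrics = d,
         truth_outlier = seq_len(n_cells) %in% out_idx)
  })
}

#' Generate single-cell annotations with a bimodal cycling profile
#'
#' Cells carry an age (pcw) and a cycling flag; the cycling probability has
#' Gaussian bumps at `peaks_pcw` on a small baseline.  One age can be given
#' fewer than `min_cells` cells to exercise the minimum-cell filter.
#'
#' @param ages_pcw ages sampled.
#' @param cells_per_age cells per age (recycled).
#' @param peaks_pcw cycling-probability peak ages.
#' @param baseline,amplitude,width_pcw cycling-probability curve parameters.
#' @param seed integer RNG seed.
#' @return list with `annotations` (data.frame `cell_id,age_pcw,cycling`)
#'   and `truth_curve` (function of age).
#' @export
generate_cycling_annotations <- function(ages_pcw = 7:24,
                                         cells_per_age = 400,
                                         peaks_pcw = c(9, 18),
                                         baseline = 0.05,
                                         amplitude = c(0.25, 0.18),
                                         width_pcw = 1.5, seed = 1L) {
  with_seed(seed, {
    amplitude <- rep_len(amplitude, length(peaks_pcw))
    curve <- function(a) baseline +
      Reduce(`+`, lapply(seq_along(peaks_pcw), function(j)
        amplitude[j] * exp(-(a - peaks_pcw[j])^2 / (2 * width_pcw^2))))
    n <- rep_len(cells_per_age, length(ages_pcw))
    age <- rep(ages_pcw, n)
    p <- curve(age)
    d <- data.frame(cell_id = sprintf("sc%06d", seq_along(age)),
                    age_pcw = age,
                    cycling = as.integer(runif(length(age)) < p))
    list(annotations = d, truth_curve = curve)
  })
}
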