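# Trajectory statistics: excess-mass multimodality testing with
# critical-bandwidth bootstrap calibration, mode/antimode estimation,
# temporal-window assignment, nonparametric comparisons, and trend fitting.

#' Empirical excess-mass multimodality statistic
#'
#' For a level `lambda`, the empirical excess mass over `m` disjoint
#' intervals is `E_{n,m}(lambda) = max sum_j [P_n(I_j) - lambda |I_j|]`.
#' The statistic for testing `k` against more than `k` modes is
#' `Delta_{n,k+1} = max_lambda [E_{n,k+1}(lambda) - E_{n,k}(lambda)]`,
#' maximised over the finite set of slopes between order statistics where
#' the optimal interval systems change.  For `k = 1`, `Delta` equals twice
#' the Hartigan dip statistic.
#'
#' @param x numeric sample (at least 3 distinct values for a meaningful
#'   statistic).
#' @param k null number of modes, default 1.
#' @return the nonnegative statistic `Delta_{n,k+1}`.
#' @seealso [dip_statistic()], [test_multimodality()]
#' @export
excess_mass_statistic <- function(x, k = 1) {
  x <- x[is.finite(x)]
  if (length(x) == 0) stop("empty sample")
  stopifnot(k >= 1)
  if (length(unique(x)) == 1) {
    warning("degenerate sample: all values identical")
    return(0)
  }
  if (length(unique(x)) < 3)
    warning("fewer than 3 distinct values: statistic is degenerate")
  .excess_mass_cpp(as.numeric(x), as.integer(k))
}

#' Hartigan dip statistic
#'
#' The sup-norm distance from the empirical CDF to the closest unimodal
#' CDF (convex below the mode, concave above it; an atom is allowed at the
#' mode).  Computed by bisection on the distance with an exact convexity
#' feasibility certificate, independent of the excess-mass construction.
#'
#' @param x numeric sample.
#' @return the dip (0 for n <= 1 or a point mass).
#' @export
dip_statistic <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) stop("empty sample")
  .dip_cpp(as.numeric(x))
}

count_kde_modes <- function(x, h, n_grid = 1024) {
  d <- density(x, bw = h, n = n_grid, cut = 4)
  y <- d$y
  sum(diff(sign(diff(y))) == -2)
}

#' Critical bandwidth for a k-modal kernel density estimate
#'
#' The smallest Gaussian-kernel bandwidth at which the KDE has at most `k`
#' modes (the mode count is nonincreasing in the bandwidth for the Gaussian
#' kernel), found by bisection.
#'
#' @param x numeric sample.
#' @param k target mode count.
#' @param tol relative bisection tolerance.
#' @return the critical bandwidth.
#' @export
critical_bandwidth <- function(x, k = 1, tol = 1e-3) {
  rng <- diff(range(x))
  if (rng == 0) return(.Machine$double.eps)
  lo <- rng * 1e-4
  hi <- rng
  while (count_kde_modes(x, lo) <= k && lo > rng * 1e-8) lo <- lo / 4
  while (count_kde_modes(x, hi) > k) hi <- hi * 2
  for (i in seq_len(ceiling(log2((hi - lo) / (hi * tol))))) {
    mid <- (lo + hi) / 2
    if (count_kde_modes(x, mid) <= k) hi <- mid else lo <- mid
  }
  hi
}

kde_modes <- function(x, h, k = NULL, n_grid = 2048) {
  d <- density(x, bw = h, n = n_grid, cut = 4)
  y <- d$y; g <- d$x
  s <- diff(sign(diff(y)))
  mi <- which(s == -2) + 1
  if (!is.null(k) && length(mi) > k)      # at the critical bandwidth a
    mi <- sort(mi[order(y[mi], decreasing = TRUE)[seq_len(k)]])  # merging
  anti <- numeric(0)                       # pair can linger numerically
  if (length(mi) > 1)
    for (j in seq_len(length(mi) - 1)) {
      seg <- mi[j]:mi[j + 1]
      anti <- c(anti, g[seg[which.min(y[seg])]])
    }
  list(modes = g[mi], antimodes = anti)
}

#' Bootstrap excess-mass test for multimodality
#'
#' Tests H0 "the distribution has (at most) `k` modes" against more than
#' `k` modes with the excess-mass statistic, calibrated by the
#' critical-bandwidth bootstrap: `B` replicas are drawn by smoothed
#' resampling from the KDE at the critical bandwidth for `k` modes
#' (variance-rescaled so the resamples match the sample variance), and the
#' p-value is the fraction of replicas whose statistic reaches the observed
#' one.  Small p rejects unimodality.  Modes and antimodes are estimated
#' from the KDE at the critical bandwidth for the accepted mode count.
#'
#' @param x numeric sample (n >= 10).
#' @param k null number of modes, default 1.
#' @param B bootstrap replicas, default 100.
#' @param alpha decision level, default 0.05.
#' @param seed integer RNG seed (mandatory: the calibration is stochastic).
#' @return object of class `mode_test`: statistic, p-value, B, alpha,
#'   modes, antimodes, bandwidth, decision
#'   (`"multimodal"` or `"unimodal_not_rejected"`).
#' @examples
#' r <- test_multimodality(c(rnorm(50), rnorm(50, 6)), seed = 7)
#' r$decision
#' @export
test_multimodality <- function(x, k = 1, B = 100, alpha = 0.05, seed) {
  x <- x[is.finite(x)]
  if (length(x) < 10)
    stop("insufficient sample: need n >= 10, got ", length(x))
  if (missing(seed) || is.null(seed))
    stop("a seed is required for the bootstrap calibration")
  if (B < 20) warning("B < 20 gives a very coarse p-value")
  n <- length(x)
  delta_obs <- excess_mass_statistic(x, k)
  h_k <- critical_bandwidth(x, k)
  xbar <- mean(x); s2 <- var(x)
  shrink <- 1 / sqrt(1 + h_k^2 / s2)
  delta_star <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      xs <- sample(x, n, replace = TRUE)
      y <- xbar + shrink * (xs - xbar + h_k * rnorm(n))
      excess_mass_statistic(y, k)
    }, numeric(1))
  })
  p <- mean(delta_star >= delta_obs)
  decision <- if (p <= alpha) "multimodal" else "unimodal_not_rejected"
  k_accept <- if (decision == "multimodal") k + 1 else k
  h_acc <- if (k_accept == k) h_k else critical_bandwidth(x, k_accept)
  mm <- kde_modes(x, h_acc, k = k_accept)
  # the KDE at its critical bandwidth can sit at the boundary of losing a
  # mode; nudge down minimally if the count collapsed below the accepted k
  if (length(mm$modes) < k_accept)
    mm <- kde_modes(x, h_acc * 0.999, k = k_accept)
  out <- list(statistic = delta_obs, p_value = p, B = B, alpha = alpha,
              modes = sort(mm$modes), antimodes = sort(mm$antimodes),
              bandwidth = h_acc, k_null = k, decision = decision, n = n)
  class(out) <- "mode_test"
  out
}

#' Print a `mode_test` object
#' @param x the object
#' @param ... ignored
#' @return `x`, invisibly
#' @param digits significant digits
#' @exportS3Method base::print
print.mode_test <- function(x, digits = 4, ...) {
  cat("Excess-mass multimodality test\n")
  cat(sprintf("  Delta_{n,%d} = %.*g, bootstrap p = %.*g (B = %d, n = %d)\n",
              x$k_null + 1, digits, x$statistic, digits, x$p_value, x$B, x$n))
  cat("  decision:", x$decision, "\n")
  cat("  modes:", paste(signif(x$modes, digits), collapse = ", "), "\n")
  if (length(x$antimodes))
    cat("  antimodes:", paste(signif(x$antimodes, digits), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a mode test result to JSON
#' @param x a `mode_test`.
#' @param path optional output path.
#' @return JSON string (invisibly when `path` is given).
#' @export
mode_test_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "mode_test"))
  j <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(j, path)
    return(invisible(j))
  }
  j
}

#' Temporal windows of human brain development
#'
#' The canonical lifespan windows on the days-post-conception axis:
#' embryonic (3-8 pcw), early fetal (9-15 pcw), mid-late fetal (16-25 pcw),
#' preterm (26-35 pcw), term (36 pcw-birth), neonatal (0-1 month), infant
#' (1-12 months), child (1-2 years), adult (>18 years).  Intervals are
#' half-open `[start, end)`; the 2-18-year gap (ages for which tissue is
#' essentially unobtainable) maps to `"unclassified"`.
#'
#' @return data.frame with `window`, `start_days`, `end_days`.
#' @export
temporal_windows <- function() {
  data.frame(
    window = c("embryonic", "early_fetal", "mid_late_fetal", "preterm",
               "term", "neonatal", "infant", "child", "unclassified",
               "adult"),
    start_days = c(3 * 7, 9 * 7, 16 * 7, 26 * 7, 36 * 7, TERM_DAYS,
                   TERM_DAYS + DAYS_PER_MONTH, TERM_DAYS + DAYS_PER_YEAR,
                   TERM_DAYS + 2 * DAYS_PER_YEAR, TERM_DAYS + 18 * DAYS_PER_YEAR),
    end_days = c(9 * 7, 16 * 7, 26 * 7, 36 * 7, TERM_DAYS,
                 TERM_DAYS + DAYS_PER_MONTH, TERM_DAYS + DAYS_PER_YEAR,
                 TERM_DAYS + 2 * DAYS_PER_YEAR, TERM_DAYS + 18 * DAYS_PER_YEAR,
                 Inf),
    stringsAsFactors = FALSE)
}

#' Assign canonical ages to temporal windows
#'
#' @param canonical_age_days positive ages in days post-conception.
#' @return character vector of window names (see [temporal_windows()]);
#'   ages before 3 pcw map to `"pre_embryonic"`.
#' @examples
#' assign_window(canonical_age(10, "pcw"))  # early_fetal
#' @export
assign_window <- function(canonical_age_days) {
  if (any(canonical_age_days <= 0)) stop("ages must be positive")
  w <- temporal_windows()
  idx <- findInterval(canonical_age_days, w$start_days)
  ifelse(idx == 0, "pre_embryonic", w$window[pmax(idx, 1)])
}

#' Tie-corrected Dunn pairwise z-tests after Kruskal-Wallis
#' @noRd
dunn_pairwise <- function(values, groups) {
  groups <- factor(groups)
  n <- length(values)
  r <- rank(values)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  lev <- levels(groups)
  mean_r <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  pairs <- utils::combn(lev, 2)
  z <- p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / n_g[a] + 1 / n_g[b]))
    z[j] <- (mean_r[a] - mean_r[b]) / se
    p[j] <- 2 * pnorm(-abs(z[j]))
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p = p,
             stringsAsFactors = FALSE)
}

#' Two-stage step-up FDR adjustment (Benjamini-Krieger-Yekutieli)
#'
#' Stage 1 runs a linear step-up procedure at `alpha / (1 + alpha)` to
#' estimate the number of true nulls `m0`; stage 2 reruns it with `m0` in
#' place of `m`.  Returned "adjusted p-values" are BH values scaled by
#' `m0 / m` (monotonised), so `adjusted p <= alpha` reproduces the
#' two-stage discovery set.
#'
#' @param p raw p-values.
#' @param alpha FDR level used to estimate `m0`, default 0.05.
#' @return adjusted p-values.
#' @export
p_adjust_bky <- function(p, alpha = 0.05) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  a1 <- alpha / (1 + alpha)
  r1 <- sum(p.adjust(p, "BH") <= a1)
  m0 <- m - r1
  if (m0 == 0) return(rep(0, m))
  pmin(1, p.adjust(p, "BH") * m0 / m)
}

#' Compare a measurement across temporal windows
#'
#' Kruskal-Wallis omnibus test on the per-case values grouped by temporal
#' window, followed by Dunn pairwise z-tests with either Bonferroni-Dunn or
#' two-stage Benjamini-Krieger-Yekutieli FDR adjustment.
#'
#' @param cohort cohort table with `canonical_age_days` and the value column.
#' @param value `"density"` or `"proliferation"` (or any column name).
#' @param windows optional precomputed window labels.
#' @param adjust `"two_stage_BKY_fdr"` (default) or `"dunn_bonferroni"`.
#' @param alpha level for the BKY stage-1 estimate.
#' @return list with `omnibus` (chi-squared statistic, df, p) and
#'   `pairwise` (data.frame with adjusted p-values).
#' @export
compare_windows <- function(cohort, value = c("density", "proliferation"),
                            windows = NULL,
                            adjust = c("two_stage_BKY_fdr", "dunn_bonferroni"),
                            alpha = 0.05) {
  adjust <- match.arg(adjust)
  col <- if (value[1] == "density") "density_per_mm2"
         else if (value[1] == "proliferation") "proliferative_index_pct"
         else value[1]
  if (!col %in% names(cohort)) stop("no column '", col, "' in cohort")
  v <- cohort[[col]]
  w <- if (is.null(windows)) assign_window(cohort$canonical_age_days) else windows
  keep <- !is.na(v) & !is.na(w) & w != "unclassified"
  v <- v[keep]; w <- factor(w[keep])
  usable <- names(which(table(w) >= 2))
  if (length(usable) < 2)
    stop("need at least 2 windows with at least 2 observations each")
  sel <- w %in% usable
  v <- v[sel]; w <- droplevels(w[sel])
  kw <- kruskal.test(v, w)
  pw <- dunn_pairwise(v, w)
  pw$p_adjusted <- if (adjust == "dunn_bonferroni")
    pmin(1, pw$p * nrow(pw)) else p_adjust_bky(pw$p, alpha)
  list(omnibus = list(statistic = unname(kw$statistic),
                      df = unname(kw$parameter), p = kw$p.value),
       pairwise = pw, adjust = adjust)
}

#' Two-sided nonparametric tests
#'
#' Uniform front end for the standard nonparametric tests used on cohort
#' measurements: two-sample Kolmogorov-Smirnov, Mann-Whitney U, paired
#' Wilcoxon, Friedman (y as a blocks x treatments matrix), and Spearman
#' correlation.  All two-sided.
#'
#' @param x numeric vector (or matrix for `friedman`).
#' @param y numeric vector (unused for `friedman`).
#' @param method test name.
#' @return list with `statistic` and `p`.
#' @export
nonparametric_test <- function(x, y = NULL,
                               method = c("ks_2samp", "mann_whitney",
                                          "wilcoxon_paired", "friedman",
                                          "spearman")) {
  method <- match.arg(method)
  if (method %in% c("wilcoxon_paired", "spearman") && length(x) != length(y))
    stop("paired methods require equal-length samples")
  res <- switch(method,
    ks_2samp = {
      k <- suppressWarnings(ks.test(x, y))
      list(statistic = unname(k$statistic), p = k$p.value)
    },
    mann_whitney = {
      k <- suppressWarnings(wilcox.test(x, y, exact = TRUE))
      list(statistic = unname(k$statistic), p = k$p.value)
    },
    wilcoxon_paired = {
      k <- suppressWarnings(wilcox.test(x, y, paired = TRUE))
      list(statistic = unname(k$statistic), p = k$p.value)
    },
    friedman = {
      k <- friedman.test(as.matrix(x))
      list(statistic = unname(k$statistic), p = k$p.value)
    },
    spearman = {
      k <- suppressWarnings(cor.test(x, y, method = "spearman"))
      list(statistic = unname(k$estimate), p = k$p.value)
    })
  res$method <- method
  res
}

#' Loess-plus-spline trend fit of a lifespan trajectory
#'
#' First pass: local linear regression (tricube weights) with a
#' 10-nearest-neighbour window.  Second pass: a cubic smoothing spline with
#' 6-8 interior knots fitted to the Loess output.  The fitted curve is
#' returned on a grid spanning the observed ages only (no extrapolation).
#'
#' @param cohort cohort table.
#' @param value `"density"`, `"proliferation"`, `"apoptosis"` or a column
#'   name.
#' @param neighborhood number of nearest neighbours in the Loess pass.
#' @param knots spline knots; values outside 6-8 are allowed with a warning.
#' @param n_grid grid resolution of the returned curve.
#' @return object of class `trend_fit` with `age_days`, `fitted` (curve on
#'   the grid), `residuals` (at the data points), `peaks` (ages of local
#'   maxima of the curve) and the parameters.
#' @export
fit_trend <- function(cohort, value = "density", neighborhood = 10,
                      knots = 8, n_grid = 512) {
  col <- switch(value, density = "density_per_mm2",
                proliferation = "proliferative_index_pct",
                apoptosis = "apoptotic_index_pct", value)
  if (!col %in% names(cohort)) stop("no column '", col, "' in cohort")
  keep <- !is.na(cohort[[col]]) & !is.na(cohort$canonical_age_days)
  t <- cohort$canonical_age_days[keep]
  y <- cohort[[col]][keep]
  n <- length(t)
  if (n < max(knots + 2, 10))
    stop("insufficient points: need at least ", max(knots + 2, 10))
  if (knots < 6 || knots > 8)
    warning("knots outside the recommended 6-8 range")
  ord <- order(t)
  t <- t[ord]; y <- y[ord]
  span <- min(1, max(neighborhood / n, 2 / n))
  # replicated ages make some local fits rank-deficient; loess falls back
  # to the pseudoinverse, which is the intended behaviour here
  smoothed <- suppressWarnings({
    lo <- loess(y ~ t, span = span, degree = 1, family = "gaussian",
                control = stats::loess.control(surface = "direct"))
    predict(lo, t)
  })
  nk <- length(unique(t))
  sp <- smooth.spline(t, smoothed, nknots = min(knots, nk),
                      keep.data = FALSE)
  grid <- seq(min(t), max(t), length.out = n_grid)
  fitted_grid <- predict(sp, grid)$y
  fitted_pts <- predict(sp, t)$y
  s <- diff(sign(diff(fitted_grid)))
  peaks <- grid[which(s == -2) + 1]
  out <- list(age_days = grid, fitted = fitted_grid, x = t, y = y,
              fitted_points = fitted_pts, residuals = y - fitted_pts,
              peaks = peaks, value = value, neighborhood = neighborhood,
              knots = knots, loess_span = span)
  class(out) <- "trend_fit"
  out
}

#' Print a `trend_fit` object
#' @param x the object
#' @param ... ignored
#' @return `x`, invisibly
#' @exportS3Method base::print
print.trend_fit <- function(x, ...) {
  cat("trend_fit of", x$value, "on", length(x$x), "cases;",
      "peaks at day(s):", paste(round(x$peaks, 1), collapse = ", "), "\n")
  invisible(x)
}

#' @export
predict.trend_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  if (any(newdata < min(object$x) | newdata > max(object$x)))
    stop("no extrapolation beyond the observed age span")
  approx(object$age_days, object$fitted, xout = newdata)$y
}

#' @export
residuals.trend_fit <- function(object, ...) object$residuals

#' @export
plot.trend_fit <- function(x, ...) {
  plot(x$x, x$y, xlab = "age (days post-conception)", ylab = x$value, ...)
  graphics::lines(x$age_days, x$fitted, col = 2, lwd = 2)
  if (length(x$peaks)) graphics::abline(v = x$peaks, lty = 3)
  invisible(x)
}
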