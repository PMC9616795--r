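# Independent oracles used by the tests.

# Brute-force dip by linear programming over piecewise-linear unimodal CDFs
# with knots at the order statistics (scipy linprog, HiGHS).  Batched: one
# interpreter call for a list of samples.
dip_lp_oracle <- function(samples) {
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  stopifnot(nzchar(py))
  script <- system.file("oracle", "dip_lp.py", package = "microdyn")
  inf <- tempfile(fileext = ".json")
  outf <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(samples = samples), digits = NA), inf)
  status <- system2(py, shQuote(script), stdin = inf, stdout = outf)
  stopifnot(status == 0)
  jsonlite::fromJSON(outf)$dip
}

# Ellipse perimeter by numerical quadrature of the arc-length integral.
ellipse_perimeter <- function(a, b) {
  stats::integrate(function(th) sqrt(a^2 * sin(th)^2 + b^2 * cos(th)^2),
                   0, 2 * pi, rel.tol = 1e-12)$value
}

# A small valid cell table used across IO tests.
make_cells <- function(n = 3) {
  data.frame(
    cell_id = sprintf("c%03d", seq_len(n)),
    x_um = seq(10, 10 * n, 10),
    y_um = seq(5, 5 * n, 5),
    area_um2 = rep(60, n),
    perimeter_um = rep(30, n),
    major_um = rep(12, n),
    minor_um = rep(6, n),
    theta_deg = rep(45, n),
    iba1 = rep(1L, n),
    ki67 = rep(0L, n),
    casp3 = rep(0L, n),
    tmem119 = rep(1L, n),
    layer = rep("CP", n),
    stringsAsFactors = FALSE)
}
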