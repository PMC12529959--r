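## Bacterial growth curves and enzyme kinetics: OD600 time courses with
## linear interpolation and a post-peak plateau, the Michaelis-Menten urease
## law, the OD-dependent carbonic anhydrase rate constant, and the synthetic
## growth-curve generator used when measured OD values are not available.

#' Enzyme and biomass parameters
#'
#' Michaelis-Menten parameters of Sporosarcina pasteurii urease, the carbonic
#' anhydrase rate law coefficients, the OD600-to-cell-count conversion and
#' the per-cell carbon content.
#'
#' @param km Michaelis constant in M (355 mM).
#' @param vmax_mmol_h_cfu maximal per-cell ureolysis rate, mmol/h/CFU.
#' @param ca_intercept uncatalysed CO2 hydration rate constant, 1/s.
#' @param ca_slope carbonic anhydrase contribution per OD600 unit, 1/s.
#' @param od_to_cfu cell count per mL at OD600 = 1.
#' @param carbon_per_cell_pmol carbon content of one cell in pmol.
#' @return list of class \code{enzyme_params}.
#' @export
enzyme_params <- function(km = 0.355, vmax_mmol_h_cfu = 6.4e-9,
                          ca_intercept = 0.065, ca_slope = 0.117,
                          od_to_cfu = 1.37e9, carbon_per_cell_pmol = 0.08) {
  p <- list(km = km, vmax_mmol_h_cfu = vmax_mmol_h_cfu,
            ca_intercept = ca_intercept, ca_slope = ca_slope,
            od_to_cfu = od_to_cfu,
            carbon_per_cell_pmol = carbon_per_cell_pmol)
  if (any(unlist(p) <= 0)) stop("all enzyme parameters must be positive")
  class(p) <- "enzyme_params"
  p
}

#' Construct a bacterial growth curve
#'
#' An OD600 time course sampled on the experimental grid. Between samples the
#' cell concentration is linearly interpolated; from the peak of exponential
#' growth onward it is held constant (stationary phase, where OD600 is no
#' longer proportional to viable cells).
#'
#' @param times sampling times in h.
#' @param od OD600 values at \code{times}.
#' @param peak_time time (h) of the exponential-phase peak; must be one of
#'   the sampling times.
#' @param od_to_cfu linear OD600-to-CFU/mL factor.
#' @param attenuation divisor applied to the cell concentration (>= 1); the
#'   value 250 reproduces the reduced-activity simulation variant.
#' @param series label.
#' @return object of class \code{growth_curve}.
#' @export
growth_curve <- function(times = c(0, 2, 5, 8, 24, 31, 48, 54), od,
                         peak_time = 24, od_to_cfu = 1.37e9,
                         attenuation = 1, series = "custom") {
  stopifnot(length(times) == length(od), all(od >= 0), attenuation >= 1,
            !is.unsorted(times))
  if (!peak_time %in% times)
    stop("peak_time must lie on the sampling grid")
  structure(list(times = times, od = od, peak_time = peak_time,
                 od_to_cfu = od_to_cfu, attenuation = attenuation,
                 series = series),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat("Growth curve '", x$series, "': OD600 ", x$od[1], " -> ",
      max(x$od), ", peak at ", x$peak_time, " h",
      if (x$attenuation != 1) paste0(" (attenuated /", x$attenuation, ")"),
      "\n", sep = "")
  invisible(x)
}

#' OD600 at an arbitrary time
#'
#' Linear interpolation between samples; constant at the peak value for
#' t >= peak_time.
#'
#' @param curve a \code{\link{growth_curve}} or \code{NULL} (no bacteria).
#' @param t time in h (vectorized).
#' @return OD600 (attenuation not applied; it only scales cell counts).
#' @export
od_at <- function(curve, t) {
  if (is.null(curve)) return(rep(0, length(t)))
  stopifnot(all(t >= 0))
  tpre <- pmin(t, curve$peak_time)
  if (any(tpre > max(curve$times)))
    stop("missing OD sample before the requested time")
  stats::approx(curve$times, curve$od, xout = tpre, rule = 2)$y
}

#' Cell concentration at an arbitrary time
#'
#' @inheritParams od_at
#' @return CFU/mL, i.e. OD600 x od_to_cfu / attenuation; 0 for a \code{NULL}
#'   curve (control series).
#' @export
biomass_at <- function(curve, t) {
  if (is.null(curve)) return(rep(0, length(t)))
  od_at(curve, t) * curve$od_to_cfu / curve$attenuation
}

#' Michaelis-Menten ureolysis rate
#'
#' Growth-dependent urease kinetics: urea is consumed at
#' \code{X * vmax * [urea] / (Km + [urea])}. With X in CFU/mL and vmax in
#' mmol/h/CFU, the product is mmol/(h mL), numerically equal to mol/(L h).
#'
#' @param urea urea concentration in M.
#' @param X cell concentration in CFU/mL.
#' @param params \code{\link{enzyme_params}}.
#' @return urea consumption rate in M/h (positive).
#' @export
ureolysis_rate <- function(urea, X, params = enzyme_params()) {
  stopifnot(all(urea >= 0), all(X >= 0))
  X * params$vmax_mmol_h_cfu * urea / (params$km + urea)
}

#' Carbonic anhydrase rate constant for CO2 hydration
#'
#' The forward rate constant of CO2(aq) hydration as a linear function of
#' cell density: the intercept is the uncatalysed hydration rate, the slope
#' the carbonic anhydrase contribution.
#'
#' @param od OD600 of the culture.
#' @param params \code{\link{enzyme_params}}.
#' @return forward rate constant in 1/s.
#' @examples
#' ca_rate_constant(0)   # 0.065, abiotic hydration
#' ca_rate_constant(5)   # 0.650
#' @export
ca_rate_constant <- function(od, params = enzyme_params()) {
  stopifnot(all(od >= 0))
  params$ca_intercept + params$ca_slope * od
}

#' Carbon bound in bacterial biomass
#'
#' @param cfu_per_ml cell concentration in CFU/mL.
#' @param params \code{\link{enzyme_params}}.
#' @return biomass carbon in mol per liter of liquid.
#' @examples
#' biomass_carbon(8e9)   # ~0.64 M
#' @export
biomass_carbon <- function(cfu_per_ml, params = enzyme_params()) {
  stopifnot(all(cfu_per_ml >= 0))
  # pmol/cell * cells/mL = pmol/mL = 1e-12 mol/mL = 1e-9 mol/L
  cfu_per_ml * params$carbon_per_cell_pmol * 1e-9
}

## synthetic growth fixtures -------------------------------------------------

.growth_presets <- list(
  "bacteria 0.04 vol % CO2(g)"      = list(peak = 24),
  "bacteria 50 vol % CO2(g)"        = list(peak = 24),
  "bacteria 60 vol % CO2(g)"        = list(peak = 31),
  "bacteria + Ca 0.04 vol % CO2(g)" = list(peak = 31),
  "bacteria + Ca 50 vol % CO2(g)"   = list(peak = 54),
  "bacteria + Ca 60 vol % CO2(g)"   = list(peak = 54)
)

#' Generate a synthetic OD600 growth curve
#'
#' Measured OD600 values are not published numerically, so batch-experiment
#' simulations use a seeded logistic stand-in: OD600(0) = 0.01, logistic
#' growth reaching within 1\% of the plateau at the series' peak time, sampled
#' on the experimental time grid, with mild lognormal measurement noise
#' (deterministic for a given seed). The plateau is held constant after the
#' peak.
#'
#' @param series one of the six bacterial series labels (see
#'   \code{names(micptrap:::.growth_presets)}) or any label when
#'   \code{peak_time} is given.
#' @param od_peak plateau OD600 (> 0.01).
#' @param peak_time peak time in h; defaults to the series' value (24, 31 or
#'   54 h).
#' @param seed integer seed; same seed, same curve.
#' @param noise_sd lognormal sd of the multiplicative sampling noise.
#' @param attenuation passed to \code{\link{growth_curve}}.
#' @return a \code{\link{growth_curve}}.
#' @export
synthetic_growth <- function(series = "bacteria 50 vol % CO2(g)",
                             od_peak = 5, peak_time = NULL, seed = 1,
                             noise_sd = 0.05, attenuation = 1) {
  stopifnot(od_peak > 0.01)
  if (is.null(peak_time)) {
    if (!series %in% names(.growth_presets))
      stop("unknown series '", series, "'; give peak_time explicitly")
    peak_time <- .growth_presets[[series]]$peak
  }
  times <- c(0, 2, 5, 8, 24, 31, 48, 54)
  if (!peak_time %in% times) stop("peak_time must be on the sampling grid")
  od0 <- 0.01
  # growth rate such that the logistic reaches 99% of the plateau at the peak
  r <- log((0.99 / 0.01) * ((od_peak - od0) / od0)) / peak_time
  od <- od_peak * od0 * exp(r * times) /
    (od_peak - od0 + od0 * exp(r * times))
  od[times >= peak_time] <- od[times == peak_time]
  noisy <- withr_seed(seed, {
    f <- exp(stats::rnorm(length(times), 0, noise_sd))
    f[1] <- 1  # the inoculation density itself is exact
    od * f
  })
  noisy <- cummax(noisy)  # keep monotone up to the plateau
  noisy[times >= peak_time] <- noisy[times == peak_time]
  noisy[1] <- od0
  growth_curve(times, noisy, peak_time = peak_time,
               attenuation = attenuation, series = series)
}

## evaluate expr under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Read / write growth curves as delimited text
#'
#' Two tab-separated columns \code{time_h}, \code{od600} with a header; peak
#' time and series are carried in comment lines.
#'
#' @param curve a \code{\link{growth_curve}}.
#' @param path file path.
#' @return \code{read_growth_curve} returns a \code{growth_curve};
#'   \code{write_growth_curve} returns \code{path} invisibly.
#' @export
write_growth_curve <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# series: ", curve$series),
               paste0("# peak_time_h: ", curve$peak_time),
               paste0("# attenuation: ", curve$attenuation),
               "time_h\tod600"), con)
  utils::write.table(data.frame(time_h = curve$times, od600 = curve$od),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_growth_curve
#' @export
read_growth_curve <- function(path) {
  hdr <- readLines(path, n = 10)
  meta <- function(key, default) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(ln)) return(default)
    sub(paste0("^# ", key, ":\\s*"), "", ln[1])
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  growth_curve(df$time_h, df$od600,
               peak_time = as.numeric(meta("peak_time_h", 24)),
               attenuation = as.numeric(meta("attenuation", 1)),
               series = meta("series", "custom"))
}
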