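## Scenario definitions: initial composition, clamps, buffers, biomass and
## reactor geometry, plus the named presets mirroring the batch experiments
## and the capacity-map sweeps.

#' Define a reactor scenario
#'
#' A scenario bundles everything needed to initialize and run one bottle or
#' reservoir simulation: initial composition, which species are clamped to a
#' constant concentration (continuous CO2(g) or Ca2+ supply), the buffer set,
#' the biomass model and the reactor geometry.
#'
#' @param urea initial urea concentration (M).
#' @param ca initial Ca2+ concentration (M); chloride is added as the inert
#'   counter-ion (2 Cl- per Ca2+, as supplied by CaCl2).
#' @param co2_fraction initial headspace CO2(g) volume fraction in \[0, 1\].
#' @param pH initial liquid pH; buffers, H+ and OH- are initialized
#'   equilibrated at this pH.
#' @param clamp character vector among \code{"CO2g"}, \code{"Ca"}: species
#'   held constant (unlimited external reservoir).
#' @param buffers a \code{\link{buffer_set}}.
#' @param growth a \code{\link{growth_curve}}, or \code{NULL} for no
#'   bacteria.
#' @param od fixed OD600 used for the carbonic anhydrase rate when no growth
#'   curve is given (e.g. a pre-grown, non-ureolytic culture).
#' @param kf_R8 CO2 gas-liquid transfer constant (1/s); \code{1e10} models
#'   instantaneous dissolution.
#' @param temperature K.
#' @param pressure atm.
#' @param v_liq,v_gas liquid and headspace volumes (L).
#' @param duration_h simulated duration (h).
#' @param label scenario name.
#' @return object of class \code{micp_scenario}.
#' @export
micp_scenario <- function(urea = 0, ca = 0, co2_fraction = 0.5, pH = 7.3,
                          clamp = character(), buffers = buffer_set(),
                          growth = NULL, od = 0, kf_R8 = 2e-2,
                          temperature = 303.15, pressure = 1,
                          v_liq = 0.05, v_gas = 0.2, duration_h = 54,
                          label = "custom") {
  stopifnot(urea >= 0, ca >= 0, co2_fraction >= 0, co2_fraction <= 1,
            pH > 0, pH < 14, v_liq > 0, v_gas > 0, duration_h > 0,
            all(clamp %in% c("CO2g", "Ca")))
  structure(list(urea = urea, ca = ca, co2_fraction = co2_fraction, pH = pH,
                 clamp = clamp, buffers = buffers, growth = growth, od = od,
                 kf_R8 = kf_R8, temperature = temperature,
                 pressure = pressure, v_liq = v_liq, v_gas = v_gas,
                 duration_h = duration_h, label = label),
            class = "micp_scenario")
}

#' @export
print.micp_scenario <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
format.micp_scenario <- function(x, ...) {
  c(paste0("Scenario '", x$label, "'"),
    sprintf("  urea %.3g M, Ca2+ %.3g M, CO2(g) %.4g vol %%, pH %.2f",
            x$urea, x$ca, 100 * x$co2_fraction, x$pH),
    paste0("  clamped: ",
           if (length(x$clamp)) paste(x$clamp, collapse = ", ") else "none"),
    paste0("  buffers: ",
           if (nrow(x$buffers)) paste0(nrow(x$buffers), " pairs") else "off"),
    paste0("  biomass: ",
           if (!is.null(x$growth)) paste0("growth curve '", x$growth$series,
                                          "'")
           else if (x$od > 0) paste0("fixed OD600 = ", x$od)
           else "none"),
    sprintf("  V_liq %.3g L, V_gas %.3g L, %.4g K, %.3g atm, %.3g h",
            x$v_liq, x$v_gas, x$temperature, x$pressure, x$duration_h))
}

.preset_names <- c(
  "control_0.04", "control_50", "control_60",
  "bacteria_0.04", "bacteria_50", "bacteria_60",
  "bacteria_ca_0.04", "bacteria_ca_50", "bacteria_ca_60",
  "fig5_sweep", "fig7_ca", "fig8_step3", "fig9_sweep", "fig10_sweep",
  "fig11_maxima", "fig12_urea20", "fig14_constant100")

#' Named scenario presets
#'
#' Builds the scenarios of the nine batch-experiment series (controls,
#' bacteria, bacteria + Ca at 0.04 / 50 / 60 vol % CO2(g); the nominal 60
#' vol % series is initialized at 70 vol %, the value consistent with its
#' first headspace measurement) and of the simulation figures: the
#' constant-headspace capacity maps, the carbonic anhydrase scenario, the
#' sedimentary step-(iii) scenario and the constant-100-vol % kinetic run.
#' Sweep presets carry their grid definition in attribute \code{"sweep"}.
#'
#' @param name preset name; see \code{preset_names()}.
#' @param seed seed for the synthetic growth curves of the bacterial series.
#' @param attenuation biomass attenuation divisor (1 or 250).
#' @return a \code{\link{micp_scenario}}.
#' @export
micp_preset <- function(name, seed = 1, attenuation = 1) {
  if (!name %in% .preset_names)
    stop("unknown preset '", name, "'; available: ",
         paste(.preset_names, collapse = ", "))
  urea20 <- mass_to_molar(20, .micp$mm_urea)
  ca20 <- mass_to_molar(20, .micp$mm_cacl2)
  frac <- function(nm) switch(nm, "0.04" = 0.0004, "50" = 0.5, "60" = 0.7)
  if (grepl("^(control|bacteria)", name)) {
    parts <- strsplit(name, "_")[[1]]
    has_ca <- parts[2] == "ca"
    f <- frac(parts[length(parts)])
    series <- if (parts[1] == "control") NULL else
      paste0("bacteria ", if (has_ca) "+ Ca ", parts[length(parts)],
             " vol % CO2(g)")
    growth <- if (!is.null(series))
      synthetic_growth(series, seed = seed, attenuation = attenuation)
    return(micp_scenario(urea = urea20, ca = if (has_ca) ca20 else 0,
                         co2_fraction = f, growth = growth, label = name))
  }
  switch(name,
    fig7_ca = micp_scenario(urea = 0, ca = 0, co2_fraction = 0.5,
                            clamp = "CO2g", od = 5, duration_h = 2,
                            label = name),
    fig8_step3 = micp_scenario(
      urea = urea20, ca = 0.66, co2_fraction = 1, pH = 10,
      clamp = "CO2g",
      buffers = buffer_set(extra_total = 0.66, extra_pKa = 10),
      growth = synthetic_growth("bacteria + Ca 60 vol % CO2(g)", seed = seed,
                                attenuation = attenuation),
      label = name),
    fig14_constant100 = micp_scenario(
      urea = urea20, ca = 0, co2_fraction = 1, clamp = "CO2g",
      growth = synthetic_growth("bacteria 60 vol % CO2(g)", seed = seed,
                                attenuation = attenuation),
      label = name),
    fig5_sweep = structure(
      micp_scenario(urea = urea20, clamp = "CO2g",
                    buffers = buffer_set(enabled = FALSE), label = name),
      sweep = list(ca = seq(0.05, 1, length.out = 20),
                   co2_fraction = c(0.0004, 0.5, 1))),
    fig9_sweep = structure(
      micp_scenario(clamp = "CO2g", label = name),
      sweep = list(urea = default_urea_grid(),
                   co2_fraction = c(0.0004, 0.1, 0.25, 0.5, 0.82, 1))),
    fig10_sweep = structure(
      micp_scenario(clamp = "CO2g", buffers = buffer_set(enabled = FALSE),
                    label = name),
      sweep = list(urea = default_urea_grid(),
                   co2_fraction = c(0.0004, 0.1, 0.25, 0.5, 0.82, 1))),
    fig11_maxima = structure(
      micp_scenario(clamp = "CO2g", buffers = buffer_set(enabled = FALSE),
                    label = name),
      sweep = list(urea = default_urea_grid(),
                   co2_fraction = c(0.0004, 0.1, 0.25, 0.5, 0.82, 1))),
    fig12_urea20 = structure(
      micp_scenario(urea = urea20, clamp = "CO2g", label = name),
      sweep = list(co2_fraction = c(0.0004, 0.1, 0.25, 0.5, 0.82, 1)))
  )
}

#' @rdname micp_preset
#' @export
preset_names <- function() .preset_names

#' Default urea grid for capacity sweeps
#'
#' Log-spaced below 0.01 M, linear above, up to 10 M.
#'
#' @param n_linear number of points in the linear part.
#' @return increasing numeric vector (M) starting at 0.
#' @export
default_urea_grid <- function(n_linear = 100) {
  c(0, 10^seq(-4, -2, length.out = 15),
    seq(0.02, 10, length.out = n_linear))
}

#' One-line description of a preset's boundary conditions
#'
#' @param scenario a \code{\link{micp_scenario}}.
#' @return character vector (printable) echoing the scenario definition.
#' @export
describe_scenario <- function(scenario) format(scenario)
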