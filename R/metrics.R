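## Derived metrics: the trapped-CO2 accounting and the staged sedimentary
## reservoir simulation.

#' Trapped CO2 of a state, trajectory or equilibrium
#'
#' Trapped CO2 is the molar concentration of carbon in the liquid phase
#' (dissolved inorganic carbon, carbamate and the CaCO3 pool) in excess of
#' the carbon delivered by urea hydrolysis, referenced to the liquid volume.
#' Positive values mean net transfer of headspace CO2 into the liquid;
#' negative values mean ureolysis-driven outgassing.
#'
#' @param x a \code{\link{micp_state}}, \code{micp_trajectory} or
#'   \code{micp_equilibrium}.
#' @param hydrolyzed cumulative hydrolyzed urea (M) for a bare state; for a
#'   trajectory the internal tally is used, for an equilibrium full
#'   hydrolysis of the scenario's urea.
#' @return trapped CO2 in M (a series for a trajectory).
#' @export
trapped_co2 <- function(x, hydrolyzed = 0) {
  liqC <- c("CO2aq", "H2CO3", "HCO3", "CO3", "CaCO3", "carbamate")
  if (inherits(x, "micp_trajectory")) return(x$trapped)
  if (inherits(x, "micp_equilibrium")) return(x$trapped)
  if (inherits(x, "micp_state")) {
    have <- intersect(liqC, names(x$conc))
    return(unname(sum(x$conc[have]) - hydrolyzed))
  }
  stop("unsupported input of class ", paste(class(x), collapse = "/"))
}

#' Carbon pools of a trajectory endpoint
#'
#' Splits total carbon into headspace CO2, dissolved inorganic carbon,
#' CaCO3, and urea-derived carbon (remaining plus hydrolyzed), in mol.
#'
#' @param traj a \code{micp_trajectory}.
#' @param i time index (default: last).
#' @return named numeric vector of mole amounts; their sum minus the
#'   hydrolysis bookkeeping equals total C in a closed system.
#' @export
carbon_pools <- function(traj, i = length(traj$times)) {
  y <- traj$conc[i, ]
  sc <- traj$scenario
  c(gas_co2 = unname(y["CO2g"]) * sc$v_gas,
    dic = sum(y[c("CO2aq", "H2CO3", "HCO3", "CO3")]) * sc$v_liq,
    caco3 = unname(y["CaCO3"]) * sc$v_liq,
    carbamate = unname(y["carbamate"]) * sc$v_liq,
    urea = unname(y["urea"]) * sc$v_liq,
    hydrolyzed = unname(traj$hydrolyzed[i]) * sc$v_liq)
}

#' Simulate MICP after sedimentary-rock buffering (step iii)
#'
#' Two-stage reservoir scenario: the system (100 vol % CO2(g) clamped,
#' 0.66 M Ca2+, 0.66 M mineral-buffer with pKa 10, initialized at pH 10) is
#' first brought to equilibrium under continued CO2 injection; at t = 0 the
#' injection switches to bacteria and urea - the urea concentration jumps to
#' 0.33 M, the headspace clamp is released and the system evolves
#' kinetically with the bacterial growth curve.
#'
#' @param seed seed for the synthetic growth curve.
#' @param duration_h length of the kinetic stage.
#' @param attenuation biomass attenuation divisor.
#' @return a \code{micp_trajectory} of the kinetic stage, with the
#'   pre-injection equilibrium in attribute \code{"pre"}.
#' @export
run_sedimentary_step3 <- function(seed = 1, duration_h = 54,
                                  attenuation = 1) {
  sc <- micp_preset("fig8_step3", seed = seed, attenuation = attenuation)
  pre_sc <- sc
  pre_sc$urea <- 0
  eq <- micp_equilibrium(pre_sc)
  run_sc <- sc
  run_sc$clamp <- character()       # injection switched off
  run_sc$duration_h <- duration_h
  state <- equilibrium_state(eq, run_sc)
  state$conc["urea"] <- sc$urea     # urea injected at t = 0
  traj <- micp_simulate(run_sc, state = state)
  attr(traj, "pre") <- eq
  traj
}
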