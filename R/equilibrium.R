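## Algebraic equilibrium: with the headspace CO2(g) clamped, every liquid
## concentration is an explicit function of [H+] through the equilibrium
## relations, the nitrogen balance (urea fully hydrolyzed) and the calcium
## balance. pH is then the single pivot unknown, fixed by requiring the net
## explicit-ion charge of the liquid to equal its value at initialization
## (all reactions conserve charge and only neutral species cross phases, so
## that quantity is a dynamical invariant; the counter-ions that set the
## initial pH of the real medium are implicit).

.eq_speciate <- function(pH, urea, ca_tot, co2aq, buffers, vratio,
                         ca_clamped = FALSE) {
  k <- .micp
  H <- 10^(-pH)
  OH <- k$Kw / H
  h2co3 <- (k$K1 / k$K_R5) * co2aq
  hco3 <- k$K1 * co2aq / H
  co3 <- k$K2 * hco3 / H
  Ka_N <- k$Kw / k$K_R3          # NH4+ acidity constant, pKa ~9.25
  # N balance: 2 urea = NH3(aq) (1 + H/Ka_N + K_R4 * Vg/Vl)
  nh3 <- 2 * urea / (1 + H / Ka_N + k$K_R4 * vratio)
  nh4 <- nh3 * H / Ka_N
  nh3g <- k$K_R4 * nh3
  if (ca_clamped) {
    ca <- ca_tot
  } else {
    ca <- ca_tot / (1 + k$K_R7 * co3)
  }
  caco3 <- k$K_R7 * ca * co3
  q <- if (nrow(buffers)) buffers$total * buffers$Ka / (buffers$Ka + H)
       else numeric()
  list(H = H, OH = OH, H2CO3 = h2co3, HCO3 = hco3, CO3 = co3, CO2aq = co2aq,
       NH3aq = nh3, NH4 = nh4, NH3g = nh3g, Ca = ca, CaCO3 = caco3, Q = q)
}

#' Thermodynamic equilibrium of a clamped-headspace scenario
#'
#' Solves the equilibrium state reached under a constant headspace CO2(g)
#' fraction (continuous CO2 injection): urea is taken as fully hydrolyzed
#' (ureolysis is irreversible), CO2(aq) follows the Henry partition of the
#' clamped gas concentration, the remaining carbonate, ammonia, buffer and
#' calcium speciation follows the equilibrium constants, ammonia outgassing
#' uses the closed-bottle headspace-to-liquid volume ratio, and pH is located
#' by a bracketed root search on the liquid charge balance.
#'
#' Ca2+ may additionally be clamped (constant-composition reservoir); the
#' delivered calcium is then assumed to arrive as neutral CaCl2 so that the
#' charge balance stays well-posed.
#'
#' @param scenario a \code{\link{micp_scenario}} with \code{"CO2g"} in its
#'   clamp set.
#' @return object of class \code{micp_equilibrium}: species concentrations
#'   (M), pH, trapped CO2 (M), and residual diagnostics (charge-balance
#'   residual and mass-action quotient error).
#' @export
micp_equilibrium <- function(scenario) {
  sc <- scenario
  if (!"CO2g" %in% sc$clamp)
    stop("the algebraic solver requires a clamped CO2(g) headspace; ",
         "use micp_simulate() for closed-system equilibration")
  k <- .micp
  co2g <- gas_molarity(sc$co2_fraction, sc$pressure, sc$temperature)
  co2aq <- k$K_R8 * co2g
  vratio <- sc$v_gas / sc$v_liq
  ca_cl <- "Ca" %in% sc$clamp
  # dynamical charge invariant of the initialized liquid (Ca and Cl cancel)
  H0 <- 10^(-sc$pH)
  Z0 <- H0 - k$Kw / H0 -
    if (nrow(sc$buffers)) sum(sc$buffers$total * sc$buffers$Ka /
                              (sc$buffers$Ka + H0)) else 0
  balance <- function(pH) {
    s <- .eq_speciate(pH, sc$urea, sc$ca, co2aq, sc$buffers, vratio, ca_cl)
    cl <- if (ca_cl) 2 * (s$Ca + s$CaCO3) else 2 * sc$ca
    (s$NH4 + s$H + 2 * s$Ca) - (s$HCO3 + 2 * s$CO3 + s$OH + cl + sum(s$Q)) -
      Z0
  }
  lo <- 0.5; hi <- 13.9
  flo <- balance(lo); fhi <- balance(hi)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0)
    stop("no pH bracket in [", lo, ", ", hi, "]; residuals ", signif(flo, 3),
         " / ", signif(fhi, 3))
  root <- stats::uniroot(balance, c(lo, hi), tol = 1e-14)
  pH <- root$root
  s <- .eq_speciate(pH, sc$urea, sc$ca, co2aq, sc$buffers, vratio, ca_cl)
  dic <- s$CO2aq + s$H2CO3 + s$HCO3 + s$CO3
  conc <- c(urea = 0, carbamate = 0, NH3aq = s$NH3aq, NH3g = s$NH3g,
            NH4 = s$NH4, H2CO3 = s$H2CO3, HCO3 = s$HCO3, CO3 = s$CO3,
            CO2aq = s$CO2aq, CO2g = co2g, Ca = s$Ca, CaCO3 = s$CaCO3,
            H = s$H, OH = s$OH,
            Cl = if (ca_cl) 2 * (s$Ca + s$CaCO3) else 2 * sc$ca)
  if (nrow(sc$buffers)) {
    qn <- sc$buffers$name
    conc[qn] <- s$Q
    conc[paste0("H", qn)] <- sc$buffers$total - s$Q
  }
  # residuals of the equilibrium relations actually used
  quot_err <- max(abs(c(
    s$HCO3 * s$H / (s$CO2aq * k$K1) - 1,
    s$CO3 * s$H / (s$HCO3 * k$K2) - 1,
    s$H * s$OH / k$Kw - 1,
    if (!ca_cl && sc$ca > 0) s$CaCO3 / (k$K_R7 * s$Ca * s$CO3) - 1)))
  structure(list(conc = conc, pH = pH, dic = dic,
                 trapped = dic + s$CaCO3 - sc$urea,
                 caco3 = s$CaCO3,
                 residuals = c(charge = balance(pH), quotient = quot_err),
                 scenario = sc),
            class = "micp_equilibrium")
}

#' @export
print.micp_equilibrium <- function(x, ...) {
  cat("MICP equilibrium '", x$scenario$label, "'\n", sep = "")
  cat(sprintf("  pH %.3f | DIC %.4g M | CaCO3 %.4g M | trapped CO2 %.4g M\n",
              x$pH, x$dic, x$caco3, x$trapped))
  cat(sprintf("  residuals: charge %.2g, quotients %.2g\n",
              x$residuals[1], x$residuals[2]))
  invisible(x)
}

#' Convert an equilibrium result into a reactor state
#'
#' Used to start staged kinetic runs from a pre-equilibrated composition.
#'
#' @param eq a \code{micp_equilibrium}.
#' @param scenario scenario supplying geometry and clamp set for the new
#'   state (defaults to the equilibrium's own).
#' @return a \code{\link{micp_state}}.
#' @export
equilibrium_state <- function(eq, scenario = eq$scenario) {
  species <- micp_species(scenario$buffers)
  y <- stats::setNames(numeric(nrow(species)), species$name)
  y[names(eq$conc)] <- eq$conc
  micp_state(y, v_liq = scenario$v_liq, v_gas = scenario$v_gas,
             temperature = scenario$temperature,
             pressure = scenario$pressure, clamped = scenario$clamp)
}

## sweeps --------------------------------------------------------------------

.sweep_cell <- function(sc, urea, ca, frac) {
  sc$urea <- urea; sc$ca <- ca; sc$co2_fraction <- frac
  eq <- tryCatch(micp_equilibrium(sc), error = function(e) e)
  if (inherits(eq, "error"))
    return(data.frame(urea_M = urea, ca_M = ca, co2_volfrac = frac,
                      buffers = nrow(sc$buffers) > 0, pH = NA, trapped_M = NA,
                      caco3_M = NA, failed = TRUE))
  data.frame(urea_M = urea, ca_M = ca, co2_volfrac = frac,
             buffers = nrow(sc$buffers) > 0, pH = eq$pH,
             trapped_M = eq$trapped, caco3_M = eq$caco3, failed = FALSE)
}

#' Equilibrium CaCO3 map over initial Ca2+ and CO2(g) fraction
#'
#' The mineral-trapping capacity map: equilibrium \eqn{[CaCO_3]} and pH on a
#' grid of initial calcium concentrations and clamped headspace CO2(g)
#' fractions, at fixed initial urea and (by default) without buffers.
#'
#' @param ca_grid initial Ca2+ values (M), strictly increasing.
#' @param co2_fraction_grid headspace CO2(g) volume fractions.
#' @param urea initial urea (M).
#' @param scenario template scenario (buffers off by default).
#' @return a \code{micp_sweep} data.frame (one row per grid cell) with the
#'   grid maximum in attribute \code{"argmax"}.
#' @export
caco3_map <- function(ca_grid = seq(0.05, 1, length.out = 20),
                      co2_fraction_grid = c(0.0004, 0.5, 1),
                      urea = mass_to_molar(20, 60.06),
                      scenario = micp_scenario(
                        clamp = "CO2g", buffers = buffer_set(enabled = FALSE),
                        label = "caco3_map")) {
  stopifnot(!is.unsorted(ca_grid, strictly = TRUE), length(ca_grid) > 0)
  rows <- list()
  for (f in co2_fraction_grid)
    for (ca in ca_grid)
      rows[[length(rows) + 1]] <- .sweep_cell(scenario, urea, ca, f)
  out <- do.call(rbind, rows)
  i <- which.max(out$caco3_M)
  attr(out, "argmax") <- out[i, ]
  class(out) <- c("micp_sweep", "data.frame")
  out
}

#' Trapped-CO2 sweep over urea at a fixed headspace fraction
#'
#' The solubility-trapping capacity curve: equilibrium trapped CO2 and pH
#' along a urea grid with the headspace CO2(g) clamped. The interior maximum
#' is refined by golden-section search between the bracketing grid points, so
#' the reported argmax does not depend on the grid resolution.
#'
#' @param urea_grid urea values (M), increasing.
#' @param co2_fraction clamped headspace volume fraction.
#' @param buffers a \code{\link{buffer_set}} (disabled by default: the
#'   no-media condition of the capacity maps).
#' @param ca initial Ca2+ (M).
#' @param scenario template scenario.
#' @return a \code{micp_sweep} data.frame with attribute \code{"argmax"}: a
#'   one-row data.frame with the refined maximizing urea, trapped CO2 and pH.
#' @export
trapped_sweep <- function(urea_grid = default_urea_grid(),
                          co2_fraction = 0.82,
                          buffers = buffer_set(enabled = FALSE), ca = 0,
                          scenario = NULL) {
  stopifnot(!is.unsorted(urea_grid, strictly = TRUE), length(urea_grid) > 1)
  if (is.null(scenario))
    scenario <- micp_scenario(clamp = "CO2g", buffers = buffers,
                              label = "trapped_sweep")
  rows <- lapply(urea_grid, function(u)
    .sweep_cell(scenario, u, ca, co2_fraction))
  out <- do.call(rbind, rows)
  i <- which.max(out$trapped_M)
  lo <- urea_grid[max(1, i - 1)]
  hi <- urea_grid[min(length(urea_grid), i + 1)]
  tr <- function(u) .sweep_cell(scenario, u, ca, co2_fraction)$trapped_M
  opt <- if (hi > lo) stats::optimize(tr, c(lo, hi), maximum = TRUE,
                                      tol = 1e-6)
         else list(maximum = urea_grid[i], objective = out$trapped_M[i])
  # keep the grid point if the local search did not improve on it
  if (opt$objective < out$trapped_M[i])
    opt <- list(maximum = urea_grid[i], objective = out$trapped_M[i])
  amax <- .sweep_cell(scenario, opt$maximum, ca, co2_fraction)
  attr(out, "argmax") <- amax
  class(out) <- c("micp_sweep", "data.frame")
  out
}

#' @export
print.micp_sweep <- function(x, ...) {
  cat("MICP equilibrium sweep:", nrow(x), "cells,",
      sum(x$failed), "failed\n")
  am <- attr(x, "argmax")
  cat(sprintf("  max trapped %.4g M / max CaCO3 %.4g M at urea %.4g M, Ca %.3g M, %.4g vol %% (pH %.3f)\n",
              am$trapped_M, am$caco3_M, am$urea_M, am$ca_M,
              100 * am$co2_volfrac, am$pH))
  invisible(x)
}
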