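## Initial-value integration of the coupled reaction system over a scenario.

#' Initialize the reactor state of a scenario
#'
#' At t = 0 only CO2(g), urea, Ca2+ (with its chloride counter-ion), H+, OH-
#' and the buffers are present. H+ and OH- follow from the initial pH and
#' the water ion product; each buffer pair is split according to its Ka at
#' that pH; the headspace CO2(g) molarity follows from the ideal gas law at
#' the scenario's volume fraction. All other species start at zero.
#'
#' @param scenario a \code{\link{micp_scenario}}.
#' @return a \code{\link{micp_state}}.
#' @export
initialize_state <- function(scenario) {
  sc <- scenario
  species <- micp_species(sc$buffers)
  y <- stats::setNames(numeric(nrow(species)), species$name)
  H <- 10^(-sc$pH)
  y["H"] <- H
  y["OH"] <- .micp$Kw / H
  y["urea"] <- sc$urea
  y["Ca"] <- sc$ca
  y["Cl"] <- 2 * sc$ca
  y["CO2g"] <- gas_molarity(sc$co2_fraction, sc$pressure, sc$temperature)
  if (nrow(sc$buffers)) {
    for (i in seq_len(nrow(sc$buffers))) {
      q <- sc$buffers$name[i]
      f <- sc$buffers$Ka[i] / (sc$buffers$Ka[i] + H)
      y[q] <- sc$buffers$total[i] * f
      y[paste0("H", q)] <- sc$buffers$total[i] * (1 - f)
    }
  }
  micp_state(y, v_liq = sc$v_liq, v_gas = sc$v_gas,
             temperature = sc$temperature, pressure = sc$pressure,
             clamped = sc$clamp)
}

#' Simulate a scenario as an initial value problem
#'
#' Integrates the coupled mass-action system (19 reactions, two phases,
#' clamped species with zero derivative) with an implicit BDF solver and an
#' analytic Jacobian. The reaction set spans first-order constants from
#' 3.2e-21 to 1e7 1/s; reactions whose constant is only known to be
#' "effectively instantaneous" are integrated at a capped relaxation rate
#' \code{k_fast} that leaves every equilibrium constant (and hence every
#' computed concentration) unchanged while keeping the system integrable in
#' double precision.
#'
#' @param scenario a \code{\link{micp_scenario}}.
#' @param times output time grid in s; default 400 points over the duration
#'   with a refined first hour.
#' @param state optional initial \code{\link{micp_state}} overriding
#'   \code{initialize_state(scenario)} (used for staged runs).
#' @param rtol,atol relative / absolute integration tolerances.
#' @param k_fast relaxation rate (1/s) substituted for the "instantaneous"
#'   placeholder constants; results are insensitive to it over at least
#'   1e3-1e6.
#' @param method a stiff \pkg{deSolve} method.
#' @param params \code{\link{enzyme_params}}.
#' @return object of class \code{micp_trajectory}: time grid (s),
#'   concentration matrix (time x species, M), derived pH, trapped-CO2 and
#'   headspace-volume-fraction series, the scenario, and integrator
#'   diagnostics.
#' @seealso \code{\link{trapped_co2}}, \code{\link{time_to_equilibrium}}
#' @export
micp_simulate <- function(scenario, times = NULL, state = NULL,
                          rtol = 1e-8, atol = 1e-12, k_fast = 1e4,
                          method = "vode", params = enzyme_params()) {
  sc <- scenario
  if (is.null(state)) state <- initialize_state(sc)
  network <- default_network(sc$buffers, sc$temperature, od = sc$od,
                             kf_R8 = sc$kf_R8)
  if (is.null(times)) {
    tend <- sc$duration_h * 3600
    times <- sort(unique(c(seq(0, min(3600, tend), length.out = 121),
                           seq(0, tend, length.out = 301))))
  }
  biomass <- if (!is.null(sc$growth)) {
    crv <- sc$growth
    function(th) biomass_at(crv, th)
  }
  od_fun <- if (!is.null(sc$growth)) {
    crv <- sc$growth
    att <- crv$attenuation
    function(th) od_at(crv, th) / att
  }
  sys <- .network_odesys(network, sc$v_liq, sc$v_gas, clamped = sc$clamp,
                         biomass = biomass, od_fun = od_fun,
                         params = params, k_fast = k_fast)
  y0 <- c(state$conc[sys$species], hydrolyzed = 0)
  out <- deSolve::ode(y = y0, times = times, func = sys$rhs, parms = NULL,
                      jacfunc = sys$jac, jactype = "fullusr",
                      method = method, rtol = rtol, atol = atol,
                      maxsteps = 1e6)
  if (max(out[, 1]) < max(times)) {
    d <- attr(out, "istate")
    stop("integration failed at t = ", max(out[, 1]),
         " s (steps: ", d[2], "); the stiffest active reactions are the ",
         "fast acid-base equilibria - consider lowering k_fast or rtol")
  }
  conc <- out[, 1 + seq_along(sys$species), drop = FALSE]
  colnames(conc) <- sys$species
  neg <- conc < 0
  if (any(conc[neg] < -1e-9)) {
    w <- which(conc < -1e-9, arr.ind = TRUE)
    stop("negative concentration beyond tolerance for species ",
         paste(unique(colnames(conc)[w[, 2]]), collapse = ", "))
  }
  conc[neg] <- 0
  hyd <- out[, "hydrolyzed"]
  liqC <- intersect(c("CO2aq", "H2CO3", "HCO3", "CO3", "CaCO3", "carbamate"),
                    colnames(conc))
  structure(list(
    times = out[, 1],
    conc = conc,
    hydrolyzed = hyd,
    pH = -log10(pmax(conc[, "H"], 1e-300)),
    trapped = rowSums(conc[, liqC, drop = FALSE]) - hyd,
    headspace_fraction = conc[, "CO2g"] * .micp$R_gas * sc$temperature /
      sc$pressure,
    scenario = sc,
    network = network,
    diagnostics = list(istate = attr(out, "istate"),
                       rstate = attr(out, "rstate"))),
    class = "micp_trajectory")
}

#' @export
print.micp_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat("MICP trajectory '", x$scenario$label, "': ",
      sprintf("%.3g h, %d output points\n", x$times[n] / 3600, n), sep = "")
  cat(sprintf("  pH %.2f -> %.2f | headspace CO2 %.3g -> %.3g vol %% | trapped CO2 %.4g M\n",
              x$pH[1], x$pH[n], 100 * x$headspace_fraction[1],
              100 * x$headspace_fraction[n], x$trapped[n]))
  invisible(x)
}

#' @export
summary.micp_trajectory <- function(object, ...) {
  n <- length(object$times)
  out <- list(
    label = object$scenario$label,
    duration_h = object$times[n] / 3600,
    pH_final = object$pH[n],
    trapped_final_M = object$trapped[n],
    headspace_final_volfrac = object$headspace_fraction[n],
    caco3_final_M = object$conc[n, "CaCO3"],
    urea_final_M = object$conc[n, "urea"],
    steps = object$diagnostics$istate[2])
  class(out) <- "summary.micp_trajectory"
  out
}

#' @export
print.summary.micp_trajectory <- function(x, ...) {
  cat("Scenario:        ", x$label, "\n")
  cat("Duration:        ", format(x$duration_h), "h\n")
  cat("Final pH:        ", format(round(x$pH_final, 3)), "\n")
  cat("Trapped CO2:     ", format(signif(x$trapped_final_M, 4)), "M\n")
  cat("Headspace CO2:   ", format(signif(100 * x$headspace_final_volfrac, 4)),
      "vol %\n")
  cat("CaCO3:           ", format(signif(x$caco3_final_M, 4)), "M\n")
  cat("Residual urea:   ", format(signif(x$urea_final_M, 4)), "M\n")
  cat("Integrator steps:", x$steps, "\n")
  invisible(x)
}

#' @export
as.data.frame.micp_trajectory <- function(x, ...) {
  data.frame(time_s = x$times, x$conc, pH = x$pH,
             trapped_co2_M = x$trapped,
             co2_headspace_volfrac = x$headspace_fraction,
             check.names = FALSE)
}

#' @export
plot.micp_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  th <- x$times / 3600
  graphics::plot(th, 100 * x$headspace_fraction, type = "l", xlab = "time (h)",
                 ylab = "headspace CO2 (vol %)", main = x$scenario$label, ...)
  graphics::plot(th, x$pH, type = "l", xlab = "time (h)", ylab = "pH", ...)
  graphics::plot(th, x$trapped, type = "l", xlab = "time (h)",
                 ylab = "trapped CO2 (M)", ...)
  graphics::matplot(th, x$conc[, c("HCO3", "CO3", "CaCO3")], type = "l",
                    lty = 1, xlab = "time (h)", ylab = "M")
  graphics::legend("topleft", c("HCO3-", "CO3 2-", "CaCO3"), col = 1:3,
                   lty = 1, bty = "n")
  invisible(x)
}

#' Time for an observable to reach its equilibrium band
#'
#' First time after which the observable stays within
#' \code{(1 - fraction) * |total change|} of its final value.
#'
#' @param traj a \code{micp_trajectory}.
#' @param observable species name or \code{"pH"}.
#' @param fraction fraction of the total change that must be completed
#'   (default 0.95).
#' @return time in s.
#' @export
time_to_equilibrium <- function(traj, observable = "pH", fraction = 0.95) {
  y <- if (identical(observable, "pH")) traj$pH else traj$conc[, observable]
  n <- length(y)
  fin <- y[n]
  # require a stationary endpoint: drift over the last decade of time
  lastdec <- traj$times >= traj$times[n] / 10
  drift <- diff(range(y[lastdec]))
  tot <- abs(fin - y[1])
  if (tot == 0) return(0)
  if (drift > 1e-4 * max(abs(fin), tot))
    stop("endpoint not stationary for ", observable,
         "; integrate longer before measuring time to equilibrium")
  inside <- abs(y - fin) <= (1 - fraction) * tot
  stay <- rev(cumprod(rev(inside))) > 0
  traj$times[which(stay)[1]]
}
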