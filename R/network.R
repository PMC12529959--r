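## The reaction network: species table, the 19-reaction set with its rate and
## equilibrium constants, stoichiometry and conservation structure, and the
## mass-action right-hand side with cross-phase transfer terms.

#' Define the pH-buffer set of the growth medium
#'
#' The amino acids of the growth medium are represented by seven monoprotic
#' buffer pairs HQa/Qa- .. HQg/Qg- with fixed acid dissociation constants.
#' Their total concentrations are configurable (the defaults are a plausible
#' order of magnitude for peptone-based media and are not validated against
#' any measurement). An optional extra buffer pair HQx/Qx- represents mineral
#' buffering in reservoir scenarios.
#'
#' @param totals numeric vector of 7 total concentrations (M) for HQa..HQg.
#' @param enabled logical; if \code{FALSE} the buffer species are omitted from
#'   the network entirely.
#' @param extra_total total concentration (M) of the extra buffer pair; 0 to
#'   omit it.
#' @param extra_pKa pKa of the extra buffer.
#' @return a data.frame of class \code{buffer_set} with columns \code{name},
#'   \code{Ka}, \code{total}.
#' @export
buffer_set <- function(totals = rep(0.005, 7), enabled = TRUE,
                       extra_total = 0, extra_pKa = 10) {
  stopifnot(length(totals) == 7, all(is.finite(totals)), all(totals >= 0),
            extra_total >= 0)
  df <- data.frame(name = names(.micp$buffer_Ka),
                   Ka = unname(.micp$buffer_Ka),
                   total = as.numeric(totals),
                   stringsAsFactors = FALSE)
  if (!enabled) df <- df[0, ]
  if (extra_total > 0) {
    df <- rbind(df, data.frame(name = "Qx", Ka = 10^(-extra_pKa),
                               total = extra_total))
  }
  class(df) <- c("buffer_set", "data.frame")
  df
}

## species table for a given buffer set ------------------------------------

.base_species <- function() {
  # name, phase, charge, element counts
  df <- data.frame(
    name   = c("urea", "carbamate", "NH3aq", "NH3g", "NH4", "H2CO3", "HCO3",
               "CO3", "CO2aq", "CO2g", "Ca", "CaCO3", "H", "OH", "Cl"),
    phase  = c("aqueous", "aqueous", "aqueous", "gas", "aqueous", "aqueous",
               "aqueous", "aqueous", "aqueous", "gas", "aqueous",
               "solid_pool", "aqueous", "aqueous", "aqueous"),
    charge = c(0, 0, 0, 0, 1, 0, -1, -2, 0, 0, 2, 0, 1, -1, -1),
    C  = c(1, 1, 0, 0, 0, 1, 1, 1, 1, 1, 0, 1, 0, 0, 0),
    N  = c(2, 1, 1, 1, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    Ca = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 1, 0, 0, 0),
    Cl = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1),
    O  = c(1, 2, 0, 0, 0, 3, 3, 3, 2, 2, 0, 3, 0, 1, 0),
    H  = c(4, 3, 3, 3, 4, 2, 1, 0, 0, 0, 0, 0, 1, 1, 0),
    stringsAsFactors = FALSE)
  df$clampable <- df$name %in% c("CO2g", "Ca")
  df
}

#' Species table of the MICP reaction network
#'
#' @param buffers a \code{\link{buffer_set}}.
#' @return data.frame with one row per chemical species: name, phase
#'   (gas / aqueous / solid_pool; the CaCO3 pool is tracked as a concentration
#'   referenced to the liquid volume), elementary charge, element counts and
#'   a clampable flag. Buffer pairs carry a pseudo-element column \code{Qcore}
#'   identifying the conserved buffer core.
#' @export
micp_species <- function(buffers = buffer_set()) {
  df <- .base_species()
  df$Qcore <- ""
  for (q in buffers$name) {
    add <- data.frame(
      name = c(paste0("H", q), q), phase = "aqueous",
      charge = c(0, -1), C = 0, N = 0, Ca = 0, Cl = 0, O = 0,
      H = c(1, 0), clampable = FALSE, Qcore = q,
      stringsAsFactors = FALSE)
    df <- rbind(df, add)
  }
  df
}

#' Backward rate constant of a reversible reaction
#'
#' From detailed balance, \code{kb = kf / K}. Units of \code{kb} are whatever
#' complements \code{kf} given the units of \code{K}.
#'
#' @param kf forward rate constant.
#' @param K equilibrium constant; \code{NA} marks an irreversible reaction.
#' @return backward rate constant.
#' @export
backward_rate_constant <- function(kf, K) {
  if (is.na(K)) stop("irreversible reaction: no backward rate")
  if (K <= 0) stop("equilibrium constant must be positive: no backward rate")
  kf / K
}

.reaction <- function(id, reactants, products, kind, kf, K = NA_real_,
                      water = 0) {
  if (!is.na(K) && K <= 0) stop("negative or zero equilibrium constant in ", id)
  if (kf < 0) stop("negative rate constant in ", id)
  structure(list(id = id, reactants = reactants, products = products,
                 kind = kind, kf = kf, K = K,
                 kb = if (is.na(K)) 0 else kf / K,
                 water = water),
            class = "micp_reaction")
}

#' Assemble the full MICP reaction network
#'
#' Builds the 19-reaction network (ureolysis, carbamate decay, ammonia and
#' carbonate speciation, calcium carbonate precipitation, gas-liquid transfer
#' of CO2 and NH3, water self-ionization and the buffer dissociations) with
#' its published forward rate constants and equilibrium constants, plus the
#' urease-catalyzed ureolysis channel whose rate is supplied at simulation
#' time by the Michaelis-Menten law.
#'
#' Reactions written with an explicit water molecule absorb it into the
#' constants (constant water activity, 55.5 M), so their rate expressions are
#' first-order in the non-water reactant; the signed \code{water} field
#' records the implicit H2O stoichiometry for the element-balance audit.
#'
#' @param buffers a \code{\link{buffer_set}}; a disabled set yields a network
#'   without any buffer species or reactions.
#' @param temperature temperature in K; constants are valid for roughly
#'   20-30 C and a value outside 10-40 C is rejected.
#' @param od optical density (OD600) used for the carbonic anhydrase rate
#'   constant of CO2 hydration stored in the network; time-varying OD is
#'   handled by the simulator.
#' @param kf_R8 forward (gas-to-liquid) effective transfer constant of CO2
#'   dissolution in 1/s; an experimental shaking-incubator estimate by
#'   default.
#' @return object of class \code{micp_network}: species table, reaction list,
#'   stoichiometry matrix \code{S} (species x reactions, flux referenced to
#'   the liquid volume) and conservation matrix for total C, N, Ca and charge.
#' @seealso \code{\link{mass_action_rhs}}, \code{\link{micp_simulate}}
#' @export
default_network <- function(buffers = buffer_set(), temperature = 303.15,
                            od = 0, kf_R8 = 2e-2) {
  if (temperature < 283.15 || temperature > 313.15)
    stop("temperature outside the 10-40 C validity range of the constants")
  k <- .micp
  kinst <- 1e10  # "instantaneous" placeholder; capped at integration time
  rx <- list(
    .reaction("R1", c(urea = 1), c(carbamate = 1, NH3aq = 1),
              "irreversible_mass_action", 3.2e-21, water = -1),
    .reaction("R1cat", c(urea = 1), c(carbamate = 1, NH3aq = 1),
              "ureolysis_mm", 0, water = -1),
    .reaction("R2", c(carbamate = 1), c(NH3aq = 1, H2CO3 = 1),
              "irreversible_mass_action", kinst, water = -1),
    .reaction("R3", c(NH3aq = 1), c(NH4 = 1, OH = 1),
              "reversible_mass_action", kinst, k$K_R3, water = -1),
    .reaction("R4", c(NH3aq = 1), c(NH3g = 1), "gas_transfer", kinst, k$K_R4),
    .reaction("R5", c(H2CO3 = 1), c(HCO3 = 1, H = 1),
              "reversible_mass_action", 1e7, k$K_R5),
    .reaction("R6", c(HCO3 = 1), c(CO3 = 1, H = 1),
              "reversible_mass_action", 3, k$K2),
    .reaction("R7", c(Ca = 1, CO3 = 1), c(CaCO3 = 1),
              "reversible_mass_action", 2, k$K_R7),
    .reaction("R8", c(CO2g = 1), c(CO2aq = 1), "gas_transfer", kf_R8, k$K_R8),
    .reaction("R9", c(CO2aq = 1), c(H2CO3 = 1), "ca_hydration",
              ca_rate_constant(od), k$K1 / k$K_R5, water = -1),
    .reaction("R10", c(H = 1, OH = 1), c(), "reversible_mass_action",
              1.4e11, 1 / k$Kw, water = 1),
    .reaction("R11", c(HCO3 = 1, OH = 1), c(CO3 = 1),
              "reversible_mass_action", 6e9, k$K2 / k$Kw, water = 1),
    .reaction("R12", c(CO2aq = 1, OH = 1), c(HCO3 = 1),
              "reversible_mass_action", 8.5e3, k$K1 / k$Kw)
  )
  if (nrow(buffers)) {
    for (i in seq_len(nrow(buffers))) {
      q <- buffers$name[i]
      id <- if (q == "Qx") "R20" else paste0("R", 12 + match(q, names(.micp$buffer_Ka)))
      rx <- c(rx, list(.reaction(id,
        stats::setNames(1, paste0("H", q)),
        stats::setNames(c(1, 1), c(q, "H")),
        "reversible_mass_action", kinst, buffers$Ka[i])))
    }
  }
  names(rx) <- vapply(rx, `[[`, "", "id")
  species <- micp_species(buffers)
  S <- matrix(0, nrow(species), length(rx),
              dimnames = list(species$name, names(rx)))
  for (j in seq_along(rx)) {
    for (n in names(rx[[j]]$reactants))
      S[n, j] <- S[n, j] - rx[[j]]$reactants[[n]]
    for (n in names(rx[[j]]$products))
      S[n, j] <- S[n, j] + rx[[j]]$products[[n]]
  }
  cons <- rbind(C = species$C, N = species$N, Ca = species$Ca,
                charge = species$charge)
  colnames(cons) <- species$name
  structure(list(species = species, reactions = rx, S = S,
                 conservation = cons, buffers = buffers,
                 temperature = temperature, od = od, kf_R8 = kf_R8),
            class = "micp_network")
}

#' @export
print.micp_network <- function(x, ...) {
  cat("MICP reaction network:", length(x$reactions), "reactions,",
      nrow(x$species), "species\n")
  cat("  buffers:", if (nrow(x$buffers)) paste(x$buffers$name, collapse = " ")
      else "(disabled)", "\n")
  cat("  kf(R8) =", x$kf_R8, "1/s, kf(R9) =", x$reactions$R9$kf,
      "1/s (OD", x$od, ")\n")
  invisible(x)
}

#' Audit element and charge balance of every reaction
#'
#' Checks that each reaction, counting its implicit water molecules, balances
#' C, N, Ca, Cl, O, H, each buffer core and total charge.
#'
#' @param network a \code{micp_network}.
#' @return data.frame with one row per reaction and the maximum absolute
#'   imbalance over all conserved quantities (0 for a balanced reaction).
#' @export
reaction_balance <- function(network) {
  sp <- network$species
  water <- c(C = 0, N = 0, Ca = 0, Cl = 0, O = 1, H = 2)
  elems <- c("C", "N", "Ca", "Cl", "O", "H")
  rows <- lapply(network$reactions, function(r) {
    bal <- stats::setNames(numeric(length(elems) + 2),
                           c(elems, "Qcore", "charge"))
    acc <- function(side, sign) {
      for (n in names(side)) {
        i <- match(n, sp$name)
        bal[elems] <<- bal[elems] + sign * side[[n]] * unlist(sp[i, elems])
        bal["charge"] <<- bal["charge"] + sign * side[[n]] * sp$charge[i]
        if (sp$Qcore[i] != "")
          bal["Qcore"] <<- bal["Qcore"] + sign * side[[n]]
      }
    }
    acc(r$reactants, -1)
    acc(r$products, 1)
    bal[elems] <- bal[elems] + r$water * water
    data.frame(id = r$id, max_imbalance = max(abs(bal)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## reactor state -------------------------------------------------------------

#' Construct a two-phase reactor state
#'
#' @param conc named concentration vector (M); gas species are molar in the
#'   gas phase, all others molar in the liquid (the CaCO3 pool is referenced
#'   to the liquid volume).
#' @param v_liq,v_gas liquid and headspace volumes in L.
#' @param temperature K.
#' @param pressure atm.
#' @param clamped character vector of species held constant (external
#'   reservoir).
#' @param time time in s.
#' @return object of class \code{micp_state}.
#' @export
micp_state <- function(conc, v_liq = 0.05, v_gas = 0.2,
                       temperature = 303.15, pressure = 1,
                       clamped = character(), time = 0) {
  stopifnot(v_liq > 0, !is.null(names(conc)))
  structure(list(conc = conc, v_liq = v_liq, v_gas = v_gas,
                 temperature = temperature, pressure = pressure,
                 clamped = clamped, time = time),
            class = "micp_state")
}

## Internal: compiled ODE system over a network ------------------------------
## Returns rhs and analytic Jacobian closures over the state vector
## c(species, hydrolyzed). Fast "instantaneous" reactions are integrated at a
## capped relaxation rate k_fast that preserves every equilibrium constant.
.network_odesys <- function(network, v_liq, v_gas, clamped = character(),
                            biomass = NULL, od_fun = NULL,
                            params = enzyme_params(), k_fast = 1e4) {
  sp <- network$species$name
  nsp <- length(sp)
  idx <- stats::setNames(seq_len(nsp), sp)
  rx <- network$reactions
  nrx <- length(rx)
  kf <- vapply(rx, `[[`, 0, "kf")
  kb <- vapply(rx, `[[`, 0, "kb")
  # reactions whose printed constant is the "instantaneous" placeholder; the
  # measured large constants (R5, R10, R11) are never touched
  inst <- names(rx) %in% c("R2", "R3", "R4", paste0("R", 13:20)) |
    (names(rx) == "R8" & kf >= 1e9)
  # cap relaxation of "instantaneous" reactions, preserving K
  resc <- which(inst & kf > k_fast)
  kb[resc] <- kb[resc] * (k_fast / kf[resc])
  kf[resc] <- k_fast
  if (is.null(od_fun)) {
    kf["R9"] <- network$reactions$R9$kf
    kb["R9"] <- kf["R9"] / network$reactions$R9$K
  }
  K_R9 <- network$reactions$R9$K
  rlist <- lapply(rx, function(r) unname(idx[names(r$reactants)]))
  plist <- lapply(rx, function(r) unname(idx[names(r$products)]))
  j_mm <- match("R1cat", names(rx))
  gas <- which(network$species$phase == "gas")
  scale <- rep(1, nsp)
  if (length(gas)) {
    if (v_gas <= 0) stop("gas transfer is ill-posed with zero gas volume")
    scale[gas] <- v_liq / v_gas
  }
  Ssc <- network$S * scale
  # hydrolyzed-urea tally rides along as state nsp+1, fed by R1 + R1cat
  hyd_cols <- c(match("R1", names(rx)), j_mm)
  clampi <- unname(idx[clamped[clamped %in% sp]])
  vmax <- params$vmax_mmol_h_cfu
  km <- params$km
  rhs <- function(t, y, parms) {
    yc <- y[seq_len(nsp)]
    fwd <- kf
    bwd <- kb
    if (!is.null(od_fun)) {
      kR9 <- 0.065 + 0.117 * od_fun(t / 3600)
      fwd[["R9"]] <- kR9
      bwd[["R9"]] <- kR9 / K_R9
    }
    for (j in seq_len(nrx)) {
      for (i in rlist[[j]]) fwd[j] <- fwd[j] * yc[i]
      for (i in plist[[j]]) bwd[j] <- bwd[j] * yc[i]
    }
    rate <- fwd - bwd
    if (!is.null(biomass)) {
      X <- biomass(t / 3600)
      rate[j_mm] <- X * vmax * yc[1] / (km + yc[1]) / 3600
    }
    dy <- as.vector(Ssc %*% rate)
    if (length(clampi)) dy[clampi] <- 0
    c(dy, sum(rate[hyd_cols]))
  }
  jac <- function(t, y, parms) {
    yc <- y[seq_len(nsp)]
    fwd <- kf
    bwd <- kb
    if (!is.null(od_fun)) {
      kR9 <- 0.065 + 0.117 * od_fun(t / 3600)
      fwd[["R9"]] <- kR9
      bwd[["R9"]] <- kR9 / K_R9
    }
    dR <- matrix(0, nrx, nsp + 1)
    for (j in seq_len(nrx)) {
      rl <- rlist[[j]]
      pl <- plist[[j]]
      for (i in rl) {
        v <- fwd[j]
        for (kk in setdiff(rl, i)) v <- v * yc[kk]
        dR[j, i] <- dR[j, i] + v
      }
      for (i in pl) {
        v <- bwd[j]
        for (kk in setdiff(pl, i)) v <- v * yc[kk]
        dR[j, i] <- dR[j, i] - v
      }
    }
    if (!is.null(biomass)) {
      X <- biomass(t / 3600)
      dR[j_mm, ] <- 0
      dR[j_mm, 1] <- X * vmax * km / (km + yc[1])^2 / 3600
    }
    J <- rbind(cbind(Ssc %*% dR[, seq_len(nsp)], 0),
               c(colSums(dR[hyd_cols, seq_len(nsp), drop = FALSE]), 0))
    if (length(clampi)) J[clampi, ] <- 0
    J
  }
  list(rhs = function(t, y, parms) list(rhs(t, y, parms)),
       jac = jac, species = sp, idx = idx, scale = scale)
}

#' Mass-action derivative of a reactor state
#'
#' Evaluates the right-hand side of the coupled rate equations at one state:
#' for a reversible reaction A + B <-> C the net rate is
#' \code{-kf[A][B] + kb[C]}, gas-transfer reactions use the same form with an
#' effective transfer constant, and the derivative of each gas species is
#' scaled by the volume ratio so that moles are conserved across phases.
#' Clamped species receive derivative zero.
#'
#' @param network a \code{micp_network}.
#' @param state a \code{\link{micp_state}}; concentrations more negative than
#'   \code{-1e-9} M are rejected.
#' @param t time in s (only relevant when \code{biomass} varies in time).
#' @param biomass optional function of time (h) giving CFU/mL for the
#'   catalyzed ureolysis channel.
#' @param params \code{\link{enzyme_params}}.
#' @return named vector of concentration derivatives in M/s (per species in
#'   its own phase), plus the urea-hydrolysis tally rate as attribute
#'   \code{hydrolyzed}.
#' @export
mass_action_rhs <- function(network, state, t = 0, biomass = NULL,
                            params = enzyme_params()) {
  conc <- state$conc[network$species$name]
  if (anyNA(conc))
    stop("state is missing species: ",
         paste(setdiff(network$species$name, names(state$conc)),
               collapse = ", "))
  bad <- which(conc < -1e-9 | !is.finite(conc))
  if (length(bad))
    stop("invalid concentration for species ",
         paste(names(conc)[bad], collapse = ", "))
  sys <- .network_odesys(network, state$v_liq, state$v_gas,
                         clamped = state$clamped, biomass = biomass,
                         params = params, k_fast = Inf)
  dy <- sys$rhs(t, c(pmax(conc, 0), 0), NULL)[[1]]
  out <- stats::setNames(dy[seq_along(conc)], names(conc))
  attr(out, "hydrolyzed") <- dy[length(dy)]
  out
}

#' Gas-liquid transfer derivatives of one transfer reaction
#'
#' The two-film transfer flux is expressed like a chemical reaction,
#' \code{flux = kf [gas] - kb [aq]} (referenced to the liquid volume), with
#' \code{kb = kf / K} and K the Henry-law partition ratio. Mole conservation
#' across phases requires the gas-side derivative to be the liquid-side flux
#' scaled by \code{-v_liq / v_gas}.
#'
#' @param reaction a gas-transfer \code{micp_reaction} (CO2 or NH3 transfer).
#' @param state a \code{\link{micp_state}}.
#' @return named vector with the gas-side and liquid-side derivatives (M/s in
#'   each phase's own volume); a clamped gas species gets derivative 0 while
#'   the liquid still receives the flux.
#' @export
gas_transfer_terms <- function(reaction, state) {
  if (reaction$kind != "gas_transfer")
    stop(reaction$id, " is not a gas-transfer reaction")
  if (state$v_gas <= 0) stop("gas transfer is ill-posed with zero gas volume")
  # forward direction as written: R8 gas->aq, R4 aq->gas
  rn <- names(reaction$reactants)
  pn <- names(reaction$products)
  flux <- reaction$kf * state$conc[[rn]] - reaction$kb * state$conc[[pn]]
  gas_sp <- if (rn %in% c("CO2g", "NH3g")) rn else pn
  liq_sp <- setdiff(c(rn, pn), gas_sp)
  d_liq <- if (liq_sp == pn) flux else -flux
  d_gas <- -d_liq * state$v_liq / state$v_gas
  if (gas_sp %in% state$clamped) d_gas <- 0
  stats::setNames(c(d_gas, d_liq), c(gas_sp, liq_sp))
}
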