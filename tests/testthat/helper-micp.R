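## shared fixtures and oracles

# constant-OD growth curve (pre-grown culture), flat at `od`
flat_growth <- function(od = 5) {
  growth_curve(od = rep(od, 8), peak_time = 24, series = "flat")
}

# total moles of one conserved element across both phases
element_moles <- function(traj, element) {
  sp <- traj$network$species
  w <- sp[[element]]
  vol <- ifelse(sp$phase == "gas", traj$scenario$v_gas, traj$scenario$v_liq)
  as.vector(traj$conc %*% (w * vol))
}

# net explicit-ion charge of the liquid (mol), a dynamical invariant
charge_moles <- function(traj) {
  sp <- traj$network$species
  as.vector(traj$conc %*% (sp$charge * traj$scenario$v_liq))
}

# closed-form abiotic carbonate speciation under a clamped CO2(g) headspace:
# charge balance [H+] = [HCO3-] + 2[CO3^2-] + [OH-] solved directly.
# Independent of the package's equilibrium solver.
abiotic_dissolved_carbon <- function(co2_fraction, temperature = 303.15) {
  K1 <- 4.47e-7; K2 <- 4.68e-11; Kw <- 1e-14; KH <- 0.84
  co2aq <- KH * co2_fraction / (0.082057366 * temperature)
  f <- function(H) H - K1 * co2aq / H - 2 * K1 * K2 * co2aq / H^2 - Kw / H
  H <- uniroot(f, c(1e-12, 1e-2), tol = 1e-18)$root
  hco3 <- K1 * co2aq / H
  list(pH = -log10(H),
       dic = co2aq + (K1 / 1.7e-4) * co2aq + hco3 + K2 * hco3 / H)
}

# construct a state satisfying every equilibrium relation exactly
# (detailed-balance fixed point); urea and carbamate zero so the
# irreversible channels are silent
balanced_state <- function(pH = 8, co2g = 0.02, nh3 = 0.01, ca = 0.001,
                           buffers = buffer_set()) {
  k <- micptrap:::.micp
  H <- 10^(-pH); OH <- k$Kw / H
  co2aq <- k$K_R8 * co2g
  h2co3 <- (k$K1 / k$K_R5) * co2aq
  hco3 <- k$K_R5 * h2co3 / H
  co3 <- k$K2 * hco3 / H
  y <- c(urea = 0, carbamate = 0, NH3aq = nh3, NH3g = k$K_R4 * nh3,
         NH4 = k$K_R3 * nh3 / OH, H2CO3 = h2co3, HCO3 = hco3, CO3 = co3,
         CO2aq = co2aq, CO2g = co2g, Ca = ca, CaCO3 = k$K_R7 * ca * co3,
         H = H, OH = OH, Cl = 2 * ca)
  if (nrow(buffers)) {
    q <- buffers$total * buffers$Ka / (buffers$Ka + H)
    y[buffers$name] <- q
    y[paste0("H", buffers$name)] <- buffers$total - q
  }
  micp_state(y)
}
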