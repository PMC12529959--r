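test_that("initialization equilibrates pH, buffers and headspace", {
  st <- initialize_state(micp_scenario(urea = 0.333, ca = 0.18,
                                       co2_fraction = 0.5))
  expect_equal(unname(st$conc["H"]), 5.011872e-8, tolerance = 1e-6)
  expect_equal(unname(st$conc["OH"]), 1e-14 / 10^(-7.3), tolerance = 1e-9)
  expect_equal(unname(st$conc["CO2g"]), 0.020099, tolerance = 1e-4)
  # buffer HQg (Ka 7.9e-8) is ~61% dissociated at pH 7.3
  frac <- st$conc["Qg"] / (st$conc["Qg"] + st$conc["HQg"])
  expect_equal(unname(frac), 0.6119, tolerance = 1e-3)
  expect_equal(unname(st$conc["Cl"]), 0.36)
  # everything not initially present is zero
  expect_equal(unname(st$conc[c("NH3aq", "NH4", "HCO3", "CO3", "CaCO3")]),
               rep(0, 5))
})

test_that("clamped species stay exactly constant; closed runs conserve mass", {
  sc <- micp_scenario(urea = 0.1, co2_fraction = 0.5, clamp = "CO2g",
                      growth = flat_growth(2), duration_h = 10,
                      label = "clamped")
  tr <- micp_simulate(sc)
  expect_true(all(tr$conc[, "CO2g"] == tr$conc[1, "CO2g"]))

  # closed bottle, bacteria, buffers: conservation audit over 24 h
  scc <- micp_scenario(urea = 0.333, ca = 0.18, co2_fraction = 0.5,
                       growth = flat_growth(1), duration_h = 24,
                       label = "closed")
  trc <- micp_simulate(scc)
  for (el in c("C", "N", "Ca")) {
    m <- element_moles(trc, el)
    expect_lt(max(abs(m - m[1])) / m[1], 1e-6)
  }
  q <- charge_moles(trc)
  qscale <- sum(abs(trc$network$species$charge) * trc$conc[1, ]) *
    scc$v_liq
  expect_lt(max(abs(q - q[1])) / qscale, 1e-6)
  # no meaningful negative excursions survive in the output
  expect_true(all(trc$conc >= 0))
})

test_that("abiotic dissolution gives the sharp early headspace drop", {
  tr <- micp_simulate(micp_preset("control_50"))
  f5min <- tr$headspace_fraction[which.min(abs(tr$times - 300))]
  expect_lt(f5min, 0.45)  # well below the initial 50 vol % within 5 min
  # approach to the dissolution equilibrium always from above
  fin <- tr$headspace_fraction[length(tr$times)]
  # (tolerance at the integrator's error level)
  expect_true(all(tr$headspace_fraction >= fin - 1e-8))
})

test_that("headspace response reproduces the trapping/outgassing signs", {
  lo <- micp_simulate(micp_preset("bacteria_0.04"))
  hi <- micp_simulate(micp_preset("bacteria_50"))
  n <- length(lo$times)
  # net outgassing at atmospheric CO2: headspace rises, trapped < 0
  expect_gt(lo$headspace_fraction[n], lo$headspace_fraction[1])
  expect_lt(lo$trapped[n], 0)
  # net trapping at 50 vol %
  expect_lt(hi$headspace_fraction[n], hi$headspace_fraction[1])
  expect_gt(hi$trapped[n], 0)
})

test_that("endpoints are stable under tolerance refinement and k_fast", {
  sc <- micp_scenario(urea = 0.1, co2_fraction = 0.5, clamp = "CO2g",
                      growth = flat_growth(2), duration_h = 6,
                      label = "refine")
  t1 <- micp_simulate(sc)
  t2 <- micp_simulate(sc, rtol = 5e-9, atol = 5e-13)
  t3 <- micp_simulate(sc, k_fast = 1e5)
  n <- length(t1$times)
  big <- t1$conc[n, ] > 1e-10
  expect_lt(max(abs(t2$conc[n, big] / t1$conc[n, big] - 1)), 1e-4)
  expect_lt(max(abs(t3$conc[n, big] / t1$conc[n, big] - 1)), 1e-4)
})

test_that("time_to_equilibrium is monotone in the threshold", {
  tr <- micp_simulate(micp_preset("fig7_ca"), times = seq(0, 7200, by = 2))
  t95 <- time_to_equilibrium(tr, "HCO3", 0.95)
  t99 <- time_to_equilibrium(tr, "HCO3", 0.99)
  expect_gte(t99, t95)
  expect_error(
    time_to_equilibrium(micp_simulate(micp_preset("fig7_ca"),
                                      times = seq(0, 60, by = 1)),
                        "HCO3"),
    "stationary")
})

test_that("carbonic anhydrase accelerates equilibration only for fast R8", {
  base <- micp_preset("fig7_ca")
  run <- function(od, kf) {
    sc <- base; sc$od <- od; sc$kf_R8 <- kf
    time_to_equilibrium(micp_simulate(sc, times = seq(0, 7200, by = 2)),
                        "HCO3")
  }
  # instantaneous dissolution: CA shortens the approach to equilibrium
  expect_lt(run(5, 1e10), run(0, 1e10) / 2)
  # slow dissolution: transfer-limited either way
  slow_ca <- run(5, 2e-2)
  slow_no <- run(0, 2e-2)
  expect_lt(abs(slow_ca - slow_no) / slow_no, 0.25)
})

test_that("the sedimentary two-stage scenario behaves as intended", {
  tr <- run_sedimentary_step3()
  pre <- attr(tr, "pre")
  expect_s3_class(pre, "micp_equilibrium")
  expect_gt(pre$caco3, 0)  # injection-stage equilibrium already precipitates
  # urea is consumed to < 1% of its injected 0.33 M
  expect_lt(tr$conc[length(tr$times), "urea"], 0.0033)
  # pH rises substantially after the injection
  expect_gt(max(tr$pH) - tr$pH[1], 1)
  # CaCO3 never redissolves during the run
  expect_true(all(diff(tr$conc[, "CaCO3"]) > -1e-10))
})
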