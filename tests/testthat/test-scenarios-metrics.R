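test_that("unit conversions match the printed reference values", {
  expect_equal(gas_molarity(1.0), 0.0402, tolerance = 1e-3)
  expect_equal(gas_molarity(0.82), 0.033, tolerance = 2e-3)
  expect_identical(gas_molarity(0), 0)
  expect_equal(mass_to_molar(20, 60.06), 0.333, tolerance = 1e-3)
  expect_equal(mass_to_molar(20, 110.98), 0.180, tolerance = 2e-3)
  expect_identical(mass_to_molar(0, 60.06), 0)
})

test_that("trapped CO2 accounting covers states, equilibria, trajectories", {
  # empty system: nothing trapped
  empty <- initialize_state(micp_scenario(co2_fraction = 0))
  expect_identical(trapped_co2(empty), 0)
  # trajectory and its endpoint state agree
  tr <- micp_simulate(micp_preset("fig14_constant100"),
                      times = seq(0, 12 * 3600, length.out = 50))
  n <- length(tr$times)
  st <- micp_state(tr$conc[n, ])
  expect_equal(trapped_co2(st, hydrolyzed = tr$hydrolyzed[n]),
               tr$trapped[n])
  # carbon pools sum to total C minus nothing in a closed system
  trc <- micp_simulate(micp_preset("control_50"),
                       times = seq(0, 3600, length.out = 30))
  p0 <- carbon_pools(trc, 1)
  p1 <- carbon_pools(trc)
  tot <- function(p) sum(p[c("gas_co2", "dic", "caco3", "carbamate", "urea")])
  expect_equal(tot(p1), tot(p0), tolerance = 1e-8)
})

test_that("presets populate the boundary-condition table", {
  f7 <- micp_preset("fig7_ca")
  expect_identical(f7$urea, 0)
  expect_identical(f7$clamp, "CO2g")
  expect_identical(f7$od, 5)
  expect_gt(nrow(f7$buffers), 0)

  f8 <- micp_preset("fig8_step3")
  expect_true("Qx" %in% f8$buffers$name)
  expect_equal(f8$buffers$total[f8$buffers$name == "Qx"], 0.66)
  expect_equal(f8$buffers$Ka[f8$buffers$name == "Qx"], 1e-10)
  expect_identical(f8$pH, 10)

  b60 <- micp_preset("bacteria_60")
  expect_identical(b60$co2_fraction, 0.7)  # reinterpreted starting fraction
  expect_identical(b60$growth$peak_time, 31)
  bca <- micp_preset("bacteria_ca_50", attenuation = 250)
  expect_identical(bca$growth$attenuation, 250)
  expect_equal(bca$ca, 0.180, tolerance = 2e-3)
  ctrl <- micp_preset("control_50")
  expect_null(ctrl$growth)

  expect_error(micp_preset("fig99"), "unknown preset")
  expect_true(all(vapply(preset_names(), function(nm)
    inherits(micp_preset(nm), "micp_scenario"), TRUE)))
  expect_match(paste(describe_scenario(f7), collapse = "\n"), "OD600 = 5")
})

test_that("model reproduces the trapping fold-increase ratios", {
  # 0.33 M urea under constant pure CO2: ~8.6x over gas-phase storage
  eq100 <- micp_equilibrium(micp_scenario(
    urea = mass_to_molar(20, 60.06), co2_fraction = 1, clamp = "CO2g",
    buffers = buffer_set(enabled = FALSE)))
  expect_equal(eq100$trapped / gas_molarity(1), 8.6, tolerance = 0.03)
  # capacity maximum at 82 vol %: ~80x over gas storage, ~93x over pure water
  sw <- trapped_sweep(urea_grid = c(seq(0.5, 12, length.out = 40)),
                      co2_fraction = 0.82)
  mx <- attr(sw, "argmax")$trapped_M
  expect_equal(mx / gas_molarity(0.82), 80, tolerance = 0.05)
  expect_equal(mx / abiotic_dissolved_carbon(0.82)$dic, 93, tolerance = 0.05)
})

test_that("constant-headspace kinetics reach the thermodynamic capacity", {
  tr <- micp_simulate(micp_preset("fig14_constant100"))
  eq <- micp_equilibrium(tr$scenario)
  expect_equal(tr$trapped[length(tr$times)], eq$trapped, tolerance = 5e-3)
  # equilibrium reached within half a day
  half_day <- which.min(abs(tr$times - 12 * 3600))
  expect_equal(tr$trapped[half_day], eq$trapped, tolerance = 5e-3)
})
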