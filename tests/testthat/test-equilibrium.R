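test_that("equilibrium requires a clamped headspace and converges cleanly", {
  expect_error(micp_equilibrium(micp_scenario(urea = 0.1)), "clamped")
  eq <- micp_equilibrium(micp_scenario(urea = 0.333, co2_fraction = 1,
                                       clamp = "CO2g",
                                       buffers = buffer_set(enabled = FALSE)))
  expect_lt(abs(eq$residuals["charge"]), 1e-10)
  expect_lt(abs(eq$residuals["quotient"]), 1e-8)
  # urea fully hydrolyzed at equilibrium
  expect_identical(unname(eq$conc["urea"]), 0)
})

test_that("urea -> 0 recovers the closed-form abiotic carbonate system", {
  for (f in c(0.1, 0.5, 0.82)) {
    ora <- abiotic_dissolved_carbon(f)
    eq <- micp_equilibrium(micp_scenario(urea = 0, co2_fraction = f,
                                         clamp = "CO2g",
                                         buffers = buffer_set(enabled = FALSE),
                                         pH = 7))
    expect_equal(eq$pH, ora$pH, tolerance = 1e-3)
    expect_equal(eq$dic, ora$dic, tolerance = 1e-3)
    expect_equal(eq$trapped, ora$dic, tolerance = 1e-3)
  }
})

test_that("algebraic equilibria match long-horizon kinetic integration", {
  # randomized clamped-headspace scenarios; the pre-grown culture hydrolyzes
  # the urea completely well inside the horizon, and urea >= 3 Ca keeps the
  # endpoint alkaline enough that the solid pool equilibrates by fast
  # precipitation rather than its ~3-year dissolution mode
  set.seed(42)
  n_match <- 0
  for (i in 1:10) {
    urea <- runif(1, 0.05, 0.4)
    sc <- micp_scenario(
      urea = urea,
      ca = sample(c(0, runif(1, 0.01, urea / 3)), 1),
      co2_fraction = runif(1, 0.05, 1),
      clamp = "CO2g",
      buffers = if (i %% 2) buffer_set() else buffer_set(enabled = FALSE),
      growth = flat_growth(5), kf_R8 = 1, duration_h = 100,
      label = paste0("rand", i))
    eq <- micp_equilibrium(sc)
    tr <- micp_simulate(sc)
    yk <- tr$conc[length(tr$times), ]
    ye <- eq$conc[names(eq$conc) %in% colnames(tr$conc)]
    comp <- names(ye)[ye > 1e-10]
    comp <- setdiff(comp, c("urea", "carbamate"))
    rel <- abs(yk[comp] / ye[comp] - 1)
    expect_lt(max(rel), 1e-3, label = paste("species mismatch in", sc$label))
    expect_equal(tr$trapped[length(tr$times)], eq$trapped, tolerance = 1e-3)
    n_match <- n_match + 1
  }
  expect_equal(n_match, 10)
})

test_that("CaCO3 capacity map: monotone in calcium, capped by urea", {
  sw <- caco3_map(ca_grid = seq(0.05, 1, length.out = 12),
                  co2_fraction_grid = c(0.0004, 0.5, 1))
  expect_false(any(sw$failed))
  u0 <- mass_to_molar(20, 60.06)
  expect_lte(max(sw$caco3_M), u0 * (1 + 1e-6))
  for (f in unique(sw$co2_volfrac)) {
    s <- sw[sw$co2_volfrac == f, ]
    expect_true(all(diff(s$caco3_M) > -1e-9))
    # pH roughly flat below the urea-equivalent Ca, dropping sharply above
    expect_lt(diff(range(s$pH[s$ca_M < 0.3])), 1)
    expect_lt(s$pH[nrow(s)], s$pH[which.min(abs(s$ca_M - 0.25))] - 1.5)
  }
})

test_that("trapped CO2 vs urea is unimodal without buffers", {
  grid <- c(1e-4, 1e-3, 1e-2, seq(0.05, 10, length.out = 60))
  for (f in c(0.0004, 0.1, 0.5, 1)) {
    sw <- trapped_sweep(urea_grid = grid, co2_fraction = f)
    y <- sw$trapped_M
    s <- sign(diff(y))
    s <- s[s != 0]
    expect_identical(sum(diff(s) != 0), 1L,
                     label = paste("single interior maximum at", f))
    am <- attr(sw, "argmax")
    expect_gte(am$trapped_M, max(y) - 1e-9)
  }
})

test_that("clamped-calcium equilibria keep a well-posed charge balance", {
  sc <- micp_scenario(urea = 0.333, ca = 0.05, co2_fraction = 1,
                      clamp = c("CO2g", "Ca"),
                      buffers = buffer_set(enabled = FALSE))
  eq <- micp_equilibrium(sc)
  expect_equal(unname(eq$conc["Ca"]), 0.05)
  expect_lt(abs(eq$residuals["charge"]), 1e-10)
})
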