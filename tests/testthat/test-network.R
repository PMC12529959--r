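test_that("every reaction balances elements, buffer cores and charge", {
  for (buf in list(buffer_set(), buffer_set(enabled = FALSE),
                   buffer_set(extra_total = 0.66, extra_pKa = 10))) {
    bal <- reaction_balance(default_network(buf))
    expect_true(all(bal$max_imbalance == 0), label = "stoichiometry audit")
  }
})

test_that("network composition follows the constant table", {
  nw <- default_network()
  expect_length(setdiff(names(nw$reactions), "R1cat"), 19)
  buf_rx <- grep("^R1[3-9]$", names(nw$reactions), value = TRUE)
  expect_length(buf_rx, 7)
  # spot-check derived backward constants kb = kf / K
  expect_equal(nw$reactions$R5$kb, 1e7 / 1.7e-4, tolerance = 1e-12)
  expect_equal(nw$reactions$R6$kb, 3 / 4.68e-11, tolerance = 1e-12)
  expect_equal(nw$reactions$R7$kb, 2 / 2e8, tolerance = 1e-12)
  # disabling buffers leaves no residual species or reactions
  nw0 <- default_network(buffer_set(enabled = FALSE))
  expect_false(any(grepl("Q", nw0$species$name)))
  expect_false(any(grepl("^R1[3-9]$|^R20$", names(nw0$reactions))))
  expect_error(default_network(temperature = 400), "validity")
})

test_that("backward_rate_constant divides and rejects irreversibility", {
  expect_equal(backward_rate_constant(1e7, 1.7e-4), 5.882353e10,
               tolerance = 1e-6)
  expect_equal(backward_rate_constant(3, 4.68e-11), 6.410256e10,
               tolerance = 1e-6)
  expect_error(backward_rate_constant(1e10, NA), "no backward rate")
  expect_error(backward_rate_constant(1e10, 0), "no backward rate")
})

test_that("a state satisfying all equilibrium constants is a fixed point", {
  nw <- default_network()
  for (pH in c(6, 8, 10)) {
    st <- balanced_state(pH = pH)
    dy <- mass_action_rhs(nw, st)
    # dominant flux scale: the largest one-way term is the fast buffer
    # dissociation kf * [HQ] ~ 1e10 * 5e-3
    scale <- 1e10 * max(st$conc[paste0("H", buffer_set()$name)])
    expect_lt(max(abs(dy)), 1e-12 * scale)
  }
})

test_that("mass_action_rhs flags bad states and clamps derivatives", {
  nw <- default_network()
  st <- balanced_state()
  st$conc["HCO3"] <- -1e-6
  expect_error(mass_action_rhs(nw, st), "HCO3")
  st2 <- balanced_state()
  st2$conc["CO2g"] <- st2$conc["CO2g"] * 2  # out of transfer equilibrium
  st2$clamped <- "CO2g"
  dy <- mass_action_rhs(nw, st2)
  expect_identical(unname(dy["CO2g"]), 0)
  expect_gt(dy["CO2aq"], 0)  # liquid still receives the dissolution flux
})

test_that("gas transfer conserves moles across phases and obeys Henry", {
  nw <- default_network()
  st <- balanced_state()
  # at the Henry partition ratio the net CO2 flux vanishes
  expect_equal(unname(gas_transfer_terms(nw$reactions$R8, st)), c(0, 0),
               tolerance = 1e-20)
  # displaced from equilibrium: gas side = -(V_liq/V_gas) x liquid side
  st$conc["CO2g"] <- 0.03
  tr <- gas_transfer_terms(nw$reactions$R8, st)
  expect_gt(tr["CO2aq"], 0)  # [CO2(g)] > [CO2(aq)]/K: net dissolution
  expect_equal(unname(tr["CO2g"]), -0.05 / 0.2 * unname(tr["CO2aq"]))
  # ammonia transfer, written liquid -> gas
  st$conc["NH3aq"] <- 0.02
  tr4 <- gas_transfer_terms(nw$reactions$R4, st)
  expect_lt(tr4["NH3aq"], 0)
  expect_equal(unname(tr4["NH3g"]), -0.25 * unname(tr4["NH3aq"]))
  st$v_gas <- 0
  expect_error(gas_transfer_terms(nw$reactions$R8, st), "ill-posed")
  expect_error(gas_transfer_terms(nw$reactions$R5, st), "not a gas-transfer")
})
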