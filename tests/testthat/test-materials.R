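test_that("wall resistance follows the half-cylinder conduction formula", {
  cap <- fep_capillary()
  # hand evaluation: ln(794/406) / (pi * 1 * 0.195)
  expect_equal(wall_resistance(cap, engagement(1)),
               log(794 / 406) / (pi * 0.195), tolerance = 1e-12)
  expect_equal(wall_resistance(cap, engagement(1)), 1.095, tolerance = 1e-3)
  # degenerate wall (d_o = d_i, bypassing the constructor invariant)
  degen <- list(inner_diameter = 5e-4, outer_diameter = 5e-4,
                wall_material = mats$FEP)
  expect_equal(wall_resistance(degen, engagement(0.02)), 0)
  # doubling the engaged length halves the resistance
  expect_equal(wall_resistance(cap, engagement(0.02)),
               2 * wall_resistance(cap, engagement(0.04)))
  expect_error(wall_resistance(cap, list(contact_length = 0)), "> 0")
})

test_that("wall resistance grows monotonically with the diameter ratio", {
  ratios <- seq(1.1, 3, by = 0.1)
  R <- vapply(ratios, function(r)
    wall_resistance(capillary_spec(4e-4, 4e-4 * r, mats$FEP), engagement(0.02)),
    numeric(1))
  expect_true(all(diff(R) > 0))
})

test_that("lump capacitance matches the cross-section formula and is linear in L", {
  cap <- fep_capillary()
  # hand evaluation per metre of engaged FEP + water
  per_m <- (pi / 4) * (997 * 4181 * (406e-6)^2 +
                         2150 * 1172 * ((794e-6)^2 - (406e-6)^2))
  expect_equal(lump_capacitance(cap, bore_contents(), engagement(1))$capacitance,
               per_m, tolerance = 1e-12)
  expect_equal(per_m, 1.461, tolerance = 1e-3)
  expect_equal(lump_capacitance(cap, bore_contents(), engagement(0.5))$capacitance,
               per_m / 2, tolerance = 1e-12)
  # zero engaged length gives zero capacitance (bypassing the constructor)
  expect_equal(lump_capacitance(cap, bore_contents(),
                                list(contact_length = 0))$capacitance, 0)
})

test_that("inclusions substitute their own heat capacity additively", {
  cap <- pc_capillary()
  eng <- engagement(0.03)
  base <- lump_capacitance(cap, bore_contents(), eng)$capacitance
  wire <- list(diameter = 50e-6, material = mats$thermocouple)
  one <- lump_capacitance(cap, bore_contents(inclusions = list(wire)),
                          eng)$capacitance
  two <- lump_capacitance(cap, tc_contents(), eng)$capacitance
  a_wire <- pi / 4 * (50e-6)^2
  delta <- a_wire * (8700 * 450 - 997 * 4181) * 0.03
  expect_equal(one - base, delta, tolerance = 1e-10)
  expect_equal(two - base, 2 * delta, tolerance = 1e-10)
  # an inclusion bundle larger than the bore is rejected
  fat <- list(diameter = 600e-6, material = mats$thermocouple)
  expect_error(lump_capacitance(cap, bore_contents(inclusions = list(fat)), eng),
               "overflow")
})

test_that("block capacitance is mass times specific heat", {
  al <- mats$aluminum
  expect_equal(block_capacitance(heater_block(0.055, al, 98))$capacitance,
               49.3, tolerance = 0.001)
  expect_equal(block_capacitance(heater_block(0, al))$capacitance, 0)
  expect_equal(block_capacitance(heater_block(0.110, al))$capacitance,
               2 * block_capacitance(heater_block(0.055, al))$capacitance)
})

test_that("predicted time constants reproduce the reference tubing cases", {
  # water-filled FEP tubing: tau ~ 1.6 s
  tau_fep <- predict_time_constant(fep_capillary())$tau
  expect_equal(tau_fep, 1.6, tolerance = 0.05)
  # thermocouple-instrumented polycarbonate tubing: tau ~ 0.59 s within 5%
  tau_pc <- predict_time_constant(pc_capillary(), tc_contents())$tau
  expect_equal(tau_pc, 0.590, tolerance = 0.05)
})

test_that("the RC product is independent of engaged length", {
  for (case in list(list(cap = fep_capillary(), ct = bore_contents()),
                    list(cap = pc_capillary(), ct = tc_contents()))) {
    taus <- vapply(c(0.001, 0.01, 1), function(L)
      wall_resistance(case$cap, engagement(L)) *
        lump_capacitance(case$cap, case$ct, engagement(L))$capacitance,
      numeric(1))
    expect_equal(taus[1], taus[2], tolerance = 1e-12)
    expect_equal(taus[1], taus[3], tolerance = 1e-12)
    expect_equal(predict_time_constant(case$cap, case$ct)$tau, taus[3],
                 tolerance = 1e-12)
  }
})

test_that("predicted tau equals term-by-term evaluation of R and C", {
  # independent oracle: evaluate every term of the resistance and
  # capacitance expressions directly, without the package's builders
  d_i <- 562e-6; d_o <- 750e-6; L <- 0.25; k_c <- 0.20
  R <- log(d_o / d_i) / (pi * L * k_c)
  a_wire <- pi / 4 * (50e-6)^2
  C <- L * ((pi / 4) * (997 * 4181 * d_i^2 + 1200 * 1200 * (d_o^2 - d_i^2)) +
              2 * a_wire * (8700 * 450 - 997 * 4181))
  expect_equal(predict_time_constant(pc_capillary(), tc_contents())$tau,
               R * C, tolerance = 1e-12)
})

test_that("optional contact resistance adds in series and raises tau", {
  tau0 <- predict_time_constant(fep_capillary())$tau
  tau1 <- predict_time_constant(fep_capillary(), contact_resistance = 0.5)$tau
  C_per_m <- lump_capacitance(fep_capillary(), bore_contents(),
                              engagement(1))$capacitance
  expect_equal(tau1 - tau0, 0.5 * C_per_m, tolerance = 1e-10)
})

test_that("equilibrium temperature is a convex combination of the two lumps", {
  blockC <- thermal_lump(49.335, "block")
  expect_equal(equilibrium_temperature(96, 60, thermal_lump(0), blockC), 96)
  expect_equal(equilibrium_temperature(96, 60, blockC, blockC), 78)
  for (r in c(0.001, 0.1, 1, 10)) {
    Teq <- equilibrium_temperature(96, 60, thermal_lump(r * 49.335), blockC)
    expect_gte(Teq, 60); expect_lte(Teq, 96)
    # weights of the convex combination sum to 1
    w_B <- 1 / (1 + r)
    expect_equal(Teq, w_B * 96 + (1 - w_B) * 60, tolerance = 1e-12)
  }
  # energy-balance oracle: conserved heat of two lumps brought together
  C_SC <- lump_capacitance(fep_capillary(), bore_contents(),
                           engagement(0.0309))$capacitance
  oracle <- (49.335 * 96 + C_SC * 60) / (49.335 + C_SC)
  expect_equal(equilibrium_temperature(96, 60, thermal_lump(C_SC), blockC),
               oracle, tolerance = 1e-12)
  expect_error(equilibrium_temperature(96, 60, blockC, thermal_lump(0)),
               "> 0")
})

test_that("constructors reject unphysical inputs", {
  expect_error(material("x", k = -1, rho = 1, cp = 1))
  expect_error(capillary_spec(794e-6, 406e-6, mats$FEP))
  expect_error(engagement(-0.1))
  expect_error(response_model(0))
  expect_error(thermal_lump(-1))
})
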