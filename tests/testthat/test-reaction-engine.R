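test_that("mass-action right-hand sides match hand evaluation", {
  net <- toy_decay_network()
  p <- parameter_set(c(k_dm = 0.105))
  rhs <- build_rhs(net, p)
  expect_equal(unname(rhs(c(M = 100))), -10.5)

  net2 <- toy_bimolecular_network()
  rhs2 <- build_rhs(net2, parameter_set(c(k = 2)))
  d <- rhs2(c(A = 3, B = 4, C = 0))
  expect_equal(unname(d), c(-24, -24, 24))

  rhs0 <- build_rhs(net2, parameter_set(c(k = 0)))
  expect_equal(unname(rhs0(c(A = 3, B = 4, C = 5))), c(0, 0, 0))

  expect_error(build_rhs(net, parameter_set(c(other = 1))),
               "not in parameter set")
})

test_that("modifiers enter the rate law but not the stoichiometry", {
  net <- reaction_network(
    list(species("M"), species("P")),
    list(reaction("cat", products = c(P = 1), modifiers = c(M = 2),
                  rate_constant = "k")))
  rhs <- build_rhs(net, parameter_set(c(k = 0.5)))
  d <- rhs(c(M = 3, P = 0))
  expect_equal(unname(d), c(0, 0.5 * 9))
  S <- stoichiometry_matrix(net)
  expect_equal(unname(S["M", ]), 0)
})

test_that("integration reproduces closed-form kinetics", {
  net <- toy_decay_network()
  p <- parameter_set(c(k_dm = 0.105))
  tr <- simulate_network(net, p, init = c(M = 1000), times = c(0, 5, 10),
                         rtol = 1e-10, atol = 1e-10)
  expect_equal(unname(tr$states[3, "M"]), 1000 * exp(-1.05),
               tolerance = 1e-8)
  expect_equal(unname(tr$states[1, "M"]), 1000)

  # zero-rate network: constant states
  tr0 <- simulate_network(net, parameter_set(c(k_dm = 0)),
                          init = c(M = 77), times = c(0, 100, 1000))
  expect_equal(unname(tr0$states[, "M"]), rep(77, 3))

  # birth-death chain reaches s/k
  bd <- toy_birth_death_network()
  pbd <- parameter_set(c(s = 1, k = 0.01))
  trbd <- simulate_network(bd, pbd, init = c(M = 0),
                           times = c(0, 1000, 2000))
  expect_equal(unname(trbd$states[3, "M"]), 100, tolerance = 1e-4)
})

test_that("simulation is deterministic and first-order dynamics are linear", {
  net <- toy_reversible_network()
  p <- parameter_set(c(kf = 0.3, kr = 0.1))
  t1 <- simulate_network(net, p, init = c(A = 10, B = 0),
                         times = c(0, 1, 5, 10))
  t2 <- simulate_network(net, p, init = c(A = 10, B = 0),
                         times = c(0, 1, 5, 10))
  expect_identical(t1$states, t2$states)

  t3 <- simulate_network(net, p, init = c(A = 20, B = 0),
                         times = c(0, 1, 5, 10))
  expect_equal(t3$states, 2 * t1$states, tolerance = 1e-5)
})

test_that("compiled and plain-R integration paths agree", {
  st <- ref_seeded_state()
  tc <- simulate_network(ref_net(), ref_params(), init = st,
                         times = c(0, 600, 3600))
  tr <- simulate_network(ref_net(), ref_params(), init = st,
                         times = c(0, 600, 3600), method = "r")
  expect_equal(tc$states, tr$states, tolerance = 1e-8)
})

test_that("invalid simulation inputs are rejected", {
  net <- toy_decay_network()
  p <- parameter_set(c(k_dm = 0.1))
  expect_error(simulate_network(net, p, init = c(M = -1),
                                times = c(0, 1)), "nonnegative")
  expect_error(simulate_network(net, p, init = c(M = 1),
                                times = c(1, 2)), "start at 0")
  expect_error(simulate_network(net, p, init = c(M = 1),
                                times = c(0, 2, 1)), "increasing")
})

test_that("pre-equilibration finds stationary states", {
  bd <- toy_birth_death_network()
  st <- pre_equilibrate(bd, parameter_set(c(s = 1, k = 0.01)),
                        init = c(M = 0), t_max = 1e5)
  expect_equal(unname(st["M"]), 100, tolerance = 1e-6)

  # zero-rate network is already stationary: init returned unchanged
  z <- pre_equilibrate(toy_decay_network(), parameter_set(c(k_dm = 0)),
                       init = c(M = 42))
  expect_equal(unname(z["M"]), 42)

  # unbounded accumulation is reported, not silently returned
  growth <- reaction_network(
    list(species("M")),
    list(reaction("birth", products = c(M = 1), rate_constant = "s")))
  expect_error(pre_equilibrate(growth, parameter_set(c(s = 1)),
                               init = c(M = 0), t_max = 1e4),
               "pre-equilibration failed")
})

test_that("linear interpolation sampling honours the trajectory contract", {
  net <- toy_decay_network()
  p <- parameter_set(c(k_dm = 0))
  tr <- simulate_network(net, p, init = c(M = 10), times = c(0, 10))
  expect_equal(unname(sample_trajectory(tr, c(0, 2.5, 10))[, "M"]),
               c(10, 10, 10))
  expect_error(sample_trajectory(tr, 11), "outside")
})

test_that("model definitions round-trip through JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  net <- ref_net()
  write_network_json(net, path)
  back <- read_network_json(path)
  expect_equal(species_names(back), species_names(net))
  expect_equal(stoichiometry_matrix(back), stoichiometry_matrix(net))
  expect_equal(vapply(back$reactions, `[[`, "", "rate_constant"),
               vapply(net$reactions, `[[`, "", "rate_constant"))
  # the shipped model file equals the built-in definition
  shipped <- herg1_network(file = system.file(
    "extdata", "herg1_integrin_v1.json", package = "herg1kin"))
  expect_equal(stoichiometry_matrix(shipped), stoichiometry_matrix(net))
})

test_that("unit/order validation flags only genuine mismatches", {
  net <- toy_decay_network()
  p <- parameter_set(c(k_dm = 0.1),
                     units = c(k_dm = "s^-1"))
  expect_identical(nrow(validate_units(net, p)), 0L)

  bi <- toy_bimolecular_network()
  pbad <- parameter_set(c(k = 1), units = c(k = "s^-1"))
  f <- validate_units(bi, pbad)
  expect_identical(nrow(f), 1L)
  expect_identical(f$reaction, "bind")
  expect_identical(f$implied_order, 1)
  expect_identical(f$declared_order, 2)
})
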