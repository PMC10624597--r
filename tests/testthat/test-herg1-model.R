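test_that("the network houses every rate constant at its declared spot", {
  net <- ref_net()
  expect_length(net$species, 16L)
  expect_length(net$reactions, 25L)
  used <- vapply(net$reactions, `[[`, "", "rate_constant")
  counts <- table(used)
  # transcription is catalysed by both free and complexed active integrin,
  # sharing k_ie; every other constant drives exactly one reaction
  expect_identical(unname(counts[["k_ie"]]), 2L)
  expect_true(all(counts[setdiff(names(counts), "k_ie")] == 1L))
  expect_setequal(names(counts), setdiff(herg1kin:::herg1_rate_names(),
                                         character(0)))
})

test_that("complex formation involves only the closed channel", {
  net <- ref_net()
  consumes_open_with_integrin <- vapply(net$reactions, function(r) {
    all(c("So", "Bs") %in% names(r$reactants))
  }, logical(1))
  expect_false(any(consumes_open_with_integrin))
  forms_complex <- vapply(net$reactions, function(r) {
    "X" %in% names(r$products)
  }, logical(1))
  expect_identical(
    names(net$reactions[forms_complex][[1]]$reactants) |> sort(),
    c("Bs", "Sc"))
})

test_that("published parameter sets carry the reported values", {
  hek <- published_parameters("HEK-hERG1")
  expect_equal(hek$values[["k_off"]], 107)
  expect_equal(hek$values[["k_dm"]], 0.105)
  expect_equal(hek$values[["kf0"]], 1.75e-5)
  pan <- published_parameters("PANC-1")
  expect_equal(pan$values[["k_on"]], 1.13e-4)
  hct <- published_parameters("HCT116")
  expect_equal(hct$values[["B0"]], 1.709e7)
  # gating rates and pools were held fixed in the fits
  for (p in list(hek, pan, hct)) {
    expect_false(any(p$floating[c("k_om", "k_o", "B0", "A0", "I0",
                                  "E0", "F0")]))
    expect_identical(sum(p$floating), 22L)
  }
  expect_error(published_parameters("HeLa"), "unknown cell line")
})

test_that("units match kinetic orders except for the flagged transcription constant", {
  f <- validate_units(ref_net(), published_parameters("HEK-hERG1"))
  expect_setequal(unique(f$rate_constant), "k_ie")
  expect_identical(nrow(f), 2L)  # both transcription reactions
  expect_true(all(f$implied_order == 2))
  expect_true(all(f$declared_order == 1))
})

test_that("basal state is stationary and respects the pools", {
  net <- ref_net()
  p <- ref_params()
  st0 <- ref_basal()
  v <- p$values
  tot <- function(who) sum(st0[who])
  expect_equal(tot(c("A", "As")), v[["A0"]], tolerance = 1e-6)
  expect_equal(tot(c("I", "Is")), v[["I0"]], tolerance = 1e-6)
  expect_equal(tot(c("N", "Ns")), v[["N0"]], tolerance = 1e-6)
  expect_equal(tot(c("B", "Bs", "X")), v[["B0"]], tolerance = 1e-6)
  expect_equal(tot(c("F", "Bs", "X")), v[["phi0"]] * v[["F0"]],
               tolerance = 1e-6)
  expect_lte(st0[["As"]], v[["A0"]])
  expect_lte(st0[["Is"]], v[["I0"]])

  # drift under basal parameters < 0.1% over 300 minutes
  tr <- simulate_network(net, p, init = st0, times = c(0, 150, 300) * 60)
  drift <- abs(tr$states[3, ] - tr$states[1, ]) /
    pmax(abs(tr$states[1, ]), 1)
  expect_lt(max(drift), 1e-3)

  # gating pre-equilibrium: So/Sc = k_o / k_om
  expect_equal(st0[["So"]] / st0[["Sc"]], v[["k_o"]] / v[["k_om"]],
               tolerance = 1e-3)
})

test_that("seeding releases fibronectin as a step, continuous elsewhere", {
  st0 <- ref_basal()
  st1 <- ref_seeded_state()
  v <- ref_params()$values
  expect_equal(st1[["F"]] - st0[["F"]], (1 - v[["phi0"]]) * v[["F0"]])
  others <- setdiff(names(st0), "F")
  expect_identical(unname(st0[others]), unname(st1[others]))
})

test_that("the seeded membrane response is biphasic", {
  obs <- compute_observables(ref_seeded_traj())
  mem <- obs$value[obs$observable == "membrane_total"]
  t <- obs$time_min[obs$observable == "membrane_total"]
  ipk <- which.max(mem)
  expect_gt(t[ipk], 0)
  expect_lt(t[ipk], 300)
  expect_gt(mem[ipk], mem[1] * 1.5)
  expect_gt(mem[ipk], mem[length(mem)] * 1.2)
})

test_that("without fibronectin engagement all fold observables stay flat", {
  net <- ref_net()
  p <- set_parameters(ref_params(), c(kf0 = 0))
  st0 <- ref_basal()  # basal state, no FN release
  tr <- simulate_network(net, p, init = st0,
                         times = canonical_grid() * 60)
  obs <- compute_observables(tr, normalize = TRUE)
  folds <- obs$value[obs$observable != "glyco_fraction"]
  expect_true(all(abs(folds - 1) < 0.1))
})

test_that("intervention presets map to the declared overrides", {
  p <- ref_params()
  none <- apply_intervention(p, "none")
  expect_identical(none$values, p$values)

  scdb <- apply_intervention(p, "scDb")
  expect_identical(scdb$values[["k_on"]], 0)
  expect_true(attr(scdb, "pretreat"))

  ptx <- apply_intervention(p, "PTX")
  expect_true(all(ptx$values[c("k_a", "k_cp", "k_gp", "k_tgp")] == 0))

  e4 <- apply_intervention(p, "E4031")
  expect_identical(e4$values[["k_om"]], 0)
  expect_false(attr(e4, "pretreat"))
  expect_identical(attr(e4, "blocked_observables"), "open_channels")

  expect_error(apply_intervention(p, "nonsense"))
})

test_that("published values admit no bounded basal state under this reconstruction", {
  # the activator lacks first-order relaxation, so with the published
  # constants any nonzero basal complex eventually silences the
  # internalisation module and membrane synthesis has no sink
  expect_error(
    initial_state(ref_net(), published_parameters("HEK-hERG1"),
                  t_max = 1e5),
    "pre-equilibration failed")
})
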