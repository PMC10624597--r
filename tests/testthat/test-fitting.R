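test_that("cost is zero on self-generated noiseless data and linear in weights", {
  net <- ref_net()
  p <- ref_params()
  ds <- generate_model_dataset(net, p, noise_cv = 0, n_rep = 2, seed = 4)
  expect_lt(fit_cost(p, net, ds), 1e-10)

  noisy <- generate_anchor_dataset(anchor_profile("HEK-hERG1"), seed = 8)
  ro <- unique(noisy$readout)
  w1 <- setNames(rep(1, length(ro)), ro)
  s1 <- fit_cost(p, net, noisy, weights = w1)
  s2 <- fit_cost(p, net, noisy, weights = 2 * w1)
  expect_gt(s1, 0)
  expect_equal(s2, 2 * s1, tolerance = 1e-12)
  expect_error(fit_cost(p, net, noisy, weights = 0 * w1), "all weights")
})

test_that("the squared-deviation score matches hand arithmetic", {
  model <- list(a = c(1, 2, 3))
  data <- list(a = c(1, 1, 1))
  expect_equal(herg1kin:::weighted_sq_score(model, data, c(a = 1)), 5)
  expect_equal(herg1kin:::weighted_sq_score(model, data, c(a = 2)), 10)
})

test_that("datasets with unknown readouts are rejected", {
  ds <- generate_anchor_dataset(anchor_profile("HEK-hERG1"), seed = 1)
  ds$readout[1] <- "voltage"
  expect_error(fit_cost(ref_params(), ref_net(), ds),
               "no defined observable")
})

test_that("the Monte-Carlo search is greedy, masked and reproducible", {
  net <- ref_net()
  start <- ref_params()
  ds <- generate_anchor_dataset(anchor_profile("HEK-hERG1"), seed = 8,
                                grid = c(0, 45, 90, 180, 300))
  f1 <- mc_fit(start, net, ds, seed = 31, max_iterations = 60L,
               patience = 30L, rel_tol = 0)
  f2 <- mc_fit(start, net, ds, seed = 31, max_iterations = 60L,
               patience = 30L, rel_tol = 0)
  expect_identical(f1$best_params$values, f2$best_params$values)
  expect_identical(f1$score_history, f2$score_history)
  # accepted-score monotonicity
  expect_true(all(diff(f1$score_history) <= 0))
  # fixed parameters bit-identical, floating ones strictly positive
  fixed <- names(start$values)[!start$floating]
  expect_identical(f1$best_params$values[fixed], start$values[fixed])
  expect_true(all(f1$best_params$values[start$floating] > 0))

  f3 <- mc_fit(start, net, ds, seed = 32, max_iterations = 60L,
               patience = 30L, rel_tol = 0)
  expect_false(identical(f3$score_history, f1$score_history))

  few <- start
  few$floating[] <- FALSE
  expect_error(mc_fit(few, net, ds), "two floating")
})

test_that("mRNA decay rate is recovered against a brute-force scan", {
  net <- ref_net()
  truth <- ref_params()
  ds <- generate_model_dataset(net, truth, noise_cv = 0, n_rep = 1,
                               seed = 3, readouts = "mrna")
  k_true <- truth$values[["k_dm"]]
  # independent oracle: a 1-D scan of the cost locates the minimum at the
  # generating value
  grid <- k_true * exp(seq(log(0.3), log(5), length.out = 17))
  scan <- vapply(grid, function(k) {
    fit_cost(set_parameters(truth, c(k_dm = k)), net, ds)
  }, numeric(1))
  expect_equal(grid[which.min(scan)], k_true,
               tolerance = exp(diff(log(grid))[1]) - 1)

  start <- truth
  start$floating[] <- FALSE
  start$floating[c("k_dm", "k_ie")] <- TRUE
  start$values[["k_dm"]] <- 5 * k_true
  fit <- mc_fit(start, net, ds, seed = 5, max_iterations = 500L,
                patience = 150L, rel_tol = 1e-6)
  expect_lt(abs(fit$best_params$values[["k_dm"]] / k_true - 1), 0.05)
})

test_that("multi-start returns the best branch with stable tie-breaking", {
  net <- ref_net()
  truth <- ref_params()
  ds <- generate_model_dataset(net, truth, noise_cv = 0, n_rep = 1,
                               seed = 6, grid = c(0, 45, 90, 180, 300))
  off <- truth
  off$values[floating_names(off)] <- off$values[floating_names(off)] * 1.3
  best <- multi_start_fit(list(truth, off), net, ds, seed = 3,
                          max_iterations = 40L, patience = 20L)
  expect_identical(attr(best, "start_index"), 1L)
  expect_lt(utils::tail(best$score_history, 1), 1e-8)

  single <- multi_start_fit(list(off), net, ds, seed = 3,
                            max_iterations = 40L, patience = 20L)
  direct <- mc_fit(off, net, ds, seed = 3, max_iterations = 40L,
                   patience = 20L)
  expect_identical(single$score_history, direct$score_history)
  expect_error(multi_start_fit(list(), net, ds), "empty")
})

test_that("fit results serialise to JSON", {
  net <- ref_net()
  ds <- generate_model_dataset(net, ref_params(), noise_cv = 0,
                               n_rep = 1, seed = 6,
                               grid = c(0, 90, 300))
  fit <- mc_fit(ref_params(), net, ds, seed = 1, max_iterations = 5L,
                patience = 5L)
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$seed, 1)
  expect_equal(back$best_params$k_off, fit$best_params$values[["k_off"]])
})
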