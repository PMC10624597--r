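#' Random perturbation ensemble around a best fit
#'
#' Draws `n_sets` parameter sets in which every floating parameter is
#' independently multiplied by `U(1 - fraction, 1 + fraction)` (uniform
#' on the linear scale); fixed parameters are untouched.  Deterministic
#' for a fixed seed.
#'
#' @param best A [parameter_set()].
#' @param n_sets Ensemble size (default 100).
#' @param fraction Relative perturbation half-width (default 0.10).
#' @param seed Integer RNG seed.
#' @return List of [parameter_set()]s of length `n_sets`.
#' @export
perturbation_ensemble <- function(best, n_sets = 100L, fraction = 0.10,
                                  seed = 1L) {
  stopifnot(n_sets >= 1, fraction >= 0)
  fl <- floating_names(best)
  set.seed(seed)
  lapply(seq_len(n_sets), function(i) {
    p <- best
    p$values[fl] <- p$values[fl] *
      runif(length(fl), 1 - fraction, 1 + fraction)
    p
  })
}

#' Observable envelope of a parameter ensemble
#'
#' Simulates every ensemble member from its own basal state, normalises
#' the observables and reports the pointwise minimum and maximum across
#' surviving members together with the central (best-fit) curve — the
#' variability band of the sensitivity analysis.  Members whose
#' pre-equilibration or integration fails are dropped and counted; more
#' than `max_fail_fraction` failures is an error.
#'
#' @param network A [reaction_network()].
#' @param best Central [parameter_set()].
#' @param ensemble List of parameter sets, e.g. from
#'   [perturbation_ensemble()].
#' @param grid Time grid in minutes.
#' @param readouts Observables to include.
#' @param max_fail_fraction Tolerated fraction of failing members
#'   (default 0.10).
#' @return Data frame `time_min`, `observable`, `lower`, `central`,
#'   `upper` with attribute `n_failed`.
#' @export
observable_envelope <- function(network, best, ensemble,
                                grid = canonical_grid(),
                                readouts = fit_readouts(),
                                max_fail_fraction = 0.10) {
  run <- function(p) {
    tryCatch(model_folds_on_grid(network, p, grid, readouts),
             error = function(e) NULL)
  }
  central <- run(best)
  if (is.null(central)) stop("central parameter set fails to simulate",
                             call. = FALSE)
  members <- lapply(ensemble, run)
  failed <- vapply(members, is.null, logical(1))
  if (sum(failed) > max_fail_fraction * length(ensemble)) {
    stop(sprintf("%d of %d ensemble members failed to simulate",
                 sum(failed), length(ensemble)), call. = FALSE)
  }
  # the central curve belongs to the band, so lower <= central <= upper
  members <- c(members[!failed], list(central))
  out <- do.call(rbind, lapply(readouts, function(ob) {
    mat <- vapply(members, function(m) m[[ob]], numeric(length(grid)))
    mat <- matrix(mat, nrow = length(grid))
    data.frame(time_min = grid, observable = ob,
               lower = apply(mat, 1, min),
               central = central[[ob]],
               upper = apply(mat, 1, max),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  structure(out, n_failed = sum(failed))
}

#' Write an envelope as CSV
#'
#' @param env Data frame from [observable_envelope()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_envelope_csv <- function(env, path) {
  write.csv(env, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
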