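#' Readouts entering the least-squares cost by default
#'
#' The five fold-change readouts with quantitative time courses; the
#' endosomal series is qualitative and the glycosylated fraction is a
#' derived ratio, so neither is fitted by default.
#'
#' @return Character vector.
#' @export
fit_readouts <- function() {
  c("membrane_total", "open_channels", "complex", "glyco_total", "mrna")
}

# Weighted sum of squared deviations between model series and data means.
weighted_sq_score <- function(model, data_means, weights) {
  total <- 0
  for (ob in names(weights)) {
    m <- model[[ob]]
    d <- data_means[[ob]]
    if (is.null(m) || is.null(d)) next
    total <- total + weights[[ob]] * sum((m - d)^2)
  }
  total
}

model_folds_on_grid <- function(network, params, grid, readouts) {
  st <- initial_state(network, params, seeding = TRUE)
  traj <- simulate_network(network, params, init = st, times = grid * 60)
  obs <- compute_observables(traj, normalize = TRUE)
  setNames(lapply(readouts, function(ob) {
    obs$value[obs$observable == ob]
  }), readouts)
}

#' Weighted least-squares cost of a parameter set
#'
#' Builds the basal state for `params`, releases fibronectin, simulates
#' on the dataset's grid and scores
#' `sum_r w_r sum_t (model_fold - replicate_mean_fold)^2`.  Any failure
#' of pre-equilibration or integration yields `Inf` (documented
#' sentinel), so the stochastic search simply avoids such regions.
#'
#' @param params A [parameter_set()].
#' @param network A [reaction_network()].
#' @param dataset A `time_course_dataset`.
#' @param weights Named nonnegative weights per readout; default: equal
#'   weight 1 for every readout present in the dataset.  Must not be all
#'   zero.
#' @return Nonnegative score (possibly `Inf`).
#' @export
fit_cost <- function(params, network, dataset, weights = NULL) {
  readouts <- unique(dataset$readout)
  unknown <- setdiff(readouts, herg1_observable_names)
  if (length(unknown)) {
    stop("dataset readouts with no defined observable: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (is.null(weights)) weights <- setNames(rep(1, length(readouts)),
                                            readouts)
  if (all(weights == 0)) stop("all weights are zero", call. = FALSE)
  grid <- sort(unique(dataset$time_min))
  dm <- dataset_means(dataset)
  data_means <- setNames(lapply(readouts, function(ob) {
    dm$mean_value[dm$readout == ob]
  }), readouts)
  model <- tryCatch(
    model_folds_on_grid(network, params, grid, readouts),
    error = function(e) NULL)
  if (is.null(model)) return(Inf)
  weighted_sq_score(model, data_means, weights)
}

#' Stochastic Monte-Carlo pairwise parameter search
#'
#' Greedy accept-if-lower random search: each iteration picks a random
#' pair of distinct floating parameters, multiplies each by
#' `exp(U(-delta, delta))` with `delta = log(1 + perturb_fraction)`
#' (multiplicative moves, since the rate constants span many orders of
#' magnitude), and accepts the candidate only if the score strictly
#' decreases.  The search stops when the relative decrease of the best
#' score over a `patience`-iteration window falls below `rel_tol`, or at
#' `max_iterations`.  Fixed parameters (floating mask `FALSE`) are never
#' touched.  Deterministic for a fixed seed.
#'
#' @param start A [parameter_set()] with at least two floating entries
#'   and a finite starting score.
#' @param network A [reaction_network()].
#' @param dataset A `time_course_dataset`.
#' @param weights Passed to [fit_cost()].
#' @param perturb_fraction Multiplicative half-width of a move
#'   (default 0.10).
#' @param rel_tol Relative-decrease stopping tolerance (default `1e-4`).
#' @param patience Window length, in iterations, for the stopping check
#'   (default 500).
#' @param max_iterations Hard iteration cap.
#' @param seed Integer RNG seed.
#' @return A `fit_result`: `best_params`, `score_history` (accepted
#'   scores, non-increasing, starting score first), `n_evaluations`,
#'   `n_iterations`, `converged`, `seed`.
#' @export
mc_fit <- function(start, network, dataset, weights = NULL,
                   perturb_fraction = 0.10, rel_tol = 1e-4,
                   patience = 500L, max_iterations = 5000L, seed = 1L) {
  stopifnot(perturb_fraction > 0, perturb_fraction < 1)
  fl <- floating_names(start)
  if (length(fl) < 2L) stop("need at least two floating parameters",
                            call. = FALSE)
  set.seed(seed)
  best <- start
  best_score <- fit_cost(start, network, dataset, weights)
  if (!is.finite(best_score)) {
    stop("non-finite score at the starting parameters", call. = FALSE)
  }
  history <- best_score
  delta <- log(1 + perturb_fraction)
  n_eval <- 1L
  window_best <- best_score
  converged <- FALSE
  iter <- 0L
  while (iter < max_iterations) {
    iter <- iter + 1L
    pair <- sample(fl, 2L)
    cand <- best
    cand$values[pair] <- cand$values[pair] * exp(runif(2L, -delta, delta))
    s <- fit_cost(cand, network, dataset, weights)
    n_eval <- n_eval + 1L
    if (is.finite(s) && s < best_score) {
      best <- cand
      best_score <- s
      history <- c(history, s)
    }
    if (iter %% patience == 0L) {
      drop_rel <- (window_best - best_score) / max(window_best, 1e-300)
      if (drop_rel < rel_tol) {
        converged <- TRUE
        break
      }
      window_best <- best_score
    }
  }
  structure(list(best_params = best, score_history = history,
                 n_evaluations = n_eval, n_iterations = iter,
                 converged = converged, seed = seed),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(paste0("<fit_result> score %.6g after %d iterations ",
                     "(%d evaluations, %d accepted moves, %s)\n"),
              utils::tail(x$score_history, 1), x$n_iterations,
              x$n_evaluations, length(x$score_history) - 1L,
              if (x$converged) "converged" else "iteration cap"))
  invisible(x)
}

#' Best of several Monte-Carlo fits
#'
#' Runs [mc_fit()] from each start (automating the manual
#' parameter-space exploration that precedes fine fitting) and returns
#' the minimum-score result; ties break to the lowest start index.
#' Start `i` uses seed `seed + i - 1`.
#'
#' @param starts Non-empty list of [parameter_set()] starts.
#' @param network,dataset,weights,... Passed to [mc_fit()].
#' @param seed Base seed.
#' @return The best `fit_result`, with attribute `start_index`.
#' @export
multi_start_fit <- function(starts, network, dataset, weights = NULL,
                            seed = 1L, ...) {
  if (!length(starts)) stop("empty list of starts", call. = FALSE)
  fits <- lapply(seq_along(starts), function(i) {
    mc_fit(starts[[i]], network, dataset, weights = weights,
           seed = seed + i - 1L, ...)
  })
  scores <- vapply(fits, function(f) utils::tail(f$score_history, 1),
                   numeric(1))
  i <- which.min(scores)  # which.min takes the first (lowest index) tie
  structure(fits[[i]], start_index = i,
            all_scores = scores)
}

#' Serialise a fit result to JSON
#'
#' @param fit A `fit_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(best_params = as.list(fit$best_params$values),
         floating = as.list(fit$best_params$floating),
         score_history = fit$score_history,
         n_evaluations = fit$n_evaluations,
         n_iterations = fit$n_iterations,
         converged = fit$converged, seed = fit$seed),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
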