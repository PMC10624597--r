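#' Canonical reporting time grid
#'
#' Union of the assay time points of the kinetic experiments, in minutes.
#'
#' @return Numeric vector `0, 5, 15, 30, 45, 60, 90, 120, 180, 240, 300`.
#' @export
canonical_grid <- function() c(0, 5, 15, 30, 45, 60, 90, 120, 180, 240, 300)

#' Kinetic anchor profile of a cell line
#'
#' Encodes the printed kinetic anchors of the fold-change readouts:
#' pulse-shaped readouts (membrane channel, open channels, complex,
#' glycosylated protein) with a peak fold near fourfold at 90 min and a
#' late elevated plateau, and a saturating mRNA readout calibrated so the
#' fold passes 2 at the 120-min doubling anchor and saturates at
#' `mrna_peak`.  Cancer lines reuse the same shapes with a faster
#' post-peak relaxation.
#'
#' @param cell_line `"HEK-hERG1"`, `"PANC-1"` or `"HCT116"`.
#' @param noise_cv Relative (s.e.m.-scale) noise of replicates.
#' @param n_rep Replicates per (readout, time) point.
#' @return An `anchor_profile` object.
#' @export
anchor_profile <- function(cell_line = "HEK-hERG1", noise_cv = 0.10,
                           n_rep = 3L) {
  cell_line <- normalise_cell_line(cell_line)
  stopifnot(noise_cv >= 0, n_rep >= 1)
  cancer <- cell_line != "HEK-hERG1"
  readouts <- data.frame(
    readout = c("membrane_total", "open_channels", "complex",
                "glyco_total"),
    peak = c(4, 4, 4, 4),
    t_peak = c(90, 90, 90, 90),
    plateau = if (cancer) c(1.15, 1.5, 1.15, 1.15) else
      c(1.3, 1.8, 1.3, 1.3),
    stringsAsFactors = FALSE)
  structure(list(cell_line = cell_line, readouts = readouts,
                 mrna_peak = 2.3, mrna_t_double = 120,
                 shape_h = 3, decay_scale = if (cancer) 1.5 else 1,
                 noise_cv = noise_cv, n_rep = as.integer(n_rep)),
            class = "anchor_profile")
}

# Gamma-type pulse, g(0) = 0, g(t_peak) = 1; the post-peak time axis can
# be stretched (decay_scale > 1 relaxes faster).
gamma_pulse <- function(t, t_peak, h, decay_scale = 1) {
  te <- ifelse(t > t_peak, t_peak + decay_scale * (t - t_peak), t)
  s <- te / t_peak
  ifelse(t <= 0, 0, s^h * exp(h * (1 - s)))
}

#' Noise-free anchor mean curves
#'
#' Pulse readouts:
#' `f(t) = 1 + (peak - 1) g(t) + (plateau - 1)(1 - e^(-t/t_peak))(1 - g(t))`
#' with `g` a normalised gamma pulse (`g(0) = 0`, `g(t_peak) = 1`), so
#' `f(0) = 1` and `f(t_peak) = peak` exactly and the curve settles at the
#' plateau.  mRNA: `1 + (peak - 1)(1 - e^(-t/tau))` with `tau` fixed by
#' the doubling anchor `f(t_double) = 2`.
#'
#' @param profile An [anchor_profile()].
#' @param readout One of the profile's readouts or `"mrna"`.
#' @param t_min Times in minutes.
#' @return Numeric vector of mean folds.
#' @export
anchor_mean_curve <- function(profile, readout, t_min) {
  if (readout == "mrna") {
    pk <- profile$mrna_peak
    stopifnot(pk > 2)
    tau <- profile$mrna_t_double / log((pk - 1) / (pk - 2))
    return(1 + (pk - 1) * (1 - exp(-t_min / tau)))
  }
  row <- profile$readouts[profile$readouts$readout == readout, ]
  if (nrow(row) != 1L) stop("unknown readout '", readout, "'",
                            call. = FALSE)
  g <- gamma_pulse(t_min, row$t_peak, profile$shape_h,
                   profile$decay_scale)
  1 + (row$peak - 1) * g +
    (row$plateau - 1) * (1 - exp(-t_min / row$t_peak)) * (1 - g)
}

make_dataset <- function(cell_line, means, grid, noise_cv, n_rep, seed,
                         mode, profile = NULL) {
  set.seed(seed)
  rows <- list()
  for (ob in names(means)) {
    mu <- means[[ob]]
    for (i in seq_along(grid)) {
      val <- pmax(mu[i] * (1 + rnorm(n_rep, 0, noise_cv)), 0)
      rows[[length(rows) + 1L]] <- data.frame(
        cell_line = cell_line, readout = ob, time_min = grid[i],
        replicate = seq_len(n_rep), value = val,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("time_course_dataset", "data.frame"),
            mode = mode, seed = seed, profile = profile)
}

#' Generate a replicate time-course dataset from kinetic anchors
#'
#' Stands in for the study's raw kinetic data (none deposited): replicate
#' fold-change measurements at the canonical time points whose means
#' follow the anchor curves and whose replicates carry multiplicative
#' Gaussian noise truncated at zero.  Deterministic for a fixed seed.
#'
#' @param profile An [anchor_profile()].
#' @param grid Time grid in minutes (subset of [canonical_grid()]).
#' @param seed Integer RNG seed.
#' @return A `time_course_dataset` data frame with columns `cell_line`,
#'   `readout`, `time_min`, `replicate`, `value` and attributes `mode`,
#'   `seed`, `profile`.
#' @export
generate_anchor_dataset <- function(profile, grid = canonical_grid(),
                                    seed = 1L) {
  stopifnot(inherits(profile, "anchor_profile"),
            all(grid %in% canonical_grid()))
  means <- c(
    setNames(lapply(profile$readouts$readout, function(ob) {
      anchor_mean_curve(profile, ob, grid)
    }), profile$readouts$readout),
    list(mrna = anchor_mean_curve(profile, "mrna", grid)))
  make_dataset(profile$cell_line, means, grid, profile$noise_cv,
               profile$n_rep, seed, mode = "anchor", profile = profile)
}

#' Generate a replicate dataset from a model simulation
#'
#' Simulates the seeded model, computes the normalised observables and
#' adds the same replicate noise model as [generate_anchor_dataset()].
#' With `noise_cv = 0` the dataset means equal the model folds exactly,
#' which makes it the natural input for parameter-recovery tests.
#'
#' @param network A [reaction_network()] (typically [herg1_network()]).
#' @param params A [parameter_set()].
#' @param noise_cv Relative replicate noise.
#' @param n_rep Replicates per point.
#' @param grid Time grid in minutes.
#' @param seed Integer RNG seed.
#' @param readouts Which observables to include (defaults to the five
#'   fitted fold-change readouts).
#' @param cell_line Label stored in the dataset.
#' @return A `time_course_dataset` (see [generate_anchor_dataset()]).
#' @export
generate_model_dataset <- function(network, params, noise_cv = 0.10,
                                   n_rep = 3L, grid = canonical_grid(),
                                   seed = 1L,
                                   readouts = fit_readouts(),
                                   cell_line = "model") {
  st <- initial_state(network, params, seeding = TRUE)
  traj <- simulate_network(network, params, init = st, times = grid * 60)
  obs <- compute_observables(traj, normalize = TRUE)
  means <- setNames(lapply(readouts, function(ob) {
    obs$value[obs$observable == ob]
  }), readouts)
  make_dataset(cell_line, means, grid, noise_cv, n_rep, seed,
               mode = "model")
}

#' Replicate means of a time-course dataset
#'
#' @param dataset A `time_course_dataset`.
#' @return Data frame `readout`, `time_min`, `mean_value`.
#' @export
dataset_means <- function(dataset) {
  agg <- stats::aggregate(value ~ readout + time_min, data = dataset,
                          FUN = mean)
  names(agg)[names(agg) == "value"] <- "mean_value"
  agg[order(agg$readout, agg$time_min), , drop = FALSE]
}

#' Write a dataset as CSV (profile as side-car JSON)
#'
#' @param dataset A `time_course_dataset`.
#' @param path Output CSV path; when the dataset carries an anchor
#'   profile, it is stored alongside as `<path>.profile.json`.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(dataset, path) {
  write.csv(as.data.frame(dataset), path, row.names = FALSE,
            quote = FALSE)
  prof <- attr(dataset, "profile")
  if (!is.null(prof)) {
    jsonlite::write_json(
      list(cell_line = prof$cell_line,
           readouts = prof$readouts,
           mrna_peak = prof$mrna_peak,
           mrna_t_double = prof$mrna_t_double,
           shape_h = prof$shape_h, decay_scale = prof$decay_scale,
           noise_cv = prof$noise_cv, n_rep = prof$n_rep,
           seed = attr(dataset, "seed")),
      paste0(path, ".profile.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA)
  }
  invisible(path)
}
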