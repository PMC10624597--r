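herg1_observable_names <- c("membrane_total", "open_channels", "complex",
                            "glyco_total", "glyco_fraction", "mrna",
                            "endosomal")

observable_series <- function(states) {
  need <- c("M", "R", "G", "Sc", "So", "X", "E")
  miss <- setdiff(need, colnames(states))
  if (length(miss)) stop("trajectory misses species: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  glyco <- states[, "G"] + states[, "Sc"] + states[, "So"] +
    states[, "X"] + states[, "E"]
  tot <- states[, "R"] + glyco
  list(
    membrane_total = states[, "Sc"] + states[, "So"] + states[, "X"],
    open_channels = states[, "So"],
    complex = states[, "X"],
    glyco_total = glyco,
    glyco_fraction = ifelse(tot > 0, glyco / tot, 0),
    mrna = states[, "M"],
    endosomal = states[, "E"])
}

#' Map a trajectory to the experimental readouts
#'
#' Readouts: `membrane_total` (`Sc + So + X`; flow-cytometry /
#' immunofluorescence membrane signal), `open_channels` (`So`;
#' patch-clamp current via [current_from_open()]), `complex` (`X`;
#' co-immunoprecipitation), `glyco_total`
#' (`G + Sc + So + X + E`; the fully glycosylated 150-155 kD western-blot
#' bands), `glyco_fraction` (glycosylated over total channel protein, a
#' ratio in `[0, 1]`), `mrna` (`M`; RQ-PCR) and `endosomal` (`E`; Rab5
#' co-localisation).
#'
#' With `normalize = TRUE` every series except `glyco_fraction` is
#' divided by its t = 0 value (fold change, the units in which the
#' kinetic data are reported); a zero baseline for a normalised series is
#' an error.
#'
#' @param traj A `trajectory` from [simulate_network()], starting at
#'   t = 0.
#' @param normalize Report fold changes (default) or raw molecule counts.
#' @return Long data frame: `time_min`, `observable`, `value`,
#'   `normalized`.
#' @export
compute_observables <- function(traj, normalize = TRUE) {
  if (traj$times[1] != 0) stop("trajectory must start at t = 0",
                               call. = FALSE)
  ser <- observable_series(traj$states)
  out <- lapply(names(ser), function(ob) {
    v <- ser[[ob]]
    norm <- normalize && ob != "glyco_fraction"
    if (norm) {
      if (v[1] <= 0) {
        if (all(v == 0)) {
          # an identically absent species (e.g. complex under a blocked
          # association) is reported as raw zeros
          norm <- FALSE
        } else {
          stop(sprintf(
            "observable '%s' has zero baseline; cannot normalise", ob),
            call. = FALSE)
        }
      } else {
        v <- v / v[1]
      }
    }
    data.frame(time_min = traj$times / 60, observable = ob, value = v,
               normalized = norm, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Electrophysiological context for current conversion
#'
#' Defaults: single-channel conductance 12 pS (typical for hERG), the
#' -120 mV hyperpolarising tail-current step, and a potassium reversal
#' potential of -80 mV.  Because the kinetic readouts are fold changes,
#' the conductance cancels in every normalised quantity.
#'
#' @param gamma Single-channel conductance (S), `> 0`.
#' @param v_m Membrane voltage (V).
#' @param e_k Potassium reversal potential (V).
#' @return A `current_context` list.
#' @export
current_context <- function(gamma = 12e-12, v_m = -0.120, e_k = -0.080) {
  stopifnot(gamma > 0)
  structure(list(gamma = gamma, v_m = v_m, e_k = e_k),
            class = "current_context")
}

#' Whole-cell current carried by a number of open channels
#'
#' `I = gamma * n_open * (v_m - e_k)`.
#'
#' @param n_open Realised open-channel count.
#' @param ctx A [current_context()].
#' @return Current in amperes.
#' @export
current_from_open <- function(n_open, ctx = current_context()) {
  ctx$gamma * n_open * (ctx$v_m - ctx$e_k)
}

#' Open-channel count from a whole-cell current
#'
#' Exact inverse of [current_from_open()]; requires a nonzero driving
#' force.
#'
#' @param current Current in amperes.
#' @param ctx A [current_context()].
#' @return Open-channel count.
#' @export
open_from_current <- function(current, ctx = current_context()) {
  drive <- ctx$v_m - ctx$e_k
  if (drive == 0) stop("zero driving force: v_m equals e_k", call. = FALSE)
  current / (ctx$gamma * drive)
}

#' Write observables as tidy CSV
#'
#' @param obs Data frame from [compute_observables()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_observables_csv <- function(obs, path) {
  write.csv(obs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
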