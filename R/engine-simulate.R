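#' Integrate a reaction network
#'
#' Stiff-capable integration (deSolve `lsoda`) of the mass-action ODE
#' system.  Rate constants in kinetic models of receptor trafficking span
#' many orders of magnitude, so an implicit stiff method is the default;
#' the compiled right-hand side keeps repeated evaluation (fitting,
#' ensembles) fast.  Tiny negative excursions within the absolute solver
#' tolerance are clipped to zero; anything more negative is an error.
#'
#' @param network A [reaction_network()].
#' @param params A [parameter_set()].
#' @param init Named numeric initial state (molecules/cell); defaults to
#'   the network's declared initials.
#' @param times Numeric vector of output times in seconds, starting at 0,
#'   strictly increasing.
#' @param method `"compiled"` (default) uses the C mass-action kernel;
#'   `"r"` uses the plain-R closure from [build_rhs()] (slower; useful for
#'   cross-checks).
#' @param rtol,atol Relative / absolute (molecules) solver tolerances.
#' @param maxsteps Maximum internal solver steps between output times.
#' @return A `trajectory` object: list with `times` (s) and `states`
#'   (time-by-species matrix).  Linear interpolation between stored points
#'   is the sampling contract (see [sample_trajectory()]).
#' @export
simulate_network <- function(network, params, init = NULL, times,
                             method = c("compiled", "r"),
                             rtol = 1e-6, atol = 1e-3, maxsteps = 50000L) {
  method <- match.arg(method)
  nm <- species_names(network)
  if (is.null(init)) init <- default_initial_state(network)
  if (!is.null(names(init))) {
    bad <- setdiff(nm, names(init))
    if (length(bad)) stop("init misses species: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    init <- init[nm]
  } else if (length(init) == length(nm)) {
    init <- setNames(as.numeric(init), nm)
  } else stop("init has wrong length", call. = FALSE)
  if (any(!is.finite(init)) || any(init < 0)) {
    stop("initial state must be finite and nonnegative", call. = FALSE)
  }
  times <- as.numeric(times)
  if (length(times) < 2L || times[1] != 0 || any(diff(times) <= 0)) {
    stop("'times' must start at 0 and be strictly increasing", call. = FALSE)
  }

  if (method == "compiled") {
    parms <- pack_network(network, params)
    out <- deSolve::lsoda(y = init, times = times, func = "ma_derivs",
                          parms = parms, dllname = "herg1kin",
                          initfunc = "ma_init", rtol = rtol, atol = atol,
                          maxsteps = maxsteps)
  } else {
    rhs <- build_rhs(network, params)
    out <- deSolve::lsoda(y = init, times = times,
                          func = function(t, y, p) list(rhs(y, t)),
                          parms = NULL, rtol = rtol, atol = atol,
                          maxsteps = maxsteps)
  }

  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1] < 0) {
    stop(sprintf("integration failed (istate %d) near t = %.6g s",
                 istate[1], max(out[, 1])), call. = FALSE)
  }
  if (nrow(out) < length(times)) {
    stop(sprintf("integration stopped early at t = %.6g s", max(out[, 1])),
         call. = FALSE)
  }
  states <- unname(as.matrix(out[, -1, drop = FALSE]))
  colnames(states) <- nm
  neg <- states < 0
  if (any(neg)) {
    worst <- min(states[neg])
    if (worst < -atol) {
      stop(sprintf("negative state beyond tolerance: %.6g (species %s)",
                   worst, colnames(states)[which(states == worst,
                                                 arr.ind = TRUE)[1, 2]]),
           call. = FALSE)
    }
    states[neg] <- 0
  }
  structure(list(times = times, states = states), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d time points (0..%g s), %d species\n",
              length(x$times), max(x$times), ncol(x$states)))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(time_s = x$times, x$states, check.names = FALSE)
}

#' Sample a trajectory by linear interpolation
#'
#' @param traj A `trajectory`.
#' @param times Seconds, within the stored range.
#' @return Matrix of interpolated states (times by species).
#' @export
sample_trajectory <- function(traj, times) {
  if (any(times < min(traj$times) - 1e-9) ||
      any(times > max(traj$times) + 1e-9)) {
    stop("requested times outside the stored trajectory", call. = FALSE)
  }
  out <- vapply(seq_len(ncol(traj$states)), function(j) {
    approx(traj$times, traj$states[, j], xout = times, rule = 2)$y
  }, numeric(length(times)))
  out <- matrix(out, nrow = length(times))
  colnames(out) <- colnames(traj$states)
  out
}

#' Write a trajectory as CSV
#'
#' First column `time_s`, one column per species, header row.
#'
#' @param traj A `trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  write.csv(as.data.frame(traj), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Per-species stationarity residual: max_i |f_i| / max(|x_i|, 1).
steady_residual <- function(rhs, x) {
  f <- rhs(x)
  max(abs(f) / pmax(abs(x), 1))
}

# Damped Newton polish towards RHS = 0, restricted to the conservation
# manifold: steps are taken in the orthogonal complement of the moiety
# rows, so every conserved total of the starting point is preserved
# exactly.  Steps that would push a species negative are damped away.
newton_polish <- function(rhs, x0, tol, laws = NULL, max_iter = 40L) {
  x <- x0
  res <- steady_residual(rhs, x)
  n <- length(x)
  Z <- diag(n)
  if (!is.null(laws) && length(laws)) {
    C <- do.call(rbind, lapply(laws, function(l) unname(l$coefficients)))
    sv <- svd(t(C), nu = n)
    keep <- seq_len(n) > qr(C)$rank
    Z <- sv$u[, keep, drop = FALSE]
  }
  for (it in seq_len(max_iter)) {
    if (res < tol) break
    f <- rhs(x)
    J <- matrix(0, n, n)
    for (j in seq_len(n)) {
      h <- max(1e-7 * abs(x[j]), 1e-9)
      xp <- x; xp[j] <- xp[j] + h
      J[, j] <- (rhs(xp) - f) / h
    }
    JZ <- J %*% Z
    sv <- svd(JZ)
    pos <- sv$d > max(sv$d) * 1e-12
    y <- -sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% f) / sv$d[pos])
    step <- as.numeric(Z %*% y)
    lambda <- 1
    improved <- FALSE
    for (k in 1:10) {
      xn <- x + lambda * step
      if (all(xn >= 0)) {
        rn <- steady_residual(rhs, xn)
        if (is.finite(rn) && rn < res) {
          x <- xn; res <- rn; improved <- TRUE
          break
        }
      }
      lambda <- lambda / 2
    }
    if (!improved) break
  }
  list(state = x, residual = res)
}

#' Relax a network to a stationary state
#'
#' Long stiff integration (optionally under parameter overrides describing
#' a basal condition) followed by a Newton polish of the algebraic
#' steady-state system.  The returned state `x*` satisfies, per species,
#' `|dx_i/dt| / max(|x_i|, 1) < tol`, which bounds the relative drift over
#' a 300-minute window well below 0.1%.
#'
#' @param network A [reaction_network()].
#' @param params A [parameter_set()].
#' @param overrides Named list/vector of absolute parameter overrides for
#'   the basal condition (applied before integration).
#' @param init Starting state (defaults to network initials).
#' @param t_max Integration horizon in seconds (default `1e6`).
#' @param tol Per-species stationarity tolerance in `s^-1` (default
#'   `1e-8`).
#' @param ... Passed to [simulate_network()].
#' @return Named steady state with attributes `residual` and `converged`.
#'   Errors if the tolerance cannot be reached (e.g. unbounded
#'   accumulation).
#' @export
pre_equilibrate <- function(network, params, overrides = list(),
                            init = NULL, t_max = 1e6, tol = 1e-8, ...) {
  params <- set_parameters(params, overrides)
  rhs <- build_rhs(network, params)
  x <- if (is.null(init)) default_initial_state(network) else init
  x <- x[species_names(network)]
  if (steady_residual(rhs, x) < tol) {
    return(structure(x, residual = steady_residual(rhs, x),
                     converged = TRUE))
  }
  laws <- conserved_moieties(network)
  horizons <- unique(pmin(c(t_max / 100, t_max / 10, t_max), t_max))
  res <- Inf
  for (h in horizons) {
    traj <- tryCatch(
      simulate_network(network, params, init = x,
                       times = c(0, h / 4, h), ...),
      error = function(e) e)
    if (inherits(traj, "error")) {
      stop(sprintf(paste0("pre-equilibration failed: relaxation ",
                          "integration aborted (%s)"),
                   conditionMessage(traj)), call. = FALSE)
    }
    x <- setNames(traj$states[nrow(traj$states), ], colnames(traj$states))
    pol <- newton_polish(rhs, x, tol, laws = laws)
    x <- pol$state
    res <- pol$residual
    if (res < tol) break
  }
  if (!(res < tol)) {
    stop(sprintf(paste0("pre-equilibration failed: residual %.3g s^-1 ",
                        "after %g s (unbounded accumulation?)"), res, t_max),
         call. = FALSE)
  }
  structure(x, residual = res, converged = TRUE)
}
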