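herg1_cell_lines <- c("HEK-hERG1", "PANC-1", "HCT116")

normalise_cell_line <- function(cell_line) {
  x <- gsub("–", "-", cell_line)  # tolerate en-dash
  m <- match(toupper(x), toupper(herg1_cell_lines))
  if (is.na(m)) {
    stop("unknown cell line '", cell_line, "'; expected one of ",
         paste(herg1_cell_lines, collapse = ", "), call. = FALSE)
  }
  herg1_cell_lines[m]
}

params_from_table <- function(tab, column) {
  parameter_set(setNames(tab[[column]], tab$name),
                units = setNames(tab$units, tab$name),
                floating = setNames(tab$floating, tab$name))
}

#' Published best-fit rate constants
#'
#' The reported best-fit values of the 22 floating rate constants and the
#' quantities held fixed during the original fits (gating rates and pool
#' sizes), per cell line, plus the package's reconstruction constants
#' (`g_dose`, `N0`, `phi0`; see the methods vignette).  These values
#' document the published model; note that under this package's
#' reconstructed rate laws they do not admit a bounded basal steady state
#' (see [reference_parameters()] and the vignette), so kinetic work
#' starts from the calibrated reference set instead.
#'
#' @param cell_line `"HEK-hERG1"`, `"PANC-1"` or `"HCT116"`.
#' @return A [parameter_set()].
#' @export
published_parameters <- function(cell_line = "HEK-hERG1") {
  cell_line <- normalise_cell_line(cell_line)
  tab <- read.csv(system.file("extdata", "published_params.csv",
                              package = "herg1kin"),
                  stringsAsFactors = FALSE, check.names = FALSE)
  params_from_table(tab, cell_line)
}

#' Calibrated reference rate constants
#'
#' The package's manually calibrated parameter set for the HEK-hERG1
#' study conditions: the "educated guess" stage of the fitting procedure,
#' chosen so that the model has a well-defined basal (suspension/BSA)
#' steady state and, after fibronectin release, reproduces the canonical
#' kinetic anchors (about fourfold membrane/open/complex/glycoprotein
#' peaks near 90 min, mRNA saturating just above twofold by 120 min,
#' relaxation most of the way back by 300 min).  It is the default
#' starting point for [mc_fit()].
#'
#' @param cell_line Currently only `"HEK-hERG1"`.
#' @return A [parameter_set()].
#' @export
reference_parameters <- function(cell_line = "HEK-hERG1") {
  cell_line <- normalise_cell_line(cell_line)
  if (cell_line != "HEK-hERG1") {
    stop("a calibrated reference set is only provided for HEK-hERG1",
         call. = FALSE)
  }
  tab <- read.csv(system.file("extdata", "reference_params.csv",
                              package = "herg1kin"),
                  stringsAsFactors = FALSE, check.names = FALSE)
  params_from_table(tab, cell_line)
}

#' Apply a perturbation preset
#'
#' Maps the experimental interventions onto parameter overrides:
#' \describe{
#'   \item{`none`}{identity.}
#'   \item{`scDb`}{the anti-complex diabody blocks hERG1/beta1 complex
#'     formation: `k_on = 0`.}
#'   \item{`PTX`, `girdin_siRNA`}{silence the activator branch
#'     (Gi-protein block / GEF knock-down): `k_a = 0` and the boost
#'     constants `k_cp`, `k_gp`, `k_tgp` set to 0.}
#'   \item{`E4031`}{traps the channel in the open, complex-incompetent
#'     state: `k_om = 0`; the open-channel observable is flagged
#'     `blocked` (attribute on the returned set) since a pore blocker
#'     carries no current.}
#' }
#'
#' @param params A [parameter_set()].
#' @param preset One of `"none"`, `"PTX"`, `"scDb"`, `"E4031"`,
#'   `"girdin_siRNA"`.
#' @return A modified [parameter_set()] (a copy).
#' @export
apply_intervention <- function(params,
                               preset = c("none", "PTX", "scDb", "E4031",
                                          "girdin_siRNA")) {
  preset <- match.arg(preset)
  out <- switch(preset,
    none = params,
    scDb = set_parameters(params, c(k_on = 0)),
    PTX = ,
    girdin_siRNA = set_parameters(params,
                                  c(k_a = 0, k_cp = 0, k_gp = 0,
                                    k_tgp = 0)),
    E4031 = {
      p <- set_parameters(params, c(k_om = 0))
      attr(p, "blocked_observables") <- "open_channels"
      p
    })
  attr(out, "intervention") <- preset
  # PTX, girdin silencing and the diabody are overnight pre-treatments and
  # act before basal pre-equilibration; the channel blocker is added at
  # seeding, on top of the untreated basal state.
  attr(out, "pretreat") <- !identical(preset, "E4031")
  out
}

#' Seeded response under an intervention preset
#'
#' Applies [apply_intervention()] with the experimentally appropriate
#' timing: pre-treatment presets (PTX, girdin siRNA, scDb) act before
#' basal pre-equilibration, E4031 is applied at the seeding step on the
#' untreated basal state.  Returns the seeded fold-change observables on
#' the requested grid.
#'
#' @param network The [herg1_network()].
#' @param params An untreated [parameter_set()].
#' @param preset Intervention name (see [apply_intervention()]).
#' @param grid Time grid in minutes.
#' @return List: `observables` (long data frame), `trajectory`, `basal`
#'   state, and the treated `params`.
#' @export
intervention_response <- function(network, params, preset = "none",
                                  grid = canonical_grid()) {
  treated <- apply_intervention(params, preset)
  basal_params <- if (isTRUE(attr(treated, "pretreat"))) treated else params
  st0 <- initial_state(network, basal_params, seeding = FALSE)
  st1 <- st0
  v <- params$values
  st1["F"] <- st1[["F"]] + (1 - v[["phi0"]]) * v[["F0"]]
  traj <- simulate_network(network, treated, init = st1,
                           times = grid * 60)
  list(observables = compute_observables(traj, normalize = TRUE),
       trajectory = traj, basal = st0, params = treated)
}

#' Basal and seeding initial states
#'
#' The basal (time-zero) condition represents cells recovered from a
#' preparatory culture before seeding: only a fraction `phi0` of the
#' fibronectin site pool `F0` is available, and the system is relaxed to
#' its stationary state with [pre_equilibrate()].  Seeding on a
#' fibronectin-coated surface releases the remaining `(1 - phi0) * F0`
#' sites as an instantaneous availability step at t = 0; every other
#' species is continuous across the step.
#'
#' @param network The [herg1_network()].
#' @param params A [parameter_set()] including the pool sizes.
#' @param seeding If `FALSE`, the pre-equilibrated basal state; if `TRUE`,
#'   the same state with the full fibronectin pool released.
#' @param basal_overrides Extra named parameter overrides defining the
#'   basal condition (applied during pre-equilibration only).
#' @param ... Passed to [pre_equilibrate()] (e.g. `t_max`, `tol`).
#' @return Named state vector (molecules/cell).
#' @export
initial_state <- function(network, params, seeding = FALSE,
                          basal_overrides = list(), ...) {
  v <- params$values
  init <- default_initial_state(network)
  init["B"] <- v[["B0"]]
  init["A"] <- v[["A0"]]
  init["I"] <- v[["I0"]]
  init["N"] <- v[["N0"]]
  init["E"] <- v[["E0"]]
  init["F"] <- v[["phi0"]] * v[["F0"]]
  st <- pre_equilibrate(network, params, overrides = basal_overrides,
                        init = init, ...)
  if (seeding) {
    st["F"] <- st[["F"]] + (1 - v[["phi0"]]) * v[["F0"]]
  }
  st
}
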