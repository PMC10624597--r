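#' Declare a molecular species
#'
#' Species are continuous copy numbers (molecules/cell); the engine uses a
#' deterministic mean-field interpretation throughout.
#'
#' @param name Short unique identifier.
#' @param role Free-text annotation (compartment, function).
#' @param initial Default initial count (molecules/cell), `>= 0`.
#' @return A `species` object (named list).
#' @export
species <- function(name, role = "", initial = 0) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(initial) || length(initial) != 1L || is.na(initial) ||
      initial < 0) {
    stop("'initial' must be a single nonnegative number", call. = FALSE)
  }
  structure(list(name = name, role = role, initial = as.numeric(initial)),
            class = "species")
}

#' Declare a mass-action reaction
#'
#' Rate law: `k * prod(reactants^stoich) * prod(modifiers^order)`.
#' Modifiers (catalysts) enter the rate law but not the stoichiometry.
#'
#' @param id Reaction identifier.
#' @param reactants,products Named numeric vectors of nonnegative integer
#'   stoichiometries (may be empty, but not both).
#' @param modifiers Named numeric vector of kinetic orders for catalytic
#'   species (positive integers).
#' @param rate_constant Name of the rate constant in the parameter set.
#' @return A `reaction` object.
#' @export
reaction <- function(id, reactants = numeric(), products = numeric(),
                     modifiers = numeric(), rate_constant) {
  chk_stoich <- function(x, what) {
    if (length(x) == 0L) return(setNames(numeric(0), character(0)))
    if (is.null(names(x)) || any(!nzchar(names(x)))) {
      stop(sprintf("reaction '%s': %s must be named", id, what),
           call. = FALSE)
    }
    if (any(x < 0) || any(x != round(x))) {
      stop(sprintf("reaction '%s': %s must be nonnegative integers",
                   id, what), call. = FALSE)
    }
    x
  }
  reactants <- chk_stoich(reactants, "reactant stoichiometries")
  products  <- chk_stoich(products, "product stoichiometries")
  modifiers <- chk_stoich(modifiers, "modifier orders")
  if (length(reactants) == 0L && length(products) == 0L) {
    stop(sprintf("reaction '%s': reactants and products both empty", id),
         call. = FALSE)
  }
  stopifnot(is.character(rate_constant), length(rate_constant) == 1L)
  structure(list(id = id, reactants = reactants, products = products,
                 modifiers = modifiers, rate_constant = rate_constant),
            class = "reaction")
}

#' Assemble a reaction network
#'
#' The ordered species and reaction lists are the single source of truth
#' for the ODE system; the stoichiometric matrix is derived from them.
#'
#' @param species List of [species()] objects.
#' @param reactions List of [reaction()] objects.
#' @return A `reaction_network` object.
#' @export
reaction_network <- function(species, reactions) {
  stopifnot(is.list(species), is.list(reactions))
  nm <- vapply(species, function(s) s$name, character(1))
  if (anyDuplicated(nm)) {
    stop("duplicate species names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  ids <- vapply(reactions, function(r) r$id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate reaction ids", call. = FALSE)
  }
  for (r in reactions) {
    ref <- c(names(r$reactants), names(r$products), names(r$modifiers))
    bad <- setdiff(ref, nm)
    if (length(bad)) {
      stop(sprintf("reaction '%s' references unknown species: %s",
                   r$id, paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  structure(list(species = species, reactions = reactions),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network> %d species, %d reactions\n",
              length(x$species), length(x$reactions)))
  invisible(x)
}

#' Species names of a network, in canonical order
#' @param network A [reaction_network()].
#' @return Character vector.
#' @export
species_names <- function(network) {
  vapply(network$species, function(s) s$name, character(1))
}

#' Default initial state of a network
#' @param network A [reaction_network()].
#' @return Named numeric vector of initial counts.
#' @export
default_initial_state <- function(network) {
  setNames(vapply(network$species, function(s) s$initial, numeric(1)),
           species_names(network))
}

#' Stoichiometric matrix
#'
#' Net stoichiometry, species by reactions (products minus reactants);
#' modifiers do not contribute.
#'
#' @param network A [reaction_network()].
#' @return Integer matrix with species rows and reaction columns.
#' @export
stoichiometry_matrix <- function(network) {
  nm <- species_names(network)
  S <- matrix(0L, nrow = length(nm), ncol = length(network$reactions),
              dimnames = list(nm, vapply(network$reactions,
                                         function(r) r$id, character(1))))
  for (j in seq_along(network$reactions)) {
    r <- network$reactions[[j]]
    for (s in names(r$reactants)) S[s, j] <- S[s, j] - as.integer(r$reactants[[s]])
    for (s in names(r$products))  S[s, j] <- S[s, j] + as.integer(r$products[[s]])
  }
  S
}

#' Construct a parameter set
#'
#' @param values Named numeric vector of nonnegative rate constants and
#'   pool sizes.
#' @param units Optional named character vector of unit strings
#'   (`"s^-1"`, `"(#/cell)^-1 s^-1"`, `"(#/cell)^-2 s^-1"`, `"#/cell"`,
#'   `"dimensionless"`).
#' @param floating Optional named logical vector: `TRUE` for constants the
#'   fit may move, `FALSE` for fixed quantities.  Defaults to all `FALSE`.
#' @return A `parameter_set` object.
#' @export
parameter_set <- function(values, units = NULL, floating = NULL) {
  stopifnot(is.numeric(values), !is.null(names(values)),
            all(nzchar(names(values))))
  if (anyDuplicated(names(values))) stop("duplicate parameter names",
                                         call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("parameter values must be finite and nonnegative", call. = FALSE)
  }
  nm <- names(values)
  if (is.null(floating)) floating <- setNames(rep(FALSE, length(nm)), nm)
  if (is.null(units))    units    <- setNames(rep(NA_character_, length(nm)), nm)
  stopifnot(all(nm %in% names(floating)), all(nm %in% names(units)))
  structure(list(values = setNames(as.numeric(values), nm),
                 units = setNames(as.character(units[nm]), nm),
                 floating = setNames(as.logical(floating[nm]), nm)),
            class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf("<parameter_set> %d parameters (%d floating)\n",
              length(x$values), sum(x$floating)))
  print(utils::head(as.data.frame(x), 10))
  if (length(x$values) > 10) cat("...\n")
  invisible(x)
}

#' @export
as.data.frame.parameter_set <- function(x, ...) {
  data.frame(name = names(x$values), value = unname(x$values),
             units = unname(x$units), floating = unname(x$floating),
             stringsAsFactors = FALSE)
}

#' Names of floating parameters
#' @param params A [parameter_set()].
#' @return Character vector.
#' @export
floating_names <- function(params) {
  names(params$values)[params$floating]
}

#' Replace parameter values
#'
#' @param params A [parameter_set()].
#' @param overrides Named numeric vector or list of absolute replacement
#'   values.
#' @return The modified parameter set.
#' @export
set_parameters <- function(params, overrides) {
  overrides <- unlist(overrides)
  if (length(overrides) == 0L) return(params)
  bad <- setdiff(names(overrides), names(params$values))
  if (length(bad)) stop("unknown parameters: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  params$values[names(overrides)] <- as.numeric(overrides)
  params
}
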