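# Rate-law construction: shared index tables for the R closure and the
# packed parameter vector consumed by the compiled solver routine.

rhs_tables <- function(network, params) {
  nm <- species_names(network)
  k <- numeric(length(network$reactions))
  terms <- vector("list", length(network$reactions))
  for (j in seq_along(network$reactions)) {
    r <- network$reactions[[j]]
    if (!r$rate_constant %in% names(params$values)) {
      stop(sprintf("reaction '%s': rate constant '%s' not in parameter set",
                   r$id, r$rate_constant), call. = FALSE)
    }
    k[j] <- params$values[[r$rate_constant]]
    ord <- c(r$reactants, r$modifiers)
    terms[[j]] <- cbind(idx = match(names(ord), nm),
                        ord = as.numeric(ord))
  }
  list(k = k, terms = terms, S = stoichiometry_matrix(network))
}

#' Build the ODE right-hand side of a network
#'
#' Returns a derivative function implementing mass-action kinetics: for
#' each reaction with constant `k`, the flux is
#' `k * prod(reactants^stoich) * prod(modifiers^order)`, and
#' `dx/dt = S %*% flux` with `S` the stoichiometric matrix.
#'
#' @param network A [reaction_network()].
#' @param params A [parameter_set()] resolving every rate constant.
#' @param check_units If `TRUE`, error when [validate_units()] reports any
#'   inconsistency (default `FALSE`: findings are diagnostics, some models
#'   intentionally carry unit-carrier constants).
#' @return `function(state, t = 0)` returning the named derivative vector
#'   (molecules/cell/s).
#' @export
build_rhs <- function(network, params, check_units = FALSE) {
  tab <- rhs_tables(network, params)
  if (check_units) {
    f <- validate_units(network, params)
    if (nrow(f)) {
      stop("unit/order inconsistencies: ",
           paste(f$rate_constant, collapse = ", "), call. = FALSE)
    }
  }
  nm <- species_names(network)
  k <- tab$k
  S <- unname(tab$S)
  storage.mode(S) <- "double"
  nr <- length(k)
  # flatten the kinetic terms into parallel index/order vectors so each
  # evaluation is fully vectorised: flux starts at k and is multiplied by
  # x[idx]^ord once per term layer (layer d holds the d-th term of every
  # reaction that has at least d terms)
  terms <- tab$terms
  nterm <- vapply(terms, nrow, integer(1))
  layers <- lapply(seq_len(max(nterm, 1)), function(d) {
    j <- which(nterm >= d)
    if (!length(j)) return(NULL)
    list(rxn = j,
         idx = vapply(terms[j], function(m) m[d, 1L], numeric(1)),
         ord = vapply(terms[j], function(m) m[d, 2L], numeric(1)))
  })
  layers <- Filter(Negate(is.null), layers)
  function(state, t = 0) {
    x <- as.numeric(state)
    x[x < 0] <- 0
    flux <- k
    for (lay in layers) {
      flux[lay$rxn] <- flux[lay$rxn] * x[lay$idx]^lay$ord
    }
    setNames(as.numeric(S %*% flux), nm)
  }
}

# Pack network + parameters into the fixed-length double vector understood
# by the compiled routine (see src/massaction.c for the layout).
MA_MAXPAR <- 8192L

pack_network <- function(network, params) {
  tab <- rhs_tables(network, params)
  nr <- length(tab$k)
  ns <- length(network$species)
  nterm <- vapply(tab$terms, nrow, integer(1))
  term_block <- unlist(lapply(tab$terms, function(m) as.numeric(t(m))))
  if (is.null(term_block)) term_block <- numeric(0)
  idx <- which(tab$S != 0, arr.ind = TRUE)
  st_block <- if (nrow(idx)) {
    as.numeric(t(cbind(idx[, 1L], idx[, 2L], tab$S[idx])))
  } else numeric(0)
  packed <- c(ns, nr, tab$k, nterm, term_block,
              nrow(idx), st_block)
  if (length(packed) > MA_MAXPAR) {
    stop("network too large for the compiled solver buffer", call. = FALSE)
  }
  c(packed, numeric(MA_MAXPAR - length(packed)))
}

unit_order <- function(u) {
  u <- gsub("\\s+", " ", trimws(u))
  map <- c("s^-1" = 1, "1/s" = 1,
           "(#/cell)^-1 s^-1" = 2, "(#/cell)^-2 s^-1" = 3,
           "(#/cell) s^-1" = 0, "#/cell s^-1" = 0)
  if (is.na(u) || !u %in% names(map)) return(NA_real_)
  unname(map[[u]])
}

#' Check kinetic orders against rate-constant units
#'
#' A first-order constant (`s^-1`) implies a rate law of total order 1,
#' `(#/cell)^-1 s^-1` order 2, `(#/cell)^-2 s^-1` order 3.  The declared
#' order of a reaction is the sum of reactant stoichiometries and modifier
#' orders.  Constants with missing or unrecognised units are skipped.
#'
#' @param network A [reaction_network()].
#' @param params A [parameter_set()] carrying unit strings.
#' @return A data frame of findings (zero rows if consistent) with columns
#'   `reaction`, `rate_constant`, `declared_order`, `implied_order`, `note`.
#' @export
validate_units <- function(network, params) {
  out <- list()
  for (r in network$reactions) {
    u <- params$units[[r$rate_constant]]
    implied <- unit_order(u)
    if (is.na(implied)) next
    declared <- sum(r$reactants) + sum(r$modifiers)
    if (declared != implied) {
      out[[length(out) + 1L]] <- data.frame(
        reaction = r$id, rate_constant = r$rate_constant,
        declared_order = declared, implied_order = implied,
        note = sprintf("rate law order %d but units '%s' imply order %d",
                       declared, u, implied),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else {
    data.frame(reaction = character(), rate_constant = character(),
               declared_order = numeric(), implied_order = numeric(),
               note = character(), stringsAsFactors = FALSE)
  }
}
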