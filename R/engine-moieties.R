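# Integer left-null-space basis of the stoichiometric matrix via
# fraction-free Gaussian elimination on [S | I]: row operations with
# integer multipliers leave integer rows; rows whose S-part vanishes
# record integer combinations of species that no reaction changes.

int_left_nullspace <- function(S) {
  S <- matrix(as.numeric(S), nrow = nrow(S))
  ns <- nrow(S); nr <- ncol(S)
  M <- cbind(S, diag(ns))
  row <- 1L
  for (col in seq_len(nr)) {
    if (row > ns) break
    piv <- which(M[row:ns, col] != 0)
    if (!length(piv)) next
    piv <- piv[which.min(abs(M[row:ns, col][piv]))] + row - 1L
    if (piv != row) M[c(row, piv), ] <- M[c(piv, row), ]
    p <- M[row, col]
    for (i in seq_len(ns)) {
      if (i == row || M[i, col] == 0) next
      M[i, ] <- M[i, ] * p - M[row, ] * M[i, col]
      g <- gcd_vec(M[i, ])
      if (g > 1) M[i, ] <- M[i, ] / g
    }
    row <- row + 1L
  }
  null_rows <- which(apply(abs(M[, seq_len(nr), drop = FALSE]), 1,
                           sum) == 0)
  basis <- M[null_rows, nr + seq_len(ns), drop = FALSE]
  if (nrow(basis)) {
    for (i in seq_len(nrow(basis))) {
      g <- gcd_vec(basis[i, ])
      if (g > 1) basis[i, ] <- basis[i, ] / g
      lead <- basis[i, which(basis[i, ] != 0)[1]]
      if (lead < 0) basis[i, ] <- -basis[i, ]
    }
  }
  basis
}

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- b; b <- a %% b; a <- t }
  a
}

gcd_vec <- function(v) {
  v <- abs(v[v != 0])
  if (!length(v)) return(1)
  Reduce(gcd2, v)
}

#' Conserved moieties of a reaction network
#'
#' Integer basis of the left null space of the stoichiometric matrix:
#' each law is a weighted species total left unchanged by every reaction
#' (e.g. total integrin across free, active and complexed forms).
#' Modifiers do not contribute to stoichiometry and therefore never break
#' a law.
#'
#' @param network A [reaction_network()].
#' @param state Optional named state at which to evaluate each conserved
#'   total.
#' @return List of `conservation_law` objects: `coefficients` (named
#'   integer vector over species) and `value` (the conserved total, `NA`
#'   if no state given).  Empty list when the stoichiometric matrix has
#'   full row rank.
#' @export
conserved_moieties <- function(network, state = NULL) {
  S <- stoichiometry_matrix(network)
  basis <- int_left_nullspace(S)
  nm <- species_names(network)
  lapply(seq_len(nrow(basis)), function(i) {
    co <- setNames(basis[i, ], nm)
    val <- if (is.null(state)) NA_real_ else sum(co * state[nm])
    structure(list(coefficients = co, value = val),
              class = "conservation_law")
  })
}

#' @export
print.conservation_law <- function(x, ...) {
  co <- x$coefficients[x$coefficients != 0]
  lab <- paste(ifelse(co == 1, names(co), paste0(co, "*", names(co))),
               collapse = " + ")
  cat(sprintf("<conservation_law> %s%s\n", lab,
              if (is.na(x$value)) "" else sprintf(" = %g", x$value)))
  invisible(x)
}

#' Conserved totals along a trajectory
#'
#' @param laws List from [conserved_moieties()].
#' @param traj A `trajectory`.
#' @return Matrix (time by law) of conserved totals.
#' @export
moiety_totals <- function(laws, traj) {
  vapply(laws, function(l) {
    as.numeric(traj$states %*% l$coefficients[colnames(traj$states)])
  }, numeric(length(traj$times)))
}
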