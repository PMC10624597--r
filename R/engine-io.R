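#' Read a model-definition JSON file
#'
#' The declarative model file holds a `species` array (`name`, `role`,
#' `initial`) and a `reactions` array (`id`, `reactants`, `products`,
#' `modifiers`, `rate_constant`), each stoichiometry map a named object.
#' The representation round-trips losslessly through
#' [write_network_json()].
#'
#' @param path JSON file.
#' @return A [reaction_network()].
#' @export
read_network_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  sp <- lapply(doc$species, function(s) {
    species(s$name, role = if (is.null(s$role)) "" else s$role,
            initial = if (is.null(s$initial)) 0 else s$initial)
  })
  rx <- lapply(doc$reactions, function(r) {
    tov <- function(x) if (length(x)) unlist(x) else numeric()
    reaction(r$id, reactants = tov(r$reactants),
             products = tov(r$products), modifiers = tov(r$modifiers),
             rate_constant = r$rate_constant)
  })
  reaction_network(sp, rx)
}

#' Write a model-definition JSON file
#'
#' @param network A [reaction_network()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(network, path) {
  doc <- list(
    species = lapply(network$species, function(s) {
      list(name = s$name, role = s$role, initial = s$initial)
    }),
    reactions = lapply(network$reactions, function(r) {
      out <- list(id = r$id)
      if (length(r$reactants)) out$reactants <- as.list(r$reactants)
      if (length(r$products))  out$products <- as.list(r$products)
      if (length(r$modifiers)) out$modifiers <- as.list(r$modifiers)
      out$rate_constant <- r$rate_constant
      out
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
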