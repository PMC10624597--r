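#' The hERG1 / beta1-integrin reaction network
#'
#' Sixteen species, twenty-five mass-action reactions.  The life cycle of
#' the channel: transcription (catalysed by active integrin, free `Bs` or
#' complexed `X`), mRNA decay, translation into the core-glycosylated ER
#' pool `R`, ER-to-Golgi transfer with full glycosylation (`G`),
#' translocation to the plasma membrane as free closed channel `Sc`,
#' gating between closed and open (`So`), complex formation with active
#' integrin (closed channels only), internalisation of free closed
#' channels into endosomes `E` (catalysed by the internalisation module
#' `Ns`), recycling and endosomal degradation.  Fibronectin engagement
#' (`F` + inactive integrin `B` -> active `Bs`) triggers a
#' balanced-inactivation module: the complex `X` catalyses activation of a
#' fast activator (`A`/`As`) and of a slower inhibitor (`I`/`Is`); the
#' activator transiently boosts translation, Golgi import/export and
#' membrane delivery and shuts down the internalisation module, while the
#' accumulating inhibitor quenches the activator (cooperatively, order 2),
#' restoring the resting turnover.
#'
#' Five conserved moieties follow from the stoichiometry: total integrin
#' `B + Bs + X`, total fibronectin sites `F + Bs + X`, and the
#' activator, inhibitor and internalisation-module pools.
#'
#' @param file Optional path to a model-definition JSON file (see
#'   [read_network_json()]).  By default the built-in definition is used;
#'   an identical editable copy ships at
#'   `system.file("extdata", "herg1_integrin_v1.json", package = "herg1kin")`.
#' @return A [reaction_network()].
#' @export
herg1_network <- function(file = NULL) {
  if (!is.null(file)) return(read_network_json(file))
  sp <- list(
    species("F",  "free fibronectin binding sites", 0),
    species("B",  "inactive beta1 integrin", 1.709e7),
    species("Bs", "active (fibronectin-bound) beta1 integrin", 0),
    species("M",  "herg1 mRNA", 0),
    species("R",  "ER core-glycosylated channel (135 kD band)", 0),
    species("G",  "Golgi fully-glycosylated channel", 0),
    species("Sc", "surface free closed channel", 0),
    species("So", "surface free open channel", 0),
    species("X",  "hERG1/beta1-integrin complex", 0),
    species("E",  "endosomal channel (Rab5-positive)", 1e3),
    species("A",  "activator, inactive", 1.5e3),
    species("As", "activator, active (girdin-Gai3-PI3K-Akt axis)", 0),
    species("I",  "inhibitor, inactive", 1.5e3),
    species("Is", "inhibitor, active", 0),
    species("N",  "internalisation module, inactive", 1e3),
    species("Ns", "internalisation module, active", 0))
  rx <- list(
    reaction("integrin_activation", c(B = 1, F = 1), c(Bs = 1),
             rate_constant = "kf0"),
    reaction("integrin_deactivation", c(Bs = 1), c(B = 1, F = 1),
             rate_constant = "k_mf"),
    reaction("transcription_free_integrin", products = c(M = 1),
             modifiers = c(Bs = 1), rate_constant = "k_ie"),
    reaction("transcription_complexed_integrin", products = c(M = 1),
             modifiers = c(X = 1), rate_constant = "k_ie"),
    reaction("mrna_decay", c(M = 1), rate_constant = "k_dm"),
    reaction("translation", products = c(R = 1), modifiers = c(M = 1),
             rate_constant = "k_c"),
    reaction("translation_boost", products = c(R = 1),
             modifiers = c(M = 1, As = 1), rate_constant = "k_cp"),
    reaction("er_to_golgi", c(R = 1), c(G = 1), rate_constant = "k_g"),
    reaction("er_to_golgi_boost", c(R = 1), c(G = 1),
             modifiers = c(As = 1), rate_constant = "k_gp"),
    reaction("golgi_to_membrane", c(G = 1), c(Sc = 1),
             rate_constant = "k_tg"),
    reaction("golgi_to_membrane_boost", c(G = 1), c(Sc = 1),
             modifiers = c(As = 1), rate_constant = "k_tgp"),
    reaction("channel_opening", c(Sc = 1), c(So = 1),
             rate_constant = "k_o"),
    reaction("channel_closing", c(So = 1), c(Sc = 1),
             rate_constant = "k_om"),
    reaction("complex_formation", c(Sc = 1, Bs = 1), c(X = 1),
             rate_constant = "k_on"),
    reaction("complex_dissociation", c(X = 1), c(Sc = 1, Bs = 1),
             rate_constant = "k_off"),
    reaction("internalization", c(Sc = 1), c(E = 1),
             modifiers = c(Ns = 1), rate_constant = "k_e"),
    reaction("recycling", c(E = 1), c(Sc = 1), rate_constant = "k_te"),
    reaction("endosomal_degradation", c(E = 1), rate_constant = "k_de"),
    reaction("activator_activation", c(A = 1), c(As = 1),
             modifiers = c(X = 1), rate_constant = "k_a"),
    reaction("activator_inactivation", c(As = 1), c(A = 1),
             modifiers = c(Is = 2), rate_constant = "k_am"),
    reaction("inhibitor_activation", c(I = 1), c(Is = 1),
             modifiers = c(X = 1), rate_constant = "k_i"),
    reaction("inhibitor_relaxation", c(Is = 1), c(I = 1),
             rate_constant = "k_iep"),
    reaction("internalization_module_activation", c(N = 1), c(Ns = 1),
             rate_constant = "k_np"),
    reaction("internalization_module_relaxation", c(Ns = 1), c(N = 1),
             rate_constant = "k_mn"),
    reaction("internalization_module_inhibition", c(Ns = 1), c(N = 1),
             modifiers = c(As = 1), rate_constant = "k_n"))
  reaction_network(sp, rx)
}

# Constant names grouped by role; used for validation and reporting.
herg1_rate_names <- function() {
  c("k_c", "k_g", "k_tg", "k_e", "k_te", "k_de", "k_off", "k_on", "k_mf",
    "k_a", "k_am", "k_i", "k_ie", "k_n", "k_np", "k_mn", "k_cp", "k_gp",
    "k_tgp", "k_dm", "kf0", "k_iep", "k_om", "k_o")
}

herg1_pool_names <- function() c("B0", "A0", "I0", "E0", "F0")

herg1_reconstruction_names <- function() c("g_dose", "N0", "phi0")
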