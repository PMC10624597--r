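# Shared fixtures: toy networks, the reference model, and an independent
# fixed-step integrator used as an oracle against the stiff solver.

toy_decay_network <- function(k_name = "k_dm") {
  reaction_network(
    list(species("M", initial = 0)),
    list(reaction("decay", c(M = 1), rate_constant = k_name)))
}

toy_birth_death_network <- function() {
  reaction_network(
    list(species("M", initial = 0)),
    list(reaction("birth", products = c(M = 1), rate_constant = "s"),
         reaction("death", c(M = 1), rate_constant = "k")))
}

toy_bimolecular_network <- function() {
  reaction_network(
    list(species("A", initial = 0), species("B", initial = 0),
         species("C", initial = 0)),
    list(reaction("bind", c(A = 1, B = 1), c(C = 1),
                  rate_constant = "k")))
}

toy_reversible_network <- function() {
  reaction_network(
    list(species("A", initial = 0), species("B", initial = 0)),
    list(reaction("fwd", c(A = 1), c(B = 1), rate_constant = "kf"),
         reaction("rev", c(B = 1), c(A = 1), rate_constant = "kr")))
}

# cache expensive shared fixtures across test files
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

ref_net <- function() fixture("net", herg1_network())
ref_params <- function() fixture("params", reference_parameters())
ref_basal <- function() {
  fixture("basal", initial_state(ref_net(), ref_params(),
                                 seeding = FALSE))
}
ref_seeded_state <- function() {
  fixture("seeded", {
    st <- ref_basal()
    v <- ref_params()$values
    st["F"] <- st[["F"]] + (1 - v[["phi0"]]) * v[["F0"]]
    st
  })
}
ref_seeded_traj <- function() {
  fixture("seeded_traj",
          simulate_network(ref_net(), ref_params(),
                           init = ref_seeded_state(),
                           times = seq(0, 300, by = 2) * 60))
}

# Classical fixed-step 4th-order Runge-Kutta on the plain-R rate law;
# independent of the compiled mass-action kernel and of lsoda.
rk4_integrate <- function(network, params, init, t_end, dt) {
  rhs <- build_rhs(network, params)
  x <- init[species_names(network)]
  n_steps <- round(t_end / dt)
  for (i in seq_len(n_steps)) {
    k1 <- rhs(x)
    k2 <- rhs(x + dt / 2 * k1)
    k3 <- rhs(x + dt / 2 * k2)
    k4 <- rhs(x + dt * k3)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  x
}
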