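# herg1kin

Kinetic modelling of integrin-driven hERG1 expression, trafficking and
hERG1/beta1-integrin complex dynamics.

## The problem

In cells adhering to fibronectin (FN), beta1-integrin engagement
remodels the life cycle of the hERG1 potassium channel: the whole-cell
hERG1 current, the channel count on the plasma membrane, the fully
glycosylated channel protein and the hERG1/beta1-integrin surface
complex all rise about fourfold with a maximum near 90 minutes after
seeding and then relax most of the way back within 300 minutes, while
the *herg1* transcript more than doubles by 120 minutes and stays up.
`herg1kin` is for modellers and quantitative cell biologists who want
to reproduce, fit and perturb that biphasic cycle *in silico*.

## The model

A deterministic mean-field mass-action network over continuous copy
numbers x (molecules/cell),

    dx/dt = S v(x),   v_j(x) = k_j * prod_i x_i^(r_ij + m_ij),

with stoichiometric matrix S, reactant orders r and catalytic modifier
orders m.  The concrete network has 16 species and 25 reactions:
FN engagement (B + F <-> B\*), integrin-catalysed transcription,
translation into the ER pool, Golgi glycosylation and membrane
delivery, closed/open gating, complex formation restricted to the
closed channel (Sc + B\* <-> X), endosomal internalisation / recycling /
degradation, and a balanced-inactivation signalling module in which the
complex drives a fast activator A\* (boosting synthesis and trafficking
and silencing internalisation) and a slower inhibitor I\* that quenches
it (flux `k_a- * A* * I*^2`), producing the transient pulse.

Around the network the package provides: stiff ODE integration with a
compiled mass-action kernel, conservation-law detection (integer left
null space of S), basal-state pre-equilibration, observable mappings to
the experimental readouts (including the single-channel current
relation `I = gamma N_open (V_m - E_K)`), a seeded synthetic
time-course generator, weighted least-squares cost with a stochastic
Monte-Carlo pairwise parameter search, +/-10% perturbation ensembles
with trajectory envelopes, and published/calibrated parameter sets for
HEK-hERG1, PANC-1 and HCT116 cells.

## Worked example

Simulate the calibrated HEK model through seeding on fibronectin and
read off the fold changes:

```r
library(herg1kin)

net    <- herg1_network()
params <- reference_parameters()              # calibrated HEK set
state  <- initial_state(net, params, seeding = TRUE)
traj   <- simulate_network(net, params, init = state,
                           times = canonical_grid() * 60)
obs    <- compute_observables(traj)
subset(obs, observable %in% c("membrane_total", "complex", "mrna") &
            time_min %in% c(0, 90, 300))
```

```
 time_min value.membrane_total value.complex value.mrna
        0             1.000000      1.000000   1.000000
       90             4.355541      3.359416   2.179943
      300             1.508866      2.795373   2.494191
```

Membrane hERG1 peaks at 4.36-fold at ~90 min and has relaxed to
1.5-fold by 300 min; the complex rises 3.4-fold; mRNA has more than
doubled by 120 min and saturates near 2.5-fold — the reported kinetic
signature.  The cross-cell-line table reproduces the published
contrasts (faster complex dissociation and endocytosis, slower
recycling in the cancer lines):

```r
cmp <- compare_cell_lines()
cmp[cmp$parameter %in% c("k_off", "k_e", "k_te"),
    c("parameter", "ratio_PANC1_HEK", "ratio_HCT116_HEK")]
```

```
 parameter ratio_PANC1_HEK ratio_HCT116_HEK
       k_e       6.3943662        9.9154930
      k_te       0.3585526        0.4802632
     k_off       3.2336449        2.1869159
```

Fitting and sensitivity, in one breath:

```r
dataset <- generate_anchor_dataset(anchor_profile("HEK-hERG1"), seed = 1)
fit     <- mc_fit(reference_parameters(), net, dataset, seed = 1)
band    <- observable_envelope(net, fit$best_params,
                               perturbation_ensemble(fit$best_params,
                                                     n_sets = 100,
                                                     seed = 1))
```

A thin command-line front end with `simulate`, `generate-data`, `fit`,
`sensitivity`, `compare` and `recover` subcommands ships at
`inst/cli/herg1kin`.

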