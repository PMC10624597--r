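---
title: "Modelling integrin-driven hERG1 trafficking kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling integrin-driven hERG1 trafficking kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herg1kin)
```

## The biological problem

When cells carrying the hERG1 potassium channel are seeded on
fibronectin (FN), beta1-integrin engagement triggers a characteristic
biphasic response: the whole-cell hERG1 current, the channel density on
the plasma membrane, the amount of fully glycosylated channel protein
and the amount of hERG1/beta1-integrin complex all rise roughly fourfold
with a maximum near 90 minutes and then relax most of the way back over
five hours, while the *herg1* transcript more than doubles by 120
minutes and then stays up.  `herg1kin` implements a deterministic
mean-field model of that cycle: a mass-action reaction network over
continuous copy numbers (molecules/cell), integrated as a stiff ODE
system, fitted to time-course data by a stochastic Monte-Carlo search,
and interrogated through perturbation ensembles.

## The network

`herg1_network()` declares 16 species and 25 mass-action reactions
(editable as data in
`system.file("extdata", "herg1_integrin_v1.json", package = "herg1kin")`):

* **Adhesion** — free FN sites `F` bind inactive integrin `B` to give
  active integrin `Bs` (`kf0`), reversibly (`k_mf`).
* **Expression** — transcription of mRNA `M` is catalysed by active
  integrin, *bound or not to the channel*, so two reactions share
  `k_ie` (modifiers `Bs` and `X`); `M` decays (`k_dm`); translation
  produces the ER core-glycosylated pool `R` (`k_c`, boosted `k_cp`);
  ER-to-Golgi transfer (`k_g`, boosted `k_gp`) yields the fully
  glycosylated pool `G`; delivery to the membrane (`k_tg`, boosted
  `k_tgp`) yields the free closed surface channel `Sc`.
* **Gating** — `Sc` and the open channel `So` interconvert
  (`k_o`, `k_om`); at their fast pre-equilibrium the open fraction is
  `k_o / (k_o + k_om)` (about 1.8% with the fixed gating rates).
* **Complex** — only the closed channel associates with active integrin
  (`k_on`) to form the hERG1/beta1 complex `X`, which dissociates with
  `k_off` and shields the channel from endocytosis.
* **Turnover** — free closed channels are internalised into the
  endosomal pool `E` under catalysis by the active internalisation
  module `Ns` (`k_e`); endosomal channels recycle (`k_te`) or are
  degraded (`k_de`).
* **Balanced inactivation** — the complex `X` catalyses activation of a
  fast activator `A -> As` (`k_a`; the coarse-grained
  girdin/Gai3/PI3K/Akt axis) and of a slower inhibitor `I -> Is`
  (`k_i`, relaxing with `k_iep`); the inhibitor quenches the activator
  cooperatively (`k_am`, order 2 in `Is`).  The activator boosts
  translation and trafficking and silences the internalisation module
  (`k_n`), which otherwise cycles between inactive and active forms
  (`k_np`, `k_mn`).

Five moiety conservation laws follow structurally and are detected by
`conserved_moieties()`: total integrin `B + Bs + X`, total FN sites
`F + Bs + X`, and the `A`, `I` and `N` pools.

The pulse logic: seeding releases FN, complexes form, the activator
rises within tens of minutes and transiently (i) boosts the supply of
channel to the membrane and (ii) switches off internalisation; the
slower inhibitor then quenches the activator, internalisation resumes,
and the membrane pool relaxes.  The mRNA rise is driven directly by
active integrin, not by the activator, which is why it saturates
instead of pulsing.

## Parameters, units, and the two bundled sets

Rate constants are in `s^-1` for first-order steps,
`(#/cell)^-1 s^-1` for second-order and `(#/cell)^-2 s^-1` for the
third-order activator quenching; pool sizes are molecules/cell.  The
canonical reporting grid is `canonical_grid()` =
{0, 5, 15, 30, 45, 60, 90, 120, 180, 240, 300} minutes; the engine works
in seconds internally.

`published_parameters()` reproduces the reported best-fit table for the
three cell lines exactly (22 floating rate constants; gating rates
`k_o`, `k_om` and the pools `B0`, `A0`, `I0`, `E0`, `F0` fixed), plus
three reconstruction constants the table does not carry:

* `g_dose = 1` — a unit carrier for the transcription rate law (the
  only place where the declared kinetic order and the tabulated units
  disagree; `validate_units()` flags exactly this constant).
* `N0 = 1e3` molecules — the internalisation-module pool.
* `phi0 = 0.4` — the fraction of the FN-site pool available before
  seeding.  A nonzero basal availability is required so that every
  fold-change readout has a nonzero baseline; its magnitude is pinned
  by the mRNA anchor, because at steady state the transcript count is
  proportional to engaged integrin and the seeded-to-basal engagement
  ratio is `1/phi0`.  `phi0 = 0.4` puts the late mRNA fold near 2.5,
  consistent with "more than doubled".

Under this package's reconstructed rate laws the published values do
**not** admit a bounded basal steady state: the activator has no
first-order relaxation, so any nonzero basal complex signal eventually
activates it fully, which silences the internalisation module and
leaves membrane synthesis without a sink.  `pre_equilibrate()` then
fails with an explicit unbounded-accumulation error, and the package
treats the published set as documentation (value lookups, cross-cell
line ratio tables via `compare_cell_lines()`) rather than as a
simulatable configuration.

`reference_parameters()` is the package's own calibrated HEK set and
the default starting point for fitting.  It was produced the way the
original fit was: a manual, order-of-magnitude exploration (choosing
timescales — mRNA lifetime about an hour, membrane turnover tens of
minutes, activator response minutes, inhibitor response about an hour —
and solving the basal balance for the remaining magnitudes), followed
by a Monte-Carlo polish against the bundled synthetic dataset.  Two
calibration choices deserve note:

* the basal activator occupancy is placed where the boost/shutdown loop
  gain is just below one, so the seeding step transiently
  self-amplifies into the fourfold peak and is then quenched;
* Golgi export `k_tg` is slow enough (about 20 minutes) to be
  rate-limiting, which keeps it kinetically visible — with a fast
  Golgi transit the delivery flux is set upstream at quasi-steady state
  and `k_tg` would be practically unidentifiable; the membrane-delivery
  boost `k_tgp` is correspondingly negligible in this set.

## Basal state, seeding, interventions

The time-zero condition represents cells recovered from a preparatory
culture before seeding.  `initial_state(..., seeding = FALSE)` exposes
`phi0 * F0` FN sites and relaxes the full dynamics to a stationary
state: stiff integration in increasing horizons (default up to `1e6` s)
followed by a damped Newton polish restricted to the conservation
manifold, so the moiety totals of the initial pools are preserved
exactly.  The returned state satisfies, per species,
`|dx/dt| / max(x, 1) < 1e-8 s^-1`, which bounds the drift over 300
minutes below 0.02%.  Seeding (`seeding = TRUE`) releases the remaining
`(1 - phi0) * F0` sites as an instantaneous availability step at t = 0;
all other species are continuous.

Intervention presets are parameter overrides with experimentally
faithful timing (`apply_intervention()`, `intervention_response()`):
pertussis toxin and girdin silencing (activator branch silenced) and
the anti-complex diabody (`k_on = 0`) are overnight pre-treatments and
act before pre-equilibration — hence an identically zero complex
baseline under the diabody — while the pore blocker E4031 is added at
seeding (`k_om = 0`, open-state trapping, a deliberate simplification
of open-state-biased block; the open-channel readout is flagged as
blocked because a blocked channel carries no current).

## Observables

`compute_observables()` maps a trajectory to the assayed quantities:
membrane channel `Sc + So + X`, open channels `So`, complex `X`,
fully glycosylated protein `G + Sc + So + X + E` (the 150–155 kD
western-blot bands; reported alongside the derived glycosylated
*fraction*, which is a ratio in [0, 1] and is never normalised), mRNA
`M` and the endosomal pool `E`.  All series except the fraction are
reported as fold change over their t = 0 value, the unit in which the
kinetic data are plotted; a zero baseline under normalisation is an
error unless the series is identically zero (a structurally absent
species, reported as raw zeros).  `current_from_open()` converts an
open-channel count to a whole-cell current via
`I = gamma * N_open * (V_m - E_K)` with defaults gamma = 12 pS (typical
hERG single-channel conductance; it cancels in every fold change),
V_m = -120 mV (the tail-current step) and E_K = -80 mV.

## The synthetic time-course generator

No raw data are distributed with the study, so `anchor_profile()` and
`generate_anchor_dataset()` emulate the printed kinetic anchors:
pulse-shaped fold-change readouts (membrane, open channels, complex,
glycosylated protein) with peak fold 4 at 90 min, and a saturating mRNA
readout whose time constant is fixed by requiring fold 2 exactly at the
120-min doubling anchor, saturating at 2.3.  The pulse mean curve is

    f(t) = 1 + (peak - 1) g(t) + (plateau - 1)(1 - e^(-t/t_p))(1 - g(t)),

with `g(t) = (t/t_p)^h exp(h (1 - t/t_p))` (`h = 3`), so `f(0) = 1` and
`f(t_p) = peak` exactly.  Late plateaus encode the reported partial
relaxation (1.3 for membrane/complex/glycoprotein, 1.8 for the current,
which stabilises above baseline); the cancer-line profiles reuse the
shapes with a 1.5-fold faster post-peak time axis, reflecting the
faster relaxation in the cancer lines.  Replicates are
`mean * (1 + N(0, noise_cv))` truncated at zero, independent, with
`n_rep = 3` and `noise_cv = 0.10` (s.e.m.-scale) by default, fully
determined by the seed.

What passing against these data does and does not show: the generator
reproduces anchor values, time courses and replicate dispersion, but
not antibody nonlinearity, between-experiment normalisation drift,
replicate correlation (wells are assumed independent; the true pairing
is unreported), or absolute molecule counts.  Agreement with it
demonstrates that the network can express the reported kinetics and
that the fitting machinery recovers them — not that the fitted rate
constants are the cell's.

## Fitting

`fit_cost()` is the weighted sum of squared deviations between the
model's fold-change series and the replicate means on the dataset grid
(equal weights by default; the original weight vector is unpublished).
Every evaluation rebuilds the basal state for the candidate parameters,
so the baseline normalisation is always self-consistent; any
pre-equilibration or integration failure scores `Inf`.

`mc_fit()` implements the stochastic search: per iteration a random
pair of distinct floating parameters is multiplied by
`exp(U(-d, d))` with `d = log(1 + 0.10)` — multiplicative moves,
because the constants span ten orders of magnitude — and the candidate
is accepted only if the score strictly decreases (greedy,
zero-temperature).  Stopping: relative best-score decrease below
`1e-4` over a 500-iteration window, or the iteration cap.  The
accepted-score history is non-increasing by construction, fixed
parameters are never touched, and the whole run is reproducible from
its seed.  `multi_start_fit()` automates the preceding coarse
exploration.  Full 22-parameter identifiability is not claimed — the
model is sloppy in the usual sense; the recovery harness demonstrates
recovery (within 10% on noiseless self-generated data) for the five
designated kinetically dominant constants `k_on`, `k_off`, `k_a`,
`k_e`, `k_tg`.

## Sensitivity ensembles

`perturbation_ensemble()` draws parameter sets with every floating
constant independently multiplied by `U(0.9, 1.1)` (uniform on the
linear scale — the natural reading of "within ±10%"), fixed entries
untouched; `observable_envelope()` simulates each member from its own
basal state and reports the pointwise minimum/maximum band around the
central best-fit curve (min/max, not percentiles, with a percentile
option left to the caller by filtering; the central curve is included
in the band, so `lower <= central <= upper` holds identically).
Members that fail to simulate are dropped and counted; more than 10%
failures is an error.  All fold-normalised bands have zero width at
t = 0.

## Numerical choices

* Stiff integration (`lsoda`) with `rtol = 1e-6`, `atol = 1e-3`
  molecules; the mass-action right-hand side is compiled C shared by
  any declarative network, with a plain-R path (`method = "r"`) kept
  for cross-checks.  The test suite verifies the stiff solver against
  an independent explicit fixed-step RK4 integration of the plain-R
  rate law (60-second horizon, `dt = 1e-4` s, agreement to 1e-4
  relative — the short horizon keeps the explicit oracle feasible).
* Negative excursions: rate laws clamp negative inputs to zero;
  sampled states may undershoot by at most `atol` (clipped to zero),
  anything larger is an error, never silently repaired.
* Conservation-law detection uses fraction-free integer Gaussian
  elimination on `[S | I]`, so the basis is exact integer arithmetic;
  tests cross-check its dimension against an SVD null space and verify
  that the five physical totals lie in its span.
* Tie-breaking in `multi_start_fit()` is by lowest start index;
  `which.min` provides it deterministically.

## Problem sizes

The bundled analyses are sized for interactive use: 11-point canonical
grids, 100-member ensembles, Monte-Carlo polishes of a few thousand
iterations (about 50 ms per cost evaluation, i.e. a few minutes), and
a dense 1-minute grid for peak/relaxation measurements.  The
end-to-end reproduction script (`scripts/acceptance.R`) uses 3000
iterations from the calibrated reference start.

## Known limitations

* The original model's full equation set is not publicly distributed;
  the reaction network here is a reconstruction from the published
  schematic, narrative and rate-constant table, kept declarative
  (JSON) precisely so it can be corrected as data.  The
  transcription rate law (`k_ie`, whose tabulated units imply a
  second-order law the reconstruction carries through a unit-carrier
  constant), the cooperative activator quenching (order 2 in `Is`;
  an `As * Is * X` alternative is a data edit in the model file), and
  the internalisation-module triplet are the least certain pieces.
* The published rate-constant values are not simulatable under this
  reconstruction (no bounded basal state; see above), so all kinetic
  work runs on the calibrated reference set.
* Deterministic mean-field only: no stochastic simulation, no spatial
  compartments, no membrane-potential model, no drug kinetics.
* Complexed integrin is assumed unable to release FN or deactivate
  (no constant is provided for it), and direct degradation of the free
  membrane channel is omitted by default (no dedicated constant); it
  can be added as a data edit with a user-supplied rate.
* With permanent FN engagement the complex plateau relaxes less than
  the measured co-IP plateau; the fitted compromise slightly
  overshoots the late complex fold while matching the membrane,
  current and mRNA series.
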