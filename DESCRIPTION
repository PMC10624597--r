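Package: herg1kin
Title: Kinetic Modelling of Integrin-Driven hERG1 Expression, Trafficking
    and Channel/Integrin Complex Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic mass-action modelling of the coupled expression,
    glycosylation, membrane trafficking, endocytic recycling and beta1
    integrin complex formation of the hERG1 potassium channel after cell
    adhesion to fibronectin.  Provides a generic declarative
    reaction-network engine with stiff ODE integration and conservation-law
    detection, the concrete 16-species hERG1/integrin network with
    published and calibrated rate-constant sets for HEK-hERG1, PANC-1 and
    HCT116 cells, observable mappings to the standard kinetic readouts
    (membrane channel count, open-channel current, co-immunoprecipitated
    complex, glycosylated fraction, mRNA, endosomal pool), a seeded
    synthetic time-course generator, a stochastic Monte-Carlo pairwise
    parameter search, and +/-10 percent perturbation ensembles with
    trajectory envelopes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
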