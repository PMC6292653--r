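Package: allostat
Title: Statistical-Thermodynamic Ensemble Model of Two-Domain Allostery
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a comprehensive statistical-thermodynamic ensemble
    model of heterotropic allostery in a two-domain protein in which each
    domain can adopt an ordered relaxed (R), an ordered tense (T), or an
    intrinsically disordered (I) state.  The model unifies the concerted
    two-state MWC mechanism (order-order transitions through RR and TT)
    with the ensemble allostery model of disordered proteins (order-disorder
    transitions through RR, RI, IR, II) in a single seven-state Boltzmann
    ensemble parameterised by six free energies.  Provides the allosteric
    coupling response CR and its closed-form maximum, decomposition of the
    response into MWC, EAM and mixed pathways with per-pathway weights and
    capacities, alternative allostery measures (thermodynamic efficacy
    alpha, the thermodynamic coupling function, normalised allosteric
    coupling), Ising and Potts interface variants, and fast vectorised
    Monte-Carlo exploration of the free-energy parameter space.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
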