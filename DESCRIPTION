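Package: tandemsite
Title: Tandem Two-Site Radioligand Binding Kinetics at Muscarinic Receptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of radioligand binding kinetics under the
    tandem two-site mechanism, in which orthosteric ligands such as
    N-methylscopolamine (NMS) and quinuclidinyl benzilate (QNB) transit a
    low-affinity extracellular vestibule site on their way to and from the
    orthosteric pocket of muscarinic acetylcholine receptors. Provides a
    mass-action ODE simulator of the mechanism, a generator of synthetic
    replicate-structured saturation and dissociation experiments, the
    multi-stage fitting pipeline used to analyse such experiments (saturation
    fits, mono/bi-exponential dissociation fits with F-test model selection,
    allosteric dissociation-retardation fits for the vestibule affinity K_A
    and slope factor nH, Dunnett-style group comparisons), per-residue RMSF
    and ligand-contact statistics for coordinate trajectories, and a
    one-dimensional Brownian-dynamics toy model of steered ligand escape.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    multcomp,
    bio3d,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    optparse
Config/testthat/edition: 3
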