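Package: foldswitch
Title: Dual-Fold Protein Sequence Design and Fold-Switch Thermodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for engineering amino acid sequences compatible with two
    protein folds, where a small fold (such as a 3-alpha bundle or beta-grasp
    domain) is embedded as a contiguous window inside a roughly 50 percent
    larger alpha/beta-plait fold.  Provides coarse-grained fold templates
    (secondary-structure topology, residue contact maps, burial classes),
    enumeration and ranking of contiguous embeddings by catastrophic-
    interaction counts, cluster-wise substitution search that conserves
    original residues while resolving conflicts in both folds simultaneously,
    and variant/truncation/tail-graft operations.  Includes the thermodynamic
    linkage analysis that converts folding free energies of short and long
    constructs into a fold-switch free energy and three-state populations,
    Gibbs-Helmholtz melting-curve simulation and fitting for CD data,
    competitive protease-inhibition kinetics (apparent Michaelis constant and
    K_I estimation), affinity-retention classification, NMR chemical-shift
    perturbation, and synthetic-data generators for all inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml,
    minpack.lm
Suggests:
    bio3d,
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
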