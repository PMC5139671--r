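Package: foldscan
Title: Exhaustive In Silico Missense Mutagenesis with Unfolding Propensities
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Saturation in silico mutagenesis of protein structures. Every
    position of a PDB structure is mutated to all twenty amino acids, mutant
    side chains are placed from a rotamer library, and a documented, pluggable
    energy function yields a folding free-energy change (ddG) per substitution.
    A two-state thermodynamic transform maps ddG onto a universal 0-1 unfolding
    propensity scale (0.5 = folding-unfolding equilibrium), from which the
    package derives per-residue descriptors (average propensity, foldability,
    Shannon entropy of the mutational profile, residue depth below the solvent
    accessible surface), a rotamer-based internal control for structure-model
    acceptance, and report artifacts: mutation matrix, descriptor table,
    standard and clustered HTML heat maps, and a structure-coloring script.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    ape,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
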