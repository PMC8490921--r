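Package: gpcriface
Title: Interface Profiling of GPCR-Partner Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for characterizing the intracellular interface between
    G-protein coupled receptors (GPCRs) and their signalling partners
    (G-proteins, arrestins) from complex structures in PDB format. Provides
    generic residue numbering (Ballesteros-Weinstein for transmembrane
    helices, 34.X-style labels for intracellular loop 2, positional labels
    for partner subdomains), residue-residue contact detection at a
    configurable alpha-carbon distance cutoff, geometric hydrogen-bond and
    salt-bridge assignment, Shrake-Rupley solvent-accessible surface area
    and buried interface area, interface amino-acid composition,
    interhelical distances and Kabsch superposition, anisotropic
    elastic-network normal-mode analysis with monomer-versus-complex
    fluctuation deltas, cross-complex consensus interaction matrices and
    wildcard motif rendering, plus a deterministic synthetic-structure
    generator so that every stage is testable without external downloads.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
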