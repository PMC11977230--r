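Package: coevdyn
Title: Coevolving Residues, Trajectory Dynamics and Biosensor Curves for
    GAF-Domain Allostery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for studying allosteric regulation in
    small-molecule-binding regulatory domains (GAF domains and similar).
    Implements statistical coupling analysis (SCA) of multiple sequence
    alignments with the field's redundancy and gap-column filters,
    hierarchical clustering of the positional coupling matrix to extract
    coevolving residue clusters, mapping of alignment positions onto
    protein structures with ligand-proximity classification at a distance
    cutoff, molecular-dynamics trajectory statistics (RMSD, RMSF, radius
    of gyration, inter-group distances, Shrake-Rupley ligand SASA,
    hydrogen-bond counts, dynamic cross-correlation), kernel-density
    conformational landscapes over secondary-structure element distances,
    and curve models for BRET biosensor data (two-Gaussian spectra,
    four-parameter logistic dose-response, Boltzmann thermal melts).
    Seeded synthetic-data generators with planted ground truth make the
    whole pipeline testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    MASS,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
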