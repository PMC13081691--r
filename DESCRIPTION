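Package: ppitriage
Title: Confidence Scoring and Interface Triage for Predicted Protein Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Post-prediction triage of candidate protein-protein interactions from
    predicted complex models (AlphaFold2-Multimer, AlphaFold3, AlphaPulldown2 style
    output). Reads structures (PDB/mmCIF) and confidence JSON in the two common
    dialects, computes a family of interface confidence metrics (weighted ipTM+pTM,
    ipSAE and its d0 variants, pDockQ, an interface-masked pTM approximation of
    actifpTM), trims models to annotated domains with consistent PAE slicing,
    compares interfaces across models by superposition-free interface lDDT, builds
    thresholded similarity networks, screens bait-candidate panels with documented
    filters, checks amphipathicity of helical segments and membrane or localization
    plausibility, and ships a synthetic-model generator so the whole pipeline can be
    exercised without running a structure predictor.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
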