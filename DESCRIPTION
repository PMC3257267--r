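Package: orthopharm
Title: Cross-Species and Within-Family Pharmacology of Small-Molecule Binding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for large-scale comparison of small-molecule binding
    affinities across homologous protein targets. Harmonizes heterogeneous
    bioactivity measurements (Ki, IC50, EC50, pA2, pKi) to a common pKi scale,
    pairs activities across human-rat orthologs and human paralogs, constructs
    an inter-assay difference distribution as an empirical null, screens target
    pairs for species-specific pharmacology with Mann-Whitney U tests and
    Bonferroni correction, relates affinity divergence to sequence identity at
    full-sequence, domain and binding-site resolution, maps binding sites to
    Pfam domains with a frequency heuristic, and clusters ligands into
    chemotypes with LINGO q-gram fingerprints and complete-linkage clustering.
    Includes a synthetic-data generator with planted ground truth so the whole
    pipeline is testable without database access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    car,
    dplyr,
    jsonlite,
    nortest,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
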