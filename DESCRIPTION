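Package: radortho
Title: Cross-Laboratory RAD-Seq Ortholog Clustering and Phylogeny Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies orthologous restriction site-associated DNA (RAD) loci
    across species from per-species consensus locus sequences, and estimates
    phylogenies from the interspecific variation they carry. Consensus loci are
    trimmed to a common length, low-complexity and repeat sequence is masked,
    multi-study datasets are merged within species, and cross-species loci are
    matched by seeded local alignment with best-hit, threshold and uniqueness
    filtering. Reciprocal best hits define a graph whose cliques (or connected
    components) are ortholog clusters; clusters pass paralogy, multiplicity and
    taxon-coverage filters, are multiply aligned, and their between-species
    single-nucleotide variants are concatenated into a supermatrix with
    missing-data coding, exported as relaxed PHYLIP. An internal
    distance-based tree builder with nonparametric bootstrap provides a
    phylogeny estimate, and a sequence-evolution simulator with known
    ground-truth orthology makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    igraph,
    phangorn,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
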