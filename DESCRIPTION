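Package: satellitome
Title: Satellite DNA Discovery, Quantification and Cross-Species Comparison
    from Low-Coverage Short Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes the satellitome (the full catalog of satellite DNA
    families) of a species from low-coverage, unassembled short reads, and
    compares catalogs across species. Implements iterative tandem-repeat
    discovery via k-mer overlap-graph cycles and within-read periodicity,
    alignment-based read subtraction between rounds, genome-proportion
    abundance and divergence estimation by best-hit read mapping against
    dimerized consensus monomers, rotation- and strand-invariant monomer
    homology via dimerization, and the standard same-variant / variant /
    superfamily classification of monomer pairs. Ships a ground-truthed
    synthetic genome and read simulator for planted tandem-repeat arrays so
    the whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    S4Vectors,
    igraph,
    data.table,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
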