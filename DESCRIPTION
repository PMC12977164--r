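Package: tetradiv
Title: Haplotype Divergence Analytics for Autotetraploid Genomes
Version: 0.1.0
Authors@R: person("tetradiv", "maintainers", email = "tetradiv@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing haplotype divergence in phased autotetraploid
    genome assemblies: synteny-block chaining and consolidation with gene
    retention statistics against a diploid relative, sliding-window variant
    densities and distance-based haplotype lineage clustering, Nei-Gojobori
    (1986) Ka/Ks estimation with Ks-distribution peak detection and
    Ks = 2*mu*T dating, a four-category allele-specific-expression classifier
    from per-allele TPM, and transposable-element density profiles over gene
    flanks. A synthetic tetraploid data generator with known truth drives
    testing of every stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ape,
    BiocGenerics,
    Biostrings,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
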