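Package: spectratree
Title: Mutation Spectrum Evolution Across Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the evolution of the germline mutation
    spectrum across a phylogeny from polymorphism data. Extracts k-mer
    context-dependent mutation spectra from VCF files polarized against an
    ancestral genome, normalizes them for accessible genome composition and
    diversity (target rescaling, multinomial downsampling, pseudocounts),
    and analyses them in Aitchison (log-ratio) compositional geometry.
    Provides permutation tests for phylogenetic signal (Mantel tests on
    distance matrices, the multivariate Blomberg's K statistic), a
    conditional permutation test for mutation-rate dependence on extended
    sequence context, Fisher's exact scans for hypermutable sequence motifs
    benchmarked against CpG transition enrichment, multinomial
    mutational-signature exposure fitting with optional novel-signature
    extraction, and a synthetic-data generator that emits VCF/FASTA/BED
    bundles with known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    stats,
    utils,
    vcfR
Suggests:
    picante,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
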