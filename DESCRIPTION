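Package: gxemap
Title: Dissecting Genotype-by-Environment Interaction into Multi-Locus
    Genotypes in Yeast Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for dissecting genotype-by-environment interaction in a
    yeast backcross into explicit multi-locus genotypes. Implements a
    genotype-to-phenotype rule engine for temperature-sensitivity classes
    of a mutationally induced colony phenotype, a backcross meiosis and
    sequencing simulator (pooled and low-coverage individual), bulk
    segregant mapping with a kernel-pooled binomial LOD scan and 2-LOD
    support intervals, hidden Markov model haplotype inference for
    low-coverage segregants, and a pairwise chi-square scan for genotypic
    heterogeneity with Storey q-value false discovery rate control and
    genotype-partitioned allele-frequency calling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
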