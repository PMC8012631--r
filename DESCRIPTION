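Package: automixr
Title: Detecting Facultative Parthenogenesis and Automixis Mechanisms from
    Genotype Trios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting facultative parthenogenesis and
    discriminating automictic mechanisms (terminal fusion, central fusion,
    gametic duplication, apomixis) from SNP genotypes of a mother and her
    putatively parthenogenetic offspring. Implements a reduced-representation
    (RADseq-style) site filter cascade, locus footprint derivation from
    per-base depth, individual heterozygosity (observed heterozygosity and
    homozygosity by loci) and pairwise allele-sharing relatedness with locus
    bootstraps, fate classification of maternal heterozygous loci with exact
    binomial inheritance-bias tests, a Jaccard permutation test for shared
    retained heterozygosity, GC-content comparison around retained versus
    lost heterozygosity, and a rule-based mechanism classifier. A
    chromatid-level meiosis simulator generates synthetic trios under each
    mechanism with ground-truth retained-heterozygosity tracts, so every
    statistic has a known-answer test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
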