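Package: chromospec
Title: Chromosome Rearrangements, Partitioned Divergence and Gene-Tree
    Concordance in Recent Radiations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether chromosomal rearrangements structure
    genomic divergence in recently diverged species groups. Maps karyotype
    characters (fusions, inversions, centric shifts) onto a species tree by
    unordered-state parsimony with full most-parsimonious-reconstruction
    ambiguity and homoplasy reporting; partitions exon loci into X,
    rearranged-autosome and non-rearranged-autosome classes and computes
    length-weighted net divergence (dA) and within-taxon diversity per
    class and chromosomal group; quantifies per-taxon monophyly and
    Robinson-Foulds incongruence across partition trees; and simulates
    matched datasets under a multispecies coalescent with class-specific
    introgression pulses and karyotype hotspot evolution, with truth logs
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phangorn,
    purrr,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
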