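Package: stockload
Title: Deleterious Mutation Load and Neutral Diversity in Supplemented Lake Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse how supplementation (stocking) shapes neutral
    genetic diversity and the distribution of putatively deleterious mutations
    across lake populations of a salmonid. Provides genotype filtering from VCF,
    per-population diversity summaries, Weir-Cockerham pairwise FST with locus
    bootstraps, codon-level classification of substitutions with effect-score
    thresholds, per-population deleterious-load statistics, Welch t tests,
    class ANOVAs and a population-effect MANOVA, distance-based Moran eigenvector
    maps, distance-based redundancy analysis with permutation inference and
    forward selection, a DAPC-style cluster-membership matrix, and a forward
    Wright-Fisher simulator with directional admixture pulses that emulates the
    sampling design of a 24-lake stocking survey.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    vegan,
    MASS,
    mclust,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    seqinr,
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
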