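Package: microClock
Title: Host Age Prediction from Fecal Microbiota Composition
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts murine host age (in weeks) from 16S rRNA amplicon
    sequence variant (ASV) count tables of fecal microbiota. Implements a
    longitudinal cohort simulator with phase-structured ASV succession,
    rarefaction and alpha/beta diversity (Shannon, Simpson, Chao1, Pielou,
    Bray-Curtis, weighted UniFrac, PCoA), pairwise PERMANOVA with
    Benjamini-Hochberg correction for selecting one representative "source"
    community per life phase, a collapsed Gibbs sampler that attributes each
    "sink" sample to life-phase sources plus an unknown component
    (Dirichlet-multinomial mixture), and the life-phase-midpoint formula that
    converts attributions to predicted age, with batch calibration and an
    uncertainty filter.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    ape,
    vegan,
    phyloseq
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Microbiome, Metagenomics, Bayesian, Regression, Software
RoxygenNote: 7.3.3
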