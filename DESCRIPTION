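Package: reefdiverge
Title: Divergence-Continuum Analysis for Sympatric Coral Taxa
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting sympatric genetic taxa in reduced-representation
    (RAD-seq) genotype data and for reconstructing their divergence histories.
    Provides a seeded structured-coalescent generator of RAD-tag genotype,
    spatial and environmental data; VCF filtering (allele-count, depth,
    missingness, clone removal and VIF-based linkage pruning); Weir-Cockerham
    F_ST, windowed D_XY, individual genetic distances with multi-peak gap
    detection, and PCA/K-means taxon assignment; construction, projection,
    folding and bootstrap of the two-population joint allele-frequency
    spectrum; diffusion-approximation fitting of isolation-with-migration
    models with heterogeneous gene flow, model comparison, composite-likelihood
    ratio tests and Fisher-information uncertainties; conversion of scaled
    parameters to demographic units; and genotype-environment association by
    partial redundancy analysis with spatial (dbMEM) conditioning.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    vcfR,
    vegan,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
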