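Package: pmcompare
Title: Phenotype-Microarray Comparison of Paired Microbial Strains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-channel kinetic phenotype-microarray
    (Biolog FF) assays comparing a pair of microbial strains, such as a
    fungal strain naturally infected with an endohyphal bacterium (EHB+)
    and its antibiotic-cured clone (EHB-). Provides corrected-absorbance
    channel arithmetic, replicate aggregation, measurable-growth
    thresholding, per-substrate Welch tests with Benjamini-Hochberg false
    discovery rate control, a five-outcome substrate classification and
    census statistics, from-scratch distance-based permutation statistics
    (Bray-Curtis dissimilarity, PERMANOVA, ANOSIM, MRPP) with exact
    enumeration for small designs, UPGMA dendrograms in Newick format, a
    per-time-point global scan, and a seeded synthetic-data generator that
    emulates the five-replicate, 96-well, 14-time-point, two-wavelength
    study design with planted per-substrate outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
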