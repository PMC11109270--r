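Package: brainphen
Title: Multimodal Brain-Health Phenotyping with Small-World Propensity
        Networks and Nutrient Biomarker Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
        email = "maintainer@example.org")
Description: Discovers Accelerated- versus Delayed-aging brain-health
        phenotypes in elderly cohorts from multimodal features. Builds
        weighted functional-connectivity networks from BOLD-like time
        series (Fisher-Z standardization, Bonferroni-thresholded positive
        correlations, 0-1 weight rescaling), computes weighted graph
        metrics including small-world propensity against degree-matched
        lattice and random null networks, residualizes features against
        covariates via the Frisch-Waugh-Lovell route, normalizes them with
        Tukey's Ladder of Powers, clusters participants by complete-linkage
        hierarchical clustering, and compares the resulting phenotypes on
        brain age, cognition and blood nutrient biomarkers. Includes a
        synthetic cohort generator with planted group structure for
        end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, graphics, utils, tools, igraph, ape, cluster, yaml,
        jsonlite
Suggests: testthat (>= 3.0.0), mclust, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
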