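Package: meapheno
Title: Electrophysiological Phenotyping of Brain Organoid Multielectrode Array Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of multielectrode array (MEA) recordings from
    neuronal cultures and brain organoids: active-electrode classification,
    two-step mean firing rate and amplitude statistics, single-channel and
    network burst detection, stimulation-evoked short-term depression and
    potentiation classification, spike-time cross-correlation connectivity
    graphs with surrogate-calibrated thresholds and binned temporal dynamics,
    and a multivariate electrophysiological phenotype (18 features) embedded by
    principal component analysis with PERMANOVA, Kruskal-Wallis plus Dunn, and
    Fisher group statistics. Includes a hierarchical synthetic MEA recording
    generator with ground truth for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
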