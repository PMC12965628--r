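Package: iscn
Title: Intra-Individual Structural Covariance Networks from Brain Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds intra-individual structural covariance networks (ISCN)
    from regional brain morphometry (Desikan-Killiany cortical thickness and
    subcortical volumes), using a healthy-control normative model with age,
    sex and intracranial-volume correction, a z-score deviation-similarity
    kernel, density thresholding, and a binary graph-metric engine (degree,
    efficiency, betweenness, clustering, modularity, small-world indices
    against degree-preserving random references) summarised as area under
    the metric-versus-density curve. Group inference uses covariate-adjusted
    (Freedman-Lane) permutation tests with false-discovery-rate correction,
    paired sign-flip tests for longitudinal change, and covariate-adjusted
    partial correlation with clinical outcome. Includes a synthetic-cohort
    generator emulating a patient/control morphometry study, readers for
    FreeSurfer-style aparc/aseg stats tables and flat delimited tables, and
    a config-driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
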