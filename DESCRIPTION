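Package: nucleimerge
Title: Ensemble Merging of Nuclei Segmentations from Multiple Deep-Learning Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates per-slide nuclei predictions produced by two deep-learning
    segmentation models with different cell-type vocabularies (e.g. HoVer-Net
    instances trained on MoNuSAC and PanNuke) into a single set of nuclei with
    harmonized cell types. Matching is by nearest-neighbor search on nucleus
    centroids (exact k-d tree by default, or an Annoy-style random-projection
    forest) under a Euclidean distance threshold; overlapping same-type nuclei
    are merged, conflicting types are resolved by prediction probability with
    high-confidence disagreements reported as equivocal, and non-overlapping
    nuclei from either model are retained. Provides per-category cell counts
    and proportions, merge and equivocal CSV reports, Lin's concordance
    correlation coefficient and two-sample t-tests for validating proportion
    estimates, a tree-structured cell-type schema harmonizing model
    vocabularies, and a synthetic paired-prediction generator so the whole
    pipeline is testable without slide data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
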