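Package: symbioscope
Title: Robustness Analysis of Host-Microbiome Metabolic Complementarity
    Predictions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Stoichiometry-free analysis of draft genome-scale metabolic
    networks and their downstream host-microbiome predictions.  Implements
    network expansion (scope) from a culture medium, selection and full
    enumeration of minimum-cardinality symbiont communities that make a set
    of host metabolites producible, indirect network-quality metrics
    (dead-end and orphan metabolites, largest strongly connected component
    after currency-metabolite removal), and the cross-pipeline comparison
    statistics used to assess how annotation pipelines affect these
    predictions (presence/absence Bray-Curtis, nonmetric multidimensional
    scaling, ANOSIM, exclusive-intersection counts, EC-category
    over-representation).  A synthetic-data generator emulates several
    annotation pipelines observing the same bacterial strains so the whole
    analysis can be exercised and validated without external genome data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
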