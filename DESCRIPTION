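Package: stemsig
Title: Stage-Specific Gene Signatures of Totipotency and Pluripotency
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives stage-specific gene signatures (totipotency, in-vivo
    pluripotency, in-vitro pluripotency) from three-group expression data.
    Implements seed-list interaction-network expansion into an
    undifferentiation network signature (UNS), empirical-Bayes moderated
    t-tests for three pairwise group contrasts, pattern-based assignment of
    genes to seven expression clusters, signature subnetwork statistics, and
    hypergeometric GO-slim enrichment with a comparison battery. Includes a
    synthetic-data generator that emulates the blastomere/ICM/hESC study
    design with planted differential expression, planted network connectors
    and planted term enrichment, so that every stage of the pipeline can be
    exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    limma,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
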