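Package: opticlustr
Title: Metric-Optimized De Novo OTU Clustering of Amplicon Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Assigns amplicon sequences to operational taxonomic units (OTUs)
    by iteratively moving sequences between clusters so as to optimize a
    clustering-quality metric -- by default the Matthews correlation
    coefficient computed over all pairs of sequences, where a pair whose
    genetic distance is at or below a cutoff (e.g. 0.03) "should" be
    co-clustered. Includes readers and writers for column and PHYLIP distance
    files and mothur-style list files, a pairwise confusion-matrix evaluation
    framework with a registry of optimization metrics, a taxonomy-based
    cluster-splitting heuristic, generators for planted-partition benchmark
    fixtures, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
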