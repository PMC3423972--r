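Package: chemoconsensus
Title: Consensus Clustering of Chemogenomic Profiles for Compound Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes candidate drug-repositioning compounds by consensus
    hierarchical clustering of compound-by-gene chemogenomic fitness-defect
    p-value profiles against a signature compound. Implements seven profile
    similarity measures (centered, uncentered and absolute correlations,
    Spearman rank correlation, Euclidean and city-block distances) with
    pairwise-complete missing-value handling, four agglomerative linkages
    (single, complete, average, centroid-in-profile-space), Cluster 3.0
    compatible CDT/GTR tree output viewable in Java TreeView, co-clustering
    frequency ranking across measure-by-linkage trials, a synthetic screen
    generator with a planted compound module for end-to-end validation, and
    the downstream quantification statistics used in angiogenesis phenotyping
    (two-sided Fisher exact test on 2x2 phenotype tables, caliper tumor
    volume, scratch-wound closure ratio, dose equivalence conversion, and
    thresholded vessel staining area).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
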