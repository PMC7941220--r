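Package: gwnet
Title: Gray- and White-Matter Resting-State Functional Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-level resting-state functional-connectivity analysis of
    gray-matter and white-matter BOLD signal: nuisance cleaning (detrending,
    band-pass filtering, 24-parameter motion regression, framewise-displacement
    spike regression, tissue-restricted smoothing), group tissue masks with
    deep-nuclei relabeling, checkerboard-subsampled voxel-by-node correlation
    matrices with subject-pairwise tissue masking, correlation-distance K-means
    parcellation with fold-based Dice stability selection of the number of
    networks, network-level Fisher-z statistics with Bonferroni correction,
    behavioral partial correlation, and detection of gray-white network loops
    in the significant-difference edge graph. Includes a synthetic BOLD
    phantom generator with planted network structure so the full pipeline can
    be exercised and validated without subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    Matrix,
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
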