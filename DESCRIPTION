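Package: rohscan
Title: Runs of Homozygosity Detection, Classification, Inbreeding and
    Hotspot Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of runs of homozygosity (ROH) from diploid SNP
    genotype panels, Gaussian-mixture classification of ROH lengths into
    short/medium/long classes, genomic inbreeding coefficients (F_ROH,
    F_HOM, F_GRM, F_UNI) and heterozygosity, ROH-based binary
    presence/absence matrices with principal component analysis, and
    permutation-based identification of ROH hotspots with family-wise
    error rate control via a max-statistic null. Includes windowed
    summarization of selection-scan statistics (|iHS| proportions, CLR
    maxima, nucleotide diversity) and hotspot-by-selection overlap
    accounting, plus a synthetic genotype-panel simulator with planted
    autozygous tracts and ground-truth tables for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
LinkingTo:
    Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
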