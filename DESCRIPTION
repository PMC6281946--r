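Package: whalesong
Title: Quantitative Comparison of Humpback Whale Song Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying similarity between symbolically
    transcribed humpback whale songs. Song cycles are treated as strings of
    theme labels (and phrases as strings of unit labels) and compared with a
    weighted or unweighted Levenshtein distance similarity index and with
    Dice's presence/absence similarity index. Singer-by-singer similarity
    matrices are clustered by average linkage (UPGMA) with multiscale
    (approximately unbiased) and ordinary bootstrap support and validated by
    the cophenetic correlation coefficient. Unit-level acoustic measurements
    drive substitution costs for the weighted analysis and a classification
    tree check of manual unit labelling. A generative simulator of
    two-population song culture (theme birth, death and evolution with
    inter-population transmission coupling) provides ground-truthed corpora,
    and packaged fixtures transcribe published median song sequences from
    Gabon and Madagascar, 2001-2005.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    ape,
    rpart,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
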