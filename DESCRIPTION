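Package: nightsong
Title: Accelerometer-Based Detection of Song Behavior in Nocturnal Birds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised identification of song behavior in free-living birds
    from single-axis accelerometer data. Decomposes raw 25 Hz acceleration into
    static and dynamic components by running-mean subtraction, segments the
    dynamic signal with a univariate Gaussian hidden Markov model (seeded random
    initialization, Baum-Welch expectation maximization with scaling, Viterbi
    decoding, BIC model comparison over 4-7 states), maps decoded states to an
    ethogram (rest, sing, fly, leap), extracts song bouts on a 1-s grid with a
    10-s minimum-duration rule, and validates classified bouts against
    audio-recorder annotations gated by GPS distance to the recorders (confusion
    counts by distance class, Spearman rank correlation, Wilcoxon signed-rank and
    paired t statistics on bout durations). A seeded synthetic-night generator
    (behavior script, acceleration trace, GPS track, audio ground truth) makes
    the whole pipeline testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
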