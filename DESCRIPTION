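Package: eggarrange
Title: Egg Arrangement Quantification and Simulated Brood Parasitism
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the arrangement of eggs in a nest cup from annotated
    clutch photographs using four geometric metrics (blunt pole distance,
    blunt pole angle, blunt pole orientation, adjacent angles) with correct
    circular and axial statistics, and scores before/after clutch change with
    a distance-transform dissimilarity between binary silhouette masks.
    Includes a synthetic clutch generator that emulates a three-treatment
    experimental parasitism design (control, constant, rearranged) on
    blackbird-sized clutches, simulates behavioral outcomes (desertion,
    ejection, latency), and runs the matching statistical stage: Fisher's
    exact test with Monte Carlo p-values, binomial and negative binomial
    generalized linear models, variance inflation factors, and backward
    elimination that always retains the treatment term.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    EBImage,
    png,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
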