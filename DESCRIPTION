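Package: cooccurbind
Title: Resampling Tests for Binding-Site Co-Occurrence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical significance of the co-occurrence of genomic
    binding sites between pairs of DNA-associated factors, as measured by
    ChIP-chip, DamID and similar genome-wide assays.  Binding profiles are
    read from BED-style interval files and reduced to a co-occurrence
    matrix of pairwise location scores; the co-occurrence statistic is the
    sum of scores over all cross-factor location pairs.  Four resampling
    null distributions are provided (whole-pool permutation, independent
    redrawing of each profile, a hybrid scheme that permutes overlapped
    locations while redrawing singletons freely, and a multi-factor pooled
    permutation), together with closed-form results for a simple paired
    model (hypergeometric assignment and pairing probabilities, and the
    limiting singleton distribution of the hybrid statistic).  An
    all-pairs screening driver with a survey-then-full runtime
    optimisation and tabular reporting is included.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
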