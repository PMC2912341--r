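Package: domaudit
Title: Auditing Protein Domain Models for Transmembrane and Signal
    Peptide Contamination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical detection of transmembrane-helix (TM) and
    signal-peptide (SP) regions inside protein domain seed alignments by
    consensus over multiple per-residue predictors (exact binomial column
    tests, per-column log probabilities, calibrated segment-score
    cutoffs), and decomposition of profile-HMM Viterbi hit scores into
    SP/TM-specific and non-SP/TM-specific parts so that domain
    annotations carried over the gathering threshold solely by a
    hydrophobic SP/TM match can be flagged as unjustified and false
    negatives recovered.  Includes writers for cleaned ("cleanup")
    alignments with SP/TM columns removed, cutoff calibration against
    labelled score sets, a minimal plan7-style profile-HMM engine with
    Gumbel E-values, and deterministic synthetic-fixture generators for
    alignments, predictor masks and toy profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
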