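Package: ctgtools
Title: Cardiotocography Analysis and Interpretable Fetal Acidosis Risk Scoring
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of intrapartum cardiotocography (CTG) recordings sampled
    at 4 Hz: gap interpolation and selection of the latest clean 30-minute
    segment, estimation of the fetal heart rate baseline with a
    stability-weighted median filter (per-sample probability of signal
    stability from a band-filtered logistic model), detection of
    accelerations, decelerations and uterine contractions, extraction of a
    25-feature vector (baseline statistics, event morphology, short- and
    long-term variability, joint deceleration-contraction measures), and a
    class-balanced logistic model of fetal acidosis (umbilical pH below a
    cutoff) whose per-feature contributions are reported alongside the
    predicted risk. Includes a ground-truth CTG simulator for calibration and
    validation, readers for CSV and WFDB records, and a command-line
    front-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
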