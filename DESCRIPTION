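Package: speechmarkers
Title: Speech Markers of Mood Symptom Severity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extraction of acoustic voice-quality indices (fundamental
    frequency, jitter, shimmer, harmonics-to-noise ratio), conversational
    timing indices (phonation, silence, latency, speech rate), and
    NLP/semantic scores (word counts, story match, word mover's distance)
    from mono speech recordings and word-timestamped transcripts, followed
    by correlation analysis against clinician-rated symptom scales
    (MADRS/YMRS) and random-forest severity regression under nested
    cross-validation with Shapley feature attribution. Includes a
    synthetic-data module (glottal pulse trains with controlled
    perturbation, sessions with planned pause structure, cohorts with
    configured feature-symptom effect sizes) so that the whole pipeline is
    testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    ranger,
    ggplot2,
    tibble,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
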