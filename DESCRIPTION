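Package: speechmarkers
Title: Speech Phenotyping from Diarized Clinical Interview Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Computes speech characteristics of structured psychiatric
    interviews from diarized, word-timestamped transcripts and estimates
    their association with positive and negative symptom severity.
    Identifies the participant speaker by comparing each speaker's turns
    against expected clinician prompts, assembles turns, and derives
    twelve features spanning amount of speech, rate of speech, pause
    timing, and lexicon-based emotional sentiment. The statistical layer
    fits linear mixed-effects models with crossed subject and visit
    random intercepts, reports partial eta-squared effect sizes with
    Benjamini-Hochberg false-discovery-rate control, and includes
    demographic screens and a baseline-averaged ordinary-least-squares
    sensitivity analysis. A seeded synthetic cohort generator produces
    mock two-speaker interviews whose word timings realize target
    feature values linked to latent severity, so the full pipeline is
    testable without access to protected recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    lmerTest,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
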