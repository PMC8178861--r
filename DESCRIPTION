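Package: speechmarker
Title: Speech and Language Markers of Cognitive Impairment from Picture Descriptions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies clinically rated speech and language change in mild
    cognitive impairment and dementia from timed picture-description
    transcripts and audio. Extracts lexical, syntactic, semantic and acoustic
    variables (pauses, speech rate, word duration, framewise zero-crossing and
    mel-frequency cepstral statistics, psycholinguistic norm scores, utterance
    repetitiveness, picture similarity, speech-graph topology), builds modal
    consensus ratings from multi-rater ordinal panels with two-way random
    intraclass correlations, screens features against consensus ratings by
    Spearman correlation, computes between-group odds ratios of impairment,
    and summarises selected variables by exploratory factor analysis with
    principal-axis extraction, Horn's parallel analysis and direct-oblimin
    rotation. A synthetic cohort generator produces severity-linked
    transcripts, waveforms and rater panels so the whole pipeline is testable
    without access to gated clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    igraph,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
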