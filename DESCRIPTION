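Package: statebound
Title: Neural State Boundary Detection and Alignment in Electrophysiological Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-driven segmentation of multichannel intracranial (ECoG)
    recordings into neural states using greedy state boundary search with
    t-distance model selection and cross-block stabilization of the state
    count; a Gaussian-weighted boundary-alignment statistic between binary
    boundary timelines with delay scanning and a state-shuffle permutation
    null; nonparametric group-level tests for stimulus alignment and for
    top-down versus bottom-up propagation of boundaries between regions of
    interest; a deterministic ECoG preprocessing chain; and a ground-truthed
    synthetic-cohort generator so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
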