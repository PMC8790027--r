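Package: carryforward
Title: Carry-Forward-Effect Analysis of Multimodal Educational Game Sessions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for motion-based educational game sessions
    instrumented with eye-tracking glasses, a wristband (electrodermal
    activity and heart rate) and a skeletal motion sensor. Segments each
    question-answering interaction into See-Solve, Move and Respond phases,
    computes gaze- and physiology-derived measurements in overlapping
    windows, and classifies each measurement's Carry Forward Effect
    (Perfect, Pseudo or None) both by repeated-measures inferential
    statistics and by feature-importance ranks from a weighted
    seven-member predictive ensemble evaluated leave-one-participant-out.
    Includes a synthetic multimodal session generator with plantable
    per-phase effect sizes, readers and writers for the on-disk session
    formats, and a feedback-prioritization step that turns classified
    effects into an ordered intervention plan.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    zoo,
    lmtest,
    e1071,
    kernlab,
    rpart
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
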