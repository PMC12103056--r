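Package: capsim
Title: Simulated Central Auditory Processing and Cognitive Test Battery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Closed-loop simulation of a central auditory processing and
    cognitive test battery for studies of mild cognitive impairment in
    older adults. Synthesizes the temporal-processing stimuli (interaural
    phase, frequency modulation, gap-in-noise, amplitude modulation),
    runs transformed up-down adaptive staircases against psychometric
    virtual listeners, scores dichotic digit, speech-in-noise, attention
    network, mental rotation and digit span tests from symbolic trial
    records, generates calibrated two-group synthetic cohorts, and runs
    the full statistical stage: Mann-Whitney group comparisons with Holm
    correction, minimum-residual factor analysis with oblimin rotation
    (KMO, Bartlett), hierarchical regression, ROC discriminability, and
    noncentral-t power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
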