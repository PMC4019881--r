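Package: seqBOLD
Title: Information-Theoretic Modeling of Action Sequences and Model-Based
    fMRI Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying statistical learning of observed action
    sequences with model-based fMRI. Generates Markov-structured action-step
    corpora under balancing constraints, annotates event streams with an
    ideal Bayesian observer's conditional surprisal and specific conditional
    entropy, builds parametric-modulation GLM design matrices with gamma HRF
    convolution and temporal precoloring, simulates multi-participant BOLD
    volumes with known injected effects, performs first- and second-level
    inference with Monte Carlo cluster-level multiple-comparison correction,
    and provides region-of-interest extraction together with behavioral
    post-test aggregation and familiarity scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
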