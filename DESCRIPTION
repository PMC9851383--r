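Package: cryptsched
Title: Colon-Crypt Cell Dynamics and Chemotherapy Dose-Schedule Optimization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An agent-based simulator of cell dynamics in human colon
    crypts (quiescent stem niche, positional divide and die gradients,
    drug-sensitive and multidrug-resistant cancer phenotypes) together
    with tooling to optimize intermittent chemotherapy dose schedules.
    Supports simulated clinical trials (mutation, therapy trigger,
    replicate aggregation), exhaustive enumeration of
    duration/interval/intensity dose-schedule grids, multi-objective
    filtering of curative, nontoxic and clinically practical schedules,
    and an active-learning loop that trains a neural-network toxicity
    surrogate by uncertainty sampling to explore combination-schedule
    spaces too large for brute force.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
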