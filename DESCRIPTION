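Package: hrlsim
Title: Homeostatic Reinforcement Learning Simulation of Nutritional
    Decision-Making
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator for homeostatic reinforcement learning, in which the
    reward of an action is the reduction it causes in a drive defined as the
    distance between an internal nutrient state and its setpoint. Provides a
    tabular Q-learning agent with a softmax policy and a learned intake
    prediction, an interoceptive gain modulating the perceived deviation from
    the setpoint, two decision tasks (intake after food restriction, and a
    mountain-climbing task trading small immediate intakes against a large
    delayed summit reward), condition-level replicate experiments with seed
    management, and the variance-gated t-test / rank-sum comparison protocol
    used to contrast conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    car,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
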