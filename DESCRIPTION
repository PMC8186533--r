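Package: touchkin
Title: Kinematic Analysis and Neural-Network Classification of Tablet Dragging Movements
Version: 0.1.0
Authors@R:
    person("Touchkin", "Developers", email = "touchkin@example.org", role = c("aut", "cre"))
Description: Tools for studying motor signatures in touchscreen dragging
    movements. Generates synthetic two-group touch-stream cohorts with
    planted kinematic contrasts, segments raw touch logs into finite
    press-to-release trajectories, extracts twelve kinematic features per
    task (speed, acceleration, straightness, directional change, bout
    length), assembles seventeen-variable samples with task indicators,
    trains a small feedforward network (tanh hidden layer, softmax output,
    Adam optimizer) under repeated k-fold cross-validation, and ranks
    feature importance by greedy backward input ablation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
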