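Package: clvns
Title: Closed-Loop Vagus Nerve Stimulation Trigger Policies and Virtual
    Rehabilitation Sessions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for closed-loop vagus nerve stimulation (CLV) paired with an
    automated isometric pull task: trial detection on sampled force traces,
    adaptively scaled reward and stimulation thresholds built from order
    statistics of the trailing ten trials, the four trigger policies (Top 20%,
    Delayed Top 20%, Bottom 20%, Top 50%) plus a rehabilitation-only control,
    and the biphasic stimulation-train scheduler. A seeded virtual-rat
    simulator with an exponential synaptic-eligibility-trace plasticity kernel
    generates pull-attempt streams across a training / injury / rehabilitation
    timeline so the closed loop can be exercised end to end without hardware.
    Includes behavioral outcome analytics (weekly peak force, stimulation-to-
    success timing, percent benefit, proficiency), quantification arithmetic
    for intracortical microstimulation maps, transsynaptic tracer counts and
    lesion sparing, and grid-search recovery of simulator parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
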