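Package: tsforce
Title: Triceps Surae Force Sharing Under Achilles Tendon Compliance and
    Subtendon Twist
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation pipeline for estimating soleus and gastrocnemius
    (medialis, lateralis) muscle forces and their percentage contributions
    to total triceps surae force during heel-drop, heel-rise and walking
    trials. Implements Hill-type muscle-tendon units with an elastic tendon
    parameterized by a normalized stiffness, tendon-excursion moment arms
    over configurable Achilles subtendon insertion geometries (no/low/
    medium/high twist, with enlargement scaling), a deterministic
    squared-activation muscle redundancy solver, synthetic exercise trial
    generation, and force-sharing analyses across grids of tendon
    compliance and twist models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
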