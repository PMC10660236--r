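Package: weeklycoach
Title: Tailored Weekly Coaching Messages for Digital Weight-Loss Interventions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rule-based engine for just-in-time adaptive coaching in
    behavioral weight-loss programs. Aggregates daily self-monitoring data
    (weight, dietary logging, activity-tracker minutes, app use) into weekly
    tailoring variables, selects message components from externalized,
    criteria-tagged message banks under anti-habituation constraints
    (no consecutive theme, no consecutive behavioral domain, no repeated
    message at the same criteria signature until alternatives are exhausted),
    and renders the weekly coaching message with a machine-readable audit
    trail. Includes a synthetic-cohort simulator so the full pipeline runs
    and is testable without participant data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
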