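Package: ctqsim
Title: Discrete-Event Simulation of CT Examination Queueing Policies
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discrete-event simulator for a single-server CT examination
    queue serving three patient classes (general, urgent, emergency).
    Implements and compares three queue disciplines: severity-ordered class
    priority, fixed-interval wedging of urgent patients among general
    patients, and a dynamic aging priority in which a patient's priority
    value equals its class waiting-time threshold divided by its current
    wait.  Includes a nonhomogeneous-Poisson arrival-stream generator with
    a calibration routine that matches a target congestion level, terminating
    daily replications with Student-t confidence intervals, common-random-number
    policy comparisons, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
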