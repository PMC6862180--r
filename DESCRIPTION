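Package: emsopt
Title: Discrete-Event Simulation and Robust Parameter Design for Emergency
    Department Crowding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An emergency-medicine-service (EMS) simulation-optimization
    pipeline for studying emergency department crowding. A discrete-event
    simulator of internal-medicine ED patient flow (Poisson arrivals, five
    TTAS triage levels, registration, physician exam, checkup rooms, bed
    admission) generates system time and EDWIN-C crowding responses under a
    dynamic Taguchi design (signal = physicians on duty, noise = arrival
    rate, L9 inner array of four control-factor policies). Responses are
    mapped to desirabilities, a small feed-forward neural network learns the
    factor-to-desirability surface, a genetic algorithm maximizes the total
    performance TP = d1 * d2^2 over the mixed factor space, and a
    one-factor-at-a-time sensitivity stage produces adjusted-TP% tables.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
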