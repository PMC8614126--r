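Package: seamsim
Title: Simulation of Two-Stage Adaptive Seamless Designs with Treatment or
    Subgroup Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plans and evaluates two-stage adaptive seamless (phase II/III)
    clinical trial designs in which an interim analysis on an early outcome
    selects treatment arms (multi-arm comparisons with a common control) or
    patient populations (a pre-defined subgroup nested in the full
    population, i.e. adaptive enrichment). Final confirmatory testing uses
    inverse-normal or Fisher combination tests embedded in a closed testing
    procedure with Dunnett, Simes, Bonferroni or Spiessens-Debois
    intersection tests, giving strong familywise error control under any
    data-driven selection. Trials are simulated at the level of multivariate
    normal summary statistics (normal, binary and time-to-event outcomes),
    so Monte Carlo evaluation of operating characteristics is fast and
    independent of patient numbers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
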