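Package: pumpleak
Title: Pump-Leak Modelling of Cell Ion and Water Homeostasis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-cell electrochemical modelling of monovalent ion and water
    homeostasis in animal cells. Combines Goldman-Hodgkin-Katz channel fluxes,
    a 3:2 Na/K pump, and the electroneutral cation-chloride cotransporters
    NC, KC and NKCC under the constraints of macroscopic electroneutrality and
    osmotic balance, with the membrane potential closed at every instant by the
    zero-net-charge-flux condition. Provides a balanced-state fitting function
    that recovers channel permeabilities and impermeant-osmolyte properties
    from resting measurements, a compiled trajectory integrator for timed
    protocols of medium changes and parameter multipliers, unidirectional and
    net flux decompositions per transport pathway, and a preset scenario
    library reproducing regulatory volume increase (RVI) and apoptotic volume
    decrease (AVD) responses of lymphoid cells in hyperosmolar NaCl and sucrose
    media.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
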