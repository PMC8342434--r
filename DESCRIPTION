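Package: scsolub
Title: Solid Solubility in Supercritical Fluids via Cubic Equations of State
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Thermodynamic modeling of solid solute solubility in supercritical
    carbon dioxide with two-parameter cubic equations of state
    (Soave-Redlich-Kwong, Peng-Robinson, Stryjek-Vera, and a
    perturbation-theory family) combined with one- and two-parameter van der
    Waals mixing rules. Provides fugacity-coefficient computation for
    mixtures, the solid-fluid equilibrium solubility fixed point with its
    enhancement factor, sublimation-pressure estimation (Clapeyron and
    extended-Antoine correlations), Joback/Lee-Kesler property estimation for
    solutes lacking measured critical constants, per-isotherm regression of
    binary interaction parameters against experimental data by minimizing the
    average absolute relative deviation, temperature trends of the fitted
    parameters, and a synthetic-data generator for validating the full
    pipeline. Ships a 27-point experimental dataset for the retinol
    (vitamin A)/supercritical CO2 binary system over 303-323 K and 90-245 bar.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lhs,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
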