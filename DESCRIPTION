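Package: helistent
Title: Mechanics-Based Design of Helical Airway Stents
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Equilibrium mechanics of a helical wire stent under uniform
    external pressure, for designing airway stents that support a malacic
    (collapsible) trachea. Models the stent as a linearly elastic Kirchhoff
    rod constrained to remain helical: given the unloaded helix diameter,
    pitch and wire diameter, the package computes the energy-minimizing
    deformed pitch (closed-form quartic stationarity condition), the radial
    contact line force from the Cosserat rod equilibrium, and the supported
    external pressure, and inverts the pressure-diameter relation by
    safeguarded Newton iteration. On top of the single-stent model it runs
    the design-space sweep over wire diameter and helix angle and solves the
    two pitch-window criteria (maximum pitch for a target cross-sectional
    area reduction, minimum pitch for wire-diameter insensitivity) used to
    size tracheal stents against positive-pressure-ventilation-equivalent
    loads. Includes a command-line interface, CSV/JSON serializers and a
    seeded fixture generator for property testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
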