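Package: ascorbox
Title: Aqueous Kinetics of Ascorbate Oxidation by Iron, Copper and
    Reactive Oxygen Species
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Box-model chemical kinetics of ascorbic acid oxidation in
    aqueous solution. Encodes a 95-reaction mechanism covering ascorbate
    acid-base chemistry, hydroxyl/hydroperoxyl/superoxide radical
    reactions, Fenton chemistry and the speciation of iron and copper,
    together with the catalytic metal-ascorbate-oxygen rate laws and
    their redox and fractional-order alternatives.  Provides a stiff
    mass-action integrator with per-reaction flux accounting, a
    simulator of a two-coil online dehydroascorbic acid (DHA) assay,
    grid and coordinate-search rate-constant estimation against DHA
    dose-response data, closed-form rate-constant conversion utilities,
    hydroxyl-radical production scenarios, and a synthetic-data
    generator for noisy DHA dose-response curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
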