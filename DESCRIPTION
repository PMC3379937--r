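Package: esadose
Title: Effective Surface Area Dosimetry for Agglomerating Carbon Nanomaterials
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Closed-form geometric models of the biologically accessible
    ("effective") surface area of agglomerated carbon nanomaterials:
    hexagonally packed single-walled carbon nanotube (SWCNT) bundles and
    concentric-graphene-layer carbon nanofibers (CNF). Converts material
    characterization (mass dose, BET specific surface area, geometric
    effective surface area, structure counts) into per-animal doses under
    competing dose metrics, and evaluates which metric tracks pulmonary
    toxicity outcomes using small-sample Pearson correlation with an
    explicit degrees-of-freedom convention. Ships a synthetic generator
    for geometry samples and dose-response outcome panels, and a packaged
    three-material reference dataset (SWCNT, CNF, crocidolite asbestos).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
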