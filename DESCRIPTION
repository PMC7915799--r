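Package: sinudens
Title: Densitometric and Discriminant Analysis of Maxillary Sinus CT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for automated preliminary diagnosis of odontogenic
    (dental-origin) maxillary sinusitis from computed-tomography volumes.
    Generates synthetic sinus phantoms with known ground truth, applies
    median filtering and Hounsfield-unit display windowing, constructs
    brightness profiles (densitograms) along radial trajectories from the
    sinus centre and classifies their signatures into typical pathology
    patterns, computes five diagnostic indicators (fluid density, ostium
    patency, mucosa and fluid volume fractions, aerodynamic nasal drag),
    models nasal airflow resistance through sectioned duct geometry, and
    implements a normalized-Euclidean discriminant model with closed-form
    decision-error probabilities and nearest-cluster patient classification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
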