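Package: harlequin
Title: Activator-Inhibitor Simulation of Harlequin Phalaenopsis
    Pigmentation Patterning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the PeMYB11-PeMYBx activator-inhibitor
    (Gierer-Meinhardt) reaction-diffusion system that underlies spotted and
    harlequin pigmentation patterning on Phalaenopsis flowers. Provides a
    spectral semi-implicit (IMEX) solver on a periodic 2-D grid with an
    explicit-Euler reference scheme, linear (Turing) stability analysis,
    named scenario presets for the documented genetic perturbations
    (solo-LTR HORT1 insertion raising the self-activation potency, reduced
    miR858 lowering activator degradation, and spatially heterogeneous
    piece-wise self-activation fields), seeded synthetic initial conditions
    and binary masks, and quantitative pattern metrics: spot labelling on a
    periodic domain, area fraction, fusion index, activator-inhibitor
    correlation, and radial decay of spots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
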