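Package: gelscope
Title: Image-Analysis Microrheology of Gelation: PIV, Differential
    Variance Analysis and Differential Dynamic Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies gelation kinetics from time-lapse microscopy of
    micron-sized tracer particles (such as fat globules in acidifying
    milk).  Implements particle image velocimetry (block-matching
    displacement fields and normalized mobility curves), differential
    variance analysis (dynamic order parameter and stretched-exponential
    relaxation times), differential dynamic microscopy (image structure
    function, intermediate scattering function and mean-square
    displacement extraction), microscopic-viscosity estimation, and
    loss-tangent rheology utilities (Winter-Chambon gel-point detection
    and aging power laws).  Includes a synthetic-data module that renders
    microscopy movies of Brownian, fractional-Brownian and trapped probes
    and synthesizes rheology traces with known ground truth, so every
    analysis stage is verifiable end to end.
License: GPL (>= 3)
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
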