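Package: fdfibrin
Title: Coupled Flow and Fibrin Accumulation Modeling for Flow-Diverting Stents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates fibrin production, transport, and accumulation on the
    braided wires of flow-diverting devices in idealized vessel and aneurysm
    geometries. Couples a fractional-step incompressible flow solver with a
    Darcy (porosity) clot feedback force to a cell-centered finite-volume
    transport-reaction solver for six plasma species (prothrombin,
    antithrombin, thrombin, fibrinogen, free fibrin, bounded fibrin), using a
    quasi-steady staggered coupling with a residual-budget re-solve criterion.
    Includes tetrahedral mesh generation for tubes, boxes and sidewall
    aneurysms, braided-device construction, immersed-boundary wire handling,
    VTU/VTP/STL input-output, and ready-made scenario configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
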