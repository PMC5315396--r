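Package: aortawall
Title: Coupled Immuno-Mechanical Simulation of Abdominal Aortic Aneurysm Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the formation and growth of abdominal aortic aneurysm
    (AAA) as a coupled biological-mechanical free-boundary problem. A
    twelve-species reaction-advection-diffusion network (macrophages, T
    cells, smooth muscle cells, MCP-1, IL-6, IL-10, IL-12, TNF-alpha,
    IFN-gamma, MMP, TIMP and extracellular matrix) is solved in a two-layer
    arterial wall (media and adventitia) with Robin exchange conditions at
    the blood interface and across the media/adventitia membrane. The wall
    is an incompressible-type hyperelastic solid whose elastic moduli
    degrade with smooth-muscle-cell loss and whose tissue pressure follows
    the extracellular-matrix density; equilibrium is solved by Newton
    iteration on a Lagrangian moving finite-element mesh with surface
    tension on the free boundaries. Given an initial aortic diameter and a
    serum IL-6 level the model predicts the bulge diameter over time. A
    spatially homogeneous two-compartment ODE reduction is included for
    verification and steady-state analysis, together with a command-line
    driver for single runs and (IL-6, diameter) prediction sweeps.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    deSolve,
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
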