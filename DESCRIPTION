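Package: coroflow
Title: Virtual Coronary Stenting and Computed Fractional Flow Reserve
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models a diseased coronary artery as connected circular
    cross-sections along a 3D centerline, deploys idealized virtual stents
    by cubic-spline trajectory smoothing and radius correction, meshes the
    lumen into a triangle-strip surface and a swept tetrahedral volume with
    boundary inflation layers, and computes virtual fractional flow reserve
    (vFFR) under a pressure inlet and a lumped distal-resistance outlet.
    Two flow backends are provided: a reduced-order Poiseuille plus
    Borda-Carnot network model and a steady incompressible finite-volume
    Navier-Stokes solver (SIMPLE) written in C++. Includes tandem-lesion
    strategy enumeration, Bland-Altman agreement and diagnostic-accuracy
    statistics, mesh import/export (VRML97, STL, VTK), and a synthetic
    stenosed-vessel generator for fully reproducible experiments.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
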