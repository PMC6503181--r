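# Shared fixtures: everything is generated in code at test time.

straight_tube <- function(length = 50, radius = 1.5, step = 0.25) {
  make_synthetic_vessel(length, radius, step = step)
}

stenosed_tube <- function(severity = 0.58, length = 50, radius = 1.5,
                          s_center = 25, lesion_length = 20, step = 0.25,
                          curvature = 0) {
  make_synthetic_vessel(length, radius,
    stenoses = list(stenosis_spec(s_center, lesion_length, severity)),
    curvature = curvature, step = step)
}

# closed-form whole-tube vFFR of a uniform tube under defaults
uniform_tube_vffr <- function(radius_mm, length_mm,
                              mu = 3.5e-3, r_distal = 8.721e9) {
  rv <- 8 * mu * (length_mm * 1e-3) / (pi * (radius_mm * 1e-3)^4)
  r_distal / (rv + r_distal)
}

# coarse-but-solvable volume mesh for 3D tests (a few thousand cells)
coarse_mesh <- function(vessel, n_circ = 16, n_layers = 2,
                        target_edge = 0.5, axial_step = 1.5) {
  build_volume_mesh(vessel, n_circ = n_circ, n_layers = n_layers,
                    target_edge = target_edge, axial_step = axial_step)
}
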