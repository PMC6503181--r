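test_that("surface mesh honors the 128-triangles-per-strip contract", {
  v <- make_synthetic_vessel(10, 1.5, step = 1)   # 11 stations
  sm <- build_surface_mesh(v)
  wall <- !is.na(sm$strip)
  expect_equal(sum(wall), 10 * 128)
  expect_equal(as.vector(table(sm$strip[wall])), rep(128L, 10))
})

test_that("a capped cylinder is watertight, oriented, with Euler characteristic 2", {
  v <- make_synthetic_vessel(20, 1.2, step = 2, curvature = 0.01)
  sm <- build_surface_mesh(v, caps = TRUE)
  d <- validate_surface_mesh(sm)
  expect_equal(d$euler_characteristic, 2)
  expect_equal(d$n_boundary_edges, 0)
  expect_gt(d$signed_volume, 0)     # outward orientation
})

test_that("wall area of a straight tube matches the lateral-surface closed form", {
  v <- straight_tube(length = 50, radius = 1.5)
  sm <- build_surface_mesh(v)
  # inscribed 64-gon underestimates by about 1 - cos(pi/64); well within 0.5%
  expect_equal(wall_area(sm), 2 * pi * 1.5 * 50, tolerance = 0.005)
})

test_that("enclosed volume converges to the cylinder closed form as n_circ grows", {
  v <- straight_tube(length = 20, radius = 1.5, step = 2)
  exact <- pi * 1.5^2 * 20
  errs <- vapply(c(8, 16, 32), function(nc) {
    d <- validate_surface_mesh(build_surface_mesh(v, n_circ = nc))
    abs(d$signed_volume - exact) / exact
  }, numeric(1))
  # second-order convergence in the circumferential step
  expect_gt(errs[1] / errs[2], 3)
  expect_gt(errs[2] / errs[3], 3)
})

test_that("too-coarse sampling of a tight bend is rejected with advice", {
  # lumen radius exceeds the centerline bend radius: rings must cross
  v <- make_synthetic_vessel(20, 2.6, curvature = 0.4, step = 0.5)
  expect_error(build_surface_mesh(v), "resample")
})

test_that("volume mesh matches the frustum closed form within 2%", {
  for (v in list(straight_tube(length = 25),
                 stenosed_tube(severity = 0.5, length = 25, s_center = 12,
                               lesion_length = 10),
                 make_synthetic_vessel(25, 1.5, curvature = 0.01))) {
    vm <- build_volume_mesh(v, axial_step = 1.0)
    sec <- resample_vessel(v, 1.0)$sections
    r <- sec$r
    frustum <- sum(pi * diff(sec$s) *
                   (r[-1]^2 + r[-1] * r[-length(r)] + r[-length(r)]^2) / 3)
    expect_equal(mesh_volume(vm), frustum, tolerance = 0.02)
  }
})

test_that("every tetrahedron is positively oriented and boundary faces close the surface", {
  v <- stenosed_tube(severity = 0.4, length = 20, s_center = 10,
                     lesion_length = 8)
  vm <- build_volume_mesh(v, n_circ = 12, axial_step = 2)
  expect_true(all(coroflow:::.signed_vol6(vm$tets, vm$vertices) > 0))
  # each boundary face triple appears exactly once among unmatched tet faces
  tet_faces <- rbind(vm$tets[, c(1, 2, 3)], vm$tets[, c(1, 2, 4)],
                     vm$tets[, c(1, 3, 4)], vm$tets[, c(2, 3, 4)])
  key <- apply(tet_faces, 1, function(x) paste(sort(x), collapse = "-"))
  unmatched <- names(which(table(key) == 1L))
  bkey <- apply(vm$boundary_faces, 1, function(x) paste(sort(x), collapse = "-"))
  expect_setequal(unmatched, bkey)
  expect_equal(length(bkey), length(unique(bkey)))
})

test_that("boundary walls lie on the analytic cylinder; inlet/outlet are planar disks", {
  v <- straight_tube(length = 20, radius = 1.5)
  vm <- build_volume_mesh(v, axial_step = 2)
  wall_v <- unique(as.vector(vm$boundary_faces[vm$boundary_label == "wall", ]))
  rr <- sqrt(vm$vertices[wall_v, 2]^2 + vm$vertices[wall_v, 3]^2)
  t1 <- vm$params$first_layer_frac * 1.5
  expect_lt(max(abs(rr - 1.5)), t1 / 2)
  inlet_v <- unique(as.vector(vm$boundary_faces[vm$boundary_label == "inlet", ]))
  expect_lt(diff(range(vm$vertices[inlet_v, 1])), 1e-9)
  outlet_v <- unique(as.vector(vm$boundary_faces[vm$boundary_label == "outlet", ]))
  expect_equal(unique(round(vm$vertices[outlet_v, 1], 9)), 20)
})

test_that("zero inflation layers give a valid all-core mesh", {
  v <- straight_tube(length = 10)
  vm <- build_volume_mesh(v, n_layers = 0, axial_step = 2)
  expect_true(all(vm$layer == 0L))
  expect_equal(mesh_volume(vm), pi * 1.5^2 * 10, tolerance = 0.02)
})

test_that("volume error decreases at second order under refinement", {
  v <- straight_tube(length = 10, radius = 1.5)
  exact <- pi * 1.5^2 * 10
  errs <- vapply(c(8, 16, 32), function(nc) {
    vm <- build_volume_mesh(v, n_circ = nc, axial_step = 2)
    abs(mesh_volume(vm) - exact) / exact
  }, numeric(1))
  expect_gt(errs[1] / errs[2], 3)
  expect_gt(errs[2] / errs[3], 3)
})

test_that("rotation-minimizing frames stay orthonormal without twisting", {
  v <- make_synthetic_vessel(40, 1.5, curvature = 0.03, step = 0.5)
  sec <- v$sections
  e1 <- rotation_minimizing_frames(as.matrix(sec[, c("x", "y", "z")]),
                                   as.matrix(sec[, c("tx", "ty", "tz")]))
  expect_equal(sqrt(rowSums(e1^2)), rep(1, nrow(e1)), tolerance = 1e-9)
  dt <- rowSums(e1 * as.matrix(sec[, c("tx", "ty", "tz")]))
  expect_lt(max(abs(dt)), 1e-9)
  # successive normals rotate slowly (no flip/twist between stations)
  turn <- rowSums(e1[-1, ] * e1[-nrow(e1), ])
  expect_gt(min(turn), 0.99)
})
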