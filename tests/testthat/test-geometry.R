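test_that("synthetic generator reproduces the stated radius profile", {
  # healthy tube: identity case
  v <- straight_tube()
  expect_equal(v$sections$r, rep(1.5, nrow(v$sections)))
  expect_equal(v$sections$s[1], 0)
  expect_equal(vessel_length(v), 50)

  # one 58% stenosis: throat radius = base * (1 - severity)
  v <- stenosed_tube(severity = 0.58)
  expect_equal(min(v$sections$r), 1.5 * (1 - 0.58), tolerance = 1e-12)
  expect_equal(v$sections$s[which.min(v$sections$r)], 25)

  # radius untouched outside the lesion
  outside <- abs(v$sections$s - 25) > 10
  expect_equal(v$sections$r[outside], rep(1.5, sum(outside)))
})

test_that("two stenoses give exactly two local minima in the profile", {
  v <- make_synthetic_vessel(50, 1.5, stenoses = list(
    stenosis_spec(15, 8, 0.5), stenosis_spec(35, 8, 0.4)))
  r <- v$sections$r
  # brute-force scan for strict interior local minima below base radius
  is_min <- which(diff(sign(diff(r))) > 0) + 1L
  is_min <- is_min[r[is_min] < 1.5 - 1e-9]
  expect_length(is_min, 2L)
  expect_equal(sort(v$sections$s[is_min]), c(15, 35))
})

test_that("generator rejects invalid lesion layouts", {
  expect_error(make_synthetic_vessel(50, 1.5, stenoses = list(
    stenosis_spec(20, 15, 0.5), stenosis_spec(28, 15, 0.4))),
    "overlap")
  expect_error(stenosis_spec(25, 10, 1.0), "occlusion")
  expect_error(stenosis_spec(25, 10, 1.4), "occlusion")
  expect_error(make_synthetic_vessel(50, 1.5,
    stenoses = list(stenosis_spec(48, 10, 0.5))), "beyond")
})

test_that("generator is deterministic for identical arguments and seed", {
  st <- list(stenosis_spec(25, 20, 0.58))
  v1 <- make_synthetic_vessel(50, 1.5, st, curvature = 0.02,
                              seed = 7, noise_sd = 0.02)
  v2 <- make_synthetic_vessel(50, 1.5, st, curvature = 0.02,
                              seed = 7, noise_sd = 0.02)
  expect_identical(v1, v2)
  # and the canonical file output is byte-identical
  f1 <- tempfile(); f2 <- tempfile()
  write_vessel(v1, f1); write_vessel(v2, f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("curvature bends the centerline without touching the radii", {
  v0 <- straight_tube()
  vc <- make_synthetic_vessel(50, 1.5, curvature = 0.02)
  expect_equal(vc$sections$r, v0$sections$r)
  expect_equal(v0$sections$z, rep(0, nrow(v0$sections)))
  expect_gt(max(abs(vc$sections$z)), 1)
  # arc-length parameterization stays consistent with chord lengths
  expect_silent(validate_vessel(vc))
})

test_that("vessel file round trip is exact to text precision", {
  v <- make_synthetic_vessel(10, 1.2, list(stenosis_spec(5, 4, 0.33)),
                             curvature = 0.01, step = 1)
  f <- tempfile(fileext = ".txt")
  write_vessel(v, f)
  v2 <- read_vessel(f)
  expect_equal(v2$sections$s, v$sections$s, tolerance = 1e-9)
  expect_equal(v2$sections$r, v$sections$r, tolerance = 1e-9)
  expect_equal(v2$sections$x, v$sections$x, tolerance = 1e-9)
  unlink(f)
})

test_that("malformed vessel files are rejected with the line number", {
  f <- tempfile()
  # radius 0 on the 7th line (5 sections ok, then bad one)
  lines <- c("# hdr", sprintf("%g %g 0 0 1.5", 0:4, 0:4), "5 5 0 0 0")
  writeLines(lines, f)
  expect_error(read_vessel(f), "line 7")
  # shuffled arc length
  writeLines(c(sprintf("%g %g 0 0 1.5", c(0, 2, 1, 3), c(0, 2, 1, 3))), f)
  expect_error(read_vessel(f), "arc length not increasing")
  # malformed line
  writeLines(c("0 0 0 0 1.5", "1 0 0 banana 1.5"), f)
  expect_error(read_vessel(f), "line 2")
  unlink(f)
})

test_that("resampling preserves profiles and is idempotent", {
  # constant profile: radii unchanged at any step
  v <- straight_tube()
  r1 <- resample_vessel(v, 0.8)
  expect_equal(unique(r1$sections$r), 1.5)

  # linear ramp at half step: midpoints are neighbor means
  s <- seq(0, 10, by = 1)
  vr <- vessel_geometry(s, cbind(s, 0, 0), 1 + 0.05 * s)
  vh <- resample_vessel(vr, 0.5)
  mids <- seq(2, nrow(vh$sections) - 1, by = 2)
  expect_equal(vh$sections$r[mids],
               (vh$sections$r[mids - 1] + vh$sections$r[mids + 1]) / 2)

  # idempotence
  va <- resample_vessel(v, 0.7)
  vb <- resample_vessel(va, 0.7)
  expect_equal(va$sections, vb$sections)

  # total length preserved; step > length rejected
  expect_equal(vessel_length(va), 50)
  expect_error(resample_vessel(v, 60), "step larger")
})

test_that("resampling keeps the extremes of a unimodal stenosis", {
  v <- stenosed_tube(severity = 0.5, step = 0.1)
  vr <- resample_vessel(v, 0.5)
  expect_equal(min(vr$sections$r), min(v$sections$r), tolerance = 0.01)
  expect_equal(max(vr$sections$r), max(v$sections$r))
  # no overshoot: interpolated radii within the original range
  expect_gte(min(vr$sections$r), min(v$sections$r) - 1e-12)
  expect_lte(max(vr$sections$r), max(v$sections$r) + 1e-12)
})

test_that("geometry operations preserve vessel invariants", {
  vs <- list(
    straight_tube(),
    stenosed_tube(0.4, curvature = 0.015),
    resample_vessel(stenosed_tube(0.7), 0.6),
    make_synthetic_vessel(30, 1.0, seed = 3, noise_sd = 0.03)
  )
  for (v in vs) expect_silent(validate_vessel(v))
  expect_error(vessel_geometry(c(0, 1), rbind(c(0, 0, 0), c(0, 0, 0)),
                               c(1, 1)), "coincide")
  expect_error(vessel_geometry(c(0, 1, 2), cbind(0:2, 0, 0), c(1, -1, 1)))
})

test_that("radius_at interpolates and rejects out-of-range queries", {
  v <- stenosed_tube(0.58)
  expect_equal(radius_at(v, 25), 0.63, tolerance = 1e-9)
  expect_equal(radius_at(v, c(0, 50)), c(1.5, 1.5))
  expect_error(radius_at(v, 51), "outside")
})
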