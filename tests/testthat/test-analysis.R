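test_that("Bland-Altman matches hand-computed bias and SD", {
  # identical pairs: perfect agreement
  ba0 <- bland_altman(c(0.7, 0.8, 0.9), c(0.7, 0.8, 0.9))
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$sd, 0)

  # differences {0.02, -0.04, 0.05}: bias 0.01, sd = sd of the differences
  m <- c(0.80, 0.70, 0.90)
  v <- m - c(0.02, -0.04, 0.05)
  ba <- bland_altman(m, v)
  expect_equal(ba$bias, 0.01, tolerance = 1e-12)
  expect_equal(ba$sd, sd(c(0.02, -0.04, 0.05)), tolerance = 1e-12)
  expect_equal(ba$sd, 0.0458, tolerance = 1e-3)
  expect_equal(unname(ba$limits), c(0.01 - 2 * ba$sd, 0.01 + 2 * ba$sd))

  # swapping the roles of the measurements negates the bias exactly
  ba_sw <- bland_altman(v, m)
  expect_equal(ba_sw$bias, -ba$bias)
  expect_equal(ba_sw$sd, ba$sd)
  expect_error(bland_altman(0.8, 0.8), "at least 2")
})

test_that("limits of agreement contain ~95% of large Gaussian samples", {
  set.seed(42)
  n <- 10000
  m <- runif(n, 0.55, 0.95)
  v <- pmin(1, pmax(0.01, m + rnorm(n, -0.02, 0.07)))
  ba <- bland_altman(m, v)
  inside <- mean(ba$data$difference >= ba$limits[1] &
                 ba$data$difference <= ba$limits[2])
  expect_gte(inside, 0.95)
})

test_that("diagnostic accuracy reproduces the derived confusion matrix metrics", {
  # TP=46, FN=4, TN=7, FP=0 against the 0.80 ischemia threshold
  mffr <- c(rep(0.70, 46), rep(0.75, 4), rep(0.90, 7))
  vffr <- c(rep(0.72, 46), rep(0.85, 4), rep(0.88, 7))
  da <- diagnostic_accuracy(mffr, vffr)
  expect_equal(c(da$tp, da$fn, da$tn, da$fp), c(46, 4, 7, 0))
  expect_equal(da$sensitivity, 46 / 50)                  # 92%
  expect_equal(da$specificity, 1)                        # 100%
  expect_equal(da$ppv, 1)                                # 100%
  expect_equal(da$npv, 7 / 11, tolerance = 1e-12)        # 63.6%
  expect_equal(da$accuracy, 53 / 57, tolerance = 1e-12)  # 93.0%
  expect_equal(round(100 * da$accuracy), 93)
})

test_that("the 0.80 boundary value is classified positive and order is irrelevant", {
  da <- diagnostic_accuracy(0.80, 0.80)
  expect_equal(da$tp, 1)
  perm <- sample(57)
  mffr <- c(rep(0.70, 46), rep(0.75, 4), rep(0.90, 7))
  vffr <- c(rep(0.72, 46), rep(0.85, 4), rep(0.88, 7))
  d1 <- diagnostic_accuracy(mffr, vffr)
  d2 <- diagnostic_accuracy(mffr[perm], vffr[perm])
  expect_equal(d1[c("tp", "fp", "tn", "fn")], d2[c("tp", "fp", "tn", "fn")])
  expect_equal(d1$tp + d1$fp + d1$tn + d1$fn, 57)
})

test_that("undefined ratios are flagged, never silently zero", {
  da <- diagnostic_accuracy(c(0.7, 0.75), c(0.7, 0.72))  # all positive
  expect_true(is.na(da$specificity))
  expect_true(is.na(da$npv))
  expect_setequal(da$undefined, c("specificity", "npv"))
  expect_equal(da$accuracy, 1)
  expect_error(diagnostic_accuracy(1.2, 0.8), "\\(0, 1\\]")
})

test_that("correlation is exact on constructed pairs", {
  x <- c(0.6, 0.7, 0.8, 0.9)
  expect_equal(ffr_correlation(x, 0.1 + 0.9 * x)$r, 1)
  expect_equal(ffr_correlation(x, 1 - 0.5 * x)$r, -1)
  # direct formula check on hand-picked pairs
  m <- c(0.62, 0.71, 0.83, 0.95)
  v <- c(0.60, 0.78, 0.80, 0.92)
  r_manual <- sum((m - mean(m)) * (v - mean(v))) /
    sqrt(sum((m - mean(m))^2) * sum((v - mean(v))^2))
  cc <- ffr_correlation(m, v)
  expect_equal(cc$r, r_manual, tolerance = 1e-12)
  expect_equal(cc$slope_through_origin, sum(m * v) / sum(m^2))
  expect_warning(ffr_correlation(c(0.8, 0.8, 0.8), v[1:3]), "variance")
})

test_that("tandem analysis reproduces the serial-lesion ordering", {
  v <- make_synthetic_vessel(60, 1.6, list(
    stenosis_spec(18, 10, 0.62), stenosis_spec(42, 10, 0.55)))
  lesions <- list(stent_spec(12, 24, 3.2), stent_spec(36, 48, 3.2))
  rep_ <- tandem_analysis(v, lesions)
  expect_equal(nrow(rep_), 4)   # baseline + 3 strategies
  vffr <- setNames(rep_$vffr, rep_$strategy)
  expect_lt(vffr["baseline"], min(vffr["stent{1}"], vffr["stent{2}"]))
  expect_gt(vffr["stent{1,2}"], max(vffr["stent{1}"], vffr["stent{2}"]))
  expect_equal(rep_$delta_vs_baseline[1], 0)
  expect_true(all(rep_$delta_vs_baseline >= 0))
})

test_that("single-lesion tandem report equals the manual composition", {
  v <- stenosed_tube(severity = 0.58)
  lesion <- stent_spec(15, 35, 3.0)
  rep_ <- tandem_analysis(v, list(lesion))
  manual_base <- compute_vffr(solve_reduced(v), 0, 50)$vffr
  manual_stented <- compute_vffr(solve_reduced(deploy_stent(v, lesion)), 0, 50)$vffr
  expect_equal(rep_$vffr[rep_$strategy == "baseline"], manual_base)
  expect_equal(rep_$vffr[rep_$strategy == "stent{1}"], manual_stented)
})

test_that("mild separated lesions lose pressure additively (reduced backend)", {
  mk <- function(stens) make_synthetic_vessel(80, 1.5, stens)
  v12 <- mk(list(stenosis_spec(20, 8, 0.25), stenosis_spec(60, 8, 0.2)))
  v1 <- mk(list(stenosis_spec(20, 8, 0.25)))
  v2 <- mk(list(stenosis_spec(60, 8, 0.2)))
  v0 <- mk(list())
  # compare pressure losses at matched flow: use resistances, which add
  r12 <- solve_reduced(v12)$R_vessel
  r1 <- solve_reduced(v1)$R_vessel
  r2 <- solve_reduced(v2)$R_vessel
  r0 <- solve_reduced(v0)$R_vessel
  expect_equal(r12 - r0, (r1 - r0) + (r2 - r0), tolerance = 0.01)
})

test_that("stenting any extra lesion never lowers the distal vFFR", {
  v <- make_synthetic_vessel(70, 1.5, list(
    stenosis_spec(15, 8, 0.5), stenosis_spec(35, 8, 0.45),
    stenosis_spec(55, 8, 0.35)))
  lesions <- list(stent_spec(10, 20, 3.0), stent_spec(30, 40, 3.0),
                  stent_spec(50, 60, 3.0))
  rep_ <- tandem_analysis(v, lesions)
  expect_equal(nrow(rep_), 8)
  # exhaustive: every superset strategy dominates each of its subsets
  subsets <- lapply(strsplit(rep_$lesions, ","), function(x)
    as.integer(x[nzchar(x)]))
  for (i in seq_along(subsets)) for (j in seq_along(subsets)) {
    if (all(subsets[[i]] %in% subsets[[j]])) {
      expect_gte(rep_$vffr[j], rep_$vffr[i] - 1e-10)
    }
  }
})

test_that("tandem analysis rejects overlapping lesions and caps the explosion", {
  v <- straight_tube(length = 60)
  expect_error(tandem_analysis(v, list(stent_spec(10, 30, 3),
                                       stent_spec(25, 40, 3))), "overlap")
  many <- lapply(seq(2, 44, by = 6), function(s) stent_spec(s, s + 4, 3))
  expect_error(tandem_analysis(v, many, max_lesions = 6), "cap")
})
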