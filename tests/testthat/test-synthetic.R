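test_that("the default phantom contains all six classes and is deterministic", {
  ph1 <- make_phantom()
  ph2 <- make_phantom()
  expect_identical(ph1$grid, ph2$grid)
  expect_setequal(unique(as.vector(ph1$grid)), 0:5)
  expect_error(make_phantom(phantom_spec(body_radii = c(15, 15),
                                         sf_thickness = 10,
                                         em_thickness = 10)),
               "nest")
})

test_that("voxel-counted SF ring volume matches the analytic elliptic cylinder", {
  spec <- phantom_spec()        # 1.5 mm in-plane
  ph <- make_phantom(spec)
  v <- compute_class_volumes(ph)
  inner <- spec$body_radii - spec$sf_thickness
  analytic <- pi * (prod(spec$body_radii) - prod(inner)) *
    spec$n_slices * spec$spacing[3] / 1000
  expect_lt(abs(v[["SF"]] - analytic) / analytic, 0.02)
})

test_that("zero VF blobs give zero VF volume", {
  ph <- make_phantom(phantom_spec(vf_blobs = 0))
  expect_identical(compute_class_volumes(ph)[["VF"]], 0)
})

test_that("zero corruption is the identity and gives DSC 1 everywhere", {
  ph <- small_phantom()
  out <- corrupt_segmentation(ph, corruption_spec(seed = 3))
  expect_identical(out$grid, ph$grid)
  m <- classwise_metrics(out, ph)
  expect_true(all(m$dsc == 1))
})

test_that("corruption is reproducible given its seed and differs across seeds", {
  ph <- small_phantom()
  spec <- corruption_spec(displacement_mm = 2, flip_rate = 0.01, seed = 9)
  expect_identical(corrupt_segmentation(ph, spec)$grid,
                   corrupt_segmentation(ph, spec)$grid)
  spec2 <- corruption_spec(displacement_mm = 2, flip_rate = 0.01, seed = 10)
  expect_false(identical(corrupt_segmentation(ph, spec)$grid,
                         corrupt_segmentation(ph, spec2)$grid))
})

test_that("mean DSC decreases monotonically with displacement scale", {
  ph <- small_phantom()
  levels <- c(0, 1, 2, 4)
  mean_dsc <- sapply(levels, function(amp) {
    mean(sapply(1:10, function(s) {
      cc <- corrupt_segmentation(ph, corruption_spec(displacement_mm = amp,
                                                     seed = s))
      attr(classwise_metrics(cc, ph), "weighted_dsc")
    }))
  })
  expect_true(all(diff(mean_dsc) <= 0))
  expect_lt(mean_dsc[4], mean_dsc[1])
})

test_that("pure dilation bias on SF inflates the predicted SF volume", {
  ph <- small_phantom()
  out <- corrupt_segmentation(ph, corruption_spec(bias_mm = c(SF = 1.5),
                                                  seed = 1))
  expect_gt(compute_class_volumes(out)[["SF"]],
            compute_class_volumes(ph)[["SF"]])
  out2 <- corrupt_segmentation(ph, corruption_spec(bias_mm = c(SF = -1.5),
                                                   seed = 1))
  expect_lt(compute_class_volumes(out2)[["SF"]],
            compute_class_volumes(ph)[["SF"]])
})

test_that("a zero within-subject SD cohort has identical baselines and wCV 0", {
  spec <- cohort_spec(n_patients = 10,
                      sigma_w = c(SF = 0, VF = 0, PM = 0, EM = 0), seed = 4)
  tab <- simulate_cohort(spec)
  pairs <- tab[tab$class == "SF" & tab$visit != "day180", ]
  b1 <- pairs$volume_ml[pairs$visit == "baseline1"]
  b2 <- pairs$volume_ml[pairs$visit == "baseline2"]
  expect_equal(b1, b2)
  expect_equal(wcv(b1, b2), 0)
})

test_that("simulated cohorts recover the generating wCV", {
  ests <- sapply(1:20, function(s) {
    tab <- simulate_cohort(cohort_spec(
      n_patients = 500, log_mean = list(SF = c(F = 8, M = 8)),
      log_sd = c(SF = 0.4), sigma_w = c(SF = 0.05), seed = s))
    r <- stratified_repeatability(tab)
    r$wcv_pct[r$class == "SF"]
  })
  # wCV relates to sigma_w by sqrt(exp(s^2)-1) ~ 5.006% here
  expect_lt(abs(mean(ests) - 5.0), 0.5)
  expect_true(all(abs(ests - 5.0) < 0.5))
})

test_that("gender log-mean separation is detectable with high power", {
  rejections <- sapply(1:20, function(s) {
    tab <- simulate_cohort(cohort_spec(
      n_patients = 400, prop_female = 0.5,
      log_mean = list(SF = c(F = 8.5, M = 8.0)),
      log_sd = c(SF = 0.4), sigma_w = c(SF = 0.05), seed = 100 + s))
    res <- compare_group_volumes(tab)
    res$p_value[res$class == "SF"] < 0.05
  })
  expect_gte(mean(rejections), 0.9)
})

test_that("bias observations follow the hierarchical linear construction", {
  # no noise: points lie exactly on the centred line
  spec0 <- bias_sim_spec(alpha = -5, beta = -0.05, sigma_inter = 0,
                         sigma_intra = 0, seed = 2)
  obs0 <- simulate_bias_observations(spec0)
  expect_equal(obs0$delta,
               -5 - 0.05 * (obs0$area - mean(tapply(obs0$area, obs0$slice,
                                                    mean))),
               tolerance = 1e-12)
  # variance of model means approximates sigma_inter^2 at M = 200
  spec <- bias_sim_spec(n_slices = 40, n_models = 200, sigma_inter = 1.5,
                        sigma_intra = 0, beta = 0, seed = 3)
  obs <- simulate_bias_observations(spec)
  mm <- tapply(obs$delta, obs$model, mean)
  expect_lt(abs(stats::var(mm) - 1.5^2), 0.5)
  # reproducibility
  expect_identical(simulate_bias_observations(spec),
                   simulate_bias_observations(spec))
})

test_that("a flat generating slope is rarely declared significant", {
  pvals <- sapply(1:100, function(s) {
    obs <- simulate_bias_observations(bias_sim_spec(
      n_slices = 25, n_models = 5, beta = 0, sigma_inter = 1,
      sigma_intra = 3, seed = s))
    summary(stats::lm(delta ~ area, data = obs))$coefficients["area", 4]
  })
  expect_gte(mean(pvals > 0.05), 0.90)
})
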