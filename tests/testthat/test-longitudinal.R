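test_that("percent change uses the averaged double baseline", {
  expect_equal(percent_change(100, 110, 126), 20)
  expect_equal(percent_change(100, 110, 105), 0)
  expect_equal(percent_change(100, 110, 52.5), -50)
  expect_error(percent_change(100, NA, 120), "present")
  expect_error(percent_change(100, 110, -5), "positive")
})

test_that("classification is strict exceedance with inclusive boundaries", {
  lim <- c(-10.7, 12.0)
  expect_identical(as.character(classify_change(0, lim)), "no_change")
  expect_identical(as.character(classify_change(15, lim)), "increase")
  expect_identical(as.character(classify_change(-15, lim)), "decrease")
  expect_identical(as.character(classify_change(12.0, lim)), "no_change")
  expect_identical(as.character(classify_change(-10.7, lim)), "no_change")
  expect_error(classify_change(0, c(5, 10)), "lower < 0 < upper")
  # monotone in the change
  ch <- sort(runif(50, -60, 60))
  lv <- as.integer(classify_change(ch, lim))
  expect_true(all(diff(lv) >= 0))
})

test_that("cohort percentages reproduce constructed increase fractions", {
  n <- 38
  chg <- c(rep(20, 16), rep(-18, 8), rep(0, 14))   # 16 up, 8 down, 14 flat
  tab <- volume_table(data.frame(
    patient = rep(sprintf("P%02d", 1:n), 3),
    visit = rep(c("baseline1", "baseline2", "day180"), each = n),
    gender = "F", class = "SF",
    volume_ml = c(rep(100, 2 * n), 100 * (1 + chg / 100))))
  res <- cohort_change_analysis(tab, list(SF = c(-10.7, 12.0)))
  expect_equal(res$summary$n, 38)
  expect_equal(res$summary$n_increase, 16)
  expect_equal(res$summary$pct_increase, 42.1)
  expect_equal(res$summary$pct_decrease, 21.1)
  expect_equal(res$summary$pct_increase + res$summary$pct_decrease +
                 res$summary$pct_no_change, 100, tolerance = 0.1)
})

test_that("a uniform +20% cohort is all-increase with a significant paired test", {
  n <- 20
  set.seed(19)
  base <- runif(n, 80, 150)
  tab <- volume_table(data.frame(
    patient = rep(sprintf("P%02d", 1:n), 3),
    visit = rep(c("baseline1", "baseline2", "day180"), each = n),
    gender = "M", class = "SF",
    volume_ml = c(base, base, base * 1.2)))
  res <- cohort_change_analysis(tab, list(SF = c(-10.7, 12.0)))
  expect_equal(res$summary$pct_increase, 100)
  expect_lt(res$summary$t_test_p, 0.05)
  expect_true(all(res$records$classification == "increase"))
})

test_that("the RC construction flags ~5% of pure test-retest pairs", {
  sw <- 0.05
  tab <- simulate_cohort(cohort_spec(
    n_patients = 1000, log_mean = list(SF = c(F = 8, M = 8)),
    log_sd = c(SF = 0.4), sigma_w = c(SF = sw), seed = 23))
  sf <- tab[tab$class == "SF", ]
  b1 <- sf$volume_ml[sf$visit == "baseline1"]
  b2 <- sf$volume_ml[sf$visit == "baseline2"]
  lim <- loa_from_sigma(sw)
  flagged <- classify_change(100 * (b2 / b1 - 1),
                             c(lim$lower, lim$upper)) != "no_change"
  # nominal 5% with binomial 95% CI at n = 1000: ~[3.7%, 6.4%]
  expect_gt(mean(flagged), 0.037)
  expect_lt(mean(flagged), 0.064)
})

test_that("change vs the averaged baseline is conservative under the null", {
  sw <- 0.05
  tab <- simulate_cohort(cohort_spec(
    n_patients = 1000, log_mean = list(SF = c(F = 8, M = 8)),
    log_sd = c(SF = 0.4), sigma_w = c(SF = sw), seed = 24))
  lim <- loa_from_sigma(sw)
  res <- cohort_change_analysis(tab, list(SF = c(lim$lower, lim$upper)))
  frac <- 1 - res$summary$pct_no_change / 100
  # averaging two baselines shrinks the null SD to sqrt(1.5) sigma_w,
  # giving a theoretical rate of 2 * pnorm(-1.96 * sqrt(2) / sqrt(1.5))
  theo <- 2 * stats::pnorm(-1.96 * sqrt(2) / sqrt(1.5))
  expect_lt(frac, 0.064)
  expect_lt(abs(frac - theo), 0.015)
})

test_that("classification recovers large true changes end to end", {
  tab <- simulate_cohort(cohort_spec(
    n_patients = 200, log_mean = list(SF = c(F = 8, M = 8)),
    log_sd = c(SF = 0.4), sigma_w = c(SF = 0.04),
    change_mean = 0.4, change_sd = 0.02, seed = 25))
  r <- stratified_repeatability(tab)
  res <- cohort_change_analysis(tab, r[r$class == "SF",
                                       c("class", "loa_lower_pct",
                                         "loa_upper_pct")])
  expect_gt(res$summary$pct_increase, 99)
})

test_that("group volume comparisons detect separation and respect TF invariance", {
  hits <- sapply(1:20, function(s) {
    tab <- simulate_cohort(cohort_spec(
      n_patients = 200, prop_female = 0.5,
      log_mean = list(SF = c(F = 8.5, M = 8.0)), log_sd = c(SF = 0.4),
      sigma_w = c(SF = 0.05), seed = 300 + s))
    compare_group_volumes(tab)$p_value < 0.05
  })
  expect_gte(mean(hits), 0.95)
  # identical groups are not systematically significant
  null_p <- sapply(1:20, function(s) {
    tab <- simulate_cohort(cohort_spec(
      n_patients = 100, prop_female = 0.5,
      log_mean = list(SF = c(F = 8, M = 8)), log_sd = c(SF = 0.4),
      sigma_w = c(SF = 0.05), seed = 400 + s))
    compare_group_volumes(tab)$p_value
  })
  expect_lte(mean(null_p < 0.05), 0.25)
  expect_gt(mean(null_p), 0.2)
})

test_that("moving volume between SF and VF leaves the TF comparison unchanged", {
  tab <- simulate_cohort(cohort_spec(n_patients = 40, seed = 26))
  shifted <- as.data.frame(tab)
  is_sf <- shifted$class == "SF"; is_vf <- shifted$class == "VF"
  shift_amt <- 50
  shifted$volume_ml[is_sf] <- shifted$volume_ml[is_sf] - shift_amt
  shifted$volume_ml[is_vf] <- shifted$volume_ml[is_vf] + shift_amt
  t1 <- compare_group_volumes(add_derived_volumes(tab))
  t2 <- compare_group_volumes(add_derived_volumes(volume_table(shifted)))
  expect_equal(t1$p_value[t1$class == "TF"], t2$p_value[t2$class == "TF"],
               tolerance = 1e-12)
  expect_true(all(c("TF", "TM") %in% t1$class))
})
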