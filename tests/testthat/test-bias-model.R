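test_that("split Gelman-Rubin flags separated chains and passes mixed ones", {
  set.seed(12)
  mixed <- cbind(rnorm(10000), rnorm(10000), rnorm(10000))
  r <- gelman_rubin(mixed)
  expect_gte(r, 1 - 1e-3)   # the split estimator can dip a hair below 1
  expect_lte(r, 1.01)
  apart <- cbind(rnorm(1000, 0), rnorm(1000, 10))
  expect_gt(gelman_rubin(apart), 1.1)
})

test_that("split Gelman-Rubin matches direct arithmetic on fixed draws", {
  ch <- rep(c(0.9, 1.1, 1.0, 1.0), 5)          # 20 draws
  draws <- cbind(ch, ch + 0.05)
  # oracle: apply the split formula by hand
  segs <- cbind(draws[1:10, 1], draws[11:20, 1],
                draws[1:10, 2], draws[11:20, 2])
  n <- 10
  W <- mean(apply(segs, 2, var))
  B <- n * var(colMeans(segs))
  oracle <- sqrt(((n - 1) / n * W + B / n) / W)
  expect_equal(as.numeric(gelman_rubin(draws)), oracle, tolerance = 1e-12)
  # constant chains are flagged, not numeric garbage
  expect_identical(attr(gelman_rubin(cbind(rep(1, 20), rep(1, 20))), "flag"),
                   "constant")
})

test_that("near-noiseless linear data reproduce the least-squares line", {
  obs <- simulate_bias_observations(bias_sim_spec(
    n_slices = 20, n_models = 4, alpha = -5, beta = -0.05,
    sigma_inter = 0, sigma_intra = 0.05, seed = 13))
  fit <- fit_bias_model(obs, chains = 2, draws = 600, warmup = 400,
                        seed = 13)
  ls <- stats::lm(delta ~ I(area - fit$data$abar), data = obs)
  cf <- coef(fit)
  expect_lt(abs(cf["alpha"] - coef(ls)[1]) / abs(coef(ls)[1]), 0.01)
  expect_lt(abs(cf["beta"] - coef(ls)[2]) / abs(coef(ls)[2]), 0.01)
})

test_that("credible intervals cover the generating parameters at the study design", {
  obs <- simulate_bias_observations(bias_sim_spec(
    n_slices = 25, n_models = 15, alpha = -5, beta = -0.05,
    sigma_inter = 1.5, sigma_intra = 4, seed = 42))
  fit <- fit_bias_model(obs, seed = 7)
  expect_true(fit$converged)
  s <- summary(fit)
  truth <- c(alpha = -5, beta = -0.05, sigma_inter = 1.5, sigma_intra = 4)
  for (p in names(truth)) {
    row <- s[s$parameter == p, ]
    expect_lte(row$ci_lower, truth[[p]])
    expect_gte(row$ci_upper, truth[[p]])
  }
})

test_that("zero between-model variance concentrates the posterior ICC near 1", {
  obs <- simulate_bias_observations(bias_sim_spec(
    n_slices = 25, n_models = 15, sigma_inter = 0, sigma_intra = 4,
    seed = 14))
  fit <- fit_bias_model(obs, chains = 2, draws = 600, warmup = 400,
                        seed = 14)
  icc_draws <- fit$flat[, "sigma_intra"]^2 /
    (fit$flat[, "sigma_intra"]^2 + fit$flat[, "sigma_inter"]^2)
  expect_gt(stats::median(icc_draws), 0.9)
})

test_that("the posterior agrees with an independent Gibbs sampler", {
  skip_if_not_installed("rjags")
  obs <- simulate_bias_observations(bias_sim_spec(seed = 15))
  fit <- fit_bias_model(obs, chains = 2, draws = 1000, warmup = 400,
                        seed = 15)
  model_str <- "
    model {
      for (i in 1:n) {
        y[i] ~ dnorm(alpha + beta * x[i] + u[m[i]], tau_e)
      }
      for (j in 1:M) { u[j] ~ dnorm(0, tau_u) }
      alpha ~ dnorm(0, 1.0E-4)
      beta ~ dnorm(0, 1.0E-4)
      sigma_inter ~ dunif(0, 100)
      sigma_intra ~ dunif(0, 100)
      tau_u <- pow(sigma_inter, -2)
      tau_e <- pow(sigma_intra, -2)
    }"
  dat <- list(y = obs$delta, x = obs$area - fit$data$abar,
              m = as.integer(factor(obs$model)), n = nrow(obs),
              M = length(unique(obs$model)))
  jm <- rjags::jags.model(textConnection(model_str), data = dat,
                          n.chains = 2, quiet = TRUE)
  update(jm, 1000)
  sm <- rjags::coda.samples(jm, c("alpha", "beta", "sigma_inter",
                                  "sigma_intra"), 3000)
  jref <- colMeans(do.call(rbind, lapply(sm, as.matrix)))
  cf <- coef(fit)
  expect_lt(abs(cf["alpha"] - jref["alpha"]), 0.3)
  expect_lt(abs(cf["beta"] - jref["beta"]), 0.01)
  expect_lt(abs(cf["sigma_intra"] - jref["sigma_intra"]), 0.2)
  expect_lt(abs(cf["sigma_inter"] - jref["sigma_inter"]), 0.5)
})

test_that("the posterior predictive band behaves like a prediction interval", {
  obs <- simulate_bias_observations(bias_sim_spec(seed = 16))
  fit <- fit_bias_model(obs, chains = 2, draws = 600, warmup = 400,
                        seed = 16)
  grid <- seq(60, 190, length.out = 20)
  band <- posterior_predictive_band(fit, grid, seed = 2)
  line <- predict(fit, grid)
  expect_true(all(band$lower <= line$fit & line$fit <= band$upper))
  # inflating the intra-model draws widens the band everywhere
  fat <- fit
  fat$flat[, "sigma_intra"] <- 2 * fat$flat[, "sigma_intra"]
  band2 <- posterior_predictive_band(fat, grid, seed = 2)
  expect_true(all(band2$upper - band2$lower >= band$upper - band$lower))
  # a zero-variance posterior collapses the band onto the line
  degen <- fit
  degen$flat <- degen$flat[1:200, ]
  degen$flat[, "alpha"] <- -5; degen$flat[, "beta"] <- -0.05
  degen$flat[, "sigma_inter"] <- 0; degen$flat[, "sigma_intra"] <- 0
  band0 <- posterior_predictive_band(degen, grid, seed = 2)
  expect_equal(band0$lower, -5 - 0.05 * (grid - fit$data$abar),
               tolerance = 1e-9)
  expect_equal(band0$lower, band0$upper, tolerance = 1e-12)
})

test_that("per-group fits order their bias estimates by the generating bias", {
  ok <- sapply(1:5, function(s) {
    o1 <- simulate_bias_observations(bias_sim_spec(
      n_slices = 40, n_models = 10, alpha = -4.4, sigma_inter = 0.5,
      sigma_intra = 2, seed = 20 + s))
    o2 <- simulate_bias_observations(bias_sim_spec(
      n_slices = 40, n_models = 10, alpha = -5.3, sigma_inter = 0.5,
      sigma_intra = 2, seed = 120 + s))
    o1$group <- "cnn"; o2$group <- "transformer"
    o2$model <- o2$model + 100
    obs <- rbind(o1, o2)
    fits <- fit_by_group(obs, "group", chains = 2, draws = 500,
                         warmup = 300, seed = s)
    coef(fits$cnn)["alpha"] > coef(fits$transformer)["alpha"]
  })
  expect_true(all(ok))
  # degenerate data are rejected
  flat <- data.frame(slice = rep(1:5, 2), model = rep(1:2, each = 5),
                     area = rep(100, 10), delta = rep(1, 10))
  expect_error(fit_bias_model(flat), "degenerate|at least")
})

test_that("model residuals centre on zero for well-specified data", {
  obs <- simulate_bias_observations(bias_sim_spec(seed = 17))
  fit <- fit_bias_model(obs, chains = 2, draws = 500, warmup = 300,
                        seed = 17)
  r <- residuals(fit)
  expect_lt(abs(mean(r)), 1)
  expect_lt(abs(stats::sd(r) - 4) / 4, 0.25)
  sims <- simulate(fit, nsim = 3, seed = 4)
  expect_equal(dim(sims), c(fit$data$n, 3L))
})
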