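#' Fit the hierarchical Bayesian segmentation-bias model
#'
#' Models per-slice area differences between automated segmentations and
#' the consensus reference. For slice n with reference area a_n and model m,
#' the difference delta_nm = A_nm - a_n follows
#'
#'   delta_nm = alpha + beta * (a_n - a_bar) + u_m + e_nm,
#'   u_m ~ Normal(0, sigma_inter^2),  e_nm ~ Normal(0, sigma_intra^2),
#'
#' so alpha is the bias at the mean reference area a_bar, beta the linear
#' dependence of the bias on the reference area, sigma_inter the
#' between-model spread and sigma_intra the residual within-model spread.
#' Priors are weakly informative and scale-adaptive:
#' alpha, beta ~ Normal(0, (10 sd(delta))^2), sigma_inter and sigma_intra
#' half-Normal(5 sd(delta)); the model effects use a non-centred
#' parameterisation. Posterior inference is by Hamiltonian Monte Carlo with
#' dual-averaging step-size and diagonal mass-matrix adaptation during
#' warmup; convergence is assessed with the split Gelman-Rubin statistic
#' and flagged against the rhat < 1.1 bar.
#'
#' @param obs Data frame with columns `slice`, `model`, `area` (a_n, cm^2)
#'   and `delta` (A_nm - a_n, cm^2); at least 3 slices and 2 models.
#'   Missing cells of the slice x model design are allowed.
#' @param chains Number of HMC chains (default 3).
#' @param draws Retained post-warmup draws per chain (default 1500).
#' @param warmup Warmup (adaptation) iterations per chain, discarded
#'   (default 500).
#' @param seed Integer seed; chains use independent sub-seeds.
#' @param target_accept Dual-averaging acceptance target (default 0.95, a
#'   conservative choice suited to hierarchical posteriors).
#' @param path_length Nominal integration path length in standardised
#'   coordinates (default 2.5, beyond a quarter period of a unit-scale
#'   Gaussian target, which decorrelates successive draws).
#' @return Object of class `bias_fit`; see [summary.bias_fit()],
#'   [coef.bias_fit()], [predict.bias_fit()], [plot.bias_fit()].
#' @export
fit_bias_model <- function(obs, chains = 3L, draws = 1500L, warmup = 500L,
                           seed = 1L, target_accept = 0.95,
                           path_length = 2.5) {
  dat <- .bias_data(obs)
  if (stats::sd(dat$y) == 0)
    stop("degenerate data: all area differences identical")
  lp_grad <- .bias_lp_grad(dat)
  M <- dat$M

  base_init <- c(mean(dat$y),
                 stats::cov(dat$x, dat$y) / max(stats::var(dat$x), 1e-12),
                 rep(0, M),
                 log(max(stats::sd(dat$y) / 3, 1e-2)),
                 log(max(stats::sd(dat$y) / 2, 1e-2)))
  runs <- lapply(seq_len(chains), function(ch) {
    init <- with_seed(sub_seed(seed, 1000L + ch),
                      base_init + stats::rnorm(length(base_init), 0, 0.1))
    hmc_chain(lp_grad, init, n_warmup = warmup, n_draws = draws,
              seed = sub_seed(seed, ch), target_accept = target_accept,
              path_length = path_length)
  })

  pnames <- c("alpha", "beta", paste0("u[", seq_len(M), "]"),
              "sigma_inter", "sigma_intra")
  arr <- array(NA_real_, dim = c(draws, chains, length(pnames)),
               dimnames = list(NULL, NULL, pnames))
  for (ch in seq_len(chains)) {
    th <- runs[[ch]]$draws
    si <- exp(th[, M + 3L]); se <- exp(th[, M + 4L])
    arr[, ch, "alpha"] <- th[, 1]
    arr[, ch, "beta"] <- th[, 2]
    for (m in seq_len(M)) arr[, ch, 2L + m] <- si * th[, 2L + m]
    arr[, ch, "sigma_inter"] <- si
    arr[, ch, "sigma_intra"] <- se
  }
  rhat <- gelman_rubin(arr)
  max_rhat <- max(unlist(rhat), na.rm = TRUE)

  flat <- matrix(arr, nrow = draws * chains, ncol = length(pnames),
                 dimnames = list(NULL, pnames))
  fit <- structure(list(
    draws = arr, flat = flat, data = dat,
    rhat = rhat, max_rhat = max_rhat, converged = max_rhat < 1.1,
    accept_rate = vapply(runs, `[[`, numeric(1), "accept_rate"),
    divergences = sum(vapply(runs, `[[`, integer(1), "divergences")),
    settings = list(chains = chains, draws = draws, warmup = warmup,
                    seed = seed, target_accept = target_accept)),
    class = "bias_fit")
  fit$summary <- .bias_summary(fit)
  fit
}

.bias_data <- function(obs) {
  req <- c("slice", "model", "area", "delta")
  if (!all(req %in% names(obs)))
    stop("obs must have columns slice, model, area, delta")
  obs <- as.data.frame(obs)
  if (length(unique(obs$slice)) < 3 || length(unique(obs$model)) < 2)
    stop("need at least 3 slices and 2 models")
  if (any(obs$area <= 0)) stop("reference areas must be positive")
  if (any(!is.finite(obs$delta))) stop("delta must be finite")
  mf <- factor(obs$model)
  abar <- mean(tapply(obs$area, obs$slice, mean))
  list(y = obs$delta, x = obs$area - abar, midx = as.integer(mf),
       models = levels(mf), M = nlevels(mf), n = nrow(obs), abar = abar,
       area = obs$area, obs = obs)
}

# log posterior and gradient in the unconstrained parameterisation
# theta = (alpha, beta, z_1..z_M, log sigma_inter, log sigma_intra).
.bias_lp_grad <- function(dat) {
  y <- dat$y; x <- dat$x; midx <- dat$midx
  M <- dat$M; n <- dat$n
  s_ab <- 10 * stats::sd(y)
  s_sig <- 5 * stats::sd(y)
  force(s_ab); force(s_sig)
  function(theta) {
    alpha <- theta[1]; beta <- theta[2]
    z <- theta[3:(M + 2L)]
    si <- exp(theta[M + 3L]); se <- exp(theta[M + 4L])
    r <- y - (alpha + beta * x + si * z[midx])
    se2 <- se^2
    lp <- -0.5 * sum(r^2) / se2 - n * log(se) -
      0.5 * (alpha^2 + beta^2) / s_ab^2 - 0.5 * sum(z^2) -
      0.5 * si^2 / s_sig^2 + log(si) -
      0.5 * se^2 / s_sig^2 + log(se)
    S_m <- as.vector(rowsum(r, midx, reorder = TRUE))
    g <- numeric(M + 4L)
    g[1] <- sum(r) / se2 - alpha / s_ab^2
    g[2] <- sum(r * x) / se2 - beta / s_ab^2
    g[3:(M + 2L)] <- si * S_m / se2 - z
    g[M + 3L] <- si * sum(z * S_m) / se2 - si^2 / s_sig^2 + 1
    g[M + 4L] <- sum(r^2) / se2 - n - se2 / s_sig^2 + 1
    list(lp = lp, grad = g)
  }
}

.bias_summary <- function(fit) {
  flat <- fit$flat
  abar <- fit$data$abar
  qs <- function(v) c(mean = mean(v), stats::quantile(v, c(0.025, 0.975)))
  pars <- c("alpha", "beta", "sigma_inter", "sigma_intra")
  tab <- t(vapply(pars, function(p) qs(flat[, p]), numeric(3)))
  icc_draws <- flat[, "sigma_intra"]^2 /
    (flat[, "sigma_intra"]^2 + flat[, "sigma_inter"]^2)
  bias_draws <- 100 * flat[, "alpha"] / abar
  tab <- rbind(tab, icc = qs(icc_draws), bias_pct = qs(bias_draws))
  colnames(tab) <- c("mean", "ci_lower", "ci_upper")
  rhat_named <- unlist(fit$rhat)
  data.frame(parameter = rownames(tab), tab,
             rhat = c(rhat_named[pars], NA, NA), row.names = NULL)
}

#' @export
print.bias_fit <- function(x, ...) {
  s <- x$settings
  cat(sprintf("<bias_fit> %d obs (%d slices x %d models), %d chains x %d draws (+%d warmup)\n",
              x$data$n, length(unique(x$data$obs$slice)), x$data$M,
              s$chains, s$draws, s$warmup))
  cat(sprintf("max split-rhat %.3f (%s); mean acceptance %.2f\n",
              x$max_rhat, if (x$converged) "converged" else "NOT converged",
              mean(x$accept_rate)))
  print(x$summary, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Summarise a fitted bias model
#'
#' Posterior means and central 95% credible intervals for alpha, beta,
#' sigma_inter and sigma_intra, plus the derived intraclass correlation
#' ICC = sigma_intra^2 / (sigma_intra^2 + sigma_inter^2) and the bias at
#' the mean reference area expressed in percent, 100 * alpha / a_bar.
#'
#' @param object A `bias_fit`.
#' @param ... Unused.
#' @return Data frame with columns parameter, mean, ci_lower, ci_upper,
#'   rhat; attributes `max_rhat`, `converged`, `abar`.
#' @export
summary.bias_fit <- function(object, ...) {
  out <- object$summary
  attr(out, "max_rhat") <- object$max_rhat
  attr(out, "converged") <- object$converged
  attr(out, "abar") <- object$data$abar
  out
}

#' @export
coef.bias_fit <- function(object, ...) {
  means <- colMeans(object$flat)
  c(alpha = unname(means["alpha"]), beta = unname(means["beta"]),
    sigma_inter = unname(means["sigma_inter"]),
    sigma_intra = unname(means["sigma_intra"]))
}

#' Predicted bias at new reference areas
#'
#' @param object A `bias_fit`.
#' @param newdata Numeric vector of reference areas (cm^2), or a data frame
#'   with an `area` column; defaults to the observed areas.
#' @param interval `"none"` (posterior-mean line), `"credible"` (95% CI of
#'   the mean line) or `"prediction"` (95% posterior predictive interval for
#'   a new model's delta, via [posterior_predictive_band()]).
#' @param level Interval level (default 0.95).
#' @param seed Seed for the predictive noise draws.
#' @param ... Unused.
#' @return Data frame with `area`, `fit` and (for intervals) `lower`,
#'   `upper`.
#' @export
predict.bias_fit <- function(object, newdata = NULL,
                             interval = c("none", "credible", "prediction"),
                             level = 0.95, seed = 1L, ...) {
  interval <- match.arg(interval)
  a <- if (is.null(newdata)) sort(unique(object$data$area))
       else if (is.data.frame(newdata)) newdata$area else as.numeric(newdata)
  x <- a - object$data$abar
  cf <- coef(object)
  out <- data.frame(area = a, fit = cf["alpha"] + cf["beta"] * x)
  if (interval == "credible") {
    mu <- outer(object$flat[, "alpha"], rep(1, length(x))) +
      outer(object$flat[, "beta"], x)
    qs <- apply(mu, 2, stats::quantile,
                probs = c((1 - level) / 2, 1 - (1 - level) / 2))
    out$lower <- qs[1, ]; out$upper <- qs[2, ]
  } else if (interval == "prediction") {
    band <- posterior_predictive_band(object, a, level = level, seed = seed)
    out$lower <- band$lower; out$upper <- band$upper
  }
  out
}

#' Posterior predictive band for new area differences
#'
#' For each reference area a, the interval quantiles of
#' alpha + beta (a - a_bar) + u* + e* with u* ~ Normal(0, sigma_inter) and
#' e* ~ Normal(0, sigma_intra) redrawn for every posterior draw -- the
#' spread expected for a previously unseen model on a new slice.
#'
#' @param fit A `bias_fit`.
#' @param a_grid Numeric vector of reference areas (cm^2).
#' @param level Interval level (default 0.95).
#' @param seed Seed for the noise draws.
#' @return Data frame with `area`, `lower`, `upper`.
#' @export
posterior_predictive_band <- function(fit, a_grid, level = 0.95, seed = 1L) {
  stopifnot(inherits(fit, "bias_fit"))
  flat <- fit$flat
  S <- nrow(flat)
  x <- a_grid - fit$data$abar
  with_seed(seed, {
    lo <- up <- numeric(length(x))
    u <- stats::rnorm(S, 0, flat[, "sigma_inter"])
    for (k in seq_along(x)) {
      v <- flat[, "alpha"] + flat[, "beta"] * x[k] + u +
        stats::rnorm(S, 0, flat[, "sigma_intra"])
      q <- stats::quantile(v, c((1 - level) / 2, 1 - (1 - level) / 2))
      lo[k] <- q[1]; up[k] <- q[2]
    }
    data.frame(area = a_grid, lower = lo, upper = up)
  })
}

#' Simulate area differences from the posterior predictive
#'
#' @param object A `bias_fit`.
#' @param nsim Number of simulated replicate datasets.
#' @param seed Seed for the draws.
#' @param ... Unused.
#' @return Data frame with `nsim` columns of simulated delta, rows matching
#'   the observed design.
#' @export
simulate.bias_fit <- function(object, nsim = 1, seed = 1L, ...) {
  flat <- object$flat
  dat <- object$data
  with_seed(seed, {
    out <- matrix(NA_real_, dat$n, nsim)
    for (s in seq_len(nsim)) {
      i <- sample.int(nrow(flat), 1)
      u <- stats::rnorm(dat$M, 0, flat[i, "sigma_inter"])
      mu <- flat[i, "alpha"] + flat[i, "beta"] * dat$x + u[dat$midx]
      out[, s] <- mu + stats::rnorm(dat$n, 0, flat[i, "sigma_intra"])
    }
    as.data.frame(out)
  })
}

#' @export
residuals.bias_fit <- function(object, ...) {
  cf <- colMeans(object$flat)
  u_hat <- cf[grep("^u\\[", names(cf))]
  object$data$y - (cf["alpha"] + cf["beta"] * object$data$x +
                     u_hat[object$data$midx])
}

#' Plot a fitted bias model
#'
#' Observed area differences against the reference area, coloured by model,
#' with the posterior-mean bias line, the 95% credible band of the line and
#' the 95% posterior predictive band.
#'
#' @param x A `bias_fit`.
#' @param seed Seed for the predictive band draws.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.bias_fit <- function(x, seed = 1L, ...) {
  dat <- x$data
  grid <- seq(min(dat$area), max(dat$area), length.out = 50)
  cred <- predict(x, grid, interval = "credible")
  pred <- predict(x, grid, interval = "prediction", seed = seed)
  ylim <- range(dat$y, pred$lower, pred$upper)
  graphics::plot(dat$area, dat$y, col = dat$midx, pch = 16,
                 xlab = "reference area (cm^2)",
                 ylab = "area difference delta (cm^2)", ylim = ylim, ...)
  graphics::polygon(c(grid, rev(grid)), c(pred$lower, rev(pred$upper)),
                    col = grDevices::adjustcolor("grey70", 0.4), border = NA)
  graphics::polygon(c(grid, rev(grid)), c(cred$lower, rev(cred$upper)),
                    col = grDevices::adjustcolor("grey40", 0.4), border = NA)
  graphics::lines(cred$area, cred$fit, lwd = 2)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Fit the bias model independently per model group
#'
#' Splits the observations by a model-group label (e.g. network
#' architecture family) and fits each group with no pooling across groups.
#'
#' @param obs Observation data frame as for [fit_bias_model()].
#' @param groups Either a vector of group labels (one per row of `obs`) or
#'   the name of a column of `obs`.
#' @param ... Passed to [fit_bias_model()]; per-group seeds are derived from
#'   `seed`.
#' @param seed Master seed.
#' @return Named list of `bias_fit` objects, one per group.
#' @export
fit_by_group <- function(obs, groups, seed = 1L, ...) {
  obs <- as.data.frame(obs)
  if (is.character(groups) && length(groups) == 1L && groups %in% names(obs))
    groups <- obs[[groups]]
  if (length(groups) != nrow(obs))
    stop("groups must label every observation row")
  gl <- split(seq_len(nrow(obs)), groups)
  out <- lapply(seq_along(gl), function(i)
    fit_bias_model(obs[gl[[i]], , drop = FALSE],
                   seed = sub_seed(seed, 7000L + i), ...))
  names(out) <- names(gl)
  out
}
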