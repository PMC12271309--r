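# Hamiltonian Monte Carlo with dual-averaging step-size adaptation and
# diagonal mass-matrix estimation during warmup. Static trajectories with a
# jittered path length; the sampler only needs the log posterior and its
# gradient, both supplied as one function returning list(lp, grad).

hmc_chain <- function(lp_grad, init, n_warmup, n_draws, seed,
                      target_accept = 0.8, path_length = 1.2,
                      max_leapfrog = 100L) {
  with_seed(seed, {
    dim_ <- length(init)
    inv_mass <- rep(1, dim_)
    theta <- init
    cur <- lp_grad(theta)
    if (!is.finite(cur$lp)) stop("initial point has non-finite log posterior")

    leapfrog <- function(theta, p, eps, L) {
      g <- lp_grad(theta)$grad
      for (l in seq_len(L)) {
        p <- p + 0.5 * eps * g
        theta <- theta + eps * inv_mass * p
        g <- lp_grad(theta)$grad
        if (any(!is.finite(g))) return(NULL)
        p <- p + 0.5 * eps * g
      }
      list(theta = theta, p = p)
    }

    hamiltonian <- function(lp, p) -lp + 0.5 * sum(inv_mass * p^2)

    # crude initial step size: scale until acceptance crosses 0.5
    eps <- 0.1
    for (rep_ in 1:20) {
      p0 <- stats::rnorm(dim_) / sqrt(inv_mass)
      st <- leapfrog(theta, p0, eps, 1L)
      if (is.null(st)) { eps <- eps / 2; next }
      h0 <- hamiltonian(cur$lp, p0)
      h1 <- hamiltonian(lp_grad(st$theta)$lp, st$p)
      if (!is.finite(h1)) { eps <- eps / 2; next }
      a <- exp(h0 - h1)
      if (a > 0.5 && eps < 2) eps <- eps * 2
      else if (a < 0.5 && eps > 1e-6) eps <- eps / 2
      else break
    }

    # dual averaging state (reset when the metric changes)
    da_init <- function(eps0) list(mu = log(10 * eps0), log_eps = log(eps0),
                                   log_eps_bar = 0, h_bar = 0, count = 0)
    da <- da_init(eps)
    da_update <- function(da, accept) {
      da$count <- da$count + 1
      gamma <- 0.05; t0 <- 10; kappa <- 0.75
      da$h_bar <- (1 - 1 / (da$count + t0)) * da$h_bar +
        (target_accept - accept) / (da$count + t0)
      da$log_eps <- da$mu - sqrt(da$count) / gamma * da$h_bar
      w <- da$count^(-kappa)
      da$log_eps_bar <- w * da$log_eps + (1 - w) * da$log_eps_bar
      da
    }

    # Welford accumulator for the metric window
    wf_n <- 0; wf_mean <- numeric(dim_); wf_m2 <- numeric(dim_)
    metric_start <- min(76L, max(1L, n_warmup %/% 4L))
    metric_end <- max(metric_start, n_warmup - 50L)

    total <- n_warmup + n_draws
    draws <- matrix(NA_real_, n_draws, dim_)
    accept_sum <- 0
    n_div <- 0L

    for (iter in seq_len(total)) {
      adapting <- iter <= n_warmup
      eps_iter <- exp(if (adapting) da$log_eps else da$log_eps_bar)
      eps_iter <- min(eps_iter, 2)
      L <- max(1L, min(max_leapfrog,
                       as.integer(round(path_length / eps_iter *
                                        stats::runif(1, 0.9, 1.1)))))
      p0 <- stats::rnorm(dim_) / sqrt(inv_mass)
      st <- leapfrog(theta, p0, eps_iter, L)
      if (is.null(st)) {
        accept <- 0
        n_div <- n_div + 1L
      } else {
        prop <- lp_grad(st$theta)
        dh <- hamiltonian(cur$lp, p0) - hamiltonian(prop$lp, st$p)
        accept <- if (is.finite(dh)) min(1, exp(dh)) else 0
        if (is.finite(dh) && stats::runif(1) < accept) {
          theta <- st$theta
          cur <- prop
        }
      }
      if (adapting) {
        da <- da_update(da, accept)
        if (iter >= metric_start && iter < metric_end) {
          wf_n <- wf_n + 1
          delta <- theta - wf_mean
          wf_mean <- wf_mean + delta / wf_n
          wf_m2 <- wf_m2 + delta * (theta - wf_mean)
        }
        if (iter == metric_end && wf_n > 10) {
          v <- wf_m2 / (wf_n - 1)
          inv_mass <- v * wf_n / (wf_n + 5) + 1e-3 * 5 / (wf_n + 5)
          da <- da_init(exp(da$log_eps_bar))
        }
      } else {
        draws[iter - n_warmup, ] <- theta
        accept_sum <- accept_sum + accept
      }
    }
    list(draws = draws, accept_rate = accept_sum / n_draws,
         step_size = exp(da$log_eps_bar), inv_mass = inv_mass,
         divergences = n_div)
  })
}
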