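#' Specification of a synthetic test-retest cohort
#'
#' Statistical structure of the simulated patient cohort: per-gender
#' log-normal true tissue volumes, multiplicative log-normal within-subject
#' (day-to-day) error applied independently to each visit, and a per-patient
#' true fractional change realised at day 180. Under this model the
#' within-subject coefficient of variation relates to the log-scale
#' within-subject SD by wCV = sqrt(exp(sigma_w^2) - 1), approximately
#' sigma_w for small values, and test-retest limits of agreement are
#' reciprocal-symmetric on the percent scale.
#'
#' Default volume scales and within-subject SDs emulate an abdominal MRI
#' body-composition cohort: females carry more subcutaneous fat, males more
#' visceral fat and muscle; visceral fat is the least repeatable tissue.
#'
#' @param n_patients Number of patients.
#' @param prop_female Proportion of female patients.
#' @param log_mean Named list per tissue class of c(F, M) log-mean true
#'   volumes (log mL).
#' @param log_sd Named vector per class of between-subject log-SD.
#' @param sigma_w Named vector per class of within-subject log-SD.
#' @param change_mean,change_sd Mean and SD of the true fractional change at
#'   day 180 (0.1 = +10%).
#' @param seed Integer seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 49,
                        prop_female = 0.5,
                        log_mean = list(SF = c(F = log(4000), M = log(3000)),
                                        VF = c(F = log(1500), M = log(2500)),
                                        PM = c(F = log(250),  M = log(350)),
                                        EM = c(F = log(1300), M = log(1800))),
                        log_sd = c(SF = 0.45, VF = 0.55, PM = 0.25, EM = 0.25),
                        sigma_w = c(SF = 0.041, VF = 0.092, PM = 0.030,
                                    EM = 0.019),
                        change_mean = 0, change_sd = 0,
                        seed = 1L) {
  if (any(sigma_w < 0)) stop("sigma_w must be >= 0")
  if (n_patients < 1) stop("need at least one patient")
  if (prop_female < 0 || prop_female > 1) stop("prop_female must be in [0,1]")
  classes <- names(log_mean)
  if (!all(classes %in% names(log_sd)) || !all(classes %in% names(sigma_w)))
    stop("log_sd and sigma_w must cover every class in log_mean")
  structure(list(n_patients = as.integer(n_patients),
                 prop_female = prop_female, log_mean = log_mean,
                 log_sd = log_sd, sigma_w = sigma_w,
                 change_mean = change_mean, change_sd = change_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a double-baseline + day-180 volume cohort
#'
#' Per patient and tissue class: a true volume V drawn log-normally with
#' gender-specific parameters; two baseline replicates V * exp(e_r) with
#' e_r ~ Normal(0, sigma_w^2); and a day-180 volume
#' V * (1 + true change) * exp(e) with an independent error draw. The true
#' per-patient change is stored in the attribute `true_change`.
#'
#' @param spec A [cohort_spec()].
#' @return A [volume_table()] with visits baseline1, baseline2, day180.
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_patients
    nf <- round(spec$prop_female * n)
    gender <- c(rep("F", nf), rep("M", n - nf))
    pid <- sprintf("P%03d", seq_len(n))
    classes <- names(spec$log_mean)
    rows <- vector("list", 0)
    truth <- vector("list", 0)
    for (cls in classes) {
      mu <- vapply(gender, function(g) spec$log_mean[[cls]][[g]], numeric(1))
      V <- exp(stats::rnorm(n, mu, spec$log_sd[[cls]]))
      sw <- spec$sigma_w[[cls]]
      b1 <- V * exp(stats::rnorm(n, 0, sw))
      b2 <- V * exp(stats::rnorm(n, 0, sw))
      chg <- stats::rnorm(n, spec$change_mean, spec$change_sd)
      chg <- pmax(chg, -0.95)
      d180 <- V * (1 + chg) * exp(stats::rnorm(n, 0, sw))
      rows[[length(rows) + 1L]] <- data.frame(
        patient = rep(pid, 3L),
        visit = rep(c("baseline1", "baseline2", "day180"), each = n),
        gender = rep(gender, 3L), class = cls,
        volume_ml = c(b1, b2, d180), stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        patient = pid, class = cls, true_volume_ml = V,
        true_change = chg, stringsAsFactors = FALSE)
    }
    tab <- volume_table(do.call(rbind, rows))
    attr(tab, "true_change") <- do.call(rbind, truth)
    tab
  })
}

#' Specification for simulated slice-area bias observations
#'
#' Generates the observations the hierarchical bias model consumes: for N
#' slices with reference (consensus) areas a_n and M models, the area
#' difference delta_nm = alpha + beta * (a_n - mean(a)) + u_m + e_nm with
#' model effects u_m ~ Normal(0, sigma_inter^2) and residuals
#' e_nm ~ Normal(0, sigma_intra^2).
#'
#' @param n_slices N, number of slices (>= 2).
#' @param n_models M, number of models (>= 2).
#' @param area_range Range of the uniform distribution of slice areas
#'   (cm^2).
#' @param alpha Bias at the mean area (cm^2).
#' @param beta Slope of the bias in the reference area (dimensionless).
#' @param sigma_inter Between-model SD (cm^2), >= 0.
#' @param sigma_intra Within-model residual SD (cm^2), >= 0.
#' @param seed Integer seed.
#' @return Object of class `bias_sim_spec`.
#' @export
bias_sim_spec <- function(n_slices = 25, n_models = 15,
                          area_range = c(50, 200), alpha = -5, beta = -0.05,
                          sigma_inter = 1.5, sigma_intra = 4, seed = 1L) {
  if (n_slices < 2 || n_models < 2) stop("need at least 2 slices and 2 models")
  if (sigma_inter < 0 || sigma_intra < 0) stop("sigmas must be >= 0")
  structure(list(n_slices = as.integer(n_slices),
                 n_models = as.integer(n_models),
                 area_range = as.numeric(area_range), alpha = alpha,
                 beta = beta, sigma_inter = sigma_inter,
                 sigma_intra = sigma_intra, seed = as.integer(seed)),
            class = "bias_sim_spec")
}

#' Simulate slice-area bias observations
#'
#' @param spec A [bias_sim_spec()].
#' @return Data frame with columns `slice`, `model`, `area` (a_n, cm^2) and
#'   `delta` (area difference, cm^2); the realised model effects are stored
#'   in the attribute `u`.
#' @export
simulate_bias_observations <- function(spec = bias_sim_spec()) {
  stopifnot(inherits(spec, "bias_sim_spec"))
  with_seed(spec$seed, {
    a <- stats::runif(spec$n_slices, spec$area_range[1], spec$area_range[2])
    u <- stats::rnorm(spec$n_models, 0, spec$sigma_inter)
    g <- expand.grid(slice = seq_len(spec$n_slices),
                     model = seq_len(spec$n_models))
    mu <- spec$alpha + spec$beta * (a[g$slice] - mean(a)) + u[g$model]
    delta <- mu + stats::rnorm(nrow(g), 0, spec$sigma_intra)
    out <- data.frame(slice = g$slice, model = g$model, area = a[g$slice],
                      delta = delta)
    attr(out, "u") <- u
    out
  })
}
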