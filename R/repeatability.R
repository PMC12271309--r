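#' Within-subject coefficient of variation for paired replicates
#'
#' Test-retest precision from duplicate measurements:
#' wCV = 100 * sqrt( (1/n) * sum_i (x_i1 - x_i2)^2 / (2 * m_i^2) ) with
#' m_i the pair mean. Scale-invariant and symmetric in the replicates.
#'
#' @param x1,x2 Positive paired measurements (replicate 1 and 2).
#' @return wCV in percent.
#' @export
wcv <- function(x1, x2) {
  .check_pairs(x1, x2, min_n = 2L)
  m <- (x1 + x2) / 2
  100 * sqrt(mean((x1 - x2)^2 / (2 * m^2)))
}

#' Test-retest intraclass correlation (one-way random effects)
#'
#' ICC(1,1) for k = 2 interchangeable replicates:
#' (MSB - MSW) / (MSB + MSW), with MSB/MSW the between/within-subject mean
#' squares of the one-way ANOVA.
#'
#' @param x1,x2 Paired measurements, n >= 3 subjects.
#' @return ICC in (-1, 1]; `NA` (flagged) when total variance is zero.
#' @export
icc_testretest <- function(x1, x2) {
  .check_pairs(x1, x2, min_n = 3L, positive = FALSE)
  n <- length(x1)
  m_i <- (x1 + x2) / 2
  grand <- mean(c(x1, x2))
  msb <- 2 * sum((m_i - grand)^2) / (n - 1)
  msw <- sum((x1 - m_i)^2 + (x2 - m_i)^2) / n
  if (msb + msw == 0)
    return(structure(NA_real_, flag = "zero_variance"))
  (msb - msw) / (msb + msw)
}

#' Asymmetric limits of agreement on the log scale
#'
#' Within-subject SD of log measurements
#' sigma_w = sqrt( sum_i (ln x_i1 - ln x_i2)^2 / (2n) ), repeatability
#' coefficient RC_log = 1.96 * sqrt(2) * sigma_w, and percent limits
#' lower = 100 * (exp(-RC_log) - 1), upper = 100 * (exp(+RC_log) - 1).
#' The limits are reciprocal-symmetric:
#' (1 + upper/100) * (1 + lower/100) = 1, so a measured change outside
#' [lower, upper] percent is larger than expected from test-retest noise at
#' 95% confidence.
#'
#' @param x1,x2 Positive paired measurements.
#' @return List with `lower`, `upper` (percent), `sigma_w_log`, `rc_log`.
#' @export
asymmetric_loa <- function(x1, x2) {
  .check_pairs(x1, x2, min_n = 2L)
  d <- log(x1) - log(x2)
  sigma <- sqrt(sum(d^2) / (2 * length(d)))
  loa_from_sigma(sigma)
}

#' Limits of agreement from a log-scale within-subject SD
#'
#' @param sigma_w_log Within-subject SD of log measurements (>= 0).
#' @return List with `lower`, `upper` (percent), `sigma_w_log`, `rc_log`
#'   where `rc_log = 1.96 * sqrt(2) * sigma_w_log`.
#' @export
loa_from_sigma <- function(sigma_w_log) {
  stopifnot(is.finite(sigma_w_log), sigma_w_log >= 0)
  rc <- 1.96 * sqrt(2) * sigma_w_log
  list(lower = 100 * (exp(-rc) - 1), upper = 100 * (exp(rc) - 1),
       sigma_w_log = sigma_w_log, rc_log = rc)
}

#' Full repeatability summary for one set of pairs
#'
#' @param x1,x2 Positive paired measurements.
#' @param stratum Optional stratum label carried through.
#' @return Object of class `repeatability_result`: data-frame row with
#'   stratum, n, wcv_pct, sigma_w_log, rc_log, icc, loa_lower_pct,
#'   loa_upper_pct.
#' @export
repeatability_summary <- function(x1, x2, stratum = "all") {
  loa <- asymmetric_loa(x1, x2)
  icc <- if (length(x1) >= 3) as.numeric(icc_testretest(x1, x2)) else NA_real_
  out <- data.frame(stratum = stratum, n = length(x1), wcv_pct = wcv(x1, x2),
                    sigma_w_log = loa$sigma_w_log, rc_log = loa$rc_log,
                    icc = icc, loa_lower_pct = loa$lower,
                    loa_upper_pct = loa$upper, stringsAsFactors = FALSE)
  class(out) <- c("repeatability_result", class(out))
  out
}

#' Stratified test-retest repeatability over a volume table
#'
#' Extracts the (baseline1, baseline2) pair for every patient with both
#' visits and computes wCV, ICC and asymmetric LOA per tissue class, overall
#' and optionally within strata (e.g. gender). Strata with fewer than two
#' complete pairs are skipped with a warning. A single-stratum call
#' reproduces the unstratified statistics exactly.
#'
#' @param tab A [volume_table()].
#' @param by Optional column name to stratify on (e.g. `"gender"`).
#' @return Data frame with one row per (class, stratum).
#' @export
stratified_repeatability <- function(tab, by = NULL) {
  tab <- volume_table(as.data.frame(tab))
  out <- list()
  for (cls in unique(tab$class)) {
    sub <- tab[tab$class == cls, , drop = FALSE]
    pairs <- .baseline_pairs(sub)
    strata <- if (is.null(by)) list(all = seq_len(nrow(pairs)))
              else split(seq_len(nrow(pairs)), pairs[[by]])
    for (s in names(strata)) {
      idx <- strata[[s]]
      if (length(idx) < 2) {
        warning(sprintf("stratum '%s' of class %s has < 2 pairs; skipped",
                        s, cls))
        next
      }
      r <- repeatability_summary(pairs$b1[idx], pairs$b2[idx], stratum = s)
      r <- cbind(class = cls, r)
      out[[length(out) + 1L]] <- r
    }
  }
  do.call(rbind, out)
}

# Wide (patient, b1, b2, gender) pairs for one tissue class.
.baseline_pairs <- function(sub) {
  b1 <- sub[sub$visit == "baseline1", c("patient", "gender", "volume_ml")]
  b2 <- sub[sub$visit == "baseline2", c("patient", "volume_ml")]
  m <- merge(b1, b2, by = "patient", suffixes = c("_1", "_2"))
  data.frame(patient = m$patient, gender = m$gender,
             b1 = m$volume_ml_1, b2 = m$volume_ml_2,
             stringsAsFactors = FALSE)
}

.check_pairs <- function(x1, x2, min_n = 2L, positive = TRUE) {
  if (length(x1) != length(x2)) stop("x1 and x2 must have equal length")
  if (length(x1) < min_n)
    stop(sprintf("need at least %d pairs", min_n))
  if (anyNA(x1) || anyNA(x2)) stop("pairs contain missing values")
  if (positive && (any(x1 <= 0) || any(x2 <= 0)))
    stop("measurements must be strictly positive")
  invisible(TRUE)
}
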