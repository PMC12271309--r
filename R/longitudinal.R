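#' Percent change from an averaged double baseline
#'
#' 100 * (followup - mean(b1, b2)) / mean(b1, b2): the follow-up volume
#' relative to the average of the two pre-treatment visits.
#'
#' @param baseline1,baseline2 Positive baseline volumes (vectors allowed).
#' @param followup Positive follow-up volume(s).
#' @return Percent change.
#' @export
percent_change <- function(baseline1, baseline2, followup) {
  if (anyNA(baseline1) || anyNA(baseline2) || anyNA(followup))
    stop("both baselines and the follow-up must be present")
  if (any(baseline1 <= 0) || any(baseline2 <= 0) || any(followup <= 0))
    stop("volumes must be strictly positive")
  b <- (baseline1 + baseline2) / 2
  100 * (followup - b) / b
}

#' Classify a percent change against repeatability limits
#'
#' A change counts as real only when it exceeds the test-retest limits:
#' strictly above the upper limit is `increase`, strictly below the lower
#' limit `decrease`, anything else (boundary values included) `no_change`.
#'
#' @param change Percent change(s).
#' @param limits Length-2 numeric `c(lower, upper)` in percent with
#'   lower < 0 < upper (e.g. asymmetric LOA from [asymmetric_loa()]).
#' @return Factor with levels decrease, no_change, increase.
#' @export
classify_change <- function(change, limits) {
  limits <- as.numeric(limits)
  if (length(limits) != 2L || !(limits[1] < 0 && limits[2] > 0))
    stop("limits must be c(lower, upper) with lower < 0 < upper")
  out <- ifelse(change > limits[2], "increase",
                ifelse(change < limits[1], "decrease", "no_change"))
  factor(out, levels = c("decrease", "no_change", "increase"))
}

#' Cohort-level longitudinal change analysis
#'
#' For every tissue class: per-patient percent change of the day-180
#' volume against the averaged double baseline, classification against the
#' class repeatability limits, category counts and percentages (to one
#' decimal), and a two-sided paired t-test of day-180 volumes against the
#' baseline means.
#'
#' @param tab A [volume_table()] with both baselines and day180 visits.
#' @param limits Named list (by class) of `c(lower, upper)` percent limits,
#'   or a data frame with columns `class`, `loa_lower_pct`, `loa_upper_pct`
#'   as produced by [stratified_repeatability()].
#' @return List with `records` (per-patient `ChangeRecord` rows) and
#'   `summary` (per class: n, counts and percentages per category, paired
#'   t-test p-value).
#' @export
cohort_change_analysis <- function(tab, limits) {
  tab <- volume_table(as.data.frame(tab))
  limits <- .as_limits(limits)
  records <- list(); summ <- list()
  for (cls in intersect(unique(tab$class), names(limits))) {
    sub <- tab[tab$class == cls, , drop = FALSE]
    pairs <- .baseline_pairs(sub)
    fu <- sub[sub$visit == "day180", c("patient", "volume_ml")]
    m <- merge(pairs, fu, by = "patient")
    if (nrow(m) < 2) stop("need at least 2 patients with a complete series")
    chg <- percent_change(m$b1, m$b2, m$volume_ml)
    cat_ <- classify_change(chg, limits[[cls]])
    rec <- data.frame(patient = m$patient, class = cls, gender = m$gender,
                      baseline_ml = (m$b1 + m$b2) / 2,
                      day180_ml = m$volume_ml, change_pct = chg,
                      classification = cat_,
                      loa_lower_pct = limits[[cls]][1],
                      loa_upper_pct = limits[[cls]][2],
                      stringsAsFactors = FALSE)
    records[[cls]] <- rec
    n <- nrow(rec)
    cnt <- table(cat_)
    tt <- stats::t.test(m$volume_ml, (m$b1 + m$b2) / 2, paired = TRUE)
    summ[[cls]] <- data.frame(
      class = cls, n = n,
      n_decrease = as.integer(cnt["decrease"]),
      n_no_change = as.integer(cnt["no_change"]),
      n_increase = as.integer(cnt["increase"]),
      pct_decrease = round(100 * cnt[["decrease"]] / n, 1),
      pct_no_change = round(100 * cnt[["no_change"]] / n, 1),
      pct_increase = round(100 * cnt[["increase"]] / n, 1),
      t_test_p = tt$p.value, stringsAsFactors = FALSE)
  }
  list(records = do.call(rbind, unname(records)),
       summary = do.call(rbind, unname(summ)))
}

.as_limits <- function(limits) {
  if (is.data.frame(limits)) {
    stopifnot(all(c("class", "loa_lower_pct", "loa_upper_pct") %in%
                    names(limits)))
    out <- lapply(seq_len(nrow(limits)), function(i)
      c(limits$loa_lower_pct[i], limits$loa_upper_pct[i]))
    names(out) <- limits$class
    return(out)
  }
  if (!is.list(limits) || is.null(names(limits)))
    stop("limits must be a named list or a data frame")
  limits
}

#' Two-group comparison of baseline tissue volumes
#'
#' Welch's two-sided unequal-variance t-test per tissue class (including
#' the derived TF and TM classes when present) on the per-patient averaged
#' baseline volumes, comparing e.g. female vs male patients.
#'
#' @param tab A [volume_table()]; run [add_derived_volumes()] first to
#'   include TF/TM.
#' @param group Grouping column (default `"gender"`).
#' @return Data frame per class: group means, difference, and Welch p-value.
#' @export
compare_group_volumes <- function(tab, group = "gender") {
  tab <- volume_table(as.data.frame(tab))
  out <- list()
  for (cls in unique(tab$class)) {
    sub <- tab[tab$class == cls & tab$visit %in% c("baseline1", "baseline2"),
               , drop = FALSE]
    vols <- tapply(sub$volume_ml, sub$patient, mean)
    grp <- tapply(as.character(sub[[group]]), sub$patient, `[`, 1)
    lv <- sort(unique(grp))
    if (length(lv) != 2L) stop("grouping must have exactly 2 levels")
    a <- vols[grp == lv[1]]; b <- vols[grp == lv[2]]
    if (length(a) < 2 || length(b) < 2)
      stop(sprintf("class %s: need >= 2 patients per group", cls))
    tt <- stats::t.test(a, b)
    out[[cls]] <- data.frame(
      class = cls, group1 = lv[1], group2 = lv[2],
      mean1 = mean(a), mean2 = mean(b), diff = mean(a) - mean(b),
      p_value = tt$p.value, stringsAsFactors = FALSE)
  }
  do.call(rbind, unname(out))
}
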