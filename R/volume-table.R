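#' Construct / validate a tissue-volume table
#'
#' The long-format table driving all repeatability and longitudinal
#' statistics: one row per (patient, visit, tissue class) with the measured
#' volume in mL. Visits are `baseline1`, `baseline2` (the double pre-treatment
#' baseline) and `day180`.
#'
#' @param df Data frame with columns `patient`, `visit`, `gender`, `class`,
#'   `volume_ml` (extra columns are preserved).
#' @return The validated data frame with class `volume_table`.
#' @export
volume_table <- function(df) {
  req <- c("patient", "visit", "gender", "class", "volume_ml")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  if (!all(df$visit %in% c("baseline1", "baseline2", "day180")))
    stop("visit must be one of baseline1, baseline2, day180")
  if (!all(df$gender %in% c("F", "M")))
    stop("gender must be 'F' or 'M'")
  if (any(!is.finite(df$volume_ml)) || any(df$volume_ml < 0))
    stop("volumes must be finite and non-negative")
  key <- paste(df$patient, df$visit, df$class, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf("duplicate row for (patient=%s, visit=%s, class=%s)",
                 d$patient, d$visit, d$class))
  }
  df <- df[, c(req, setdiff(names(df), req)), drop = FALSE]
  class(df) <- unique(c("volume_table", class(df)))
  df
}

#' Write a volume table to CSV
#'
#' Columns are written in the stable order patient, visit, gender, class,
#' volume_ml so that round trips are lossless.
#'
#' @param tab A [volume_table()] (or plain data frame with those columns).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_volume_table <- function(tab, path) {
  tab <- volume_table(as.data.frame(tab))
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}

#' Read a volume table from CSV
#'
#' @param path CSV path as written by [write_volume_table()].
#' @return A [volume_table()].
#' @export
read_volume_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  volume_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Patients eligible for test-retest analysis
#'
#' Repeatability statistics need both pre-treatment baselines. For a given
#' tissue class this returns the patients that have a volume at `baseline1`
#' and at `baseline2`; patients missing either visit are dropped (and can be
#' inspected via the `incomplete` attribute).
#'
#' @param tab A [volume_table()].
#' @param class Tissue class to check (default: every class seen, a patient
#'   must be complete in all of them).
#' @return Character vector of eligible patient ids; attribute `incomplete`
#'   lists patients excluded for a missing baseline.
#' @export
repeatability_eligible <- function(tab, class = NULL) {
  tab <- volume_table(as.data.frame(tab))
  if (!is.null(class)) tab <- tab[tab$class %in% class, , drop = FALSE]
  pats <- unique(tab$patient)
  has_both <- vapply(pats, function(p) {
    v <- tab$visit[tab$patient == p]
    all(c("baseline1", "baseline2") %in% v)
  }, logical(1))
  out <- pats[has_both]
  attr(out, "incomplete") <- pats[!has_both]
  out
}

#' Append derived total-fat / total-muscle rows
#'
#' Adds TF = SF + VF and TM = PM + EM rows for every (patient, visit) where
#' both constituents are present.
#'
#' @param tab A [volume_table()].
#' @return A [volume_table()] with TF and TM rows appended.
#' @export
add_derived_volumes <- function(tab) {
  tab <- volume_table(as.data.frame(tab))
  base <- as.data.frame(tab)
  extra <- list()
  for (dc in names(derived_classes())) {
    parts <- derived_classes()[[dc]]
    sub <- base[base$class %in% parts, , drop = FALSE]
    if (!nrow(sub)) next
    key <- interaction(sub$patient, sub$visit, drop = TRUE)
    for (k in levels(key)) {
      rows <- sub[key == k, , drop = FALSE]
      if (!setequal(rows$class, parts)) next
      r <- rows[1, , drop = FALSE]
      r$class <- dc
      r$volume_ml <- sum(rows$volume_ml)
      extra[[length(extra) + 1L]] <- r
    }
  }
  if (length(extra))
    base <- rbind(base, do.call(rbind, extra))
  volume_table(base)
}
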