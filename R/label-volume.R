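#' Tissue label scheme
#'
#' The fixed six-class abdominal labelling used throughout the package:
#' 0 background (Bgd), 1 part of the abdominal cavity excluded from analysis
#' (CavityExcluded), 2 subcutaneous fat (SF), 3 visceral / intra-abdominal
#' fat (VF), 4 psoas muscle (PM), 5 external muscle (EM). Total fat
#' (TF = SF + VF) and total muscle (TM = PM + EM) are derived quantities and
#' are never stored as voxel labels.
#'
#' @return Named character vector mapping label index (as name) to tissue name.
#' @export
label_scheme <- function() {
  c(`0` = "Bgd", `1` = "CavityExcluded", `2` = "SF",
    `3` = "VF", `4` = "PM", `5` = "EM")
}

#' Derived tissue classes
#'
#' @return Named list mapping each derived class (TF, TM) to the base tissue
#'   names it sums.
#' @export
derived_classes <- function() {
  list(TF = c("SF", "VF"), TM = c("PM", "EM"))
}

.valid_labels <- 0:5

#' Construct a label volume
#'
#' A 3D integer class map with voxel spacing in millimetres. Voxel values
#' must lie in the 0-5 label scheme (see [label_scheme()]).
#'
#' @param grid 3D array of integer labels in 0-5.
#' @param spacing Numeric length-3 voxel spacing (dx, dy, dz) in mm, all > 0.
#' @param orientation Orientation tag (default "RAS"); informational.
#' @return Object of class `label_volume` with fields `grid`, `spacing`,
#'   `orientation`.
#' @export
label_volume <- function(grid, spacing, orientation = "RAS") {
  if (!is.array(grid) || length(dim(grid)) != 3L || length(grid) == 0L)
    stop("`grid` must be a non-empty 3D array")
  v <- as.vector(grid)
  if (anyNA(v)) stop("label grid contains missing values")
  if (any(v != round(v)))
    stop("label grid contains non-integer voxel values")
  bad <- setdiff(unique(v), .valid_labels)
  if (length(bad))
    stop(sprintf("label(s) outside the 0-5 scheme: %s",
                 paste(sort(bad), collapse = ", ")))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values (mm)")
  storage.mode(grid) <- "integer"
  structure(list(grid = grid, spacing = spacing, orientation = orientation),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<label_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm (%s)\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              x$orientation))
  tab <- table(factor(x$grid, levels = .valid_labels))
  names(tab) <- label_scheme()
  print(tab)
  invisible(x)
}

#' Construct a per-class probability volume
#'
#' Six aligned probability channels over a common grid; per voxel the
#' channels must be non-negative and sum to 1 (tolerance 1e-6).
#'
#' @param channels 4D array (x, y, z, class) with 6 channels in class order
#'   0-5.
#' @param spacing Voxel spacing in mm as for [label_volume()].
#' @param orientation Orientation tag.
#' @return Object of class `prob_volume`.
#' @export
prob_volume <- function(channels, spacing, orientation = "RAS") {
  if (!is.array(channels) || length(dim(channels)) != 4L)
    stop("`channels` must be a 4D array (x, y, z, class)")
  if (dim(channels)[4] != 6L)
    stop("`channels` must have exactly 6 class channels")
  if (any(channels < 0)) stop("probabilities must be non-negative")
  s <- apply(channels, c(1, 2, 3), sum)
  if (max(abs(s - 1)) > 1e-6)
    stop("per-voxel channel probabilities must sum to 1 (tolerance 1e-6)")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values (mm)")
  structure(list(channels = channels, spacing = spacing,
                 orientation = orientation),
            class = "prob_volume")
}

#' Hard-label a probability volume
#'
#' Per-voxel argmax over the class channels; exact ties resolve to the
#' lowest class index for determinism.
#'
#' @param pv A `prob_volume`.
#' @return A `label_volume`.
#' @export
prob_argmax <- function(pv) {
  stopifnot(inherits(pv, "prob_volume"))
  d <- dim(pv$channels)
  m <- matrix(pv$channels, nrow = prod(d[1:3]), ncol = d[4])
  lab <- max.col(m, ties.method = "first") - 1L
  label_volume(array(lab, dim = d[1:3]), pv$spacing, pv$orientation)
}

#' Class-wise tissue volumes of a label volume
#'
#' Volume of class c is its voxel count times the voxel volume
#' dx*dy*dz / 1000, reported in millilitres. The derived classes
#' TF = SF + VF and TM = PM + EM are appended.
#'
#' @param vol A `label_volume`.
#' @return Named numeric vector of volumes in mL for Bgd, CavityExcluded,
#'   SF, VF, PM, EM, TF, TM.
#' @export
compute_class_volumes <- function(vol) {
  stopifnot(inherits(vol, "label_volume"))
  vox_ml <- prod(vol$spacing) / 1000
  counts <- tabulate(vol$grid + 1L, nbins = 6L)
  out <- counts * vox_ml
  names(out) <- unname(label_scheme())
  for (dc in names(derived_classes()))
    out[dc] <- sum(out[derived_classes()[[dc]]])
  out
}
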