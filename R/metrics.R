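#' Dice similarity coefficient
#'
#' Overlap 2|A n B| / (|A| + |B|) between two binary masks on the same
#' grid. When both masks are empty the value is 1.0 by convention and the
#' result carries attribute `flag = "both_empty"`.
#'
#' @param pred,ref Logical (or 0/1) arrays on the same grid.
#' @return Value in [0, 1].
#' @export
dsc <- function(pred, ref) {
  pred <- .as_mask(pred); ref <- .as_mask(ref)
  check_same_grid(pred, ref)
  na <- sum(pred); nb <- sum(ref)
  if (na + nb == 0) return(structure(1, flag = "both_empty"))
  2 * sum(pred & ref) / (na + nb)
}

#' Intersection over union
#'
#' |A n B| / |A u B|; satisfies the identity IoU = DSC / (2 - DSC).
#' Both-empty masks give 1.0 with a flag, matching [dsc()].
#'
#' @inheritParams dsc
#' @return Value in [0, 1].
#' @export
iou <- function(pred, ref) {
  pred <- .as_mask(pred); ref <- .as_mask(ref)
  check_same_grid(pred, ref)
  u <- sum(pred | ref)
  if (u == 0) return(structure(1, flag = "both_empty"))
  sum(pred & ref) / u
}

#' 95th-percentile Hausdorff distance
#'
#' Pools the directed surface distances pred -> ref and ref -> pred
#' (Euclidean between surface-voxel centres, spacing-aware) and returns the
#' 95th percentile of the pooled set, linearly interpolated between order
#' statistics. A robust variant of the Hausdorff distance. The alternative
#' convention (maximum of the two directed 95th percentiles) is available
#' via `convention = "max_directed"`.
#'
#' @inheritParams dsc
#' @param spacing Voxel spacing (dx, dy, dz) in mm.
#' @param percentile Percentile of the distance set (default 0.95).
#' @param convention `"pooled"` (default) or `"max_directed"`.
#' @return Distance in mm, or `NA` with attribute `flag` when either mask
#'   is empty (undefined).
#' @export
hd95 <- function(pred, ref, spacing = c(1, 1, 1), percentile = 0.95,
                 convention = c("pooled", "max_directed")) {
  convention <- match.arg(convention)
  pred <- .as_mask(pred); ref <- .as_mask(ref)
  check_same_grid(pred, ref)
  if (sum(pred) == 0 || sum(ref) == 0)
    return(structure(NA_real_,
                     flag = if (sum(pred) + sum(ref) == 0) "both_empty"
                            else "one_empty"))
  sp <- .surface_mask(pred)
  sr <- .surface_mask(ref)
  d_pr <- .directed_surface_dists(sp, sr, spacing)
  d_rp <- .directed_surface_dists(sr, sp, spacing)
  if (convention == "pooled")
    unname(stats::quantile(c(d_pr, d_rp), percentile, type = 7))
  else
    max(stats::quantile(d_pr, percentile, type = 7),
        stats::quantile(d_rp, percentile, type = 7))
}

#' Normalised surface Dice
#'
#' Fraction of the combined boundary lying within a tolerance distance tau
#' of the other mask's boundary:
#' (|S_pred within tau of S_ref| + |S_ref within tau of S_pred|) /
#' (|S_pred| + |S_ref|).
#'
#' @inheritParams hd95
#' @param tau Tolerance distance in mm.
#' @return Value in [0, 1], or `NA` flagged when either mask is empty.
#' @export
nsd <- function(pred, ref, spacing = c(1, 1, 1), tau = 2) {
  pred <- .as_mask(pred); ref <- .as_mask(ref)
  check_same_grid(pred, ref)
  if (sum(pred) == 0 || sum(ref) == 0)
    return(structure(NA_real_,
                     flag = if (sum(pred) + sum(ref) == 0) "both_empty"
                            else "one_empty"))
  sp <- .surface_mask(pred)
  sr <- .surface_mask(ref)
  d_pr <- .directed_surface_dists(sp, sr, spacing)
  d_rp <- .directed_surface_dists(sr, sp, spacing)
  (sum(d_pr <= tau) + sum(d_rp <= tau)) / (length(d_pr) + length(d_rp))
}

#' Surface voxels of a binary mask
#'
#' A foreground voxel is a surface voxel when at least one of its six
#' face-adjacent neighbours is background; voxels on the array border count
#' as surface. Distances elsewhere in the package are measured between
#' surface-voxel centres.
#'
#' @param mask Logical 3D array.
#' @param spacing Voxel spacing in mm.
#' @return Matrix (n x 3) of physical surface-voxel-centre coordinates.
#' @export
surface_coords <- function(mask, spacing = c(1, 1, 1)) {
  surf <- which(.surface_mask(mask), arr.ind = TRUE)
  sweep(surf, 2, spacing, `*`)
}

.surface_mask <- function(mask) {
  mask <- .as_mask(mask)
  interior <- mask
  for (off in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0),
                   c(0,0,1), c(0,0,-1)))
    interior <- interior & shift3d(mask, off, FALSE)
  mask & !interior
}

# Distances from every voxel of `from_surf` to the nearest voxel centre of
# `to_surf`, via an exact anisotropic squared Euclidean distance transform.
.directed_surface_dists <- function(from_surf, to_surf, spacing) {
  sqrt(.edt_sq(to_surf, spacing)[from_surf])
}

# Exact squared Euclidean distance transform of a voxel set (separable
# lower-envelope scan per axis, anisotropic spacing in mm).
.edt_sq <- function(mask, spacing) {
  d <- dim(mask)
  g <- array(Inf, dim = d)
  g[mask] <- 0
  g <- array(apply(g, c(2, 3), .edt_sq_line, step = spacing[1]), dim = d)
  g <- aperm(array(apply(g, c(1, 3), .edt_sq_line, step = spacing[2]),
                   dim = d[c(2, 1, 3)]), c(2, 1, 3))
  g <- aperm(array(apply(g, c(1, 2), .edt_sq_line, step = spacing[3]),
                   dim = d[c(3, 1, 2)]), c(2, 3, 1))
  g
}

# 1D squared-distance transform d(q) = min_p f(p) + ((q - p) * step)^2 over
# the finite sites p, by the lower envelope of parabolas.
.edt_sq_line <- function(f, step) {
  n <- length(f)
  sites <- which(is.finite(f))
  if (!length(sites)) return(rep(Inf, n))
  s2 <- step^2
  v <- integer(length(sites)); z <- numeric(length(sites) + 1L)
  k <- 1L; v[1] <- sites[1]; z[1] <- -Inf; z[2] <- Inf
  if (length(sites) > 1L) for (qi in 2:length(sites)) {
    q <- sites[qi]
    repeat {
      p <- v[k]
      s <- ((f[q] + s2 * q^2) - (f[p] + s2 * p^2)) / (2 * s2 * (q - p))
      if (s <= z[k]) k <- k - 1L else break
    }
    k <- k + 1L
    v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
  }
  d <- numeric(n); k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < q) k <- k + 1L
    p <- v[k]
    d[q] <- f[p] + s2 * (q - p)^2
  }
  d
}

.as_mask <- function(x) {
  if (inherits(x, "label_volume")) stop("expected a binary mask, not a label volume")
  if (!is.array(x)) stop("mask must be an array")
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  x != 0
}

#' Class-wise accuracy metrics between two label volumes
#'
#' One-vs-rest DSC, IoU, NSD (at tolerance `tau` mm) and HD95 for every
#' class 0-5, plus the reference-weighted mean DSC over foreground classes
#' (see [weighted_mean_dsc()]). Undefined boundary metrics (empty masks) are
#' `NA` with the convention recorded in the `flag` column.
#'
#' @param pred,ref [label_volume()]s on the same grid and spacing.
#' @param tau NSD tolerance in mm (default 2).
#' @return Object of class `seg_metrics`: a data frame with one row per
#'   class (columns class, label, dsc, iou, nsd, hd95, flag) and attribute
#'   `weighted_dsc`.
#' @export
classwise_metrics <- function(pred, ref, tau = 2) {
  stopifnot(inherits(pred, "label_volume"), inherits(ref, "label_volume"))
  check_same_grid(pred$grid, ref$grid)
  if (max(abs(pred$spacing - ref$spacing)) > 1e-9)
    stop("spacings differ between prediction and reference")
  sp <- ref$spacing
  rows <- lapply(.valid_labels, function(cl) {
    pm <- pred$grid == cl; rm_ <- ref$grid == cl
    d <- dsc(pm, rm_); i <- iou(pm, rm_)
    h <- hd95(pm, rm_, sp); n <- nsd(pm, rm_, sp, tau)
    fl <- attr(d, "flag"); if (is.null(fl)) fl <- attr(h, "flag")
    data.frame(class = cl, label = unname(label_scheme()[as.character(cl)]),
               dsc = as.numeric(d), iou = as.numeric(i),
               nsd = as.numeric(n), hd95 = as.numeric(h),
               flag = if (is.null(fl)) "" else fl,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "weighted_dsc") <- weighted_mean_dsc(
    stats::setNames(out$dsc, out$class), ref)
  attr(out, "tau") <- tau
  class(out) <- c("seg_metrics", class(out))
  out
}

#' @export
print.seg_metrics <- function(x, ...) {
  cat(sprintf("Class-wise segmentation metrics (NSD tolerance %.2g mm)\n",
              attr(x, "tau")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  cat(sprintf("Weighted mean DSC (foreground classes): %.4f\n",
              attr(x, "weighted_dsc")))
  invisible(x)
}

#' Reference-weighted mean DSC
#'
#' Weighted average of per-class DSC with weights proportional to the
#' reference voxel count of each foreground class (classes 1-5; background
#' excluded).
#'
#' @param dsc_by_class Named numeric vector of per-class DSC, names "0".."5"
#'   (background may be absent).
#' @param ref Reference [label_volume()] supplying the weights.
#' @return Weighted mean DSC.
#' @export
weighted_mean_dsc <- function(dsc_by_class, ref) {
  stopifnot(inherits(ref, "label_volume"))
  counts <- tabulate(ref$grid + 1L, nbins = 6L)[2:6]
  names(counts) <- as.character(1:5)
  if (sum(counts) == 0)
    stop("reference contains no foreground voxels; weights undefined")
  use <- names(counts)[counts > 0]
  if (!all(use %in% names(dsc_by_class)))
    stop("dsc_by_class must cover every foreground class present in ref")
  sum(counts[use] * dsc_by_class[use]) / sum(counts[use])
}

#' Average metric tables across test subjects
#'
#' Unweighted mean of per-class metrics over a list of [classwise_metrics()]
#' results (one per subject).
#'
#' @param results List of `seg_metrics` objects.
#' @return Data frame of per-class means plus mean weighted DSC in the
#'   attribute `weighted_dsc`.
#' @export
aggregate_metrics <- function(results) {
  stopifnot(length(results) >= 1)
  num <- c("dsc", "iou", "nsd", "hd95")
  base <- results[[1]][, c("class", "label")]
  for (v in num)
    base[[v]] <- rowMeans(sapply(results, function(r) r[[v]]), na.rm = TRUE)
  attr(base, "weighted_dsc") <-
    mean(vapply(results, function(r) attr(r, "weighted_dsc"), numeric(1)))
  base
}
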