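#' Specification of a simulated imperfect rater / model
#'
#' Parameters of the corruption applied to a ground-truth label volume to
#' emulate inter-observer (or model) variation: a smooth random in-plane
#' displacement of class boundaries, a per-class over/under-segmentation
#' bias, and a sparse label-flip noise floor. Displacement and bias act in
#' physical millimetres so degradation levels transfer across resolutions.
#'
#' @param displacement_mm RMS amplitude of the smooth boundary-displacement
#'   field, mm (0 disables).
#' @param bias_mm Signed over(+)/under(-) segmentation bias in mm; either a
#'   single value applied to classes 2-5 or a named vector, e.g.
#'   `c(SF = 1.5)`.
#' @param flip_rate Fraction of voxels whose label is replaced by a uniform
#'   random label, in [0, 1).
#' @param seed Integer seed; the corruption is bit-reproducible given
#'   (spec, seed).
#' @return Object of class `corruption_spec`.
#' @export
corruption_spec <- function(displacement_mm = 0, bias_mm = 0, flip_rate = 0,
                            seed = 1L) {
  if (!is.finite(displacement_mm) || displacement_mm < 0)
    stop("displacement_mm must be finite and >= 0")
  if (any(!is.finite(bias_mm))) stop("bias_mm must be finite")
  if (!is.finite(flip_rate) || flip_rate < 0 || flip_rate >= 1)
    stop("flip_rate must be in [0, 1)")
  structure(list(displacement_mm = displacement_mm, bias_mm = bias_mm,
                 flip_rate = flip_rate, seed = as.integer(seed)),
            class = "corruption_spec")
}

#' Corrupt a ground-truth segmentation
#'
#' Applies, in order: (1) resampling of the label map along a smooth random
#' in-plane displacement field with the requested RMS amplitude, which
#' displaces all class boundaries while keeping labels in the 0-5 scheme;
#' (2) per-class morphological dilation (positive bias) or erosion (negative
#' bias) by the bias radius in mm; (3) uniform label flips at the flip rate.
#' With all parameters zero the output is identical to the input.
#'
#' @param truth A [label_volume()] ground truth.
#' @param spec A [corruption_spec()].
#' @return A corrupted [label_volume()] on the same grid.
#' @export
corrupt_segmentation <- function(truth, spec) {
  stopifnot(inherits(truth, "label_volume"), inherits(spec, "corruption_spec"))
  with_seed(spec$seed, {
    grid <- truth$grid
    d <- dim(grid)
    if (spec$displacement_mm > 0)
      grid <- .displace_labels(grid, truth$spacing, spec$displacement_mm)
    bias <- .expand_bias(spec$bias_mm)
    for (cls in names(bias)) {
      b <- bias[[cls]]
      if (b == 0) next
      idx <- match(cls, label_scheme()) - 1L
      grid <- if (b > 0) .dilate_class(grid, idx, b, truth$spacing)
              else .erode_class(grid, idx, -b, truth$spacing)
    }
    if (spec$flip_rate > 0) {
      nflip <- round(spec$flip_rate * length(grid))
      if (nflip > 0) {
        at <- sample.int(length(grid), nflip)
        grid[at] <- sample(0:5, nflip, replace = TRUE)
      }
    }
    label_volume(grid, truth$spacing, truth$orientation)
  })
}

.expand_bias <- function(bias_mm) {
  tissue <- c("SF", "VF", "PM", "EM")
  if (is.null(names(bias_mm))) {
    if (length(bias_mm) != 1L)
      stop("unnamed bias_mm must be a single value")
    out <- as.list(rep(bias_mm, length(tissue)))
    names(out) <- tissue
  } else {
    if (!all(names(bias_mm) %in% unname(label_scheme())))
      stop("bias_mm names must be tissue names from the label scheme")
    out <- as.list(bias_mm)
  }
  out[vapply(out, function(x) x != 0, logical(1))]
}

# Smooth random in-plane displacement: iid normal control points on a coarse
# lattice, bilinearly upsampled, scaled to the requested RMS (mm); the label
# map is then looked up at the displaced coordinates (nearest neighbour).
.displace_labels <- function(grid, spacing, amp_mm, knot_vox = 12L) {
  d <- dim(grid)
  field <- function() {
    nk <- pmax(2L, ceiling(d[1:2] / knot_vox) + 1L)
    ctrl <- matrix(stats::rnorm(nk[1] * nk[2]), nk[1], nk[2])
    up <- .bilinear_upsample(ctrl, d[1], d[2])
    up / sqrt(mean(up^2))
  }
  fx <- field() * amp_mm / spacing[1]   # displacement in voxel units
  fy <- field() * amp_mm / spacing[2]
  ix <- matrix(seq_len(d[1]), d[1], d[2])
  iy <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  sx <- pmin(pmax(round(ix + fx), 1L), d[1])
  sy <- pmin(pmax(round(iy + fy), 1L), d[2])
  out <- grid
  flat <- cbind(as.vector(sx), as.vector(sy))
  for (z in seq_len(d[3]))
    out[, , z] <- matrix(grid[, , z][flat], d[1], d[2])
  out
}

.bilinear_upsample <- function(ctrl, nx, ny) {
  nk <- dim(ctrl)
  gx <- seq(1, nk[1], length.out = nx)
  gy <- seq(1, nk[2], length.out = ny)
  x0 <- pmin(floor(gx), nk[1] - 1L); tx <- gx - x0
  y0 <- pmin(floor(gy), nk[2] - 1L); ty <- gy - y0
  a <- ctrl[x0,     y0,     drop = FALSE]
  b <- ctrl[x0 + 1, y0,     drop = FALSE]
  cc <- ctrl[x0,    y0 + 1, drop = FALSE]
  e <- ctrl[x0 + 1, y0 + 1, drop = FALSE]
  TX <- matrix(tx, nx, ny); TY <- matrix(ty, nx, ny, byrow = TRUE)
  a * (1 - TX) * (1 - TY) + b * TX * (1 - TY) + cc * (1 - TX) * TY + e * TX * TY
}

# In-plane integer offsets whose physical length is within r mm.
.ball_offsets <- function(r_mm, spacing) {
  mx <- floor(r_mm / spacing[1]); my <- floor(r_mm / spacing[2])
  off <- expand.grid(ox = -mx:mx, oy = -my:my)
  keep <- (off$ox * spacing[1])^2 + (off$oy * spacing[2])^2 <= r_mm^2
  off <- off[keep & !(off$ox == 0 & off$oy == 0), , drop = FALSE]
  off
}

.dilate_class <- function(grid, cls, r_mm, spacing) {
  off <- .ball_offsets(r_mm, spacing)
  mask <- grid == cls
  grown <- mask
  for (i in seq_len(nrow(off)))
    grown <- grown | shift3d(mask, c(off$ox[i], off$oy[i], 0L), FALSE)
  grid[grown] <- cls
  grid
}

.erode_class <- function(grid, cls, r_mm, spacing) {
  off <- .ball_offsets(r_mm, spacing)
  mask <- grid == cls
  core <- mask
  for (i in seq_len(nrow(off)))
    core <- core & shift3d(mask, c(off$ox[i], off$oy[i], 0L), FALSE)
  removed <- mask & !core
  if (any(removed)) {
    # removed voxels take the label of a nearby non-class voxel
    repl <- array(NA_integer_, dim = dim(grid))
    for (i in seq_len(nrow(off))) {
      cand <- shift3d(grid, c(off$ox[i], off$oy[i], 0L), cls)
      take <- removed & is.na(repl) & (cand != cls)
      repl[take] <- cand[take]
    }
    repl[removed & is.na(repl)] <- 0L
    grid[removed] <- repl[removed]
  }
  grid
}
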