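#' Specification of the synthetic abdominal phantom
#'
#' Describes a voxelised nested-ellipse cross-section replicated over axial
#' slices: an outer body ellipse whose rim is subcutaneous fat (SF), an
#' external-muscle (EM) ring inside it, and an abdominal cavity containing
#' visceral-fat (VF) blobs and two psoas-muscle (PM) discs; the remaining
#' cavity voxels carry the cavity-excluded label. All geometry is in mm.
#'
#' @param n_slices Number of axial slices.
#' @param size In-plane grid size (voxels per side).
#' @param spacing Voxel spacing (dx, dy, dz) in mm.
#' @param body_radii Semi-axes (a, b) of the outer body ellipse, mm.
#' @param sf_thickness Thickness of the subcutaneous-fat rim, mm.
#' @param em_thickness Thickness of the external-muscle ring, mm.
#' @param vf_blobs Number of visceral-fat blobs (0 allowed).
#' @param vf_radius Radius of each VF blob, mm.
#' @param pm_radius Radius of each of the two psoas discs, mm.
#' @param pm_offset (x, y) offset of the psoas discs from centre, mm; discs
#'   are placed at (+x, y) and (-x, y).
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_slices = 12, size = 96, spacing = c(1.5, 1.5, 4),
                         body_radii = c(60, 45), sf_thickness = 12,
                         em_thickness = 8, vf_blobs = 5, vf_radius = 7,
                         pm_radius = 8, pm_offset = c(16, -10)) {
  spec <- list(n_slices = as.integer(n_slices), size = as.integer(size),
               spacing = as.numeric(spacing), body_radii = as.numeric(body_radii),
               sf_thickness = sf_thickness, em_thickness = em_thickness,
               vf_blobs = as.integer(vf_blobs), vf_radius = vf_radius,
               pm_radius = pm_radius, pm_offset = as.numeric(pm_offset))
  if (spec$n_slices < 1 || spec$size < 8) stop("phantom grid too small")
  if (any(spec$spacing <= 0)) stop("spacing must be positive")
  inner <- spec$body_radii - spec$sf_thickness - spec$em_thickness
  if (any(inner <= 0))
    stop("rings do not nest: SF + EM thickness exceeds body radii")
  if (spec$vf_radius <= 0 || spec$pm_radius <= 0) stop("radii must be > 0")
  # psoas discs must sit inside the cavity ellipse
  if (sum((abs(spec$pm_offset) + spec$pm_radius)^2 / inner^2) >= 2)
    stop("psoas discs do not fit inside the cavity")
  structure(spec, class = "phantom_spec")
}

#' Build the voxelised phantom
#'
#' Deterministic given the spec (no randomness): every slice carries the
#' same cross-section, so analytic elliptic-cylinder volumes are available
#' as an independent check on voxel-counted volumes.
#'
#' @param spec A [phantom_spec()].
#' @return A [label_volume()] using the 0-5 scheme with all requested
#'   classes present.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$size
  dx <- spec$spacing[1]; dy <- spec$spacing[2]
  # voxel-centre physical coordinates, origin at grid centre
  xs <- (seq_len(n) - 0.5 - n / 2) * dx
  ys <- (seq_len(n) - 0.5 - n / 2) * dy
  X <- matrix(xs, n, n)
  Y <- matrix(ys, n, n, byrow = TRUE)

  inside_ellipse <- function(a, b) (X / a)^2 + (Y / b)^2 <= 1
  ab  <- spec$body_radii
  em_out <- ab - spec$sf_thickness
  cav    <- em_out - spec$em_thickness

  sl <- matrix(0L, n, n)
  sl[inside_ellipse(ab[1], ab[2])]         <- 2L  # SF rim
  sl[inside_ellipse(em_out[1], em_out[2])] <- 5L  # EM ring
  sl[inside_ellipse(cav[1], cav[2])]       <- 1L  # cavity (excluded)

  in_cavity <- inside_ellipse(cav[1], cav[2])
  # VF blobs on an arc in the upper half of the cavity
  if (spec$vf_blobs > 0) {
    ang <- pi * (seq_len(spec$vf_blobs) - 0.5) / spec$vf_blobs
    cx <- 0.55 * cav[1] * cos(ang)
    cy <- 0.45 * cav[2] * sin(ang)
    for (k in seq_len(spec$vf_blobs)) {
      blob <- (X - cx[k])^2 + (Y - cy[k])^2 <= spec$vf_radius^2
      sl[blob & in_cavity] <- 3L
    }
  }
  # two psoas discs, posterior
  for (sgn in c(-1, 1)) {
    disc <- (X - sgn * spec$pm_offset[1])^2 +
            (Y - spec$pm_offset[2])^2 <= spec$pm_radius^2
    sl[disc & in_cavity] <- 4L
  }
  grid <- array(sl, dim = c(n, n, spec$n_slices))
  label_volume(grid, spec$spacing)
}
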