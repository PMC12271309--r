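# Independent brute-force oracles for the surface-distance metrics, written
# by direct definition (voxel-by-voxel loops, full pairwise distance
# matrix). Only intended for masks of up to ~10^3 voxels.

bf_surface <- function(mask) {
  d <- dim(mask)
  offs <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  out <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask[i, j, k]) next
    is_surf <- FALSE
    for (off in offs) {
      p <- c(i, j, k) + off
      if (any(p < 1) || any(p > d) || !mask[p[1], p[2], p[3]]) {
        is_surf <- TRUE
        break
      }
    }
    if (is_surf) out <- rbind(out, c(i, j, k))
  }
  out
}

bf_directed <- function(A, B) {
  out <- numeric(nrow(A))
  for (i in seq_len(nrow(A))) {
    best <- Inf
    for (j in seq_len(nrow(B)))
      best <- min(best, sqrt(sum((A[i, ] - B[j, ])^2)))
    out[i] <- best
  }
  out
}

bf_surface_distances <- function(pred, ref, spacing) {
  A <- sweep(bf_surface(pred), 2, spacing, `*`)
  B <- sweep(bf_surface(ref), 2, spacing, `*`)
  list(pr = bf_directed(A, B), rp = bf_directed(B, A))
}

bf_hd95 <- function(pred, ref, spacing, q = 0.95) {
  d <- bf_surface_distances(pred, ref, spacing)
  unname(stats::quantile(c(d$pr, d$rp), q, type = 7))
}

bf_nsd <- function(pred, ref, spacing, tau) {
  d <- bf_surface_distances(pred, ref, spacing)
  (sum(d$pr <= tau) + sum(d$rp <= tau)) / (length(d$pr) + length(d$rp))
}

# random blob mask on a small grid: union of a few random balls
random_mask <- function(d = c(9, 9, 9), n_balls = 2, r_max = 3) {
  arr <- array(FALSE, dim = d)
  ctr <- matrix(runif(3 * n_balls), n_balls, 3) %*% diag(d - 1) + 1
  r <- runif(n_balls, 1, r_max)
  for (b in seq_len(n_balls)) {
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
      if (sum((c(i, j, k) - ctr[b, ])^2) <= r[b]^2) arr[i, j, k] <- TRUE
  }
  arr
}

# small phantom shared by consensus / ensemble tests
small_phantom <- function(n_slices = 3, size = 48) {
  make_phantom(phantom_spec(n_slices = n_slices, size = size,
                            body_radii = c(30, 24), sf_thickness = 7,
                            em_thickness = 5, vf_blobs = 3, vf_radius = 4,
                            pm_radius = 4, pm_offset = c(8, -5)))
}
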