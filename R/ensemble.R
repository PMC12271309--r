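#' Ensemble by probability averaging
#'
#' Voxel label = argmax of the channel-wise mean probability over the
#' member models; exact ties resolve to the lowest class index.
#'
#' @param members List of aligned [prob_volume()]s.
#' @return A [label_volume()].
#' @export
ensemble_average <- function(members) {
  stopifnot(is.list(members), length(members) >= 1)
  stopifnot(all(vapply(members, inherits, logical(1), "prob_volume")))
  for (m in members) check_same_grid(members[[1]]$channels, m$channels)
  acc <- members[[1]]$channels
  if (length(members) > 1)
    for (m in members[-1]) acc <- acc + m$channels
  acc <- acc / length(members)
  prob_argmax(prob_volume(acc, members[[1]]$spacing,
                          members[[1]]$orientation))
}

#' Ensemble by hard-label voting
#'
#' Per-voxel modal label over the members; ties resolve to the lowest class
#' index. Invariant to member order.
#'
#' @param members List of aligned [label_volume()]s.
#' @return A [label_volume()].
#' @export
ensemble_vote <- function(members) {
  stopifnot(is.list(members), length(members) >= 1)
  stopifnot(all(vapply(members, inherits, logical(1), "label_volume")))
  for (m in members) check_same_grid(members[[1]]$grid, m$grid)
  d <- dim(members[[1]]$grid)
  counts <- matrix(0L, prod(d), 6L)
  for (m in members)
    for (cl in 0:5) {
      hit <- as.vector(m$grid == cl)
      if (any(hit)) counts[hit, cl + 1L] <- counts[hit, cl + 1L] + 1L
    }
  lab <- max.col(counts, ties.method = "first") - 1L
  label_volume(array(as.integer(lab), dim = d), members[[1]]$spacing,
               members[[1]]$orientation)
}

#' Enumerate ensemble configurations from four base models
#'
#' All subsets of exactly four base members: the 4 singletons, the 6 pairs,
#' the 4 triples and the full quadruple -- 15 configurations in
#' deterministic lexicographic order, numbered with the singletons first,
#' then pairs, triples, and the full ensemble.
#'
#' @param base Character vector of exactly 4 member identifiers.
#' @param method Combination method recorded on each configuration.
#' @return Named list of `ensemble_spec` objects (fields `members`,
#'   `method`), names M1..M15.
#' @export
enumerate_ensembles <- function(base, method = "averaging") {
  if (length(base) == 1L)
    return(stats::setNames(list(structure(list(members = base,
                                               method = method),
                                          class = "ensemble_spec")), base))
  if (length(base) != 4L)
    stop("expected exactly 4 base member identifiers")
  specs <- list()
  for (k in 1:4) {
    sets <- utils::combn(base, k, simplify = FALSE)
    for (s in sets)
      specs[[length(specs) + 1L]] <-
        structure(list(members = s, method = method),
                  class = "ensemble_spec")
  }
  names(specs) <- sprintf("M%d", seq_along(specs))
  specs
}

#' Keep only the largest connected foreground component
#'
#' Connected components are computed on the union of all foreground classes
#' (labels 1-5) with 26-connectivity in 3D; every voxel outside the largest
#' component is relabelled to background (0), labels inside it are
#' untouched. This removes stray islands (e.g. arms labelled outside the
#' abdominal region) regardless of their class.
#'
#' @param vol A [label_volume()].
#' @return A post-processed [label_volume()]; an all-background input is
#'   returned unchanged with a warning.
#' @export
largest_component <- function(vol) {
  stopifnot(inherits(vol, "label_volume"))
  fg <- vol$grid > 0L
  if (!any(fg)) {
    warning("volume is all background; nothing to post-process")
    return(vol)
  }
  comp <- label_components(fg)
  sizes <- tabulate(comp[fg])
  keep <- which.max(sizes)
  grid <- vol$grid
  grid[fg & comp != keep] <- 0L
  label_volume(grid, vol$spacing, vol$orientation)
}

#' Label 26-connected components of a 3D mask
#'
#' Breadth-first flood fill with a vectorised frontier: each unvisited
#' foreground voxel seeds a new component which is grown layer by layer over
#' the 26-neighbourhood until exhausted.
#'
#' @param mask Logical 3D array.
#' @return Integer array of the same shape: 0 for background, component id
#'   1..K for foreground (components numbered in first-voxel order).
#' @export
label_components <- function(mask) {
  mask <- .as_mask(mask)
  d <- dim(mask)
  offs <- as.matrix(expand.grid(ox = -1:1, oy = -1:1, oz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  comp <- array(0L, dim = d)
  visited <- !mask
  fgidx <- which(mask)
  k <- 0L
  d12 <- d[1] * d[2]
  for (seed in fgidx) {
    if (visited[seed]) next
    k <- k + 1L
    visited[seed] <- TRUE
    comp[seed] <- k
    frontier <- seed
    while (length(frontier)) {
      i0 <- frontier - 1L
      ix <- i0 %% d[1] + 1L
      iy <- (i0 %/% d[1]) %% d[2] + 1L
      iz <- i0 %/% d12 + 1L
      nxt <- integer(0)
      for (o in seq_len(nrow(offs))) {
        jx <- ix + offs[o, 1]; jy <- iy + offs[o, 2]; jz <- iz + offs[o, 3]
        ok <- jx >= 1L & jx <= d[1] & jy >= 1L & jy <= d[2] &
              jz >= 1L & jz <= d[3]
        if (!any(ok)) next
        lin <- jx[ok] + (jy[ok] - 1L) * d[1] + (jz[ok] - 1L) * d12
        lin <- lin[!visited[lin]]
        if (!length(lin)) next
        visited[lin] <- TRUE
        nxt <- c(nxt, lin)
      }
      comp[nxt] <- k
      frontier <- nxt
    }
  }
  comp
}
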