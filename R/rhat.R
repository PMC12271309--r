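#' Split-chain Gelman-Rubin statistic
#'
#' Potential scale reduction factor computed on split chains: each chain is
#' halved, giving 2C segments of length n, and
#' rhat = sqrt( ((n-1)/n * W + B/n) / W ) with W the mean within-segment
#' variance and B = n * Var(segment means). Values near 1 indicate that the
#' chains have mixed; the conventional convergence bar used in this package
#' is rhat < 1.1.
#'
#' @param draws Matrix of posterior draws, iterations x chains (>= 2 chains
#'   after splitting, i.e. >= 8 draws per chain), or a 3D array
#'   iterations x chains x parameters.
#' @return For a matrix, the scalar rhat (`NA` flagged if the within
#'   variance is zero); for a 3D array, a named vector per parameter.
#' @export
gelman_rubin <- function(draws) {
  if (length(dim(draws)) == 3L) {
    out <- apply(draws, 3, gelman_rubin)
    return(out)
  }
  draws <- as.matrix(draws)
  n_iter <- nrow(draws)
  if (n_iter < 8L) stop("need at least 8 draws per chain to split")
  half <- n_iter %/% 2L
  segs <- do.call(cbind, lapply(seq_len(ncol(draws)), function(j)
    cbind(draws[seq_len(half), j],
          draws[(n_iter - half + 1L):n_iter, j])))
  n <- nrow(segs); m <- ncol(segs)
  mu <- colMeans(segs)
  W <- mean(apply(segs, 2, stats::var))
  if (W == 0) {
    if (stats::var(mu) == 0) return(structure(1, flag = "constant"))
    return(structure(NA_real_, flag = "zero_within_variance"))
  }
  B <- n * stats::var(mu)
  sqrt(((n - 1) / n * W + B / n) / W)
}
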