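# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All generators route randomness through
# this so results are bit-reproducible given (spec, seed).
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Counter-based fan-out: derive the k-th independent sub-seed from a master
# seed, staying inside the 32-bit signed range.
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 2654435761 + k * 40503) %% 2147483647)
}

# Shift a 3D array by integer offset (ox, oy, oz), padding with `fill`.
shift3d <- function(a, off, fill = 0L) {
  d <- dim(a)
  out <- array(fill, dim = d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    o <- off[ax]
    if (abs(o) >= d[ax]) return(out)
    if (o >= 0) { dst[[ax]] <- (1 + o):d[ax]; src[[ax]] <- 1:(d[ax] - o) }
    else        { dst[[ax]] <- 1:(d[ax] + o); src[[ax]] <- (1 - o):d[ax] }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

check_same_grid <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("grids are not aligned: dimensions differ")
  invisible(TRUE)
}
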