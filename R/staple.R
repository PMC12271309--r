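#' Binary STAPLE consensus (expectation-maximisation)
#'
#' Simultaneous truth and performance level estimation for J binary rater
#' decisions over the same grid. E-step: with prior foreground probability
#' pi, the voxel consensus weight is W_i = a_i / (a_i + b_i) with
#' a_i = pi * prod_j p_j^D_ij (1-p_j)^(1-D_ij) and
#' b_i = (1-pi) * prod_j (1-q_j)^D_ij q_j^(1-D_ij).
#' M-step: p_j = sum(W_i D_ij)/sum(W_i), q_j = sum((1-W_i)(1-D_ij)) /
#' sum(1-W_i). Iterates until max |delta W| < `tol`.
#'
#' @param decisions List of aligned logical/0-1 arrays (one per rater), or a
#'   voxel-by-rater 0/1 matrix.
#' @param prior Prior foreground probability pi in (0, 1); default is the
#'   empirical foreground fraction of the rater average.
#' @param tol Convergence tolerance on max |delta W| (default 1e-6).
#' @param max_iters Maximum EM iterations (default 100).
#' @param init_p,init_q Initial sensitivity/specificity for every rater
#'   (default 1 - 1e-5, i.e. near-perfect raters).
#' @return Object of class `staple_fit`: list with `W` (consensus weights,
#'   same shape as the input masks), `performance` (data frame rater, p
#'   sensitivity, q specificity), `iterations`, `converged`, `loglik`
#'   (trace), `prior`.
#' @export
staple_binary <- function(decisions, prior = NULL, tol = 1e-6,
                          max_iters = 100L, init_p = 1 - 1e-5,
                          init_q = 1 - 1e-5) {
  shp <- NULL
  if (is.list(decisions)) {
    stopifnot(length(decisions) >= 1)
    shp <- dim(decisions[[1]])
    for (d in decisions) check_same_grid(decisions[[1]], d)
    D <- vapply(decisions, function(m) as.numeric(m != 0),
                numeric(length(decisions[[1]])))
  } else {
    D <- as.matrix(decisions) * 1
  }
  V <- nrow(D); J <- ncol(D)
  fg <- mean(D)
  if (fg == 0 || fg == 1) {
    warning("degenerate rater stack (all-background or all-foreground); ",
            "falling back to majority vote")
    W <- rowMeans(D)
    return(.staple_result(W, shp,
                          data.frame(rater = seq_len(J), p = 1, q = 1),
                          0L, TRUE, numeric(0), fg))
  }
  if (is.null(prior)) prior <- fg
  if (prior <= 0 || prior >= 1) stop("prior must be in (0, 1)")
  eps <- 1e-7
  p <- rep(init_p, J)
  q <- rep(init_q, J)
  W <- rowMeans(D)
  loglik <- numeric(0)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iters)) {
    lp  <- pmin(pmax(p, eps), 1 - eps)
    lq  <- pmin(pmax(q, eps), 1 - eps)
    la <- log(prior)     + D %*% log(lp) + (1 - D) %*% log(1 - lp)
    lb <- log(1 - prior) + D %*% log(1 - lq) + (1 - D) %*% log(lq)
    m <- pmax(la, lb)
    a <- exp(la - m); b <- exp(lb - m)
    Wnew <- as.vector(a / (a + b))
    loglik <- c(loglik, sum(m + log(a + b)))
    p <- as.vector(crossprod(D, Wnew)) / sum(Wnew)
    q <- as.vector(crossprod(1 - D, 1 - Wnew)) / sum(1 - Wnew)
    if (max(abs(Wnew - W)) < tol) { W <- Wnew; converged <- TRUE; break }
    W <- Wnew
  }
  .staple_result(W, shp, data.frame(rater = seq_len(J), p = p, q = q),
                 it, converged, loglik, prior)
}

.staple_result <- function(W, shp, perf, it, converged, loglik, prior) {
  if (!is.null(shp)) W <- array(W, dim = shp)
  structure(list(W = W, performance = perf, iterations = it,
                 converged = converged, loglik = loglik, prior = prior),
            class = "staple_fit")
}

#' @export
print.staple_fit <- function(x, ...) {
  cat(sprintf("<staple_fit> %d raters, %d EM iterations (%s)\n",
              nrow(x$performance), x$iterations,
              if (x$converged) "converged" else "not converged"))
  print(x$performance, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Multi-class STAPLE consensus
#'
#' Runs binary STAPLE one-vs-rest for every foreground class (1-5) and
#' assigns each voxel to the class with the largest consensus weight;
#' background when every class weight is below 0.5. Exact ties break to the
#' lowest class index for determinism.
#'
#' @param stack List of aligned [label_volume()]s, one per rater (J >= 2
#'   recommended).
#' @param prior Optional per-class prior passed to [staple_binary()].
#' @param tol,max_iters EM controls, as in [staple_binary()].
#' @return List with `consensus` (a [label_volume()]), `performance` (data
#'   frame rater x class with p, q), and `fits` (per-class `staple_fit`s).
#' @export
staple_multiclass <- function(stack, prior = NULL, tol = 1e-6,
                              max_iters = 100L) {
  stopifnot(is.list(stack), length(stack) >= 1)
  stopifnot(all(vapply(stack, inherits, logical(1), "label_volume")))
  for (s in stack) check_same_grid(stack[[1]]$grid, s$grid)
  classes <- 1:5
  fits <- list()
  Wmat <- matrix(0, length(stack[[1]]$grid), length(classes))
  for (k in seq_along(classes)) {
    cl <- classes[k]
    masks <- lapply(stack, function(s) s$grid == cl)
    if (!any(vapply(masks, any, logical(1)))) {
      fits[[as.character(cl)]] <- NULL
      next
    }
    f <- staple_binary(masks, prior = prior, tol = tol,
                       max_iters = max_iters)
    fits[[as.character(cl)]] <- f
    Wmat[, k] <- as.vector(f$W)
  }
  best <- max.col(Wmat, ties.method = "first")
  lab <- ifelse(Wmat[cbind(seq_len(nrow(Wmat)), best)] >= 0.5,
                classes[best], 0L)
  cons <- label_volume(array(as.integer(lab), dim = dim(stack[[1]]$grid)),
                       stack[[1]]$spacing, stack[[1]]$orientation)
  perf <- do.call(rbind, lapply(names(fits), function(cl) {
    if (is.null(fits[[cl]])) return(NULL)
    cbind(class = as.integer(cl), fits[[cl]]$performance)
  }))
  list(consensus = cons, performance = perf, fits = fits)
}

#' Reader study: rank raters and models against the STAPLE consensus
#'
#' Builds the multi-class STAPLE consensus of the rater stack, then scores
#' every rater and every model output against it with class-wise DSC and
#' the reference-weighted mean, sorted in descending order of weighted mean
#' (rank 1 = best agreement with consensus).
#'
#' @param stack List of rater [label_volume()]s (named for labelling).
#' @param model_outputs Optional named list of model [label_volume()]s
#'   scored against the same consensus.
#' @param tau NSD tolerance passed through to [classwise_metrics()].
#' @return List with `consensus`, `table` (one row per rater/model: id,
#'   type, per-class DSC columns dsc_0..dsc_5, weighted_dsc, rank) and
#'   `n_slices` (axial slice count of the evaluated stack).
#' @export
reader_study <- function(stack, model_outputs = list(), tau = 2) {
  fit <- staple_multiclass(stack)
  cons <- fit$consensus
  ids <- names(stack)
  if (is.null(ids)) ids <- sprintf("H%d", seq_along(stack))
  mids <- names(model_outputs)
  if (length(model_outputs) && is.null(mids))
    mids <- sprintf("M%d", seq_along(model_outputs))
  all_vols <- c(stack, model_outputs)
  all_ids <- c(ids, mids)
  type <- c(rep("rater", length(stack)), rep("model", length(model_outputs)))
  rows <- lapply(seq_along(all_vols), function(i) {
    m <- classwise_metrics(all_vols[[i]], cons, tau = tau)
    r <- data.frame(id = all_ids[i], type = type[i],
                    stringsAsFactors = FALSE)
    for (cl in m$class) r[[paste0("dsc_", cl)]] <- m$dsc[m$class == cl]
    r$weighted_dsc <- attr(m, "weighted_dsc")
    r
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$weighted_dsc), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  list(consensus = cons, table = tab, n_slices = dim(cons$grid)[3])
}
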