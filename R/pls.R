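# NIPALS PLS2 regression. This is the projection engine behind the
# real-virtual cell pairing: a pair of these models (one per direction)
# forms the dual-PLS state-transition model.

# Fit a PLS2 regression Y ~ X with per-column centering (no scaling: the
# inputs are already log-normalized expression). Returns weights W, X
# loadings P, Y loadings C, the centers, the regression operator B, and the
# covariance captured per component.
fit_pls2 <- function(x, y, ncomp, tol = 1e-10, max_iter = 500L) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(nrow(x) == nrow(y))
  n <- nrow(x)
  xbar <- colMeans(x); ybar <- colMeans(y)
  xc <- sweep(x, 2, xbar); yc <- sweep(y, 2, ybar)
  px <- ncol(x); py <- ncol(y)
  max_rank <- min(n - 1L, px)
  if (ncomp > max_rank) {
    warn_named("ncomp reduced from %d to %d (rank limit)", ncomp, max_rank)
    ncomp <- max_rank
  }
  W <- matrix(0, px, ncomp); P <- matrix(0, px, ncomp)
  C <- matrix(0, py, ncomp); Tm <- matrix(0, n, ncomp)
  exp_cov <- numeric(ncomp)
  xscale <- sum(xc^2)
  a <- 0L
  for (comp in seq_len(ncomp)) {
    u <- yc[, which.max(colSums(yc^2))]
    if (sum(u^2) < tol * max(1, xscale)) break
    t_old <- rep(Inf, n)
    tt <- NULL
    for (it in seq_len(max_iter)) {
      w <- crossprod(xc, u)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-300) break
      w <- w / nw
      tt <- xc %*% w
      cc <- crossprod(yc, tt) / sum(tt^2)
      u <- yc %*% cc / sum(cc^2)
      if (sqrt(sum((tt - t_old)^2)) < tol * sqrt(sum(tt^2))) break
      t_old <- tt
    }
    if (is.null(tt) || sum(tt^2) < 1e-12 * max(1, xscale)) {
      warn_named("rank-deficient input: stopping at %d component(s)", a)
      break
    }
    p <- crossprod(xc, tt) / sum(tt^2)
    # covariance captured by this component (what PLS maximizes)
    exp_cov[comp] <- sum(crossprod(yc, tt)^2) / sum(tt^2)
    xc <- xc - tt %*% t(p)
    yc <- yc - tt %*% t(cc)
    W[, comp] <- w; P[, comp] <- p; C[, comp] <- cc; Tm[, comp] <- tt
    a <- comp
  }
  if (a == 0L) stop_named("PLS fit failed: input has no usable variation")
  W <- W[, seq_len(a), drop = FALSE]; P <- P[, seq_len(a), drop = FALSE]
  C <- C[, seq_len(a), drop = FALSE]
  B <- W %*% solve(crossprod(P, W), t(C))
  list(xbar = xbar, ybar = ybar, W = W, P = P, C = C, B = B,
       ncomp = a, explained_cov = exp_cov[seq_len(a)])
}

predict_pls2 <- function(model, xnew) {
  xnew <- as.matrix(xnew)
  sweep(sweep(xnew, 2, model$xbar) %*% model$B, 2, model$ybar, "+")
}

#' Fit the dual PLS state-transition model
#'
#' Fits two directed PLS2 regressions on pseudo-paired cells: A cells onto
#' their B-space pseudo-partners (direction A to B) and B cells onto their
#' A-space pseudo-partners (B to A). Each model projects a measured cell
#' into the other condition's expression space, yielding its virtual
#' counterpart.
#'
#' @param pairs output of [build_pseudo_pairs()].
#' @param params an [scstar_params] (uses `n_components`).
#' @return An object of class `dual_pls_model` holding both directed
#'   models and the per-component captured covariance.
#' @export
fit_dual_pls <- function(pairs, params = scstar_params()) {
  ncomp <- params$n_components
  if (nrow(pairs$a$x) <= ncomp || nrow(pairs$b$x) <= ncomp)
    ncomp <- max(1L, min(nrow(pairs$a$x), nrow(pairs$b$x)) - 1L)
  structure(list(
    ab = fit_pls2(pairs$a$x, pairs$a$y, ncomp),
    ba = fit_pls2(pairs$b$x, pairs$b$y, ncomp),
    genes = colnames(pairs$a$x)
  ), class = "dual_pls_model")
}

#' Project cells into the counterpart condition's space
#'
#' @param profiles cells x genes matrix in the model's gene space.
#' @param model a [fit_dual_pls()] model.
#' @param direction `"ab"` (A-condition cells projected into B space) or
#'   `"ba"`.
#' @return Matrix of virtual counterpart profiles, same shape as input.
#' @export
project_virtual <- function(profiles, model, direction = c("ab", "ba")) {
  direction <- match.arg(direction)
  profiles <- as.matrix(profiles)
  if (!is.null(model$genes) && !is.null(colnames(profiles)) &&
      !identical(colnames(profiles), model$genes))
    stop_named("gene space of the input does not match the model")
  if (ncol(profiles) != nrow(model[[direction]]$B))
    stop_named("input has %d genes but the model expects %d",
               ncol(profiles), nrow(model[[direction]]$B))
  predict_pls2(model[[direction]], profiles)
}
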