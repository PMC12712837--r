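#' Soft-thresholding operator
#'
#' Elementwise `sign(w) * max(|w| - delta, 0)`, the shrinkage operator at
#' the heart of the penalized rank-1 SVD.
#'
#' @param w numeric vector.
#' @param delta nonnegative threshold.
#' @return Thresholded vector.
#' @export
soft_threshold <- function(w, delta) {
  stopifnot(delta >= 0)
  sign(w) * pmax(abs(w) - delta, 0)
}

#' Joint L1/L2 projection of a weight vector
#'
#' Returns the unit-L2-norm soft-thresholded version of `w` whose L1 norm
#' meets the sparsity budget `c`: the threshold is 0 when the plainly
#' normalized vector already satisfies the budget, otherwise found by
#' bisection on `[0, max|w_j|]` so that the result's L1 norm equals `c`
#' within `tol`. Budgets live on the standard penalized-matrix-decomposition
#' scale: `c = 1` forces a single nonzero entry, `c = sqrt(length(w))`
#' deactivates the constraint.
#'
#' @param w nonzero numeric vector.
#' @param c L1 budget in `[1, sqrt(length(w))]`.
#' @param tol bisection tolerance on the achieved L1 norm.
#' @return Unit-norm vector with `sum(abs(.)) <= c + tol`.
#' @export
l1_l2_project <- function(w, c, tol = 1e-6) {
  if (c < 1 - 1e-12 || c > sqrt(length(w)) + 1e-12)
    stop("l1_l2_project: budget must lie in [1, sqrt(length(w))]")
  if (all(w == 0) || !any(is.finite(w) & w != 0))
    stop("l1_l2_project: input vector is numerically zero")
  drop(.l1l2_project_cpp(as.numeric(w), c, tol))
}

# Pure-R mirror of the C++ projection, used as an engine cross-check.
l1_l2_project_r <- function(w, c, tol = 1e-6) {
  nrm <- sqrt(sum(w^2))
  if (nrm <= 0) stop("l1_l2_project: input vector is numerically zero")
  u <- w / nrm
  if (sum(abs(u)) <= c + tol) return(u)
  if (c <= 1 + 1e-12) {
    s <- numeric(length(w))
    j <- which.max(abs(w))
    s[j] <- sign(w[j])
    return(s)
  }
  lo <- 0; hi <- max(abs(w)); s <- u
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    st <- soft_threshold(w, mid)
    n2 <- sqrt(sum(st^2))
    l1 <- if (n2 > 0) sum(abs(st)) / n2 else 0
    if (n2 <= 0 || l1 < c) hi <- mid else lo <- mid
    if (n2 > 0) s <- st / n2
    if (abs(l1 - c) <= tol && n2 > 0) break
    if (hi - lo < 1e-15 * (1 + hi)) break
  }
  s
}

# Leading right singular vector of M. For wide M (p << q) the eigen
# decomposition of the small p x p Gram matrix is much cheaper than a
# direct SVD; the result differs from it only by an irrelevant global sign.
leading_right_sv <- function(M) {
  if (nrow(M) <= ncol(M)) {
    e <- eigen(tcrossprod(M), symmetric = TRUE)
    v0 <- drop(crossprod(M, e$vectors[, 1]))
    n <- sqrt(sum(v0^2))
    if (n > 0) return(v0 / n)
  }
  svd(M, nu = 0, nv = 1)$v[, 1]
}

#' Construct a sparsity-budget grid
#'
#' Geometric grids of L1 budgets for both views on the standard
#' `[1, sqrt(dim)]` scale, crossed into a joint search grid.
#'
#' @param p,q blood and brain feature counts.
#' @param n_u,n_v grid sizes per view (default 8 x 8).
#' @return `data.frame` with columns `c_u`, `c_v`.
#' @export
budget_grid <- function(p, q, n_u = 8, n_v = 8) {
  gu <- exp(seq(0, log(sqrt(p)), length.out = n_u))
  gv <- exp(seq(0, log(sqrt(q)), length.out = n_v))
  expand.grid(c_u = gu, c_v = gv, KEEP.OUT.ATTRS = FALSE)
}

# Rank-1 fit from a precomputed cross-product matrix M = t(X) %*% Y.
# Initialization: leading right singular vector of M (deterministic);
# callers fitting many budgets on the same M pass it precomputed.
spls_rank1_m <- function(M, c_u, c_v, tol = 1e-6, max_iter = 200,
                         engine = c("cpp", "R"), v0 = NULL) {
  engine <- match.arg(engine)
  if (is.null(v0)) v0 <- leading_right_sv(M)
  if (engine == "cpp") {
    fit <- .spls_rank1_cpp(M, c_u, c_v, v0, tol, as.integer(max_iter))
    fit$u <- drop(fit$u); fit$v <- drop(fit$v)
  } else {
    v <- v0; u <- NULL; obj <- -Inf; converged <- FALSE; monotone <- TRUE
    for (iter in seq_len(max_iter)) {
      u_new <- l1_l2_project_r(drop(M %*% v), c_u)
      v_new <- l1_l2_project_r(drop(crossprod(M, u_new)), c_v)
      obj_new <- drop(u_new %*% M %*% v_new)
      if (obj_new < obj - 1e-10 * (1 + abs(obj))) monotone <- FALSE
      du <- if (is.null(u)) Inf else max(abs(u_new - u))
      dv <- max(abs(v_new - v))
      u <- u_new; v <- v_new; obj <- obj_new
      if (du < tol && dv < tol) { converged <- TRUE; break }
    }
    jmax <- which.max(abs(u))
    if (u[jmax] < 0) { u <- -u; v <- -v }
    fit <- list(u = u, v = v, objective = obj, n_iter = iter,
                converged = converged, monotone = monotone)
  }
  if (!fit$converged)
    warning(sprintf("spls rank-1 fit did not converge in %d iterations", max_iter))
  if (!fit$monotone)
    warning("spls rank-1 objective decreased during alternation (numerical issue)")
  structure(fit[c("u", "v", "objective", "n_iter", "converged")],
            budget = c(c_u = c_u, c_v = c_v), class = "weight_pair")
}

#' Fit one sparse weight-vector pair (penalized rank-1 SVD)
#'
#' Alternating maximization of `t(u) %*% M %*% v` with `M = t(X) %*% Y`,
#' each weight vector constrained to unit L2 norm and an L1 budget.
#' Each half-step solves its constrained subproblem exactly via
#' [l1_l2_project()], so the objective is non-decreasing. Initialization is
#' the leading right singular vector of `M` (deterministic); the fitted
#' pair is sign-flipped jointly so the largest-magnitude blood weight is
#' positive. Convergence is declared when the max-abs change of both
#' vectors falls below `tol`; non-convergence yields a warning, not an
#' error.
#'
#' At inactive budgets (`c_u = sqrt(p)`, `c_v = sqrt(q)`) the fit equals
#' the leading singular vector pair of `M` and the objective its top
#' singular value.
#'
#' @param X,Y row-aligned preprocessed views (complete, standardized).
#' @param c_u,c_v L1 budgets (see [budget_grid()]).
#' @param tol convergence tolerance on weight change.
#' @param max_iter maximum alternation sweeps.
#' @param engine `"cpp"` (default) or the pure-R reference `"R"`.
#' @return A `weight_pair`: list with `u`, `v`, `objective`, `n_iter`,
#'   `converged`.
#' @export
fit_rank1 <- function(X, Y, c_u = sqrt(ncol(X)), c_v = sqrt(ncol(Y)),
                      tol = 1e-6, max_iter = 200, engine = c("cpp", "R")) {
  stopifnot(nrow(X) == nrow(Y))
  fit <- spls_rank1_m(crossprod(X, Y), c_u, c_v, tol, max_iter,
                      engine = match.arg(engine))
  names(fit$u) <- colnames(X); names(fit$v) <- colnames(Y)
  fit
}

#' @export
print.weight_pair <- function(x, ...) {
  b <- attr(x, "budget")
  cat(sprintf(
    "SPLS weight pair: %d/%d nonzero blood, %d/%d nonzero brain\n",
    sum(x$u != 0), length(x$u), sum(x$v != 0), length(x$v)))
  cat(sprintf("  objective %.4g, budgets (c_u=%.3g, c_v=%.3g), %d iter%s\n",
              x$objective, b["c_u"], b["c_v"], x$n_iter,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Latent scores of a view under a weight vector
#'
#' One score per participant: the matrix-vector product of the view with
#' the weight vector. The correlation between a blood and a brain latent
#' score vector is the strength of the corresponding LV.
#'
#' @param view numeric matrix (participants x features).
#' @param w weight vector of length `ncol(view)`.
#' @return Numeric score vector.
#' @export
latent_scores <- function(view, w) {
  if (ncol(view) != length(w))
    stop(sprintf("latent_scores: dimension mismatch (%d features vs %d weights)",
                 ncol(view), length(w)))
  drop(view %*% w)
}

#' Projection deflation of a view
#'
#' Removes an extracted component: `X <- X (I - w w')` with unit-norm `w`,
#' after which the view's scores on `w` are exactly zero. Idempotent and
#' rank-reducing by one for generic matrices.
#'
#' @param view numeric matrix.
#' @param w unit-L2-norm weight vector.
#' @return Deflated matrix.
#' @export
deflate <- function(view, w) {
  if (abs(sqrt(sum(w^2)) - 1) > 1e-8)
    stop("deflate: weight vector must have unit L2 norm")
  view - (view %*% w) %*% t(w)
}
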