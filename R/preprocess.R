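#' @title Fold-safe preprocessing: standardization, imputation, harmonization
#' @description All preprocessing follows strict fit-on-train /
#'   apply-on-test semantics: `fit_*` functions see only the training
#'   partition and return an immutable state object; `apply_*` functions
#'   transform any data with the stored training parameters. This is what
#'   keeps the nested cross-validation free of test-fold leakage.
#' @name preprocess
NULL

new_preproc_state <- function(type, ...) {
  structure(list(type = type, ...), class = "preproc_state")
}

# n x q matrix whose every row is v (fast BLAS-backed broadcast)
rowmat <- function(v, n) tcrossprod(rep(1, n), as.numeric(v))

#' @export
print.preproc_state <- function(x, ...) {
  cat(sprintf("preproc_state <%s> (%d features)\n", x$type,
              length(x$center %||% x$values %||% x$sigma %||% numeric(0))))
  invisible(x)
}

#' Fit / apply column standardization
#'
#' `fit_standardize()` records per-column means and standard deviations of
#' the training view (ignoring missing cells); `apply_standardize()`
#' z-scores any view with those training parameters. Zero-variance training
#' columns are flagged with a warning and map to all-zero columns.
#'
#' @param view numeric matrix, participants in rows.
#' @param state a state from `fit_standardize()`.
#' @return `fit_standardize()`: a `preproc_state`; `apply_standardize()`:
#'   the transformed matrix.
#' @export
fit_standardize <- function(view) {
  n_ok <- colSums(!is.na(view))
  if (any(n_ok < 2)) {
    bad <- colnames(view)[n_ok < 2] %||% which(n_ok < 2)
    stop("fit_standardize: column(s) with fewer than 2 non-missing values: ",
         paste(bad, collapse = ", "))
  }
  center <- colMeans(view, na.rm = TRUE)
  scale <- if (anyNA(view)) apply(view, 2, sd, na.rm = TRUE) else
    sqrt(pmax((colSums(view^2) - nrow(view) * center^2) /
                (nrow(view) - 1), 0))
  if (any(scale == 0)) {
    bad <- colnames(view)[scale == 0] %||% which(scale == 0)
    warning("fit_standardize: zero-variance column(s) mapped to zeros: ",
            paste(bad, collapse = ", "))
  }
  new_preproc_state("standardize", center = center, scale = scale)
}

#' @rdname fit_standardize
#' @export
apply_standardize <- function(state, view) {
  stopifnot(inherits(state, "preproc_state"), state$type == "standardize",
            ncol(view) == length(state$center))
  s <- ifelse(state$scale == 0, 1, state$scale)
  n <- nrow(view)
  out <- view * rowmat(1 / s, n) - rowmat(state$center / s, n)
  if (any(state$scale == 0)) out[, state$scale == 0] <- 0
  out
}

#' Fit / apply median imputation
#'
#' `fit_impute()` records training-fold column medians; columns with more
#' than 20% training missingness are rejected, mirroring the cohort
#' inclusion rule that allowed at most 20% missing data per participant
#' record. `apply_impute()` replaces missing cells by the stored medians.
#'
#' @param view numeric matrix with possible `NA` cells.
#' @param state a state from `fit_impute()`.
#' @param max_missing maximum tolerated per-column training missing
#'   fraction (default 0.2).
#' @return `fit_impute()`: a `preproc_state`; `apply_impute()`: the
#'   completed matrix.
#' @export
fit_impute <- function(view, max_missing = 0.2) {
  frac <- colMeans(is.na(view))
  if (any(frac > max_missing)) {
    bad <- colnames(view)[frac > max_missing] %||% which(frac > max_missing)
    stop(sprintf(paste0("fit_impute: column(s) exceed the %.0f%% missingness",
                        " inclusion bound (at most 20%% missing allowed): %s"),
                 100 * max_missing, paste(bad, collapse = ", ")))
  }
  values <- apply(view, 2, median, na.rm = TRUE)
  new_preproc_state("impute", values = values)
}

#' @rdname fit_impute
#' @export
apply_impute <- function(state, view) {
  stopifnot(inherits(state, "preproc_state"), state$type == "impute",
            ncol(view) == length(state$values))
  for (j in which(colSums(is.na(view)) > 0))
    view[is.na(view[, j]), j] <- state$values[j]
  view
}

#' Fit / apply multi-site ComBat harmonization
#'
#' Location/scale batch adjustment of the brain view for scanner/site
#' effects, with parametric empirical-Bayes shrinkage of the per-site
#' parameters (ComBat). Fitted on training data only; `apply_harmonize()`
#' adjusts any data with the stored estimates. Covariates (for instance
#' diagnostic group) can be preserved: their effects are removed before
#' site estimation and restored afterwards.
#'
#' Test participants from a site unseen in training are passed through
#' unadjusted with a warning. A single-site fit is a no-op with a warning
#' (there is nothing to harmonize).
#'
#' @param brain numeric matrix (participants x voxels), complete.
#' @param site character/factor site labels, one per row.
#' @param covar optional data.frame of covariates to preserve (fit and
#'   apply must use the same columns).
#' @param eb logical: apply empirical-Bayes shrinkage (default `TRUE`).
#' @param keep_adjusted also return the harmonized training data as
#'   attribute `"adjusted"` (avoids a redundant pass when fitting and
#'   transforming the same partition).
#' @param state a state from `fit_harmonize()`.
#' @return `fit_harmonize()`: a `preproc_state`; `apply_harmonize()`: the
#'   harmonized matrix.
#' @export
fit_harmonize <- function(brain, site, covar = NULL, eb = TRUE,
                          keep_adjusted = FALSE) {
  site <- as.character(site)
  stopifnot(nrow(brain) == length(site))
  levels <- sort(unique(site))
  if (length(levels) < 2) {
    warning("fit_harmonize: single site in training data; harmonization is a no-op")
    return(new_preproc_state("harmonize", no_op = TRUE, site_levels = levels))
  }
  tab <- table(site)
  if (any(tab < 2))
    stop("fit_harmonize: every training site needs at least 2 participants")
  n <- nrow(brain); q <- ncol(brain)
  site_f <- factor(site, levels = levels)
  B <- model.matrix(~ 0 + site_f)
  C <- if (!is.null(covar)) {
    stopifnot(nrow(covar) == n)
    stats::model.matrix(~ ., data = as.data.frame(covar))[, -1, drop = FALSE]
  } else NULL
  D <- cbind(B, C)
  beta <- tryCatch(solve(crossprod(D), crossprod(D, brain)),
                   error = function(e) {
                     b <- qr.coef(qr(D), brain)
                     b[is.na(b)] <- 0
                     b
                   })
  beta_site <- beta[seq_along(levels), , drop = FALSE]
  beta_cov <- if (!is.null(C)) beta[-seq_along(levels), , drop = FALSE] else NULL
  alpha <- drop(crossprod(as.numeric(tab[levels]) / n, beta_site))
  resid <- brain - D %*% beta
  sigma2 <- colSums(resid^2) / n
  sigma <- sqrt(pmax(sigma2, 1e-12))

  cov_part <- if (!is.null(C)) C %*% beta_cov else 0
  Z <- (brain - cov_part) * rowmat(1 / sigma, n) - rowmat(alpha / sigma, n)
  gamma_hat <- rowsum(Z, site_f) / as.numeric(tab[levels])
  # per-site variance of Z around the site mean
  delta2_hat <- t(sapply(levels, function(s) {
    zs <- Z[site_f == s, , drop = FALSE]
    pmax((colSums(zs^2) - nrow(zs) * gamma_hat[s, ]^2) / (nrow(zs) - 1), 0)
  }))

  if (eb) {
    post <- lapply(levels, function(s) {
      eb_site_posterior(Z[site_f == s, , drop = FALSE],
                        gamma_hat[s, ], delta2_hat[s, ])
    })
    gamma_star <- do.call(rbind, lapply(post, `[[`, "gamma"))
    delta2_star <- do.call(rbind, lapply(post, `[[`, "delta2"))
    rownames(gamma_star) <- rownames(delta2_star) <- levels
  } else {
    gamma_star <- gamma_hat
    delta2_star <- delta2_hat
  }
  state <- new_preproc_state("harmonize", no_op = FALSE, site_levels = levels,
                    alpha = alpha, sigma = sigma, beta_cov = beta_cov,
                    covar_template = if (!is.null(covar)) colnames(as.data.frame(covar)) else NULL,
                    gamma_star = gamma_star, delta2_star = delta2_star,
                    eb = eb)
  if (keep_adjusted) {
    adj <- brain
    for (s in levels) {
      idx <- which(site == s)
      ns <- length(idx)
      a <- 1 / sqrt(pmax(delta2_star[s, ], 1e-12))
      zadj <- (Z[idx, , drop = FALSE] - rowmat(gamma_star[s, ], ns)) *
        rowmat(a, ns)
      adj[idx, ] <- zadj * rowmat(sigma, ns) + rowmat(alpha, ns)
    }
    if (!identical(cov_part, 0)) adj <- adj + cov_part
    attr(state, "adjusted") <- adj
  }
  state
}

# Parametric empirical-Bayes posteriors for one site's location (normal
# prior across features) and scale (inverse-gamma prior, moment-matched),
# solved by the standard fixed-point iteration.
eb_site_posterior <- function(Zs, g_hat, d2_hat, tol = 1e-4, max_iter = 50) {
  ns <- nrow(Zs)
  g_bar <- mean(g_hat); t2 <- var(g_hat)
  m <- mean(d2_hat); s2 <- var(d2_hat)
  a_prior <- (2 * s2 + m^2) / s2
  b_prior <- (m * s2 + m^3) / s2
  g_new <- g_hat; d2_new <- d2_hat
  ss_fixed <- colSums(Zs^2); cs <- colSums(Zs)
  for (it in seq_len(max_iter)) {
    g_old <- g_new; d2_old <- d2_new
    g_new <- (t2 * ns * g_hat + d2_new * g_bar) / (t2 * ns + d2_new)
    sse <- ss_fixed - 2 * g_new * cs + ns * g_new^2
    d2_new <- (0.5 * sse + b_prior) / (ns / 2 + a_prior - 1)
    if (max(abs(g_new - g_old)) < tol && max(abs(d2_new - d2_old)) < tol)
      break
  }
  list(gamma = g_new, delta2 = d2_new)
}

#' @rdname fit_harmonize
#' @export
apply_harmonize <- function(state, brain, site, covar = NULL) {
  stopifnot(inherits(state, "preproc_state"), state$type == "harmonize")
  if (isTRUE(state$no_op)) return(brain)
  site <- as.character(site)
  stopifnot(nrow(brain) == length(site))
  known <- site %in% state$site_levels
  if (!all(known))
    warning("apply_harmonize: participants from unseen site(s) passed through unadjusted: ",
            paste(unique(site[!known]), collapse = ", "))
  cov_part <- if (!is.null(state$beta_cov)) {
    stopifnot(!is.null(covar))
    C <- stats::model.matrix(~ ., data = as.data.frame(covar))[, -1, drop = FALSE]
    C %*% state$beta_cov
  } else 0
  out <- brain
  # the full adjustment collapses to a per-site affine map
  #   out = (x - cov) * a_s + b_s + cov,  a_s = 1/sqrt(delta2*_s),
  #   b_s = alpha (1 - a_s) - gamma*_s sigma a_s
  for (s in intersect(unique(site), state$site_levels)) {
    idx <- which(site == s)
    ns <- length(idx)
    a <- 1 / sqrt(pmax(state$delta2_star[s, ], 1e-12))
    b <- state$alpha * (1 - a) - state$gamma_star[s, ] * state$sigma * a
    A <- rowmat(a, ns)
    adj <- brain[idx, , drop = FALSE] * A + rowmat(b, ns)
    if (!identical(cov_part, 0))
      adj <- adj + cov_part[idx, , drop = FALSE] * (1 - A)
    out[idx, ] <- adj
  }
  out
}

#' Fit / apply the full per-fold preprocessing pipeline
#'
#' Composite of the module's three steps in the order impute (blood) ->
#' harmonize (brain) -> standardize (both). Harmonization assumes complete
#' data, and standardization comes last so the SPLS input is unit scale.
#'
#' @param blood,brain training-partition views.
#' @param site optional site labels (enables harmonization of the brain
#'   view when more than one site is present).
#' @param group optional diagnostic-group labels preserved as a covariate
#'   during harmonization.
#' @param harmonize,eb,impute switches for the respective steps.
#' @param state a state from `fit_preprocess()`.
#' @return `fit_preprocess()`: a `preproc_state` of type `"pipeline"`;
#'   `apply_preprocess()`: `list(blood =, brain =)` transformed matrices.
#' @export
fit_preprocess <- function(blood, brain, site = NULL, group = NULL,
                           harmonize = !is.null(site), eb = TRUE,
                           impute = TRUE) {
  st <- list()
  if (impute && anyNA(blood)) {
    st$blood_impute <- fit_impute(blood)
    blood <- apply_impute(st$blood_impute, blood)
  }
  if (anyNA(brain)) {
    st$brain_impute <- fit_impute(brain)
    brain <- apply_impute(st$brain_impute, brain)
  }
  if (harmonize && !is.null(site)) {
    covar <- if (!is.null(group)) data.frame(group = factor(group)) else NULL
    st$brain_harmonize <- fit_harmonize(brain, site, covar = covar, eb = eb,
                                        keep_adjusted = TRUE)
    brain <- attr(st$brain_harmonize, "adjusted")
    attr(st$brain_harmonize, "adjusted") <- NULL
  }
  st$blood_scale <- fit_standardize(blood)
  st$brain_scale <- fit_standardize(brain)
  state <- new_preproc_state("pipeline", steps = st,
                             has_group_covar = harmonize && !is.null(group))
  # transformed training partition as a by-product of the fit
  attr(state, "train") <- list(blood = apply_standardize(st$blood_scale, blood),
                               brain = apply_standardize(st$brain_scale, brain))
  state
}

#' @rdname fit_preprocess
#' @export
apply_preprocess <- function(state, blood, brain, site = NULL, group = NULL) {
  stopifnot(inherits(state, "preproc_state"), state$type == "pipeline")
  st <- state$steps
  if (!is.null(st$blood_impute)) blood <- apply_impute(st$blood_impute, blood)
  if (!is.null(st$brain_impute)) brain <- apply_impute(st$brain_impute, brain)
  if (!is.null(st$brain_harmonize)) {
    covar <- if (state$has_group_covar) data.frame(group = factor(group)) else NULL
    brain <- apply_harmonize(st$brain_harmonize, brain, site, covar = covar)
  }
  list(blood = apply_standardize(st$blood_scale, blood),
       brain = apply_standardize(st$brain_scale, brain))
}
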