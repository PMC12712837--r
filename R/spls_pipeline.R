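#' Control parameters for the SPLS nested cross-validation
#'
#' @param n_outer,n_inner outer and inner fold counts (default 10/10).
#' @param tol,max_iter rank-1 fit convergence knobs.
#' @param harmonize harmonize the brain view per fold when site labels are
#'   available.
#' @param eb empirical-Bayes shrinkage in harmonization.
#' @param agg aggregation of out-of-fold correlations: plain `"mean"`
#'   (default) or `"fisher"` (Fisher-z averaging).
#' @param br_threshold bootstrap-ratio magnitude marking a feature stable.
#' @param engine rank-1 fit engine, `"cpp"` or `"R"`.
#' @param reselect_perm rerun inner budget selection inside every
#'   permutation (`TRUE`) or reuse the per-fold budgets selected on the
#'   observed data (default `FALSE`; see the methods vignette).
#' @return A list of class `spls_control`.
#' @export
spls_control <- function(n_outer = 10, n_inner = 10, tol = 1e-6,
                         max_iter = 200, harmonize = TRUE, eb = TRUE,
                         agg = c("mean", "fisher"), br_threshold = 2,
                         engine = c("cpp", "R"), reselect_perm = FALSE) {
  structure(list(n_outer = n_outer, n_inner = n_inner, tol = tol,
                 max_iter = max_iter, harmonize = harmonize, eb = eb,
                 agg = match.arg(agg), br_threshold = br_threshold,
                 engine = match.arg(engine),
                 reselect_perm = reselect_perm), class = "spls_control")
}

agg_rho <- function(rho, agg) {
  if (agg == "fisher") {
    z <- atanh(pmin(pmax(rho, -1 + 1e-12), 1 - 1e-12))
    tanh(mean(z))
  } else mean(rho)
}

#' Group-stratified cross-validation folds
#'
#' Every participant lands in exactly one outer test fold; within each
#' stratification group the fold sizes differ by at most one, so per-fold
#' group proportions track the global proportions to within one
#' participant. Deterministic for a fixed seed. Inner folds are derived
#' per outer-train partition from the same seed.
#'
#' @param groups stratification labels (diagnostic group), one per
#'   participant.
#' @param n_outer,n_inner fold counts.
#' @param seed integer seed.
#' @return A `fold_scheme`: list with `outer` (fold index per participant),
#'   `n_outer`, `n_inner`, `strata`, `seed`.
#' @export
make_stratified_folds <- function(groups, n_outer = 10, n_inner = 10,
                                  seed = 1) {
  groups <- as.factor(groups)
  tab <- table(groups)
  if (any(tab < n_outer))
    stop("make_stratified_folds: group(s) smaller than the fold count: ",
         paste(names(tab)[tab < n_outer], collapse = ", "))
  outer <- integer(length(groups))
  with_local_seed(derive_seed(seed, 17), {
    for (g in levels(groups)) {
      idx <- which(groups == g)
      outer[idx] <- sample(rep_len(seq_len(n_outer), length(idx)))
    }
  })
  structure(list(outer = outer, n_outer = n_outer, n_inner = n_inner,
                 strata = groups, seed = as.integer(seed)),
            class = "fold_scheme")
}

# Preprocess one outer fold (fit on train only) and apply any accumulated
# deflation vectors to both partitions of both views.
prep_fold <- function(blood, brain, tr, te, site, group, deflate_uv,
                      control) {
  st <- fit_preprocess(blood[tr, , drop = FALSE], brain[tr, , drop = FALSE],
                       site = site[tr], group = group[tr],
                       harmonize = control$harmonize && !is.null(site),
                       eb = control$eb)
  train <- attr(st, "train")
  attr(st, "train") <- NULL
  test <- apply_preprocess(st, blood[te, , drop = FALSE],
                           brain[te, , drop = FALSE],
                           site = site[te], group = group[te])
  out <- list(Xtr = train$blood, Ytr = train$brain,
              Xte = test$blood, Yte = test$brain, state = st)
  if (!is.null(deflate_uv)) {
    for (k in seq_len(ncol(deflate_uv$U))) {
      out$Xtr <- deflate(out$Xtr, deflate_uv$U[, k])
      out$Xte <- deflate(out$Xte, deflate_uv$U[, k])
      out$Ytr <- deflate(out$Ytr, deflate_uv$V[, k])
      out$Yte <- deflate(out$Yte, deflate_uv$V[, k])
    }
  }
  out
}

safe_cor <- function(a, b, what = "fold") {
  if (sd(a) == 0 || sd(b) == 0) {
    warning(sprintf("degenerate %s: zero-variance latent scores, correlation set to 0",
                    what))
    return(0)
  }
  as.numeric(cor(a, b))
}

#' Select sparsity budgets by inner cross-validation
#'
#' For every inner fold the full preprocessing is refit on the inner-train
#' partition, every grid point is fit, and the absolute out-of-sample
#' latent-score correlation recorded. The grid point with the highest mean
#' inner-test |correlation| wins; ties break toward sparser budgets
#' (smaller `c_u + c_v`), then lexicographically.
#'
#' @param blood,brain raw training-partition views.
#' @param strata stratification labels for the inner folds.
#' @param grid budget grid ([budget_grid()]).
#' @param seed integer seed for the inner fold split.
#' @param site,group optional labels for harmonization.
#' @param deflate_uv optional list `(U =, V =)` of previously extracted
#'   weight vectors (columns) to project out.
#' @param control [spls_control()].
#' @return List with `budget` (one grid row), `score` (mean inner-test
#'   |correlation| per grid point) and `covariance` (mean inner-test
#'   |covariance| of the latent scores per grid point).
#' @export
select_budget <- function(blood, brain, strata, grid, seed = 1,
                          site = NULL, group = NULL, deflate_uv = NULL,
                          control = spls_control()) {
  if (is.null(grid) || nrow(grid) == 0)
    stop("configuration error: empty budget grid")
  if (nrow(grid) == 1)
    return(list(budget = grid[1, ], score = NA_real_,
                covariance = NA_real_))
  inner <- make_stratified_folds(strata, n_outer = control$n_inner,
                                 n_inner = 1, seed = seed)
  score <- covar <- matrix(NA_real_, control$n_inner, nrow(grid))
  for (f in seq_len(control$n_inner)) {
    tr <- inner$outer != f; te <- !tr
    pf <- prep_fold(blood, brain, tr, te, site, group, deflate_uv, control)
    M <- crossprod(pf$Xtr, pf$Ytr)
    v0 <- leading_right_sv(M)
    for (g in seq_len(nrow(grid))) {
      fit <- suppressWarnings(
        spls_rank1_m(M, grid$c_u[g], grid$c_v[g], control$tol,
                     control$max_iter, engine = control$engine, v0 = v0))
      sx <- pf$Xte %*% fit$u; sy <- pf$Yte %*% fit$v
      score[f, g] <- abs(safe_cor(sx, sy, "inner fold"))
      covar[f, g] <- abs(cov(sx, sy))
    }
  }
  mean_score <- colMeans(score)
  cand <- which(mean_score >= max(mean_score) - 1e-12)
  cand <- cand[order(grid$c_u[cand] + grid$c_v[cand], grid$c_u[cand],
                     grid$c_v[cand])]
  list(budget = grid[cand[1], ], score = mean_score,
       covariance = colMeans(covar))
}

#' Evaluate one latent variable by nested cross-validation
#'
#' For each outer fold: preprocessing is fit on the outer-train partition,
#' budgets are selected on inner folds (when the grid has more than one
#' point), the weight pair is refit on the outer-train data, and the
#' out-of-sample correlation between the blood and brain latent scores is
#' computed on the outer-test fold. The reported statistic is the
#' aggregated out-of-fold correlation.
#'
#' @inheritParams select_budget
#' @param scheme a [make_stratified_folds()] scheme.
#' @param fixed_budgets optional data.frame of per-outer-fold budgets
#'   (columns `c_u`, `c_v`), bypassing inner selection.
#' @return List of class `lv_evaluation`: `rho_test`, `fold_rho`,
#'   `fold_budgets`, `fold_fits` (weight pairs per fold).
#' @export
evaluate_lv <- function(blood, brain, scheme, grid, site = NULL,
                        group = NULL, deflate_uv = NULL,
                        control = spls_control(), fixed_budgets = NULL) {
  n_outer <- scheme$n_outer
  fold_rho <- numeric(n_outer)
  fold_budgets <- data.frame(c_u = numeric(n_outer), c_v = numeric(n_outer))
  fold_fits <- vector("list", n_outer)
  fold_scores <- fold_covariance <- NULL
  for (f in seq_len(n_outer)) {
    tr <- scheme$outer != f; te <- !tr
    pf <- prep_fold(blood, brain, tr, te, site, group, deflate_uv, control)
    if (!is.null(fixed_budgets)) {
      budget <- fixed_budgets[f, ]
    } else if (nrow(grid) == 1) {
      budget <- grid[1, ]
    } else {
      sel <- select_budget(blood[tr, , drop = FALSE],
                           brain[tr, , drop = FALSE],
                           strata = scheme$strata[tr], grid = grid,
                           seed = derive_seed(scheme$seed, 50 + f),
                           site = site[tr], group = group[tr],
                           deflate_uv = deflate_uv,
                           control = control)
      budget <- sel$budget
      fold_scores <- rbind(fold_scores, sel$score)
      fold_covariance <- rbind(fold_covariance, sel$covariance)
    }
    fit <- suppressWarnings(
      spls_rank1_m(crossprod(pf$Xtr, pf$Ytr), budget$c_u, budget$c_v,
                   control$tol, control$max_iter, engine = control$engine))
    fold_rho[f] <- safe_cor(pf$Xte %*% fit$u, pf$Yte %*% fit$v, "outer fold")
    fold_budgets[f, ] <- as.numeric(budget[c("c_u", "c_v")])
    fold_fits[[f]] <- fit
  }
  structure(list(rho_test = agg_rho(fold_rho, control$agg),
                 fold_rho = fold_rho, fold_budgets = fold_budgets,
                 fold_fits = fold_fits, fold_scores = fold_scores,
                 fold_covariance = fold_covariance),
            class = "lv_evaluation")
}

#' Permutation significance of a latent variable
#'
#' The blood-view rows are globally permuted, breaking the blood-brain
#' linkage while preserving each view's internal structure, and the
#' out-of-fold correlation statistic is recomputed for each permutation.
#' The p-value is `(1 + #{rho_perm >= rho_obs}) / (P + 1)`, never zero.
#'
#' By default each permutation reuses the per-fold budgets selected on the
#' observed data (per-fold preprocessing is still refit on the permuted
#' blood view); `control$reselect_perm = TRUE` reruns the full inner
#' selection instead.
#'
#' @inheritParams evaluate_lv
#' @param P number of permutations (at least 99).
#' @param seed integer seed for the permutations.
#' @param obs an existing [evaluate_lv()] result to test (computed if
#'   `NULL`).
#' @param early_stop_h optional sequential stopping count (Besag-Clifford):
#'   permutation sampling stops once `h` null statistics have reached the
#'   observed one and the p-value is reported as `h / b` at the stopping
#'   point, which is a valid (conservative) Monte-Carlo p-value. Leaves
#'   p-values of clearly significant statistics untouched while sparing
#'   most permutations for clear nulls.
#' @return List with `p_perm`, `rho_obs`, `null_rho` (the permutations
#'   actually run).
#' @export
permutation_test_lv <- function(blood, brain, scheme, grid, P = 999,
                                seed = 1, site = NULL, group = NULL,
                                deflate_uv = NULL, control = spls_control(),
                                obs = NULL, early_stop_h = NULL) {
  stopifnot(P >= 99)
  if (is.null(obs))
    obs <- evaluate_lv(blood, brain, scheme, grid, site, group, deflate_uv,
                       control)
  n <- nrow(blood)
  null_rho <- numeric(P)
  n_done <- 0L; n_exceed <- 0L; stopped <- FALSE
  if (control$reselect_perm) {
    with_local_seed(derive_seed(seed, 23), {
      perms <- replicate(P, sample.int(n), simplify = FALSE)
    })
    for (b in seq_len(P)) {
      ev <- suppressWarnings(
        evaluate_lv(blood[perms[[b]], , drop = FALSE], brain, scheme, grid,
                    site, group, deflate_uv, control))
      null_rho[b] <- ev$rho_test
      n_done <- b
      n_exceed <- n_exceed + (ev$rho_test >= obs$rho_test)
      if (!is.null(early_stop_h) && n_exceed >= early_stop_h) {
        stopped <- TRUE
        break
      }
    }
  } else {
    # Fast exact path for fixed budgets: the brain side of every fold is
    # unchanged under blood-row permutation, so its preprocessing and
    # deflation are computed once; the blood side is refit per permutation.
    folds <- lapply(seq_len(scheme$n_outer), function(f) {
      tr <- scheme$outer != f; te <- !tr
      pf <- prep_fold(blood, brain, tr, te, site, group, deflate_uv, control)
      list(tr = which(tr), te = which(te), Ytr = pf$Ytr, Yte = pf$Yte,
           budget = obs$fold_budgets[f, ])
    })
    with_local_seed(derive_seed(seed, 23), {
      perms <- replicate(P, sample.int(n), simplify = FALSE)
    })
    for (b in seq_len(P)) {
      bl <- blood[perms[[b]], , drop = FALSE]
      rho <- vapply(folds, function(fd) {
        xtr <- bl[fd$tr, , drop = FALSE]
        st_i <- if (anyNA(xtr)) fit_impute(xtr) else NULL
        if (!is.null(st_i)) xtr <- apply_impute(st_i, xtr)
        st_s <- suppressWarnings(fit_standardize(xtr))
        xtr <- apply_standardize(st_s, xtr)
        xte <- bl[fd$te, , drop = FALSE]
        if (!is.null(st_i)) xte <- apply_impute(st_i, xte)
        xte <- apply_standardize(st_s, xte)
        if (!is.null(deflate_uv))
          for (k in seq_len(ncol(deflate_uv$U))) {
            xtr <- deflate(xtr, deflate_uv$U[, k])
            xte <- deflate(xte, deflate_uv$U[, k])
          }
        fit <- suppressWarnings(
          spls_rank1_m(crossprod(xtr, fd$Ytr), fd$budget$c_u, fd$budget$c_v,
                       control$tol, control$max_iter,
                       engine = control$engine))
        suppressWarnings(safe_cor(xte %*% fit$u, fd$Yte %*% fit$v))
      }, numeric(1))
      null_rho[b] <- agg_rho(rho, control$agg)
      n_done <- b
      n_exceed <- n_exceed + (null_rho[b] >= obs$rho_test)
      if (!is.null(early_stop_h) && n_exceed >= early_stop_h) {
        stopped <- TRUE
        break
      }
    }
  }
  null_rho <- null_rho[seq_len(n_done)]
  p_perm <- if (stopped) early_stop_h / n_done
            else (1 + n_exceed) / (P + 1)
  list(p_perm = p_perm, rho_obs = obs$rho_test, null_rho = null_rho,
       early_stopped = stopped)
}

#' Bootstrap ratios for feature stability
#'
#' Refits the rank-1 weight pair at a fixed budget on `B` row resamples
#' (with replacement), aligns each resample's signs to the reference fit
#' (flipping jointly when the blood weights' inner product with the
#' reference is negative), and reports per-feature bootstrap ratios
#' `BR_j = mean_b(w_jb) / sd_b(w_jb)`. Features with zero bootstrap spread
#' get `BR = 0` when their mean is also zero and a signed infinite
#' sentinel (maximally stable) otherwise. Resamples that produce a
#' constant column in either view are skipped.
#'
#' @param X,Y preprocessed (and, beyond the first LV, deflated) views.
#' @param c_u,c_v the selected budgets.
#' @param B number of bootstrap resamples (at least 100).
#' @param seed integer seed.
#' @param control [spls_control()].
#' @return List of class `bootstrap_ratios`: `br_u`, `br_v`, `mean_u`,
#'   `mean_v`, `stable_u`, `stable_v`, `n_eff`, `n_skipped`.
#' @export
bootstrap_ratios <- function(X, Y, c_u, c_v, B = 500, seed = 1,
                             control = spls_control()) {
  stopifnot(B >= 100, nrow(X) == nrow(Y))
  n <- nrow(X)
  ref <- suppressWarnings(
    spls_rank1_m(crossprod(X, Y), c_u, c_v, control$tol, control$max_iter,
                 engine = control$engine))
  su <- su2 <- numeric(ncol(X)); sv <- sv2 <- numeric(ncol(Y))
  n_eff <- 0L; n_skipped <- 0L
  with_local_seed(derive_seed(seed, 31), {
    for (b in seq_len(B)) {
      idx <- sample.int(n, replace = TRUE)
      Xb <- X[idx, , drop = FALSE]; Yb <- Y[idx, , drop = FALSE]
      cx <- n * colSums(Xb^2) - colSums(Xb)^2
      cy <- n * colSums(Yb^2) - colSums(Yb)^2
      if (any(cx <= 1e-12 * n) || any(cy <= 1e-12 * n)) {
        n_skipped <- n_skipped + 1L
        next
      }
      fit <- suppressWarnings(
        spls_rank1_m(crossprod(Xb, Yb), c_u, c_v, control$tol,
                     control$max_iter, engine = control$engine))
      d <- sum(fit$u * ref$u)
      if (d == 0) d <- sum(fit$v * ref$v)
      if (d < 0) { fit$u <- -fit$u; fit$v <- -fit$v }
      su <- su + fit$u; su2 <- su2 + fit$u^2
      sv <- sv + fit$v; sv2 <- sv2 + fit$v^2
      n_eff <- n_eff + 1L
    }
  })
  if (n_skipped > 0)
    message(sprintf("bootstrap_ratios: skipped %d resample(s) with constant columns",
                    n_skipped))
  ratio <- function(s, s2, m) {
    mean_w <- s / m
    var_w <- pmax((s2 - m * mean_w^2) / (m - 1), 0)
    se <- sqrt(var_w)
    br <- ifelse(se > 0, mean_w / se,
                 ifelse(mean_w == 0, 0, sign(mean_w) * Inf))
    list(br = br, mean = mean_w)
  }
  ru <- ratio(su, su2, n_eff); rv <- ratio(sv, sv2, n_eff)
  structure(list(br_u = setNames(ru$br, colnames(X)),
                 br_v = setNames(rv$br, colnames(Y)),
                 mean_u = ru$mean, mean_v = rv$mean,
                 stable_u = abs(ru$br) >= control$br_threshold,
                 stable_v = abs(rv$br) >= control$br_threshold,
                 n_eff = n_eff, n_skipped = n_skipped),
            class = "bootstrap_ratios")
}

# Consolidate the final-refit budget from the pooled inner-CV surfaces.
# The out-of-fold correlation surface plateaus once a few informative
# features carry the latent scores, so budgets with very different weight
# quality predict almost equally well. Within the statistical plateau
# (two standard errors of the pooled correlation optimum) the budget with
# the largest pooled out-of-fold score covariance is chosen: covariance —
# the quantity SPLS itself maximizes — keeps growing with support
# coverage where correlation saturates, and gains nothing out-of-sample
# from noise features. See the methods vignette.
consolidate_budget <- function(ev, grid) {
  if (is.null(ev$fold_scores) || nrow(grid) == 1)
    return(modal_budget(ev$fold_budgets))
  pooled <- colMeans(ev$fold_scores)
  se <- apply(ev$fold_scores, 2, sd) / sqrt(nrow(ev$fold_scores))
  best <- which.max(pooled)
  cand <- which(pooled >= pooled[best] - 2 * se[best])
  cv <- colMeans(ev$fold_covariance)[cand]
  cand <- cand[order(-cv, grid$c_u[cand] + grid$c_v[cand],
                     grid$c_u[cand], grid$c_v[cand])]
  grid[cand[1], ]
}

# Modal per-fold budget pair; frequency ties go to the tied pair closest
# (log scale) to the componentwise median of all fold selections, then to
# the sparser pair.
modal_budget <- function(fold_budgets) {
  key <- paste(signif(fold_budgets$c_u, 10), signif(fold_budgets$c_v, 10))
  tab <- table(key)
  cand_keys <- names(tab)[tab == max(tab)]
  cand <- fold_budgets[match(cand_keys, key), , drop = FALSE]
  if (nrow(cand) > 1) {
    target <- c(median(log(fold_budgets$c_u)), median(log(fold_budgets$c_v)))
    d2 <- (log(cand$c_u) - target[1])^2 + (log(cand$c_v) - target[2])^2
    cand <- cand[order(d2, cand$c_u + cand$c_v, cand$c_u), , drop = FALSE]
  }
  cand[1, ]
}

#' Extract the full SPLS model: significant LVs with deflation
#'
#' The level-1 inference loop. For each candidate LV the out-of-fold
#' correlation is computed by nested CV ([evaluate_lv()]) and tested by
#' permutation ([permutation_test_lv()]). While significant at `alpha`,
#' the LV is refit on the full preprocessed sample with the budget
#' selected most often across outer folds (ties toward sparser), bootstrap
#' ratios are computed, both views are deflated by the final weight pair,
#' and extraction continues; the loop stops at the first non-significant
#' LV or after `K_max` components.
#'
#' @param blood,brain raw views (participants x features).
#' @param group diagnostic-group labels (stratification + harmonization
#'   covariate).
#' @param site optional site labels enabling harmonization.
#' @param grid budget grid; defaults to `budget_grid(ncol(blood),
#'   ncol(brain))`.
#' @param alpha significance level for the permutation test.
#' @param K_max maximum number of LVs to extract.
#' @param P permutations per LV; `B` bootstrap resamples per LV.
#' @param B bootstrap resamples.
#' @param seed integer seed (folds, permutations, bootstrap).
#' @param control [spls_control()].
#' @return An `spls_model`: list with `lvs` (significant LVs, in
#'   extraction order), `prep_state`, `scheme`, `termination`,
#'   `last_candidate` (the first non-significant evaluation, if any), and
#'   the call configuration.
#' @export
extract_model <- function(blood, brain, group, site = NULL, grid = NULL,
                          alpha = 0.05, K_max = 10, P = 999, B = 500,
                          seed = 1, control = spls_control()) {
  stopifnot(nrow(blood) == nrow(brain))
  if (is.null(grid)) grid <- budget_grid(ncol(blood), ncol(brain))
  scheme <- make_stratified_folds(group, control$n_outer, control$n_inner,
                                  seed)
  prep <- fit_preprocess(blood, brain, site = site, group = group,
                         harmonize = control$harmonize && !is.null(site),
                         eb = control$eb)
  full <- apply_preprocess(prep, blood, brain, site = site, group = group)
  Xd <- full$blood; Yd <- full$brain
  defl <- NULL
  lvs <- list(); termination <- "K_max reached"; last_candidate <- NULL
  for (k in seq_len(K_max)) {
    ev <- suppressWarnings(
      evaluate_lv(blood, brain, scheme, grid, site, group, defl, control))
    pt <- permutation_test_lv(blood, brain, scheme, grid, P = P,
                              seed = derive_seed(seed, 100 + k),
                              site = site, group = group, deflate_uv = defl,
                              control = control, obs = ev,
                              early_stop_h = ceiling(alpha * (P + 1)))
    if (pt$p_perm >= alpha) {
      termination <- "first non-significant LV"
      last_candidate <- list(k = k, rho_test = ev$rho_test,
                             p_perm = pt$p_perm)
      break
    }
    budget <- consolidate_budget(ev, grid)
    fit <- suppressWarnings(
      spls_rank1_m(crossprod(Xd, Yd), budget$c_u, budget$c_v, control$tol,
                   control$max_iter, engine = control$engine))
    names(fit$u) <- colnames(blood); names(fit$v) <- colnames(brain)
    rho_train <- safe_cor(Xd %*% fit$u, Yd %*% fit$v, "full-sample fit")
    br <- bootstrap_ratios(Xd, Yd, budget$c_u, budget$c_v, B = B,
                           seed = derive_seed(seed, 200 + k),
                           control = control)
    lvs[[k]] <- structure(
      list(k = k, u = fit$u, v = fit$v, budget = budget,
           rho_train = rho_train, rho_test = ev$rho_test,
           fold_rho = ev$fold_rho, fold_budgets = ev$fold_budgets,
           p_perm = pt$p_perm, bootstrap = br), class = "latent_variable")
    Xd <- deflate(Xd, fit$u); Yd <- deflate(Yd, fit$v)
    defl <- list(U = cbind(defl$U, fit$u), V = cbind(defl$V, fit$v))
  }
  structure(list(lvs = lvs, prep_state = prep, scheme = scheme,
                 termination = termination, last_candidate = last_candidate,
                 feature_names = list(blood = colnames(blood),
                                      brain = colnames(brain)),
                 alpha = alpha, P = P, B = B, seed = seed, grid = grid,
                 control = control), class = "spls_model")
}

#' @export
print.spls_model <- function(x, ...) {
  cat(sprintf("SPLS model: %d significant LV(s) [%s]\n", length(x$lvs),
              x$termination))
  for (lv in x$lvs)
    cat(sprintf(
      "  LV%d: rho_test = %.3f, rho_train = %.3f, p_perm = %.4g, budgets (%.3g, %.3g), nonzero %d/%d blood, %d/%d brain\n",
      lv$k, lv$rho_test, lv$rho_train, lv$p_perm, lv$budget$c_u,
      lv$budget$c_v, sum(lv$u != 0), length(lv$u), sum(lv$v != 0),
      length(lv$v)))
  if (!is.null(x$last_candidate))
    cat(sprintf("  stopped at candidate LV%d: rho_test = %.3f, p_perm = %.4g\n",
                x$last_candidate$k, x$last_candidate$rho_test,
                x$last_candidate$p_perm))
  invisible(x)
}

#' Project a replication sample through a fitted SPLS model
#'
#' Applies the stored full-sample preprocessing state and the stored
#' deflation sequence to new data, scores each significant LV with its
#' final weight pair, and reports the replication latent-score correlation
#' together with a row-permutation p-value computed on the replication
#' scores only.
#'
#' @param model an [extract_model()] result.
#' @param blood_new,brain_new replication views sharing feature names and
#'   order with the training views.
#' @param site,group optional labels for the stored preprocessing.
#' @param P permutations for the score-level test.
#' @param seed integer seed.
#' @return `data.frame` with one row per LV: `lv`, `rho`, `p_perm`. The
#'   projected score matrices are attached as attribute `"scores"`.
#' @export
project_replication <- function(model, blood_new, brain_new, site = NULL,
                                group = NULL, P = 999, seed = 1) {
  mismatch <- c(
    if (!identical(colnames(blood_new), model$feature_names$blood))
      paste("blood:", paste(head(c(
        setdiff(model$feature_names$blood, colnames(blood_new)),
        setdiff(colnames(blood_new), model$feature_names$blood)), 10),
        collapse = ", ")),
    if (!identical(colnames(brain_new), model$feature_names$brain))
      paste("brain:", paste(head(c(
        setdiff(model$feature_names$brain, colnames(brain_new)),
        setdiff(colnames(brain_new), model$feature_names$brain)), 10),
        collapse = ", ")))
  if (length(mismatch) > 0)
    stop("project_replication: feature mismatch with training views — ",
         paste(mismatch, collapse = "; "))
  new <- apply_preprocess(model$prep_state, blood_new, brain_new,
                          site = site, group = group)
  Xd <- new$blood; Yd <- new$brain
  n <- nrow(Xd)
  out <- data.frame(lv = integer(0), rho = numeric(0), p_perm = numeric(0))
  scores <- list()
  for (lv in model$lvs) {
    sx <- latent_scores(Xd, lv$u); sy <- latent_scores(Yd, lv$v)
    rho <- safe_cor(sx, sy, sprintf("replication LV%d", lv$k))
    null_rho <- with_local_seed(derive_seed(seed, 300 + lv$k), {
      vapply(seq_len(P), function(b)
        suppressWarnings(safe_cor(sx[sample.int(n)], sy)), numeric(1))
    })
    out <- rbind(out, data.frame(
      lv = lv$k, rho = rho,
      p_perm = (1 + sum(null_rho >= rho)) / (P + 1)))
    scores[[lv$k]] <- cbind(blood = sx, brain = sy)
    Xd <- deflate(Xd, lv$u); Yd <- deflate(Yd, lv$v)
  }
  attr(out, "scores") <- scores
  out
}
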