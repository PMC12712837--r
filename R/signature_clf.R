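#' Quartile-conjunction signature groups
#'
#' High scorers have both their blood and brain latent scores strictly
#' above the respective 75th percentiles; low scorers have both strictly
#' below the 25th percentiles; everyone else is excluded. Percentiles use
#' the linear-interpolation definition (`quantile(type = 7)`), and the
#' strict inequalities guarantee high/low disjointness under heavy ties.
#'
#' @param blood_scores,brain_scores aligned latent score vectors (length
#'   at least 8).
#' @param ids optional participant ids (defaults to names or indices).
#' @return A `signature_groups` object: list with `high`, `low`,
#'   `excluded` id vectors and the `thresholds` used.
#' @export
assign_quartile_groups <- function(blood_scores, brain_scores, ids = NULL) {
  stopifnot(length(blood_scores) == length(brain_scores))
  if (length(blood_scores) < 8)
    stop("assign_quartile_groups: need at least 8 participants")
  if (is.null(ids))
    ids <- names(blood_scores) %||% as.character(seq_along(blood_scores))
  qb <- quantile(blood_scores, c(0.25, 0.75), type = 7, names = FALSE)
  qr <- quantile(brain_scores, c(0.25, 0.75), type = 7, names = FALSE)
  high <- ids[blood_scores > qb[2] & brain_scores > qr[2]]
  low <- ids[blood_scores < qb[1] & brain_scores < qr[1]]
  if (length(high) < 2 || length(low) < 2)
    stop(sprintf(paste0("assign_quartile_groups: unclassifiable — fewer than",
                        " 2 members in a group (high = %d, low = %d)"),
                 length(high), length(low)))
  structure(list(high = high, low = low,
                 excluded = setdiff(ids, c(high, low)),
                 thresholds = list(blood = qb, brain = qr)),
            class = "signature_groups")
}

#' @export
print.signature_groups <- function(x, ...) {
  cat(sprintf("Signature groups: %d high, %d low, %d excluded\n",
              length(x$high), length(x$low), length(x$excluded)))
  invisible(x)
}

stratified_label_folds <- function(y, n_folds, seed) {
  folds <- integer(length(y))
  with_local_seed(seed, {
    for (lev in levels(y)) {
      idx <- which(y == lev)
      folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
  })
  folds
}

svm_fold_model <- function(xtr, ytr, cost) {
  wts <- length(ytr) / (2 * table(ytr))
  e1071::svm(xtr, ytr, kernel = "linear", cost = cost, scale = FALSE,
             class.weights = wts)
}

# Decision values and primal weights oriented so that positive = "high".
svm_decision <- function(model, xte) {
  pred <- stats::predict(model, xte, decision.values = TRUE)
  dv <- drop(attr(pred, "decision.values"))
  first <- strsplit(colnames(attr(pred, "decision.values"))[1], "/")[[1]][1]
  if (first != "high") dv <- -dv
  dv
}

svm_weights <- function(model) {
  w <- drop(crossprod(model$coefs, model$SV))
  if (model$levels[1] != "high") w <- -w
  w
}

confusion_stats <- function(y, pred_high) {
  sens <- mean(pred_high[y == "high"])
  spec <- mean(!pred_high[y == "low"])
  c(sensitivity = sens, specificity = spec, bac = (sens + spec) / 2)
}

# Rank-based AUC of decision values for the "high" class.
rank_auc <- function(dv, y) {
  r <- rank(dv)
  n1 <- sum(y == "high"); n0 <- sum(y == "low")
  (sum(r[y == "high"]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Repeated nested-CV linear SVM for signature classification
#'
#' Classifies high versus low signature scorers with a linear-kernel
#' maximum-margin classifier inside a repeated nested cross-validation:
#' the regularization constant is selected on inner (CV1) folds by
#' balanced accuracy over a geometric grid, the outer (CV2) partition is
#' repeated `n_repeats` times, per-fold preprocessing (median imputation +
#' z-scoring) is fit on the training folds only, and class imbalance is
#' handled by inverse-frequency misclassification weights. Out-of-fold
#' decision values are averaged across repetitions; the reported balanced
#' accuracy is the mean of sensitivity and specificity of the aggregated
#' decisions.
#'
#' @param features predictor matrix (participants x features), rownames =
#'   participant ids.
#' @param groups a [assign_quartile_groups()] result (or a factor with
#'   levels `low`/`high` aligned to `features` rows).
#' @param n_folds,n_repeats outer CV folds and partition repetitions.
#' @param inner_folds inner CV folds for cost selection.
#' @param cost_grid geometric grid of SVM costs.
#' @param seed integer seed.
#' @return A `classifier_result`: `bac`, `sensitivity`, `specificity`,
#'   `auc`, aggregated `decision` values, the per-fold-model primal
#'   `weights` matrix, `mean_weight`, selected `costs`, `y`, and the CV
#'   configuration.
#' @export
fit_svm_nested <- function(features, groups, n_folds = 10, n_repeats = 10,
                           inner_folds = 10,
                           cost_grid = 10^seq(-3, 3, length.out = 9),
                           seed = 1) {
  if (inherits(groups, "signature_groups")) {
    keep <- c(groups$high, groups$low)
    stopifnot(all(keep %in% rownames(features)))
    x <- features[keep, , drop = FALSE]
    y <- factor(ifelse(keep %in% groups$high, "high", "low"),
                levels = c("low", "high"))
  } else {
    x <- as.matrix(features)
    y <- factor(as.character(groups), levels = c("low", "high"))
  }
  if (min(table(y)) < n_folds)
    stop("fit_svm_nested: both classes need at least n_folds members")
  n <- nrow(x); p <- ncol(x)
  dv_mat <- matrix(NA_real_, n, n_repeats)
  weights <- matrix(NA_real_, n_repeats * n_folds, p,
                    dimnames = list(NULL, colnames(x)))
  costs <- numeric(n_repeats * n_folds)
  m <- 0L
  for (r in seq_len(n_repeats)) {
    folds <- stratified_label_folds(y, n_folds, derive_seed(seed, 400 + r))
    for (f in seq_len(n_folds)) {
      tr <- folds != f; te <- !tr
      xtr <- x[tr, , drop = FALSE]; ytr <- y[tr]
      st_i <- if (anyNA(xtr)) fit_impute(xtr) else NULL
      if (!is.null(st_i)) xtr <- apply_impute(st_i, xtr)
      st_s <- suppressWarnings(fit_standardize(xtr))
      xtr <- apply_standardize(st_s, xtr)
      xte <- x[te, , drop = FALSE]
      if (!is.null(st_i)) xte <- apply_impute(st_i, xte)
      xte <- apply_standardize(st_s, xte)
      cost <- if (length(cost_grid) == 1) cost_grid else
        select_svm_cost(xtr, ytr, cost_grid, inner_folds,
                        derive_seed(seed, 500 + r * n_folds + f))
      model <- svm_fold_model(xtr, ytr, cost)
      dv_mat[te, r] <- svm_decision(model, xte)
      m <- m + 1L
      weights[m, ] <- svm_weights(model)
      costs[m] <- cost
    }
  }
  dv <- rowMeans(dv_mat)
  pred_high <- dv > 0
  cs <- confusion_stats(y, pred_high)
  stopifnot(abs(cs["bac"] - (cs["sensitivity"] + cs["specificity"]) / 2) < 1e-12)
  structure(list(bac = unname(cs["bac"]),
                 sensitivity = unname(cs["sensitivity"]),
                 specificity = unname(cs["specificity"]),
                 auc = rank_auc(dv, y), decision = dv,
                 weights = weights, mean_weight = colMeans(weights),
                 costs = costs, y = y, n_folds = n_folds,
                 n_repeats = n_repeats), class = "classifier_result")
}

select_svm_cost <- function(xtr, ytr, cost_grid, inner_folds, seed) {
  k <- min(inner_folds, min(table(ytr)))
  folds <- stratified_label_folds(ytr, k, seed)
  bac <- sapply(cost_grid, function(cost) {
    hit_high <- 0; n_high <- 0; hit_low <- 0; n_low <- 0
    for (f in seq_len(k)) {
      tr <- folds != f
      model <- svm_fold_model(xtr[tr, , drop = FALSE], ytr[tr], cost)
      dv <- svm_decision(model, xtr[!tr, , drop = FALSE])
      yte <- ytr[!tr]
      hit_high <- hit_high + sum(dv > 0 & yte == "high")
      n_high <- n_high + sum(yte == "high")
      hit_low <- hit_low + sum(dv <= 0 & yte == "low")
      n_low <- n_low + sum(yte == "low")
    }
    (hit_high / n_high + hit_low / n_low) / 2
  })
  cost_grid[which(bac >= max(bac) - 1e-12)[1]]
}

#' @export
print.classifier_result <- function(x, ...) {
  cat(sprintf("Nested-CV linear SVM: BAC %.1f%% (sens %.1f%%, spec %.1f%%), AUC %.3f\n",
              100 * x$bac, 100 * x$sensitivity, 100 * x$specificity, x$auc))
  cat(sprintf("  %d x %d-fold CV, %d fold models\n", x$n_repeats, x$n_folds,
              nrow(x$weights)))
  invisible(x)
}

#' Label-permutation significance of a signature classifier
#'
#' Permutes the high/low labels, reruns the nested-CV classifier for each
#' permutation (with a reduced number of CV repetitions, by default 1, to
#' keep large permutation counts tractable), and reports
#' `p = (1 + #{BAC_perm >= BAC_obs}) / (n_perm + 1)`.
#'
#' @inheritParams fit_svm_nested
#' @param n_perm number of label permutations (the reference analysis uses
#'   5000; reduced counts are fine for calibration runs, minimum 99).
#' @param perm_repeats CV repetitions per permutation.
#' @param obs an existing observed [fit_svm_nested()] result (computed
#'   with the full `n_repeats` if `NULL`).
#' @param n_null_weights keep the fold-model weight matrices of this many
#'   permutations (for permutation-calibrated feature significance, see
#'   [sign_based_consistency()]).
#' @return List with `p_perm`, `bac_obs`, `null_bac`, and `null_weights`
#'   (a list of fold-weight matrices, when requested).
#' @export
label_permutation_test <- function(features, groups, n_perm = 5000,
                                   seed = 1, n_folds = 10, n_repeats = 10,
                                   perm_repeats = 1, inner_folds = 10,
                                   cost_grid = 10^seq(-3, 3, length.out = 9),
                                   obs = NULL, n_null_weights = 0) {
  stopifnot(n_perm >= 99)
  if (inherits(groups, "signature_groups")) {
    keep <- c(groups$high, groups$low)
    x <- features[keep, , drop = FALSE]
    y <- factor(ifelse(keep %in% groups$high, "high", "low"),
                levels = c("low", "high"))
  } else {
    x <- as.matrix(features)
    y <- factor(as.character(groups), levels = c("low", "high"))
  }
  if (is.null(obs))
    obs <- fit_svm_nested(x, y, n_folds = n_folds, n_repeats = n_repeats,
                          inner_folds = inner_folds, cost_grid = cost_grid,
                          seed = seed)
  perms <- with_local_seed(derive_seed(seed, 600), {
    replicate(n_perm, sample.int(length(y)), simplify = FALSE)
  })
  null_weights <- if (n_null_weights > 0) vector("list", min(n_null_weights, n_perm)) else NULL
  null_bac <- vapply(seq_len(n_perm), function(b) {
    fit <- fit_svm_nested(x, y[perms[[b]]], n_folds = n_folds,
                          n_repeats = perm_repeats,
                          inner_folds = inner_folds,
                          cost_grid = cost_grid,
                          seed = derive_seed(seed, 700 + b))
    if (b <= length(null_weights)) null_weights[[b]] <<- fit$weights
    fit$bac
  }, numeric(1))
  list(p_perm = (1 + sum(null_bac >= obs$bac)) / (n_perm + 1),
       bac_obs = obs$bac, null_bac = null_bac,
       null_weights = null_weights)
}

#' Sign-based consistency of classifier features
#'
#' For each feature, counts the fraction of CV fold models in which the
#' primal weight carries the majority sign and combines it with the mean
#' normalized weight into a stability score. Two significance modes:
#'
#' * **Binomial** (`null_weights = NULL`): the majority-sign count is
#'   tested against a binomial(0.5) null (one-sided tail) and BH-adjusted.
#'   This assumes independent fold models; with overlapping CV training
#'   folds a spuriously associated noise feature keeps one sign across
#'   folds, so this mode is strongly anti-conservative and should be read
#'   as a ranking, not a calibrated test.
#' * **Permutation-calibrated** (`null_weights` = list of fold-weight
#'   matrices from label-permuted refits, as produced by
#'   [label_permutation_test()]): each feature's stability score
#'   (sign-consistency times |mean L2-normalized weight|) is z-scored
#'   against its own permutation null moments and tested one-sided, then
#'   BH-adjusted. This mode inherits the correlation structure of the
#'   fold models and is the one [classify_signature()] uses.
#'
#' Features whose weight is zero in every fold model have undefined
#' consistency and are flagged non-significant.
#'
#' @param weights fold-model weight matrix (models x features), at least
#'   20 models.
#' @param fdr FDR level for the significance flags.
#' @param null_weights optional list of fold-weight matrices from
#'   label-permuted fits (at least 20 for stable null moments).
#' @return `data.frame` with per-feature `consistency`, `z`, `p_value`,
#'   `p_adjusted`, `significant`; the significance mode is recorded in
#'   attribute `"method"`.
#' @export
sign_based_consistency <- function(weights, fdr = 0.05,
                                   null_weights = NULL) {
  stopifnot(nrow(weights) >= 20)
  cons_stat <- function(W) {
    Wn <- W / (sqrt(rowSums(W^2)) + 1e-12)
    cons <- apply(W, 2, function(w) {
      k <- max(sum(w > 0), sum(w < 0)); n <- sum(w != 0)
      if (n == 0) NA_real_ else k / n
    })
    list(cons = cons, stat = ifelse(is.na(cons), 0,
                                    cons * abs(colMeans(Wn))))
  }
  obs <- cons_stat(weights)
  out <- data.frame(feature = colnames(weights) %||%
                      as.character(seq_len(ncol(weights))),
                    consistency = obs$cons)
  if (is.null(null_weights)) {
    bin <- lapply(seq_len(ncol(weights)), function(j) {
      s <- sign(weights[, j])
      k_pos <- sum(s > 0); k_neg <- sum(s < 0)
      n_eff <- k_pos + k_neg
      if (n_eff == 0) return(c(z = NA_real_, p = 1))
      k <- max(k_pos, k_neg)
      c(z = (k - n_eff / 2) / sqrt(n_eff / 4),
        p = pbinom(k - 1, n_eff, 0.5, lower.tail = FALSE))
    })
    out$z <- vapply(bin, `[[`, numeric(1), "z")
    out$p_value <- vapply(bin, `[[`, numeric(1), "p")
    method <- "binomial"
  } else {
    stopifnot(length(null_weights) >= 20)
    null_stat <- vapply(null_weights, function(W) cons_stat(W)$stat,
                        numeric(ncol(weights)))
    mu <- rowMeans(null_stat)
    sdv <- apply(null_stat, 1, sd) + 1e-12
    out$z <- (obs$stat - mu) / sdv
    out$p_value <- stats::pnorm(out$z, lower.tail = FALSE)
    out$p_value[is.na(out$consistency)] <- 1
    method <- "permutation-calibrated"
  }
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  out$significant <- !is.na(out$consistency) & out$p_adjusted < fdr
  rownames(out) <- NULL
  attr(out, "method") <- method
  out
}

#' Classify a latent signature from a predictor domain
#'
#' One-call level-2 analysis: nested-CV linear SVM on a predictor domain,
#' label-permutation significance, and the sign-based-consistency feature
#' table.
#'
#' @inheritParams fit_svm_nested
#' @inheritParams label_permutation_test
#' @param domain optional domain name carried into the result.
#' @param fdr FDR level for feature significance.
#' @return A `signature_classification`: the `classifier_result` plus
#'   `p_perm`, the `features` significance table and `domain`.
#' @export
classify_signature <- function(features, groups, domain = "predictors",
                               n_folds = 10, n_repeats = 10,
                               inner_folds = 10,
                               cost_grid = 10^seq(-3, 3, length.out = 9),
                               n_perm = 5000, perm_repeats = 1, fdr = 0.05,
                               seed = 1) {
  fit <- fit_svm_nested(features, groups, n_folds = n_folds,
                        n_repeats = n_repeats, inner_folds = inner_folds,
                        cost_grid = cost_grid, seed = seed)
  pt <- label_permutation_test(features, groups, n_perm = n_perm,
                               seed = seed, n_folds = n_folds,
                               n_repeats = n_repeats,
                               perm_repeats = perm_repeats,
                               inner_folds = inner_folds,
                               cost_grid = cost_grid, obs = fit,
                               n_null_weights = min(40, n_perm))
  sbc <- sign_based_consistency(fit$weights, fdr = fdr,
                                null_weights = pt$null_weights)
  sbc$mean_weight <- fit$mean_weight
  structure(list(domain = domain, fit = fit, p_perm = pt$p_perm,
                 null_bac = pt$null_bac, features = sbc),
            class = "signature_classification")
}

#' @export
print.signature_classification <- function(x, ...) {
  cat(sprintf("Signature classification [%s]: BAC %.1f%% (AUC %.3f), p_perm = %.4g\n",
              x$domain, 100 * x$fit$bac, x$fit$auc, x$p_perm))
  cat(sprintf("  %d/%d features significant by sign-based consistency\n",
              sum(x$features$significant), nrow(x$features)))
  invisible(x)
}
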