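quick_ctl <- function(...) spls_control(n_outer = 4, n_inner = 3, ...)

test_that("stratified folds balance groups and are deterministic", {
  groups <- rep(c("a", "b", "c", "d"), each = 100)
  sc <- make_stratified_folds(groups, n_outer = 10, seed = 3)
  counts <- table(sc$outer, groups)
  expect_true(all(counts == 10))
  expect_identical(sc, make_stratified_folds(groups, n_outer = 10, seed = 3))
  expect_error(make_stratified_folds(rep(c("a", "b"), c(5, 100)), 10),
               "smaller than the fold count")
})

test_that("folds of a 678-participant cohort track the group proportions within one", {
  spec <- truth_spec(n_participants = 678, seed = 2)
  co <- generate_cohort(spec)
  sc <- make_stratified_folds(co$group, n_outer = 10, seed = 1)
  counts <- table(sc$outer, co$group)
  targets <- c(ROD = 16.3, ROP = 17.7, `CHR-P` = 17.2, HC = 16.6)
  for (g in names(targets))
    expect_true(all(abs(counts[, g] - targets[g]) <= 1))
})

test_that("budget selection honors trivial grids and rejects empty ones", {
  spec <- tiny_spec(seed = 4)
  ds <- generate_linked_views(generate_cohort(spec), spec)
  one <- data.frame(c_u = 2, c_v = 3)
  sel <- select_budget(ds$blood, ds$brain, ds$cohort$group, one, seed = 1,
                       control = quick_ctl())
  expect_equal(sel$budget, one)
  expect_error(select_budget(ds$blood, ds$brain, ds$cohort$group,
                             one[0, ], seed = 1), "empty budget grid")
})

test_that("noiseless planted data yields near-perfect out-of-fold correlation", {
  spec <- truth_spec(n_participants = 120, p_blood = 10, q_brain = 40,
                     n_sites = 2, K_true = 1, rho_star = 1, u_support = 3,
                     v_support = 8, noise_sd = 0, site_effect_sd = 0,
                     missing_rate = 0,
                     group_proportions = c(ROD = 0.25, ROP = 0.25,
                                           `CHR-P` = 0.25, HC = 0.25),
                     seed = 5)
  ds <- generate_linked_views(generate_cohort(spec), spec)
  sc <- make_stratified_folds(ds$cohort$group, 4, 3, seed = 2)
  # noiseless off-support columns are constant, hence the zero-variance
  # warnings from per-fold standardization
  ev <- suppressWarnings(
    evaluate_lv(ds$blood, ds$brain, sc,
                grid = data.frame(c_u = sqrt(10), c_v = sqrt(40)),
                control = quick_ctl(harmonize = FALSE)))
  expect_gte(ev$rho_test, 0.99)
})

test_that("outer-fold fits never see their test participants", {
  spec <- tiny_spec(seed = 6)
  ds <- generate_linked_views(generate_cohort(spec), spec)
  sc <- make_stratified_folds(ds$cohort$group, 4, 3, seed = 7)
  grid <- data.frame(c_u = 2, c_v = 4)
  ev1 <- suppressWarnings(
    evaluate_lv(ds$blood, ds$brain, sc, grid, site = ds$cohort$site,
                group = ds$cohort$group, control = quick_ctl()))
  blood2 <- ds$blood; brain2 <- ds$brain
  te1 <- sc$outer == 1
  blood2[te1, ] <- blood2[te1, ] * 3 + 7  # corrupt fold-1 test rows only
  brain2[te1, ] <- brain2[te1, ] - 11
  ev2 <- suppressWarnings(
    evaluate_lv(blood2, brain2, sc, grid, site = ds$cohort$site,
                group = ds$cohort$group, control = quick_ctl()))
  expect_equal(ev1$fold_fits[[1]]$u, ev2$fold_fits[[1]]$u)
  expect_equal(ev1$fold_fits[[1]]$v, ev2$fold_fits[[1]]$v)
})

test_that("the permutation p-value follows the add-one formula at both extremes", {
  spec <- tiny_spec(seed = 8)
  ds <- generate_linked_views(generate_cohort(spec), spec)
  sc <- make_stratified_folds(ds$cohort$group, 4, 3, seed = 9)
  grid <- data.frame(c_u = 2, c_v = 4)
  ctl <- quick_ctl(harmonize = FALSE)
  obs_hi <- structure(list(rho_test = 1.01, fold_rho = rep(1.01, 4),
                           fold_budgets = grid[rep(1, 4), ],
                           fold_fits = NULL), class = "lv_evaluation")
  pt <- suppressWarnings(
    permutation_test_lv(ds$blood, ds$brain, sc, grid, P = 99, seed = 1,
                        control = ctl, obs = obs_hi))
  expect_equal(pt$p_perm, 1 / 100)
  obs_lo <- obs_hi; obs_lo$rho_test <- -1.01
  pt2 <- suppressWarnings(
    permutation_test_lv(ds$blood, ds$brain, sc, grid, P = 99, seed = 1,
                        control = ctl, obs = obs_lo))
  expect_equal(pt2$p_perm, 1)
  # sequential early stopping preserves the rejection decision
  pt3 <- suppressWarnings(
    permutation_test_lv(ds$blood, ds$brain, sc, grid, P = 99, seed = 1,
                        control = ctl, obs = obs_lo, early_stop_h = 5))
  expect_true(pt3$early_stopped)
  expect_gte(pt3$p_perm, 0.05)
})

test_that("bootstrap ratios separate planted from noise features and flag degeneracy", {
  d <- planted_rank1(n = 250, p = 12, q = 30, u_supp = 3, v_supp = 6,
                     rho = 0.9, noise_sd = 0.15, seed = 10)
  br <- bootstrap_ratios(d$X, d$Y, c_u = 2, c_v = 2.6, B = 120, seed = 3,
                         control = spls_control())
  on_support <- which(d$u_star != 0)
  expect_gte(min(abs(br$br_u[on_support])), 3)
  expect_lt(median(abs(br$br_u[-on_support])), 2)
  # a weight that is identical in every resample gets the +Inf sentinel
  # and is flagged stable: engineered via a dominant single feature
  d2 <- planted_rank1(n = 150, p = 6, q = 10, u_supp = 1, v_supp = 2,
                      rho = 1, noise_sd = 0.01, seed = 11)
  br2 <- bootstrap_ratios(d2$X, d2$Y, c_u = 1, c_v = 1, B = 100, seed = 4,
                          control = spls_control())
  j <- which(d2$u_star != 0)
  expect_true(is.infinite(br2$br_u[j]))
  expect_true(br2$stable_u[j])
  expect_equal(unname(br2$br_u[-j]), rep(0, 5))
})

test_that("extract_model recovers a single planted factor and its deflation chain", {
  spec <- truth_spec(n_participants = 160, p_blood = 12, q_brain = 50,
                     n_sites = 2, K_true = 1, rho_star = 0.8, u_support = 3,
                     v_support = 10, noise_sd = 0.1, site_effect_sd = 0.3,
                     missing_rate = 0.05,
                     group_proportions = c(ROD = 0.25, ROP = 0.25,
                                           `CHR-P` = 0.25, HC = 0.25),
                     seed = 12)
  ds <- generate_linked_views(generate_cohort(spec), spec)
  grid <- budget_grid(12, 50, 3, 3)
  m <- suppressMessages(suppressWarnings(
    extract_model(ds$blood, ds$brain, group = ds$cohort$group,
                  site = ds$cohort$site, grid = grid, P = 99, B = 100,
                  seed = 13, control = spls_control(n_outer = 5,
                                                    n_inner = 4))))
  expect_gte(length(m$lvs), 1)
  lv1 <- m$lvs[[1]]
  expect_gte(abs_cos(lv1$u, spec$u_star[, 1]), 0.9)
  expect_gte(abs_cos(lv1$v, spec$v_star[, 1]), 0.9)
  expect_lt(lv1$p_perm, 0.05)
  expect_true(abs(sqrt(sum(lv1$u^2)) - 1) < 1e-8)
  # deflation chain: later deflated matrices are orthogonal to earlier weights
  pre <- apply_preprocess(m$prep_state, ds$blood, ds$brain,
                          site = ds$cohort$site, group = ds$cohort$group)
  Xd <- deflate(pre$blood, lv1$u)
  expect_lt(max(abs(Xd %*% lv1$u)), 1e-8)
  # projecting the discovery data itself reproduces the training correlation
  rep_self <- suppressWarnings(
    project_replication(m, ds$blood, ds$brain, site = ds$cohort$site,
                        group = ds$cohort$group, P = 99, seed = 14))
  expect_equal(rep_self$rho[1], lv1$rho_train, tolerance = 1e-10)
})

test_that("replication projection demands matching feature names", {
  spec <- tiny_spec(seed = 15)
  ds <- generate_linked_views(generate_cohort(spec), spec)
  grid <- data.frame(c_u = 2, c_v = 4)
  m <- suppressMessages(suppressWarnings(
    extract_model(ds$blood, ds$brain, group = ds$cohort$group,
                  site = ds$cohort$site, grid = grid, P = 99, B = 100,
                  seed = 16, control = quick_ctl())))
  skip_if(length(m$lvs) == 0, "no significant LV on this fixture")
  bad <- ds$blood; colnames(bad)[1] <- "renamed"
  expect_error(project_replication(m, bad, ds$brain), "feature mismatch")
})
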