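test_that("standardization uses training parameters and handles degenerate columns", {
  x <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  expect_warning(st <- fit_standardize(x), "zero-variance")
  expect_equal(st$center, c(a = 2, b = 5))
  expect_equal(st$scale, c(a = 1, b = 0))
  z <- apply_standardize(st, x)
  expect_equal(z[, "a"], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(z[, "b"], c(0, 0, 0), ignore_attr = TRUE)
  # a test row is transformed with the training parameters, not its own
  z_new <- apply_standardize(st, cbind(a = c(10, 20), b = c(1, 2)))
  expect_equal(z_new[, "a"], c(8, 18), ignore_attr = TRUE)
  expect_error(fit_standardize(cbind(a = c(NA, NA, 1))), "non-missing")
})

test_that("standardization is idempotent on its own training data", {
  set.seed(4)
  x <- matrix(rnorm(200), 40, 5)
  x[sample(200, 20)] <- NA
  st <- fit_standardize(x)
  z <- apply_standardize(st, x)
  expect_lt(max(abs(colMeans(z, na.rm = TRUE))), 1e-8)
  expect_lt(max(abs(apply(z, 2, sd, na.rm = TRUE) - 1)), 1e-8)
  z2 <- apply_standardize(fit_standardize(z), z)
  expect_lt(max(abs(z2 - z), na.rm = TRUE), 1e-8)
})

test_that("median imputation enforces the 20% missingness inclusion bound", {
  st <- fit_impute(cbind(a = c(1, 2, 3), b = c(2, 2, 2)))
  x <- cbind(a = c(1, NA, 3), b = c(2, 2, 2))
  expect_equal(apply_impute(st, x)[, "a"], c(1, 2, 3), ignore_attr = TRUE)
  y <- cbind(a = 1:3, b = 4:6)
  expect_identical(apply_impute(fit_impute(y), y), y)
  # 21 of 100 missing in one column: violates the <= 20% rule
  z <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("ok", "bad")))
  z[1:21, "bad"] <- NA
  expect_error(fit_impute(z), "20% missing")
})

test_that("an exactly removable batch offset is removed", {
  set.seed(8)
  base <- matrix(rnorm(40 * 30), 40, 30)
  brain <- rbind(base, base + 2)  # site2 = site1 + constant offset
  site <- rep(c("s1", "s2"), each = 40)
  st <- fit_harmonize(brain, site, eb = FALSE)
  out <- apply_harmonize(st, brain, site)
  gap <- colMeans(out[site == "s1", ]) - colMeans(out[site == "s2", ])
  expect_lt(max(abs(gap)), 1e-6)
})

test_that("single-site and unseen-site inputs are passed through with warnings", {
  x <- matrix(rnorm(100), 20, 5)
  expect_warning(st <- fit_harmonize(x, rep("s1", 20)), "single site")
  expect_identical(apply_harmonize(st, x, rep("s1", 20)), x)
  brain <- matrix(rnorm(200), 40, 5)
  site <- rep(c("s1", "s2"), each = 20)
  st2 <- fit_harmonize(brain, site, eb = FALSE)
  new <- matrix(rnorm(10), 2, 5)
  expect_warning(out <- apply_harmonize(st2, new, c("s3", "s3")), "unseen")
  expect_identical(out, new)
})

test_that("empirical-Bayes harmonization matches the reference ComBat on training data", {
  skip_if_not_installed("sva")
  set.seed(12)
  n <- 60; q <- 25
  site <- sample(rep(c("s1", "s2", "s3"), each = 20))
  brain <- matrix(rnorm(n * q), n, q) +
    matrix(rnorm(3 * q, sd = 0.5), 3, q)[as.integer(factor(site)), ]
  st <- fit_harmonize(brain, site, eb = TRUE)
  mine <- apply_harmonize(st, brain, site)
  ref <- t(sva::ComBat(t(brain), batch = site, par.prior = TRUE,
                       prior.plots = FALSE))
  expect_lt(max(abs(mine - ref)), 1e-6)
})

test_that("harmonization shrinks between-site variance and fits on train only", {
  spec <- truth_spec(n_participants = 200, q_brain = 300,
                     site_effect_sd = 0.5, missing_rate = 0, seed = 33)
  ds <- generate_linked_views(generate_cohort(spec), spec)
  site <- ds$cohort$site
  bsv <- function(m) {
    mu <- rowsum(m, site) / as.numeric(table(site))
    mean(apply(mu, 2, var))
  }
  st <- fit_harmonize(ds$brain, site)
  out <- apply_harmonize(st, ds$brain, site)
  expect_lt(bsv(out), 0.2 * bsv(ds$brain))
  # the fitted state is a pure function of the training partition
  tr <- seq_len(150); te <- 151:200
  st_tr <- fit_harmonize(ds$brain[tr, ], site[tr])
  brain2 <- ds$brain
  brain2[te, ] <- brain2[te, ] + 100  # corrupt test rows only
  st_tr2 <- fit_harmonize(brain2[tr, ], site[tr])
  expect_identical(st_tr, st_tr2)
  # and test rows are adjusted with training estimates
  a1 <- apply_harmonize(st_tr, ds$brain[te, ], site[te])
  a2 <- apply_harmonize(st_tr2, brain2[te, ] - 100, site[te])
  expect_equal(a1, a2)
})

test_that("the composite pipeline imputes, harmonizes and standardizes in order", {
  spec <- tiny_spec(seed = 9)
  ds <- generate_linked_views(generate_cohort(spec), spec)
  tr <- seq_len(90); te <- 91:120
  st <- fit_preprocess(ds$blood[tr, ], ds$brain[tr, ],
                       site = ds$cohort$site[tr],
                       group = ds$cohort$group[tr])
  out_tr <- apply_preprocess(st, ds$blood[tr, ], ds$brain[tr, ],
                             site = ds$cohort$site[tr],
                             group = ds$cohort$group[tr])
  expect_false(anyNA(out_tr$blood))
  expect_lt(max(abs(colMeans(out_tr$blood))), 1e-8)
  expect_lt(max(abs(colMeans(out_tr$brain))), 1e-8)
  expect_lt(max(abs(apply(out_tr$brain, 2, sd) - 1)), 1e-6)
  # the fit-time training by-product equals the explicit application
  st2 <- fit_preprocess(ds$blood[tr, ], ds$brain[tr, ],
                        site = ds$cohort$site[tr],
                        group = ds$cohort$group[tr])
  expect_equal(attr(st2, "train")$brain, out_tr$brain)
  # test rows use training parameters (means not re-centered to zero)
  out_te <- apply_preprocess(st, ds$blood[te, ], ds$brain[te, ],
                             site = ds$cohort$site[te],
                             group = ds$cohort$group[te])
  expect_gt(max(abs(colMeans(out_te$blood))), 1e-8)
})
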