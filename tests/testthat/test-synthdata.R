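test_that("truth_spec validates its configuration", {
  expect_error(truth_spec(group_proportions = c(0.3, 0.3, 0.3, 0.3)),
               "sum to 1")
  expect_error(truth_spec(missing_rate = 0.25), "missing_rate")
  expect_error(truth_spec(K_true = 3, rho_star = c(0.5, 0.4, 0.3),
                          u_support = 8, p_blood = 20),
               "supports exceed")
  spec <- truth_spec(seed = 3)
  expect_equal(sqrt(colSums(spec$u_star^2)), rep(1, 2))
  expect_equal(sqrt(colSums(spec$v_star^2)), rep(1, 2))
  # disjoint supports across planted LVs
  expect_length(intersect(which(spec$u_star[, 1] != 0),
                          which(spec$u_star[, 2] != 0)), 0)
  expect_length(intersect(which(spec$v_star[, 1] != 0),
                          which(spec$v_star[, 2] != 0)), 0)
})

test_that("cohort composition and determinism hold", {
  spec <- truth_spec(n_participants = 100,
                     group_proportions = c(ROD = 0.25, ROP = 0.25,
                                           `CHR-P` = 0.25, HC = 0.25),
                     seed = 5)
  co <- generate_cohort(spec)
  expect_equal(sum(table(co$group)), 100)
  expect_equal(as.numeric(table(co$group)), rep(25, 4))
  expect_identical(co, generate_cohort(spec))
})

test_that("a 678-participant cohort reproduces the reference group sizes", {
  spec <- truth_spec(n_participants = 678, seed = 2)
  co <- generate_cohort(spec)
  counts <- table(co$group)
  expect_equal(unname(c(counts["ROD"], counts["ROP"], counts["CHR-P"],
                        counts["HC"])),
               c(163, 177, 172, 166), ignore_attr = TRUE)
})

test_that("linked views are deterministic and respect the noiseless limit", {
  spec <- truth_spec(n_participants = 150, p_blood = 10, q_brain = 40,
                     K_true = 1, rho_star = 1, u_support = 3, v_support = 8,
                     noise_sd = 0, site_effect_sd = 0, missing_rate = 0,
                     seed = 11)
  co <- generate_cohort(spec)
  ds <- generate_linked_views(co, spec)
  expect_identical(ds, generate_linked_views(co, spec))
  r <- cor(ds$blood %*% spec$u_star[, 1], ds$brain %*% spec$v_star[, 1])
  expect_equal(as.numeric(r), 1, tolerance = 1e-10)
})

test_that("realized latent correlation sits in the Fisher-z band of the target", {
  spec <- truth_spec(n_participants = 2000, p_blood = 10, q_brain = 50,
                     K_true = 1, rho_star = 0.7, u_support = 3,
                     v_support = 10, noise_sd = 0.01, site_effect_sd = 0,
                     missing_rate = 0, seed = 21)
  ds <- generate_linked_views(generate_cohort(spec), spec)
  r <- cor(ds$blood %*% spec$u_star[, 1], ds$brain %*% spec$v_star[, 1])
  band <- tanh(atanh(0.7) + c(-1, 1) * 1.96 / sqrt(2000 - 3))
  expect_gt(r, band[1])
  expect_lt(r, band[2])
})

test_that("missingness is inserted in the blood view only, at the stated rate", {
  spec <- truth_spec(missing_rate = 0.1, seed = 7)
  ds <- generate_linked_views(generate_cohort(spec), spec)
  frac <- mean(is.na(ds$blood))
  expect_gte(frac, 0.08)
  expect_lte(frac, 0.12)
  expect_false(anyNA(ds$brain))
})

test_that("site offsets shift per-site brain column means as injected", {
  spec <- truth_spec(seed = 13)
  ds <- generate_linked_views(generate_cohort(spec), spec)
  m1 <- colMeans(ds$brain[ds$cohort$site == "site1", ])
  m2 <- colMeans(ds$brain[ds$cohort$site == "site2", ])
  injected <- spec$site_offsets["site1", ] - spec$site_offsets["site2", ]
  expect_gt(cor(m1 - m2, injected), 0.9)
})

test_that("regressing the brain view on realized latent scores recovers the planted support", {
  spec <- truth_spec(noise_sd = 0.02, site_effect_sd = 0, missing_rate = 0,
                     seed = 17)
  ds <- generate_linked_views(generate_cohort(spec), spec)
  om <- ds$truth$omega
  coef <- solve(crossprod(om), crossprod(om, ds$brain))
  for (k in 1:2) {
    top <- order(abs(coef[k, ]), decreasing = TRUE)[1:100]
    expect_setequal(top, which(spec$v_star[, k] != 0))
  }
})

test_that("predictor tables have the reference domain widths and planted effects", {
  spec <- truth_spec(seed = 23)
  ds <- simulate_dataset(spec, effect_size = 1.5)
  expect_equal(vapply(ds$predictors, ncol, integer(1)),
               c(psychosocial = 43L, neurocognition = 7L, medication = 4L))
  grp <- attr(ds$predictors$psychosocial, "groups")
  expect_gte(min(length(grp$high), length(grp$low)), 40)
  # planted columns separate high from low scorers decisively (d = 1.5)
  for (j in attr(ds$predictors$psychosocial, "informative")) {
    p <- t.test(ds$predictors$psychosocial[grp$high, j],
                ds$predictors$psychosocial[grp$low, j])$p.value
    expect_lt(p, 1e-3)
  }
  # medication is a planted null
  expect_length(attr(ds$predictors$medication, "informative"), 0)
})

test_that("zero effect size produces exchangeable predictor columns", {
  spec <- truth_spec(seed = 29)
  ds <- generate_linked_views(generate_cohort(spec), spec)
  pred <- generate_predictor_tables(ds$cohort, ds$truth$xi[, 1],
                                    ds$truth$omega[, 1], effect_size = 0,
                                    seed = 31)
  grp <- attr(pred$psychosocial, "groups")
  pvals <- apply(pred$psychosocial, 2, function(col)
    t.test(col[ds$cohort$id %in% grp$high],
           col[ds$cohort$id %in% grp$low])$p.value)
  expect_lt(mean(pvals < 0.05), 0.2)
  expect_error(
    generate_predictor_tables(ds$cohort, ds$truth$xi[, 1],
                              ds$truth$omega[, 1],
                              n_informative = c(psychosocial = 50,
                                                neurocognition = 0,
                                                medication = 0)),
    "configuration error")
})
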