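test_that("atlas summaries count strictly signed voxels per label", {
  atlas <- label_atlas(rep(1:2, each = 10),
                       c(`1` = "regionA", `2` = "regionB"))
  v <- c(c(1, 1, 1, rep(0, 7)), rep(-1, 10))
  s <- summarize_weights_by_label(v, atlas)
  a <- s[s$name == "regionA", ]
  expect_equal(a$pct_pos, 30)
  expect_equal(a$pct_neg, 0)
  # the fully nonzero label sorts first
  expect_equal(s$name[1], "regionB")
  # single label covering everything reproduces the global fractions
  whole <- label_atlas(rep(1L, 20), c(`1` = "all"))
  sw <- summarize_weights_by_label(v, whole)
  expect_equal(sw$pct_pos, 100 * mean(v > 0))
  expect_equal(sw$pct_neg, 100 * mean(v < 0))
  expect_warning(empty <- summarize_weights_by_label(rep(0, 20), atlas),
                 "all-zero")
  expect_equal(nrow(empty), 0)
  expect_error(summarize_weights_by_label(v[1:5], atlas), "lengths differ")
  expect_error(label_atlas(c(1, 2), c(`1` = "only-one")), "unnamed")
})

test_that("a planted brain pattern tops the ranking of its block region", {
  spec <- tiny_spec(seed = 31)
  atlas <- make_block_atlas(spec$q_brain, n_regions = 6)
  support <- which(spec$v_star[, 1] != 0)
  region_of_support <- as.integer(names(which.max(
    table(atlas$labels[support]))))
  # concentrate the weights fully inside one region for a clean check
  v <- numeric(spec$q_brain)
  idx <- which(atlas$labels == 3)[1:5]
  v[idx] <- c(0.5, -0.2, 0.3, 0.4, -0.1)
  s <- summarize_weights_by_label(v, atlas)
  expect_equal(s$label[1], 3)
  expect_gt(s$pct_pos[1] + s$pct_neg[1], 0)
})

test_that("datasets round-trip through delimited text", {
  spec <- tiny_spec(seed = 32)
  ds <- simulate_dataset(spec)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(all(file.exists(file.path(dir,
    c("cohort.csv", "blood.csv", "brain.csv", "predictors_psychosocial.csv",
      "truth.json")))))
  back <- read_dataset(dir)
  expect_equal(back$blood, ds$blood, tolerance = 1e-12)
  expect_equal(back$brain, ds$brain, tolerance = 1e-12)
  expect_equal(as.character(back$cohort$group), as.character(ds$cohort$group))
  expect_equal(back$truth$spec$seed, spec$seed)
})

test_that("preprocessing states round-trip through JSON", {
  spec <- tiny_spec(seed = 33)
  ds <- generate_linked_views(generate_cohort(spec), spec)
  st <- fit_preprocess(ds$blood, ds$brain, site = ds$cohort$site,
                       group = ds$cohort$group)
  attr(st, "train") <- NULL
  path <- withr::local_tempfile(fileext = ".json")
  write_preproc_state(st, path)
  st2 <- read_preproc_state(path)
  out1 <- apply_preprocess(st, ds$blood, ds$brain, site = ds$cohort$site,
                           group = ds$cohort$group)
  out2 <- apply_preprocess(st2, ds$blood, ds$brain, site = ds$cohort$site,
                           group = ds$cohort$group)
  expect_equal(out1$blood, out2$blood, tolerance = 1e-12)
  expect_equal(out1$brain, out2$brain, tolerance = 1e-12)
})

test_that("run configurations validate unknown keys with their path", {
  cfg <- default_run_config()
  expect_equal(cfg$svm$n_perm, 5000)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_run_config(list(spls = list(P = 199)), path)
  merged <- read_run_config(path)
  expect_equal(merged$spls$P, 199)
  expect_equal(merged$spls$alpha, 0.05)
  write_run_config(list(spls = list(nonsense = 1)), path)
  expect_error(read_run_config(path), "spls.nonsense")
})

test_that("the command-line front end simulates reproducibly", {
  cli <- system.file("cli", "bbspls.R", package = "bbspls")
  skip_if(cli == "", "CLI script not installed")
  rscript <- file.path(R.home("bin"), "Rscript")
  cfg <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(synth = list(n_participants = 60, q_brain = 80,
                                     v_support = 10, u_support = 3,
                                     missing_rate = 0.05)), cfg)
  libs <- paste(.libPaths(), collapse = .Platform$path.sep)
  run <- function(out) system2(rscript,
    c(cli, "simulate", "--config", shQuote(cfg), "--seed", "7",
      "--out", shQuote(out)),
    env = paste0("R_LIBS=", libs), stdout = TRUE, stderr = TRUE)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run(d1); run(d2)
  expect_true(file.exists(file.path(d1, "cohort.csv")))
  expect_true(file.exists(file.path(d1, "run_config.yaml")))
  expect_identical(readLines(file.path(d1, "blood.csv")),
                   readLines(file.path(d2, "blood.csv")))
  expect_identical(readLines(file.path(d1, "cohort.csv")),
                   readLines(file.path(d2, "cohort.csv")))
})
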