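#' Write / read a synthetic dataset as delimited text
#'
#' Views go to CSV (header row = feature names, first column = participant
#' id), the cohort table to `cohort.csv`, predictor domains to
#' `predictors_<domain>.csv`, and the truth echo (spec scalars, planted
#' weights as sparse triplets, realized latent scores) to `truth.json`.
#'
#' @param dataset a `bbspls_dataset`.
#' @param dir output directory (created if needed).
#' @return `write_dataset()`: the directory, invisibly; `read_dataset()`:
#'   a list with `cohort`, `blood`, `brain`, `predictors`, `truth` (the
#'   truth slot is `NULL` when no sidecar is present).
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "bbspls_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_view <- function(m, path) {
    df <- data.frame(id = rownames(m), as.data.frame(m),
                     check.names = FALSE)
    write.csv(df, path, row.names = FALSE)
  }
  write.csv(dataset$cohort, file.path(dir, "cohort.csv"), row.names = FALSE)
  write_view(dataset$blood, file.path(dir, "blood.csv"))
  write_view(dataset$brain, file.path(dir, "brain.csv"))
  for (dom in names(dataset$predictors))
    write_view(dataset$predictors[[dom]],
               file.path(dir, paste0("predictors_", dom, ".csv")))
  spec <- dataset$truth$spec
  sparse <- function(W) {
    idx <- which(W != 0, arr.ind = TRUE)
    data.frame(feature = idx[, 1], lv = idx[, 2], weight = W[idx])
  }
  truth <- list(
    spec = spec[c("n_participants", "p_blood", "q_brain", "n_sites",
                  "group_proportions", "K_true", "rho_star",
                  "site_effect_sd", "noise_sd", "missing_rate",
                  "discovery_fraction", "seed")],
    u_star = sparse(spec$u_star), v_star = sparse(spec$v_star),
    group_shift = spec$group_shift,
    xi = dataset$truth$xi, omega = dataset$truth$omega)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  read_view <- function(path) {
    df <- read.csv(path, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
  }
  cohort <- read.csv(file.path(dir, "cohort.csv"))
  cohort$group <- factor(cohort$group,
                         levels = unique(c("ROD", "ROP", "CHR-P", "HC",
                                           unique(cohort$group))))
  cohort$group <- droplevels(cohort$group)
  pred_files <- list.files(dir, pattern = "^predictors_.*\\.csv$")
  predictors <- if (length(pred_files) > 0) {
    out <- lapply(pred_files, function(f) read_view(file.path(dir, f)))
    names(out) <- sub("^predictors_(.*)\\.csv$", "\\1", pred_files)
    out
  } else NULL
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path))
    jsonlite::read_json(truth_path, simplifyVector = TRUE) else NULL
  list(cohort = cohort, blood = read_view(file.path(dir, "blood.csv")),
       brain = read_view(file.path(dir, "brain.csv")),
       predictors = predictors, truth = truth)
}

#' Serialize a preprocessing state or SPLS model to JSON
#'
#' States round-trip exactly (numeric vectors/matrices restored), so a
#' replication sample can be projected through the very parameters of the
#' original fit.
#'
#' @param state a `preproc_state`.
#' @param path JSON file path.
#' @return `write_preproc_state()`: `path`, invisibly;
#'   `read_preproc_state()`: the restored state.
#' @export
write_preproc_state <- function(state, path) {
  stopifnot(inherits(state, "preproc_state"))
  jsonlite::write_json(serialize_state(state), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

serialize_state <- function(x) {
  if (inherits(x, "preproc_state")) {
    out <- lapply(unclass(x), serialize_state)
    out$.class <- "preproc_state"
    out
  } else if (is.list(x)) lapply(x, serialize_state)
  else if (is.matrix(x))
    list(.matrix = TRUE, data = as.numeric(x), nrow = nrow(x),
         rownames = rownames(x), colnames = colnames(x))
  else x
}

#' @rdname write_preproc_state
#' @export
read_preproc_state <- function(path) {
  restore <- function(x) {
    if (!is.list(x)) return(x)
    if (isTRUE(x$.matrix)) {
      m <- matrix(unlist(x$data), nrow = x$nrow)
      if (!is.null(x$rownames)) rownames(m) <- unlist(x$rownames)
      if (!is.null(x$colnames)) colnames(m) <- unlist(x$colnames)
      return(m)
    }
    cls <- x$.class
    x$.class <- NULL
    out <- lapply(x, restore)
    # scalars parsed as length-1 lists come back as vectors
    out <- lapply(out, function(e)
      if (is.list(e) && all(!vapply(e, is.list, logical(1))) &&
          length(e) > 0 && is.null(base::names(e))) unlist(e) else e)
    if (!is.null(cls)) class(out) <- cls
    out
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  restore(obj)
}

#' Export the weight tables of a fitted SPLS model
#'
#' Writes one CSV per significant LV (feature, weight, bootstrap ratio,
#' stability flag, per view) plus a compact `model.json` (nonzero weights
#' only, per-LV statistics, termination reason).
#'
#' @param model an `spls_model`.
#' @param dir output directory.
#' @return The directory, invisibly.
#' @export
write_spls_model <- function(model, dir) {
  stopifnot(inherits(model, "spls_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lv_json <- lapply(model$lvs, function(lv) {
    nz_u <- which(lv$u != 0); nz_v <- which(lv$v != 0)
    for (view in c("blood", "brain")) {
      w <- if (view == "blood") lv$u else lv$v
      br <- if (view == "blood") lv$bootstrap$br_u else lv$bootstrap$br_v
      st <- if (view == "blood") lv$bootstrap$stable_u else lv$bootstrap$stable_v
      tab <- data.frame(feature = names(w), weight = w,
                        bootstrap_ratio = br, stable = st)
      write.csv(tab, file.path(dir, sprintf("lv%d_%s_weights.csv", lv$k,
                                            view)), row.names = FALSE)
    }
    list(k = lv$k, rho_train = lv$rho_train, rho_test = lv$rho_test,
         p_perm = lv$p_perm,
         budget = as.list(lv$budget),
         u = as.list(setNames(lv$u[nz_u], names(lv$u)[nz_u])),
         v = as.list(setNames(lv$v[nz_v], names(lv$v)[nz_v])))
  })
  jsonlite::write_json(
    list(n_lvs = length(model$lvs), termination = model$termination,
         alpha = model$alpha, P = model$P, B = model$B, seed = model$seed,
         lvs = lv_json),
    file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run configuration handling
#'
#' `default_run_config()` returns every tunable knob of the pipeline with
#' its default; `read_run_config()` loads a YAML file and validates it
#' against the defaults, rejecting unknown keys with their path;
#' `write_run_config()` writes the resolved configuration next to a run's
#' outputs for reproducibility.
#'
#' @param path YAML file path.
#' @param config a configuration list.
#' @return A named configuration list.
#' @export
default_run_config <- function() {
  list(
    synth = list(n_participants = 400, p_blood = 20, q_brain = 2000,
                 n_sites = 3, K_true = 2, rho_star = c(0.5, 0.35),
                 u_support = 5, v_support = 100, site_effect_sd = 0.5,
                 noise_sd = 0.2, missing_rate = 0.1,
                 discovery_fraction = 2 / 3, effect_size = 1),
    spls = list(n_outer = 10, n_inner = 10, grid_u = 8, grid_v = 8,
                alpha = 0.05, K_max = 10, P = 999, B = 500,
                harmonize = TRUE, eb = TRUE, br_threshold = 2,
                reselect_perm = FALSE),
    svm = list(n_folds = 10, n_repeats = 10, inner_folds = 10,
               n_perm = 5000, perm_repeats = 1, fdr = 0.05),
    seed = 1)
}

#' @rdname default_run_config
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_cfg <- function(base, new, prefix = "") {
    for (key in names(new)) {
      path_key <- paste0(prefix, key)
      if (!key %in% names(base))
        stop("read_run_config: unknown configuration key: ", path_key)
      if (is.list(base[[key]]) && is.list(new[[key]]))
        base[[key]] <- merge_cfg(base[[key]], new[[key]],
                                 paste0(path_key, "."))
      else base[[key]] <- new[[key]]
    }
    base
  }
  merge_cfg(default_run_config(), user)
}

#' @rdname default_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
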