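#' Specify the ground truth of a synthetic blood-brain cohort
#'
#' A `truth_spec` fixes everything the generator needs: cohort composition,
#' view dimensions, the planted sparse weight-vector pairs, the target
#' latent-score correlations, site batch effects, residual noise and the
#' missingness rate. All randomness downstream is a deterministic function
#' of `seed`, so identical specs reproduce identical datasets.
#'
#' Planted weight vectors are unit L2 norm with disjoint supports across
#' latent variables (LVs), which makes recovery identifiable. When
#' `u_star`/`v_star` are not supplied they are drawn once from the seed:
#' supports are disjoint blocks of a random feature permutation, support
#' values standard normal, then normalized.
#'
#' @param n_participants cohort size.
#' @param p_blood,q_brain number of blood and brain (voxel) features.
#' @param n_sites number of acquisition sites.
#' @param group_proportions named fractions for the four diagnostic groups
#'   (ROD, ROP, CHR-P, HC); must sum to 1. Defaults to the proportions of a
#'   678-participant early-psychosis cohort (163/177/172/166).
#' @param K_true number of planted LVs.
#' @param rho_star latent-score correlation targets, length `K_true`, in
#'   `[0, 1]`.
#' @param u_support,v_support support sizes of the planted blood and brain
#'   weight vectors (per LV).
#' @param u_star,v_star optional explicit planted weights (`p_blood x K` and
#'   `q_brain x K` matrices, unit-norm disjoint-support columns).
#' @param group_shift optional `4 x K_true` matrix of per-group mean offsets
#'   added to both members of each latent pair (rows in the order of
#'   `group_proportions`). Default all zero, so `rho_star` is exactly the
#'   latent correlation.
#' @param site_effect_sd standard deviation of the additive per-site,
#'   per-voxel offsets on the brain view.
#' @param noise_sd residual noise standard deviation in both views.
#' @param missing_rate fraction of blood-view cells set missing completely
#'   at random, in `[0, 0.2]` (mirrors a 20% missingness inclusion bound).
#' @param discovery_fraction fraction assigned to the discovery split,
#'   stratified by group.
#' @param seed integer seed governing all generation.
#' @return An object of class `truth_spec`.
#' @export
truth_spec <- function(n_participants = 400, p_blood = 20, q_brain = 2000,
                       n_sites = 3,
                       group_proportions = c(ROD = 163, ROP = 177,
                                             `CHR-P` = 172, HC = 166) / 678,
                       K_true = 2, rho_star = c(0.5, 0.35),
                       u_support = 5, v_support = 100,
                       u_star = NULL, v_star = NULL, group_shift = NULL,
                       site_effect_sd = 0.5, noise_sd = 0.2,
                       missing_rate = 0.1, discovery_fraction = 2 / 3,
                       seed = 1) {
  if (length(group_proportions) != 4 || any(group_proportions < 0))
    stop("configuration error: group_proportions must be 4 nonnegative fractions")
  if (abs(sum(group_proportions) - 1) > 1e-9)
    stop("configuration error: group_proportions must sum to 1 (within 1e-9)")
  if (length(rho_star) != K_true || any(rho_star < 0 | rho_star > 1))
    stop("configuration error: rho_star must be length K_true with values in [0, 1]")
  if (missing_rate < 0 || missing_rate > 0.2)
    stop("configuration error: missing_rate must lie in [0, 0.2]")
  if (K_true * u_support > p_blood || K_true * v_support > q_brain)
    stop("configuration error: disjoint planted supports exceed feature counts")
  if (is.null(names(group_proportions)))
    names(group_proportions) <- c("ROD", "ROP", "CHR-P", "HC")
  if (is.null(group_shift))
    group_shift <- matrix(0, 4, K_true,
                          dimnames = list(names(group_proportions), NULL))
  stopifnot(nrow(group_shift) == 4, ncol(group_shift) == K_true)

  draw_planted <- function(dim, supp, K, sub_seed) {
    with_local_seed(sub_seed, {
      perm <- sample.int(dim)
      W <- matrix(0, dim, K)
      for (k in seq_len(K)) {
        idx <- perm[((k - 1) * supp + 1):(k * supp)]
        # support magnitudes bounded away from zero keep the planted
        # support identifiable (no vanishing weights)
        w <- sample(c(-1, 1), supp, replace = TRUE) * runif(supp, 0.5, 1.5)
        W[idx, k] <- w / sqrt(sum(w^2))
      }
      W
    })
  }
  if (is.null(u_star))
    u_star <- draw_planted(p_blood, u_support, K_true, derive_seed(seed, 11))
  if (is.null(v_star))
    v_star <- draw_planted(q_brain, v_support, K_true, derive_seed(seed, 13))
  # scanner offsets are a fixed property of the sites, drawn once with the
  # spec so that discovery and replication draws share them
  site_offsets <- with_local_seed(derive_seed(seed, 19), {
    matrix(rnorm(n_sites * q_brain, sd = site_effect_sd), n_sites, q_brain,
           dimnames = list(paste0("site", seq_len(n_sites)), NULL))
  })
  stopifnot(nrow(u_star) == p_blood, nrow(v_star) == q_brain,
            ncol(u_star) == K_true, ncol(v_star) == K_true)
  if (any(abs(sqrt(colSums(u_star^2)) - 1) > 1e-8) ||
      any(abs(sqrt(colSums(v_star^2)) - 1) > 1e-8))
    stop("configuration error: planted weight columns must have unit L2 norm")

  structure(list(
    n_participants = n_participants, p_blood = p_blood, q_brain = q_brain,
    n_sites = n_sites, group_proportions = group_proportions,
    K_true = K_true, rho_star = rho_star,
    u_star = u_star, v_star = v_star, group_shift = group_shift,
    site_offsets = site_offsets,
    site_effect_sd = site_effect_sd, noise_sd = noise_sd,
    missing_rate = missing_rate, discovery_fraction = discovery_fraction,
    seed = as.integer(seed)), class = "truth_spec")
}

# Largest-remainder apportionment of n among proportions (sums exactly to n).
apportion <- function(n, proportions) {
  raw <- n * proportions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a synthetic cohort table
#'
#' Assigns diagnostic group (largest-remainder apportionment of the group
#' proportions), site, and a group-stratified discovery/replication split.
#' Deterministic for a fixed spec and seed.
#'
#' @param spec a [truth_spec()].
#' @return A `data.frame` with columns `id`, `group`, `site`, `split`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "truth_spec"))
  n <- spec$n_participants
  counts <- apportion(n, spec$group_proportions)
  group <- factor(rep(names(spec$group_proportions), counts),
                  levels = names(spec$group_proportions))
  with_local_seed(derive_seed(spec$seed, 1), {
    group <- group[sample.int(n)]
    site <- sample(rep_len(paste0("site", seq_len(spec$n_sites)), n))
    split <- rep("replication", n)
    for (g in levels(group)) {
      idx <- which(group == g)
      n_disc <- round(spec$discovery_fraction * length(idx))
      split[sample(idx, n_disc)] <- "discovery"
    }
    data.frame(id = sprintf("S%04d", seq_len(n)), group = group,
               site = site, split = split, stringsAsFactors = FALSE)
  })
}

#' Generate linked blood and brain views with planted latent structure
#'
#' For each participant and planted LV k a latent pair is drawn from a
#' bivariate normal with correlation `rho_star[k]`, with the group's mean
#' shift added to both members. The blood row is the latent blood scores
#' mixed through the planted blood weights plus isotropic noise; the brain
#' row adds per-site constant voxel offsets (the batch effect) on top of the
#' planted brain structure and noise. Missing cells are inserted completely
#' at random, in the blood view only, at exactly `missing_rate`.
#'
#' @param cohort output of [generate_cohort()] for the same spec.
#' @param spec a [truth_spec()].
#' @return An object of class `bbspls_dataset`: list with `cohort`, `blood`,
#'   `brain`, `predictors` (NULL until [generate_predictor_tables()] is
#'   used), and `truth` (the spec plus the realized latent score matrices
#'   `xi` (blood side) and `omega` (brain side)).
#' @export
generate_linked_views <- function(cohort, spec) {
  stopifnot(inherits(spec, "truth_spec"), nrow(cohort) == spec$n_participants)
  n <- spec$n_participants; p <- spec$p_blood; q <- spec$q_brain
  K <- spec$K_true
  with_local_seed(derive_seed(spec$seed, 2), {
    xi <- matrix(0, n, K); omega <- matrix(0, n, K)
    for (k in seq_len(K)) {
      z1 <- rnorm(n)
      z2 <- spec$rho_star[k] * z1 + sqrt(1 - spec$rho_star[k]^2) * rnorm(n)
      shift <- spec$group_shift[as.character(cohort$group), k]
      xi[, k] <- z1 + shift
      omega[, k] <- z2 + shift
    }
    blood <- xi %*% t(spec$u_star) +
      matrix(rnorm(n * p, sd = spec$noise_sd), n, p)
    site_off <- spec$site_offsets
    brain <- omega %*% t(spec$v_star) +
      site_off[cohort$site, , drop = FALSE] +
      matrix(rnorm(n * q, sd = spec$noise_sd), n, q)
    if (spec$missing_rate > 0) {
      n_miss <- round(spec$missing_rate * n * p)
      blood[sample.int(n * p, n_miss)] <- NA_real_
    }
    dimnames(blood) <- list(cohort$id, sprintf("blood_%02d", seq_len(p)))
    dimnames(brain) <- list(cohort$id, sprintf("voxel_%05d", seq_len(q)))
    rownames(xi) <- rownames(omega) <- cohort$id
    structure(list(cohort = cohort, blood = blood, brain = brain,
                   predictors = NULL,
                   truth = list(spec = spec, xi = xi, omega = omega,
                                site_offsets = site_off)),
              class = "bbspls_dataset")
  })
}

#' Generate clinical predictor tables tied to a latent signature
#'
#' Emulates three predictor domains — psychosocial (43 features),
#' neurocognition (7) and medication (4). Participants are first grouped by
#' quartile conjunction of the supplied blood and brain latent scores (both
#' in the top quartile = high, both in the bottom = low). A configurable
#' subset of columns per domain then differs between high and low scorers
#' by `effect_size` standard deviations; all remaining columns are pure
#' standard-normal noise. The medication domain is generated with zero
#' planted effect by default, mirroring a null medication model.
#'
#' @param cohort cohort table (row order defines participant order).
#' @param blood_scores,brain_scores latent score vectors for the targeted LV.
#' @param effect_size standardized mean difference on informative columns.
#' @param n_informative named counts of informative columns per domain.
#' @param widths named domain widths.
#' @param seed integer seed.
#' @return Named list of numeric matrices (one per domain), each with an
#'   `informative` attribute naming the planted columns and a `groups`
#'   attribute holding the [assign_quartile_groups()] result used.
#' @export
generate_predictor_tables <- function(cohort, blood_scores, brain_scores,
                                      effect_size = 1,
                                      n_informative = c(psychosocial = 5,
                                                        neurocognition = 3,
                                                        medication = 0),
                                      widths = c(psychosocial = 43,
                                                 neurocognition = 7,
                                                 medication = 4),
                                      seed = 1) {
  stopifnot(length(blood_scores) == nrow(cohort),
            length(brain_scores) == nrow(cohort))
  if (any(n_informative[names(widths)] > widths))
    stop("configuration error: informative-column count exceeds domain width")
  grp <- assign_quartile_groups(blood_scores, brain_scores, ids = cohort$id)
  offset <- numeric(nrow(cohort))
  offset[match(grp$high, cohort$id)] <- effect_size / 2
  offset[match(grp$low, cohort$id)] <- -effect_size / 2
  with_local_seed(derive_seed(seed, 3), {
    out <- lapply(names(widths), function(dom) {
      w <- widths[[dom]]
      k <- n_informative[[dom]] %||% 0L
      x <- matrix(rnorm(nrow(cohort) * w), nrow(cohort), w,
                  dimnames = list(cohort$id,
                                  sprintf("%s_%02d", substr(dom, 1, 3),
                                          seq_len(w))))
      info <- if (k > 0) sample(colnames(x), k) else character(0)
      for (j in info) x[, j] <- x[, j] + offset
      attr(x, "informative") <- info
      attr(x, "groups") <- grp
      x
    })
    names(out) <- names(widths)
    out
  })
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper: cohort, linked views, and predictor tables tied to
#' the first planted LV's realized latent scores.
#'
#' @param spec a [truth_spec()].
#' @param effect_size standardized mean difference for informative predictor
#'   columns (see [generate_predictor_tables()]).
#' @return A `bbspls_dataset` with the `predictors` slot filled.
#' @export
simulate_dataset <- function(spec, effect_size = 1) {
  cohort <- generate_cohort(spec)
  ds <- generate_linked_views(cohort, spec)
  ds$predictors <- generate_predictor_tables(
    cohort, ds$truth$xi[, 1], ds$truth$omega[, 1],
    effect_size = effect_size, seed = derive_seed(spec$seed, 4))
  ds
}

#' Derive a replication spec sharing the planted truth
#'
#' Returns the same truth (planted weights, latent correlations, group
#' shifts, site offsets) under a new sampling seed — an independent cohort
#' draw from the same population measured on the same scanners, the
#' synthetic analogue of a replication sample.
#'
#' @param spec a [truth_spec()].
#' @param seed new sampling seed.
#' @param n_participants optional replication cohort size (defaults to the
#'   original).
#' @return A `truth_spec`.
#' @export
replicate_spec <- function(spec, seed, n_participants = NULL) {
  stopifnot(inherits(spec, "truth_spec"))
  spec$seed <- as.integer(seed)
  if (!is.null(n_participants)) spec$n_participants <- n_participants
  spec
}

#' @export
print.bbspls_dataset <- function(x, ...) {
  cat("Synthetic blood-brain dataset\n")
  cat(sprintf("  participants: %d  (groups: %s)\n", nrow(x$cohort),
              paste(sprintf("%s=%d", levels(x$cohort$group),
                            table(x$cohort$group)), collapse = ", ")))
  cat(sprintf("  blood view: %d features (%.1f%% missing)\n",
              ncol(x$blood), 100 * mean(is.na(x$blood))))
  cat(sprintf("  brain view: %d voxels, %d sites\n", ncol(x$brain),
              length(unique(x$cohort$site))))
  cat(sprintf("  planted LVs: %d (rho* = %s)\n", x$truth$spec$K_true,
              paste(format(x$truth$spec$rho_star), collapse = ", ")))
  invisible(x)
}
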