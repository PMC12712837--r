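# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the whole suite stays fast.

# A desk-scale truth spec for pipeline tests.
tiny_spec <- function(seed = 1, ...) {
  truth_spec(n_participants = 120, p_blood = 10, q_brain = 60, n_sites = 2,
             group_proportions = c(ROD = 0.25, ROP = 0.25, `CHR-P` = 0.25,
                                   HC = 0.25),
             K_true = 1, rho_star = 0.8, u_support = 3, v_support = 10,
             site_effect_sd = 0.3, noise_sd = 0.1, missing_rate = 0.05,
             seed = seed, ...)
}

# Planted one-factor views without cohort plumbing, for spls_core tests.
planted_rank1 <- function(n = 200, p = 20, q = 50, u_supp = 5, v_supp = 10,
                          rho = 1, noise_sd = 0, seed = 1) {
  set.seed(seed)
  mag <- function(k) sample(c(-1, 1), k, TRUE) * runif(k, 0.5, 1.5)
  u <- numeric(p); u[seq_len(u_supp)] <- mag(u_supp)
  u <- u / sqrt(sum(u^2))
  v <- numeric(q); v[q - seq_len(v_supp) + 1] <- mag(v_supp)
  v <- v / sqrt(sum(v^2))
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  X <- tcrossprod(z1, u) + matrix(rnorm(n * p, sd = noise_sd), n, p)
  Y <- tcrossprod(z2, v) + matrix(rnorm(n * q, sd = noise_sd), n, q)
  # center only: column rescaling would rotate the planted direction
  list(X = scale(X, scale = FALSE), Y = scale(Y, scale = FALSE),
       u_star = u, v_star = v, xi = z1, omega = z2)
}

# Balanced two-class predictor fixture with planted mean shifts.
clf_fixture <- function(n_per_class = 60, p = 20, n_informative = 4,
                        effect = 1.5, seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("low", "high"), each = n_per_class),
              levels = c("low", "high"))
  x <- matrix(rnorm(2 * n_per_class * p), 2 * n_per_class, p,
              dimnames = list(NULL, sprintf("f%02d", seq_len(p))))
  info <- seq_len(n_informative)
  x[y == "high", info] <- x[y == "high", info] + effect
  list(x = x, y = y, informative = colnames(x)[info])
}

abs_cos <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))

with_seed_shuffle <- function(x, seed) {
  set.seed(seed)
  sample(x)
}
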