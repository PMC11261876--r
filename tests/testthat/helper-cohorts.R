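# shared fixtures and independent oracles, built in code

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small 4-class cohort (2 squamous) with ample per-class signal; imputed and
# annotated once, reused across files
demo_cohort <- function(seed = 3L) {
  cached(paste0("demo", seed), {
    sim <- simulate_cohort(simulation_config(
      n_classes = 4L, n_squamous_classes = 2L, samples_per_class = 20L,
      n_probes = 400L, dmc_per_class = 15L, missing_frac = 0.02,
      metastatic_frac = 0, seed = seed))
    sim$bm <- impute_missing_median(filter_probes_by_presence(sim$beta))
    sim$ann <- annotate_samples(sim$annotations, sim$class_map)
    sim
  })
}

random_beta_matrix <- function(n_probes, n_samples, seed, missing_frac = 0) {
  set.seed(seed)
  v <- matrix(runif(n_probes * n_samples), n_probes, n_samples,
              dimnames = list(sprintf("cg%06d", seq_len(n_probes)),
                              sprintf("S%03d", seq_len(n_samples))))
  if (missing_frac > 0) v[runif(length(v)) < missing_frac] <- NA
  BetaMatrix(v)
}

# all permutations of a vector (exhaustive oracle for tiny IGTD instances)
all_perms <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_perms(v[-i])) out <- c(out, list(c(v[i], p)))
  out
}

# independent Mann-Whitney oracle: U by explicit pair counting, p by label
# permutation
oracle_mw_u <- function(x, y) {
  u <- 0
  for (xi in x) u <- u + sum(xi > y) + 0.5 * sum(xi == y)
  u
}

oracle_mw_perm_p <- function(x, y, n_perm = 100000L, seed = 1L) {
  set.seed(seed)
  pooled <- c(x, y)
  n1 <- length(x)
  mu <- n1 * length(y) / 2
  obs <- abs(oracle_mw_u(x, y) - mu)
  r <- rank(pooled)
  offset <- n1 * (n1 + 1) / 2
  stat <- replicate(n_perm, abs(sum(r[sample(length(pooled), n1)]) - offset - mu))
  mean(stat >= obs - 1e-12)
}

# brute-force rank-matching error (double loop)
oracle_assignment_error <- function(fr, pr, ord) {
  n <- nrow(fr)
  e <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      e <- e + abs(fr[ord[i], ord[j]] - pr[i, j])
  e
}
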