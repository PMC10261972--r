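# Shared fixtures, all built in code at test time.

# Small deterministic synthetic library, memoised per test run.
.fixture_env <- new.env(parent = emptyenv())

small_sim <- function(seed = 42, n_replicates = 4, noise_sd = 0.002,
                      intraspecific_cv = 0.08) {
  key <- paste("sim", seed, n_replicates, noise_sd, intraspecific_cv,
               sep = "_")
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_library(simulation_config(
      n_replicates = n_replicates, seed = seed, noise_sd = noise_sd,
      intraspecific_cv = intraspecific_cv))
  }
  .fixture_env[[key]]
}

# Tiny hand-built library: explicit reflectance on a short grid. `values` is
# a records x wavelengths matrix; metadata derived from ids.
toy_library <- function(values, species, times, grid = NULL) {
  n <- nrow(values)
  if (is.null(grid)) grid <- seq(350, 350 + ncol(values) - 1)
  reps <- stats::ave(seq_len(n), paste(species, times), FUN = seq_along)
  sample_id <- sprintf("%s_%02d", species, reps)
  meta <- tibble::tibble(
    record_id = sprintf("%s_%s", sample_id, times),
    sample_id = sample_id, species = species, measurement_time = times)
  rownames(values) <- meta$record_id
  spectral_library(values, meta, grid)
}

# Exact two-sided rank-sum p-value by full enumeration of all assignments of
# the pooled ranks to group 1 (tie-free data only). Independent of the
# package's wilcox.test-based path.
enumerate_rank_sum_p <- function(x, y) {
  n1 <- length(x)
  pooled <- rank(c(x, y))
  w_obs <- sum(pooled[seq_len(n1)])
  combos <- utils::combn(length(pooled), n1)
  w_all <- apply(combos, 2, function(i) sum(pooled[i]))
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Closed-form OLS of y on x by the normal equations, with R^2 and
# n-denominator RMSE. Oracle for fit_ri_on_moisture and the scan surfaces.
ols_oracle <- function(y, x) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  sst <- sum((y - mean(y))^2)
  list(intercept = beta[1], slope = beta[2],
       r2 = 1 - sum(res^2) / sst,
       rmse = sqrt(mean(res^2)))
}
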