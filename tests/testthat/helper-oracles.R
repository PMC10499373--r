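# Independent brute-force oracles used to cross-check the package's fast
# vectorized implementations. These are deliberately written as plain loops
# over definitions, sharing no code with the package internals.

# Log-likelihood: one dnorm per record, looked up row by row.
oracle_log_likelihood <- function(params, data, linear = FALSE) {
  animals <- sort(unique(as.character(data$animal_id)))
  total <- 0
  for (i in seq_len(nrow(data))) {
    j <- which(animals == as.character(data$animal_id[i]))
    b <- if (length(params$beta) > 1) params$beta[j] else params$beta
    g <- if (linear) 1 else if (length(params$gamma) > 1) params$gamma[j] else params$gamma
    mu <- b * data$burst_duration_s[i]^g
    total <- total + dnorm(data$torque_uNm[i], mu, params$sigma, log = TRUE)
  }
  total
}

# Textbook split-chain Gelman-Rubin: explicit half-chain means/variances.
oracle_split_rhat <- function(arr_chain_iter) {
  m <- nrow(arr_chain_iter)
  n_iter <- ncol(arr_chain_iter)
  half <- floor(n_iter / 2)
  pieces <- list()
  for (ch in seq_len(m)) {
    x <- arr_chain_iter[ch, ]
    pieces[[2 * ch - 1]] <- x[1:half]
    pieces[[2 * ch]] <- x[(n_iter - half + 1):n_iter]
  }
  k <- length(pieces)
  means <- sapply(pieces, mean)
  vars <- sapply(pieces, var)
  W <- mean(vars)
  B <- half * var(means)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# Naive log-sum-exp, valid when the inputs are moderate enough not to
# overflow; used on random values in [-30, 30].
oracle_log_sum_exp <- function(x) log(sum(exp(x)))

# Reference simulation conditions used across the recovery and
# model-selection tests: the hierarchical linear population.
reference_truth <- function() {
  population_truth(mu_beta = 100, sigma_beta = 30, mu_gamma = 1,
                   sigma_gamma = 0, sigma_obs = 10, generating_model = "1-2")
}

reference_design <- function(seed, n_animals = 10, stims = 60) {
  experiment_design(n_animals = n_animals,
                    stims_per_animal = rep(stims, n_animals), seed = seed)
}

# Chain lengths used by the heavier simulation tests: long enough for the
# split-Rhat check to pass for every model variant, short enough that the
# full suite runs in minutes.
ci_chains <- function(seed) {
  chain_config(n_chains = 2, n_warmup = 800, n_samples = 600, seed = seed)
}

# Per-model ground truths for the six-variant recovery property.
truth_for_model <- function(id) {
  switch(id,
    "1-1" = population_truth(100, 0, 1, 0, 10, "1-1"),
    "1-2" = population_truth(100, 30, 1, 0, 10, "1-2"),
    "2-1" = population_truth(100, 0, 0.8, 0, 10, "2-1"),
    "2-2" = population_truth(100, 30, 0.8, 0, 10, "2-2"),
    "2-3" = population_truth(100, 0, 0.8, 0.15, 10, "2-3"),
    "2-4" = population_truth(100, 30, 0.8, 0.15, 10, "2-4"))
}

# Top-level truth values a fit of `id` should recover, named as in the
# parameter layout.
truth_values_for_model <- function(id) {
  tr <- truth_for_model(id)
  spec <- model_spec(id)
  out <- c(sigma = tr$sigma_obs)
  if (spec$hier_beta) {
    out <- c(out, mu_beta = tr$mu_beta, sigma_beta = tr$sigma_beta)
  } else {
    out <- c(out, beta = tr$mu_beta)
  }
  if (!spec$linear) {
    if (spec$hier_gamma) {
      out <- c(out, mu_gamma = tr$mu_gamma, sigma_gamma = tr$sigma_gamma)
    } else {
      out <- c(out, gamma = tr$mu_gamma)
    }
  }
  out
}
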