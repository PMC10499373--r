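test_that("log_sum_exp is exact and underflow-safe", {
  expect_identical(log_sum_exp(c(-1000, -1000)), -1000 + log(2))
  expect_identical(log_sum_exp(c(1000, 1000)), 1000 + log(2))
  set.seed(61)
  for (rep in 1:10) {
    x <- runif(sample(2:40, 1), -30, 30)
    expect_equal(log_sum_exp(x), oracle_log_sum_exp(x), tolerance = 1e-12)
  }
  expect_identical(log_sum_exp(c(-Inf, -Inf)), -Inf)
})

test_that("the analytic new-animal marginal hits its closed-form anchors", {
  # model 1-2 at the marginal mean: density of N(50, sqrt(30^2*0.25 + 100))
  draw <- list(mu_beta = 100, sigma_beta = 30, sigma = 10)
  ld <- new_animal_logdensity("1-2", draw, T_s = 0.5, tau = 50)
  expect_equal(ld, -log(sqrt(325)) - 0.5 * log(2 * pi), tolerance = 1e-12)
  expect_equal(round(ld, 3), -3.811)

  # sigma_beta -> 0 collapses to the non-hierarchical density
  draw0 <- list(mu_beta = 100, sigma_beta = 1e-12, sigma = 10)
  plain <- list(beta = 100, sigma = 10)
  expect_equal(new_animal_logdensity("1-2", draw0, 0.4, 35),
               new_animal_logdensity("1-1", plain, 0.4, 35), tolerance = 1e-9)
})

test_that("Simpson marginalization agrees with the closed form over a grid", {
  integ <- integration_config()
  T_grid <- seq(0.05, 1, length.out = 20)
  for (id in c("1-2", "2-2")) {
    draw <- list(mu_beta = 100, sigma_beta = 30, sigma = 10)
    if (id == "2-2") draw$gamma <- 0.8
    for (T_s in T_grid) {
      mu <- 100 * T_s^(if (id == "2-2") 0.8 else 1)
      sdv <- sqrt(30^2 * T_s^(2 * (if (id == "2-2") 0.8 else 1)) + 100)
      tau_grid <- seq(mu - 4 * sdv, mu + 4 * sdv, length.out = 20)
      a <- new_animal_logdensity(id, draw, rep(T_s, 20), tau_grid, integ, "analytic")
      s <- new_animal_logdensity(id, draw, rep(T_s, 20), tau_grid, integ, "simpson")
      expect_lt(max(abs(a - s)), 1e-6)
    }
  }
})

test_that("the 2-D Simpson cross-check matches the mixed analytic path for 2-4", {
  integ <- integration_config()
  draw <- list(mu_beta = 100, sigma_beta = 30, mu_gamma = 0.9,
               sigma_gamma = 0.1, sigma = 10)
  T_s <- c(0.2, 0.5, 0.9)
  tau <- c(30, 55, 95)
  mixed <- new_animal_logdensity("2-4", draw, T_s, tau, integ)
  full2d <- new_animal_logdensity("2-4", draw, T_s, tau, integ, "simpson2d")
  expect_equal(mixed, full2d, tolerance = 1e-6)
  expect_error(new_animal_logdensity("1-2", draw, T_s, tau, integ, "simpson2d"),
               "doubly hierarchical")
})

test_that("integration settings are validated", {
  expect_error(integration_config(n_points = 200), "odd")
  expect_error(integration_config(n_points = 9), "odd integer >= 11")
  expect_error(integration_config(range_sd = 3), "range_sd")
})

test_that("WAIC has the per-observation Watanabe form", {
  # hand-built draws matrix: model 1-1, two draws; everything computable
  # from the Gaussian density by hand
  d <- data.frame(animal_id = "a1", burst_duration_s = c(0.5, 1.0),
                  torque_uNm = c(50, 90))
  m <- matrix(c(100, 10, 90, 12), nrow = 2, byrow = TRUE,
              dimnames = list(NULL, c("beta", "sigma")))
  w <- waic("1-1", m, d)
  ld <- function(beta, sigma, T_s, tau) dnorm(tau, beta * T_s, sigma, log = TRUE)
  l_is <- rbind(c(ld(100, 10, 0.5, 50), ld(100, 10, 1, 90)),
                c(ld(90, 12, 0.5, 50), ld(90, 12, 1, 90)))
  lppd_i <- apply(l_is, 2, function(col) log(mean(exp(col))))
  pen_i <- apply(l_is, 2, var)
  expect_equal(w$lppd_term, mean(lppd_i), tolerance = 1e-12)
  expect_equal(w$penalty_term, mean(pen_i), tolerance = 1e-12)
  expect_equal(w$waic, mean(-lppd_i + pen_i), tolerance = 1e-12)
  expect_equal(w$waic, -w$lppd_term + w$penalty_term, tolerance = 1e-12)
  expect_gte(w$penalty_term, 0)
})

test_that("a single draw gives zero penalty with a warning", {
  d <- data.frame(animal_id = "a1", burst_duration_s = 0.5, torque_uNm = 50)
  m <- matrix(c(100, 10), nrow = 1, dimnames = list(NULL, c("beta", "sigma")))
  expect_warning(w <- waic("1-1", m, d), "one draw")
  expect_equal(w$penalty_term, 0)
  expect_equal(w$waic, -dnorm(50, 50, 10, log = TRUE), tolerance = 1e-12)
})

test_that("WAIC lppd matches a numerical-integration oracle of the Bayes predictive", {
  # conjugate linear model with known sigma: posterior of beta is normal,
  # so we can draw from it directly and integrate the predictive density
  # with stats::integrate as an independent oracle
  set.seed(71)
  T_s <- runif(12, 0.1, 1)
  tau <- 100 * T_s + rnorm(12, 0, 10)
  d <- data.frame(animal_id = "a1", burst_duration_s = T_s, torque_uNm = tau)
  post_mean <- sum(tau * T_s) / sum(T_s^2)
  post_sd <- 10 / sqrt(sum(T_s^2))
  S <- 40000
  m <- cbind(beta = rnorm(S, post_mean, post_sd), sigma = rep(10, S))
  w <- waic("1-1", m, d)
  oracle_lppd <- sapply(seq_len(12), function(i) {
    log(integrate(function(b) dnorm(tau[i], b * T_s[i], 10) *
                    dnorm(b, post_mean, post_sd),
                  post_mean - 10 * post_sd, post_mean + 10 * post_sd,
                  rel.tol = 1e-10)$value)
  })
  expect_equal(w$lppd_term, mean(oracle_lppd), tolerance = 2e-3)
})

test_that("duplicating the dataset leaves per-observation WAIC unchanged", {
  d <- generate_dataset(population_truth(), experiment_design(
    n_animals = 3, stims_per_animal = rep(15, 3), seed = 8))
  set.seed(72)
  S <- 200
  m <- cbind(mu_beta = rnorm(S, 100, 5), sigma_beta = abs(rnorm(S, 30, 3)),
             sigma = abs(rnorm(S, 10, 1)))
  w1 <- waic("1-2", m, d)
  w2 <- waic("1-2", m, rbind(d, d))
  expect_equal(w2$waic, w1$waic, tolerance = 1e-12) # same draws: exact
})

test_that("model ranking is ascending in WAIC with deterministic tie-breaks", {
  mk <- function(id, waic_val, n_params, n_obs = 60) {
    structure(list(lppd_term = -waic_val, penalty_term = 0, waic = waic_val,
                   pointwise = NULL, n_obs = n_obs, n_params = n_params,
                   model_id = id), class = "waic_result")
  }
  tab <- compare_models(list(mk("1-1", 0.5, 2), mk("2-2", -1.2, 14)))
  expect_equal(tab$model_id[1], "2-2")
  expect_equal(tab$rank, 1:2)

  # exact tie: fewer parameters wins, then lexicographic id
  tab2 <- compare_models(list(mk("2-2", 1.0, 14), mk("1-2", 1.0, 13),
                              mk("2-1", 1.0, 3)))
  expect_equal(tab2$model_id, c("2-1", "1-2", "2-2"))

  expect_error(compare_models(list(mk("1-1", 0.5, 2, n_obs = 60),
                                   mk("1-2", 0.4, 13, n_obs = 61))),
               "different sizes")
})

test_that("doubling Simpson nodes leaves hierarchical WAIC unchanged to 1e-6", {
  d <- generate_dataset(population_truth(), experiment_design(
    n_animals = 4, stims_per_animal = rep(12, 4), seed = 9))
  set.seed(73)
  S <- 60
  draws <- cbind(mu_beta = rnorm(S, 100, 8), sigma_beta = abs(rnorm(S, 30, 4)),
                 mu_gamma = rnorm(S, 0.9, 0.05),
                 sigma_gamma = abs(rnorm(S, 0.1, 0.02)),
                 gamma = rnorm(S, 0.9, 0.05),
                 beta = rnorm(S, 100, 8),
                 sigma = abs(rnorm(S, 10, 1)))
  for (id in c("1-2", "2-2", "2-3", "2-4")) {
    w1 <- waic(id, draws, d, integration_config(n_points = 201),
               method = if (id %in% c("1-2", "2-2")) "simpson" else "auto")
    w2 <- waic(id, draws, d, integration_config(n_points = 401),
               method = if (id %in% c("1-2", "2-2")) "simpson" else "auto")
    expect_lt(abs(w1$waic - w2$waic), 1e-6)
  }
})

test_that("model selection sanity: the mismatched hierarchy ranks where it should", {
  # data with slope hierarchy only: the exponent-hierarchy-only model (2-3)
  # is strictly the worst predictor of a new animal
  for (r in 1:2) {
    d <- generate_dataset(reference_truth(), reference_design(seed = 7200 + r,
                                                              stims = 40))
    tab <- compare_models(lapply(seq_along(model_ids()), function(mi) {
      id <- model_ids()[mi]
      fit <- sample_posterior(id, d, config = ci_chains(seed = 7300 + 10 * r + mi))
      waic(id, fit, d)
    }))
    expect_equal(tab$model_id[6], "2-3")
  }

  # data with both hierarchies and substantial exponent spread: the doubly
  # hierarchical model must not be reliably worst
  last <- character(0)
  for (r in 1:2) {
    tr24 <- population_truth(100, 30, 0.8, 0.15, 10, "2-4")
    d <- generate_dataset(tr24, experiment_design(10, rep(40L, 10),
                                                  seed = 7000 + r))
    tab <- compare_models(lapply(seq_along(model_ids()), function(mi) {
      id <- model_ids()[mi]
      fit <- sample_posterior(id, d, config = ci_chains(seed = 7100 + 10 * r + mi))
      waic(id, fit, d)
    }))
    last <- c(last, tab$model_id[6])
  }
  expect_false(any(last == "2-4"))
})

test_that("predictive surface columns integrate to one", {
  set.seed(74)
  S <- 100
  draws <- cbind(mu_beta = rnorm(S, 100, 8), sigma_beta = abs(rnorm(S, 30, 4)),
                 sigma = abs(rnorm(S, 10, 1)))
  T_grid <- seq(0.1, 1, length.out = 8)
  sd_max <- sqrt(45^2 + 13^2) # conservative upper predictive SD
  tau_grid <- seq(-8 * sd_max, 130 + 8 * sd_max, length.out = 351)
  surf <- predictive_surface("1-2", draws, T_grid, tau_grid)
  expect_true(all(surf$density >= 0))
  dt <- diff(tau_grid)[1]
  for (k in seq_along(T_grid)) {
    integral <- sum(surf$density[, k]) * dt -
      dt * (surf$density[1, k] + surf$density[nrow(surf$density), k]) / 2
    expect_lt(abs(integral - 1), 1e-3)
  }
})

test_that("the predictive surface is invariant to permuting the draws", {
  set.seed(75)
  S <- 50
  draws <- cbind(beta = rnorm(S, 100, 5), sigma = abs(rnorm(S, 10, 1)))
  T_grid <- c(0.3, 0.6)
  tau_grid <- seq(0, 120, length.out = 40)
  s1 <- predictive_surface("1-1", draws, T_grid, tau_grid)
  s2 <- predictive_surface("1-1", draws[sample(S), ], T_grid, tau_grid)
  expect_equal(s1$density, s2$density, tolerance = 1e-12)
})

test_that("concentrated posteriors put the predictive mass on the mean curve", {
  draws <- cbind(mu_beta = rep(100, 20), sigma_beta = rep(1e-4, 20),
                 sigma = rep(1e-3, 20))
  surf <- predictive_surface("1-2", draws, T_grid = c(0.5),
                             tau_grid = seq(45, 55, length.out = 101))
  expect_equal(surf$tau_grid[which.max(surf$density[, 1])], 50, tolerance = 0.1)
})

test_that("top-density curves follow the stored log posterior ordering", {
  d <- generate_dataset(population_truth(), experiment_design(
    n_animals = 3, stims_per_animal = rep(20, 3), seed = 10))
  fit <- sample_posterior("1-2", d, config = chain_config(2, 300, 200, seed = 44))
  T_grid <- seq(0.1, 1, length.out = 5)

  top1 <- top_density_curves("1-2", fit, k = 1, T_grid = T_grid)
  m <- as_draws_matrix(fit)
  lp <- attr(m, "lp")
  map_mu_beta <- m[which.max(lp), "mu_beta"]
  expect_equal(top1$torque_uNm, map_mu_beta * T_grid, tolerance = 1e-12)

  all_curves <- top_density_curves("1-2", fit, k = nrow(m), T_grid = T_grid)
  expect_equal(length(unique(all_curves$curve)), nrow(m))
  expect_true(all(diff(unique(all_curves$lp)) <= 0)) # decreasing density order

  expect_error(top_density_curves("1-2", fit, k = 0, T_grid = T_grid), "k must be")
  expect_error(top_density_curves("1-2", fit, k = nrow(m) + 1, T_grid = T_grid),
               "exceeds")
})
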