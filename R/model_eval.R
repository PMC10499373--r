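#' Numerical-integration settings for the new-animal marginal
#'
#' Hierarchical per-animal parameters are integrated out of the predictive
#' density with composite Simpson quadrature over `mu +/- range_sd * sd`
#' of the population normal. Defaults (201 nodes, +/- 8 SD) put the
#' quadrature error below 1e-9 on the log density for these Gaussian
#' integrands out to +/- 4 predictive SDs; the truncation tail, not the
#' Simpson h^4 term, is what limits accuracy here.
#'
#' @param n_points Odd number of Simpson nodes (>= 11).
#' @param range_sd Half-width of the integration range in population-SD
#'   units (>= 4).
#' @return An object of class `integration_config`.
#' @export
integration_config <- function(n_points = 201L, range_sd = 8) {
  if (n_points < 11L || n_points %% 2L == 0L) {
    stop("n_points must be an odd integer >= 11")
  }
  if (range_sd < 4) stop("range_sd must be >= 4")
  structure(list(n_points = as.integer(n_points), range_sd = range_sd),
            class = "integration_config")
}

# Extract the columns the new-animal density needs from a draws matrix.
marginal_columns <- function(spec, m) {
  get <- function(nm) {
    if (!nm %in% colnames(m)) stop("draws are missing parameter '", nm, "'")
    m[, nm]
  }
  out <- list(sigma = get("sigma"))
  if (spec$hier_beta) {
    out$mu_beta <- get("mu_beta"); out$sigma_beta <- get("sigma_beta")
  } else {
    out$beta <- get("beta")
  }
  if (spec$linear) {
    out$gamma <- rep.int(1, nrow(m))
  } else if (spec$hier_gamma) {
    out$mu_gamma <- get("mu_gamma"); out$sigma_gamma <- get("sigma_gamma")
  } else {
    out$gamma <- get("gamma")
  }
  out
}

# S x n matrix of per-draw, per-observation new-animal log predictive
# densities. `m` is a draws matrix (columns named as in param_layout),
# T_s/tau are length-n observation vectors.
pointwise_log_density <- function(spec, m, T_s, tau, integ = integration_config(),
                                  method = c("auto", "analytic", "simpson")) {
  method <- match.arg(method)
  spec <- as_model_spec(spec)
  if (any(T_s <= 0)) stop("burst duration must be > 0 s")
  cols <- marginal_columns(spec, m)
  S <- nrow(m); n <- length(T_s)
  logT <- log(T_s)
  half_log_2pi <- 0.5 * log(2 * pi)

  if (!spec$hier_gamma) {
    gam <- cols$gamma
    Tg <- exp(gam %o% logT) # S x n, element [s, i] = T_i^gamma_s
    if (!spec$hier_beta) {
      mu <- Tg * cols$beta
      dev <- sweep(mu, 2L, tau) / cols$sigma
      return(-log(cols$sigma) - half_log_2pi - 0.5 * dev^2)
    }
    if (method == "simpson") {
      return(simpson_beta_log_density(cols, Tg, tau, integ))
    }
    # closed-form Gaussian marginal over beta: tau | T ~
    # N(mu_beta T^gamma, sqrt(sigma_beta^2 T^(2 gamma) + sigma^2))
    mu <- Tg * cols$mu_beta
    sd <- sqrt((Tg * cols$sigma_beta)^2 + cols$sigma^2)
    dev <- sweep(mu, 2L, tau) / sd
    return(-log(sd) - half_log_2pi - 0.5 * dev^2)
  }

  # hierarchical gamma: 1-D Simpson over gamma per draw (beta marginalized
  # analytically when it is itself hierarchical, i.e. model 2-4)
  K <- integ$n_points
  x <- seq(-integ$range_sd, integ$range_sd, length.out = K) # standardized nodes
  w_std <- simpson_weights(K, -integ$range_sd, integ$range_sd)
  log_phi <- stats::dnorm(x, log = TRUE) # N(g | mu_g, sg) * dg in standardized units
  out <- matrix(NA_real_, S, n)
  for (s in seq_len(S)) {
    g <- cols$mu_gamma[s] + x * cols$sigma_gamma[s] # length K
    Tg <- exp(logT %o% g) # n x K, [i, k] = T_i^g_k
    if (spec$hier_beta) {
      mu <- Tg * cols$mu_beta[s]
      sd <- sqrt((Tg * cols$sigma_beta[s])^2 + cols$sigma[s]^2)
    } else {
      mu <- Tg * cols$beta[s]
      sd <- cols$sigma[s]
    }
    log_norm <- -log(sd) - half_log_2pi - 0.5 * ((tau - mu) / sd)^2
    li <- sweep(log_norm, 2L, log(w_std) + log_phi, `+`)
    out[s, ] <- row_log_sum_exp(li)
  }
  out
}

# Simpson marginalization over beta for models 1-2 / 2-2 (cross-check path
# for the closed form). Tg is the S x n matrix of T^gamma.
simpson_beta_log_density <- function(cols, Tg, tau, integ) {
  K <- integ$n_points
  x <- seq(-integ$range_sd, integ$range_sd, length.out = K)
  w_std <- simpson_weights(K, -integ$range_sd, integ$range_sd)
  log_phi <- stats::dnorm(x, log = TRUE)
  half_log_2pi <- 0.5 * log(2 * pi)
  S <- nrow(Tg); n <- ncol(Tg)
  out <- matrix(NA_real_, S, n)
  for (s in seq_len(S)) {
    b <- cols$mu_beta[s] + x * cols$sigma_beta[s] # K beta nodes
    mu <- Tg[s, ] %o% b # n x K
    log_norm <- -log(cols$sigma[s]) - half_log_2pi -
      0.5 * ((tau - mu) / cols$sigma[s])^2
    li <- sweep(log_norm, 2L, log(w_std) + log_phi, `+`)
    out[s, ] <- row_log_sum_exp(li)
  }
  out
}

# Full 2-D Simpson marginal for model 2-4 (cross-check of the mixed
# analytic/Simpson default path).
log_density_2d_simpson <- function(cols_s, T_s, tau, integ) {
  K <- integ$n_points
  x <- seq(-integ$range_sd, integ$range_sd, length.out = K)
  w_std <- simpson_weights(K, -integ$range_sd, integ$range_sd)
  log_phi <- stats::dnorm(x, log = TRUE)
  lw <- log(w_std) + log_phi
  b <- cols_s$mu_beta + x * cols_s$sigma_beta
  g <- cols_s$mu_gamma + x * cols_s$sigma_gamma
  half_log_2pi <- 0.5 * log(2 * pi)
  vapply(seq_along(T_s), function(i) {
    Tg <- T_s[i]^g # K gamma nodes
    mu <- b %o% Tg # K beta x K gamma
    ln <- -log(cols_s$sigma) - half_log_2pi - 0.5 * ((tau[i] - mu) / cols_s$sigma)^2
    log_sum_exp(ln + outer(lw, lw, `+`))
  }, numeric(1))
}

#' New-animal log predictive density for one posterior draw
#'
#' The predictive density of a torque measurement from an unseen animal:
#' per-animal parameters are integrated out over their population
#' distribution. Non-hierarchical models need no integration; the slope
#' hierarchy has an exact Gaussian marginal (the mean is linear in beta),
#' available either in closed form or by Simpson quadrature; the exponent
#' hierarchy is integrated with Simpson quadrature (for model 2-4 the slope
#' is still marginalized analytically inside the exponent integrand).
#'
#' @param spec A [model_spec()] or model id.
#' @param draw Named list/vector with the draw's top-level parameters
#'   (`sigma`, and `beta` or `mu_beta`/`sigma_beta` etc. as the model
#'   requires).
#' @param T_s Burst durations (s), vectorized with `tau`.
#' @param tau Torques (uNm).
#' @param integ An [integration_config()].
#' @param method `"auto"` (closed form where available), `"analytic"`,
#'   `"simpson"` (force quadrature over beta), or `"simpson2d"` (full 2-D
#'   quadrature, model 2-4 only).
#' @return Vector of log densities, one per (T, tau) pair.
#' @export
new_animal_logdensity <- function(spec, draw, T_s, tau,
                                  integ = integration_config(),
                                  method = c("auto", "analytic", "simpson", "simpson2d")) {
  method <- match.arg(method)
  spec <- as_model_spec(spec)
  n <- max(length(T_s), length(tau))
  T_s <- rep_len(T_s, n); tau <- rep_len(tau, n)
  draw <- as.list(draw)
  if (method == "simpson2d") {
    if (!(spec$hier_beta && spec$hier_gamma)) {
      stop("simpson2d applies only to the doubly hierarchical model (2-4)")
    }
    return(log_density_2d_simpson(draw, T_s, tau, integ))
  }
  need <- c("sigma",
            if (spec$hier_beta) c("mu_beta", "sigma_beta") else "beta",
            if (spec$hier_gamma) c("mu_gamma", "sigma_gamma")
            else if (!spec$linear) "gamma")
  missing <- setdiff(need, names(draw))
  if (length(missing)) stop("draw is missing: ", paste(missing, collapse = ", "))
  m <- matrix(unlist(draw[need]), nrow = 1, dimnames = list(NULL, need))
  drop(pointwise_log_density(spec, m, T_s, tau, integ,
                             method = if (method == "auto") "auto" else method))
}

#' Widely applicable information criterion for a new animal
#'
#' Per-observation WAIC in the training-loss form: for observation `i` with
#' per-draw new-animal log densities `l_is`,
#' `lppd_i = logsumexp_s(l_is) - log S` and
#' `penalty_i = Var_s(l_is)` (the functional variance);
#' `WAIC = mean_i(-lppd_i + penalty_i)`. Smaller (more negative) means
#' better predictive performance. All reductions over draws use
#' log-sum-exp; no raw exponentials of extreme values occur.
#'
#' @param spec A [model_spec()] or model id.
#' @param draws A `posterior_draws` object (or draws matrix with named
#'   columns).
#' @param data Stimulation data frame.
#' @param integ An [integration_config()].
#' @param method Marginalization path, see [new_animal_logdensity()].
#' @param check_convergence Warn if the draws fail the Rhat threshold.
#' @return An object of class `waic_result` with `lppd_term`,
#'   `penalty_term`, `waic`, pointwise contributions, `n_obs`, `model_id`.
#' @export
waic <- function(spec, draws, data, integ = integration_config(),
                 method = c("auto", "analytic", "simpson"),
                 check_convergence = FALSE) {
  method <- match.arg(method)
  spec <- as_model_spec(spec)
  m <- if (inherits(draws, "posterior_draws")) {
    if (check_convergence) {
      rep_ <- compute_rhat(draws)
      if (!rep_$pass) warning("draws failed the Rhat<", rep_$threshold,
                              " convergence check; WAIC may be unreliable")
    }
    as_draws_matrix(draws)
  } else {
    as.matrix(draws)
  }
  S <- nrow(m)
  ld <- pointwise_log_density(spec, m, data$burst_duration_s, data$torque_uNm,
                              integ, method = method)
  lppd_i <- row_log_sum_exp(t(ld)) - log(S)
  if (S < 2L) {
    warning("only one draw: functional variance set to 0 by convention")
    penalty_i <- rep.int(0, ncol(ld))
  } else {
    mu_i <- colMeans(ld)
    penalty_i <- colSums(sweep(ld, 2L, mu_i)^2) / (S - 1)
  }
  n <- ncol(ld)
  structure(list(lppd_term = mean(lppd_i),
                 penalty_term = mean(penalty_i),
                 waic = mean(-lppd_i + penalty_i),
                 pointwise = data.frame(lppd = lppd_i, penalty = penalty_i),
                 n_obs = n,
                 n_params = ncol(m),
                 model_id = spec$model_id),
            class = "waic_result")
}

#' @export
print.waic_result <- function(x, ...) {
  cat(sprintf("WAIC (new-animal) for model %s: %.4f\n", x$model_id, x$waic))
  cat(sprintf("  lppd term %.4f, penalty %.4f over %d observations\n",
              x$lppd_term, x$penalty_term, x$n_obs))
  invisible(x)
}

#' Rank models by new-animal WAIC
#'
#' @param results List of [waic()] results computed on the same dataset.
#' @return Data frame sorted ascending by WAIC (best first) with a `rank`
#'   column; ties broken by fewer parameters, then model id.
#' @export
compare_models <- function(results) {
  stopifnot(length(results) >= 1L)
  n_obs <- vapply(results, function(r) r$n_obs, numeric(1))
  if (length(unique(n_obs)) != 1L) {
    stop("WAIC results were computed on datasets of different sizes (",
         paste(unique(n_obs), collapse = " vs "), " observations)")
  }
  tab <- data.frame(
    model_id = vapply(results, function(r) r$model_id, character(1)),
    n_obs = n_obs,
    lppd_term = vapply(results, function(r) r$lppd_term, numeric(1)),
    penalty_term = vapply(results, function(r) r$penalty_term, numeric(1)),
    waic = vapply(results, function(r) r$waic, numeric(1)),
    n_params = vapply(results, function(r) r$n_params, numeric(1)),
    stringsAsFactors = FALSE)
  ord <- order(tab$waic, tab$n_params, tab$model_id)
  tab <- tab[ord, c("model_id", "n_obs", "lppd_term", "penalty_term", "waic", "n_params")]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}

#' Posterior-predictive density surface over (T, tau)
#'
#' `density(T, tau) = (1/S) sum_s exp(new_animal_logdensity(draw_s, T, tau))`
#' on the cartesian grid. With `animal` set (hierarchical models), the
#' conditional predictive for that specific animal is returned instead,
#' using its own per-animal parameter draws with no marginalization.
#'
#' @param spec,draws,integ As in [waic()].
#' @param T_grid Strictly increasing burst durations (s).
#' @param tau_grid Strictly increasing torques (uNm); should span the
#'   predictive mass (about +/- 8 predictive SDs) if column-normalization
#'   is to hold.
#' @param animal Optional animal id (as in the fitted data) for a
#'   per-animal conditional surface.
#' @return Object of class `predictive_surface`: list with `T_grid`,
#'   `tau_grid`, and a `density` matrix (rows = tau, columns = T).
#' @export
predictive_surface <- function(spec, draws, T_grid, tau_grid,
                               integ = integration_config(), animal = NULL) {
  spec <- as_model_spec(spec)
  if (any(diff(T_grid) <= 0) || any(diff(tau_grid) <= 0)) {
    stop("grids must be strictly increasing")
  }
  grid <- expand.grid(tau = tau_grid, T_s = T_grid, KEEP.OUT.ATTRS = FALSE)
  if (is.null(animal)) {
    m <- if (inherits(draws, "posterior_draws")) as_draws_matrix(draws) else as.matrix(draws)
    ld <- pointwise_log_density(spec, m, grid$T_s, grid$tau, integ)
  } else {
    ld <- conditional_log_density(spec, draws, animal, grid$T_s, grid$tau)
  }
  S <- nrow(ld)
  log_dens <- row_log_sum_exp(t(ld)) - log(S)
  structure(list(T_grid = T_grid, tau_grid = tau_grid,
                 density = matrix(exp(log_dens), nrow = length(tau_grid)),
                 model_id = spec$model_id, animal = animal),
            class = "predictive_surface")
}

# Conditional (within-animal) log predictive density: uses the animal's own
# beta_j / gamma_j draws directly.
conditional_log_density <- function(spec, draws, animal, T_s, tau) {
  stopifnot(inherits(draws, "posterior_draws"))
  j <- match(as.character(animal), draws$animals)
  if (is.na(j)) stop("unknown animal '", animal, "'; fitted animals: ",
                     paste(draws$animals, collapse = ", "))
  m <- as_draws_matrix(draws)
  beta <- if (spec$hier_beta) m[, sprintf("beta[%d]", j)] else m[, "beta"]
  gamma <- if (spec$linear) rep.int(1, nrow(m)) else if (spec$hier_gamma) {
    m[, sprintf("gamma[%d]", j)]
  } else {
    m[, "gamma"]
  }
  sigma <- m[, "sigma"]
  mu <- exp(gamma %o% log(T_s)) * beta
  dev <- sweep(mu, 2L, tau) / sigma
  -log(sigma) - 0.5 * log(2 * pi) - 0.5 * dev^2
}

#' Long-format export of a predictive surface
#'
#' @param x A `predictive_surface`.
#' @return Data frame with columns `T_s`, `tau_uNm`, `density`.
#' @export
surface_to_df <- function(x) {
  stopifnot(inherits(x, "predictive_surface"))
  data.frame(T_s = rep(x$T_grid, each = length(x$tau_grid)),
             tau_uNm = rep(x$tau_grid, times = length(x$T_grid)),
             density = as.vector(x$density))
}

#' Highest-posterior-density mean-torque curves
#'
#' Selects the `k` posterior draws with the highest stored log posterior and
#' evaluates each draw's population-level mean curve
#' (`mu_beta * T^mu_gamma` for hierarchical parameters, the shared value
#' otherwise) on `T_grid`, in decreasing order of log posterior.
#'
#' @param spec A [model_spec()] or model id.
#' @param draws A `posterior_draws` object.
#' @param k Number of curves (default 20).
#' @param T_grid Burst durations (s).
#' @return Data frame with columns `curve` (1 = highest density), `lp`,
#'   `T_s`, `torque_uNm`.
#' @export
top_density_curves <- function(spec, draws, k = 20L, T_grid) {
  spec <- as_model_spec(spec)
  stopifnot(inherits(draws, "posterior_draws"))
  if (k <= 0) stop("k must be >= 1")
  m <- as_draws_matrix(draws)
  lp <- attr(m, "lp")
  if (k > nrow(m)) stop("k exceeds the number of draws (", nrow(m), ")")
  sel <- order(lp, decreasing = TRUE)[seq_len(k)]
  beta <- if (spec$hier_beta) m[sel, "mu_beta"] else m[sel, "beta"]
  gamma <- if (spec$linear) rep.int(1, k) else if (spec$hier_gamma) {
    m[sel, "mu_gamma"]
  } else {
    m[sel, "gamma"]
  }
  curves <- lapply(seq_len(k), function(r) {
    data.frame(curve = r, lp = lp[sel[r]], T_s = T_grid,
               torque_uNm = mean_torque(beta[r], gamma[r], T_grid))
  })
  do.call(rbind, curves)
}
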