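#' MCMC chain configuration
#'
#' @param n_chains Number of independent chains (>= 2, required for Rhat).
#' @param n_warmup Adaptation iterations discarded before sampling.
#' @param n_samples Post-warmup iterations kept per chain (>= 100).
#' @param seed Root seed; each chain runs on a derived stream.
#' @param target_accept Target acceptance rate of the per-parameter
#'   Metropolis updates (0.44 is standard for single-coordinate proposals).
#' @param adapt_batch Warmup iterations between proposal-scale adaptations.
#' @return An object of class `chain_config`.
#' @export
chain_config <- function(n_chains = 4, n_warmup = 1000, n_samples = 1000,
                         seed = 1L, target_accept = 0.44, adapt_batch = 25L) {
  if (n_chains < 2) stop("n_chains must be >= 2 (Rhat needs at least 2 chains)")
  if (n_samples < 100) stop("n_samples must be >= 100")
  if (n_warmup < 0) stop("n_warmup must be >= 0")
  structure(list(n_chains = as.integer(n_chains), n_warmup = as.integer(n_warmup),
                 n_samples = as.integer(n_samples), seed = as.integer(seed),
                 target_accept = target_accept, adapt_batch = as.integer(adapt_batch)),
            class = "chain_config")
}

# log posterior closure over the flat natural-scale parameter vector.
# Fast path used millions of times by the sampler: avoids dnorm() in favour
# of the explicit Gaussian log density and touches only precomputed indices.
make_log_posterior <- function(spec, cd, priors, layout) {
  J <- length(cd$animals)
  n <- cd$n
  nm <- layout$name
  half_log_2pi <- 0.5 * log(2 * pi)

  i_sigma <- match("sigma", nm)
  i_beta <- if (spec$hier_beta) match(sprintf("beta[%d]", seq_len(J)), nm) else match("beta", nm)
  i_gamma <- if (spec$linear) integer(0) else if (spec$hier_gamma) {
    match(sprintf("gamma[%d]", seq_len(J)), nm)
  } else {
    match("gamma", nm)
  }
  i_mu_beta <- match("mu_beta", nm)
  i_sigma_beta <- match("sigma_beta", nm)
  i_mu_gamma <- match("mu_gamma", nm)
  i_sigma_gamma <- match("sigma_gamma", nm)

  # observation-level index into beta/gamma vectors
  jb <- if (spec$hier_beta) cd$j else rep.int(1L, n)
  jg <- if (spec$hier_gamma) cd$j else rep.int(1L, n)

  top <- which(!is.na(layout$lower))
  top_lower <- layout$lower[top]
  top_upper <- layout$upper[top]
  log_width <- sum(log(top_upper - top_lower))

  tau <- cd$tau; T_s <- cd$T_s; logT <- cd$logT
  linear <- spec$linear; hier_b <- spec$hier_beta; hier_g <- spec$hier_gamma

  function(theta) {
    v <- theta[top]
    if (any(v < top_lower) || any(v > top_upper)) return(-Inf)
    sigma <- theta[i_sigma]
    if (sigma <= 0) return(-Inf)

    lp <- -log_width
    if (hier_b) {
      sb <- theta[i_sigma_beta]
      if (sb <= 0) return(-Inf)
      b <- theta[i_beta]
      lp <- lp - J * log(sb) - J * half_log_2pi -
        0.5 * sum(((b - theta[i_mu_beta]) / sb)^2)
    }
    if (hier_g) {
      sg <- theta[i_sigma_gamma]
      if (sg <= 0) return(-Inf)
      g <- theta[i_gamma]
      lp <- lp - J * log(sg) - J * half_log_2pi -
        0.5 * sum(((g - theta[i_mu_gamma]) / sg)^2)
    }

    beta_obs <- theta[i_beta][jb]
    mu <- if (linear) beta_obs * T_s else beta_obs * exp(theta[i_gamma][jg] * logT)
    lp - n * log(sigma) - n * half_log_2pi - 0.5 * sum(((tau - mu) / sigma)^2)
  }
}

# Draw an initial point from the priors (hierarchical children from their
# population normal given the freshly drawn hyperparameters).
draw_init <- function(spec, layout, priors, J) {
  theta <- numeric(nrow(layout))
  names(theta) <- layout$name
  runif1 <- function(b) stats::runif(1, b[1], b[2])
  if (spec$hier_beta) {
    theta["mu_beta"] <- runif1(priors$mu_beta)
    theta["sigma_beta"] <- runif1(c(max(priors$sigma_beta[1], 1e-3), priors$sigma_beta[2]))
    theta[sprintf("beta[%d]", seq_len(J))] <-
      stats::rnorm(J, theta["mu_beta"], theta["sigma_beta"])
  } else {
    theta["beta"] <- runif1(priors$beta)
  }
  if (!spec$linear) {
    if (spec$hier_gamma) {
      theta["mu_gamma"] <- runif1(priors$mu_gamma)
      theta["sigma_gamma"] <- runif1(c(max(priors$sigma_gamma[1], 1e-3), priors$sigma_gamma[2]))
      theta[sprintf("gamma[%d]", seq_len(J))] <-
        stats::rnorm(J, theta["mu_gamma"], theta["sigma_gamma"])
    } else {
      theta["gamma"] <- runif1(priors$gamma)
    }
  }
  theta["sigma"] <- runif1(c(max(priors$sigma[1], 1e-3), priors$sigma[2]))
  theta
}

#' Sample the posterior of a stimulus-torque model
#'
#' Self-contained adaptive random-walk Metropolis-within-Gibbs sampler: each
#' free parameter is updated in turn with a Gaussian proposal whose scale is
#' adapted during warmup toward the target acceptance rate and then frozen.
#' SD parameters (`sigma`, `sigma_beta`, `sigma_gamma`) are proposed on the
#' log scale (with the Jacobian correction) and reported on the natural
#' scale. Runs are exactly reproducible given the configuration seed.
#'
#' @param spec A [model_spec()] or model id.
#' @param data Stimulation data frame (columns `animal_id`,
#'   `burst_duration_s`, `torque_uNm`).
#' @param priors A [prior_spec()].
#' @param config A [chain_config()].
#' @param fixed Optional named numeric vector pinning parameters at fixed
#'   values (they are excluded from sampling); mainly for conjugate checks.
#' @return An object of class `posterior_draws` holding a
#'   `[chain, iteration, parameter]` array of natural-scale draws, the log
#'   posterior of every draw, acceptance statistics, and the model metadata.
#' @export
sample_posterior <- function(spec, data, priors = prior_spec(),
                             config = chain_config(), fixed = NULL) {
  spec <- as_model_spec(spec)
  cd <- compile_data(data)
  J <- length(cd$animals)
  layout <- param_layout(spec, J, priors)
  log_post <- make_log_posterior(spec, cd, priors, layout)

  if (!is.null(fixed)) {
    unknown <- setdiff(names(fixed), layout$name)
    if (length(unknown)) stop("cannot fix unknown parameter(s): ",
                              paste(unknown, collapse = ", "))
  }
  free_idx <- which(!(layout$name %in% names(fixed)))
  log_scale <- layout$log_scale
  P <- nrow(layout)

  draws <- array(NA_real_,
                 dim = c(config$n_chains, config$n_samples, P),
                 dimnames = list(NULL, NULL, layout$name))
  lp_mat <- matrix(NA_real_, config$n_chains, config$n_samples)
  accept <- matrix(0, config$n_chains, P, dimnames = list(NULL, layout$name))

  T0 <- exp(mean(cd$logT)) # geometric-mean duration anchors the rescale move
  joint_moves <- build_joint_moves(spec, layout, J, fixed, T0)
  for (ch in seq_len(config$n_chains)) {
    res <- with_seed(split_seed(config$seed, ch), {
      run_chain(spec, layout, priors, log_post, J, fixed, free_idx, log_scale,
                config, joint_moves)
    })
    draws[ch, , ] <- res$draws
    lp_mat[ch, ] <- res$lp
    accept[ch, ] <- res$accept
  }

  structure(list(draws = draws, lp = lp_mat, accept_rate = accept,
                 spec = spec, animals = cd$animals, layout = layout,
                 priors = priors, config = config, fixed = fixed),
            class = "posterior_draws")
}

# Joint moves that break the posterior correlations single-site updates
# struggle with: (a) translating a hierarchical mean together with all its
# children, (b) trading the exponent against a rescaling of the whole slope
# block (the beta/gamma ridge of the power law), anchored at a reference
# duration T0 so the mean curve is preserved near T0.
build_joint_moves <- function(spec, layout, J, fixed, T0) {
  nm <- layout$name
  fixed_names <- names(fixed)
  ok <- function(idx) length(idx) > 0 && !any(nm[idx] %in% fixed_names)
  moves <- list()
  if (spec$hier_beta) {
    idx <- match(c(sprintf("beta[%d]", seq_len(J)), "mu_beta"), nm)
    if (ok(idx)) moves[[length(moves) + 1L]] <- list(type = "shift", idx = idx)
  }
  if (spec$hier_gamma) {
    idx <- match(c(sprintf("gamma[%d]", seq_len(J)), "mu_gamma"), nm)
    if (ok(idx)) moves[[length(moves) + 1L]] <- list(type = "shift", idx = idx)
  }
  if (spec$hier_beta) {
    ch_idx <- match(sprintf("beta[%d]", seq_len(J)), nm)
    ms <- match(c("mu_beta", "sigma_beta"), nm)
    if (ok(c(ch_idx, ms))) {
      moves[[length(moves) + 1L]] <- list(type = "funnel", children = ch_idx,
                                          mu = ms[1], sigma = ms[2])
    }
  }
  if (spec$hier_gamma) {
    ch_idx <- match(sprintf("gamma[%d]", seq_len(J)), nm)
    ms <- match(c("mu_gamma", "sigma_gamma"), nm)
    if (ok(c(ch_idx, ms))) {
      moves[[length(moves) + 1L]] <- list(type = "funnel", children = ch_idx,
                                          mu = ms[1], sigma = ms[2])
    }
  }
  if (!spec$linear && spec$hier_beta) {
    g_idx <- if (spec$hier_gamma) {
      match(c(sprintf("gamma[%d]", seq_len(J)), "mu_gamma"), nm)
    } else {
      match("gamma", nm)
    }
    b_idx <- match(c(sprintf("beta[%d]", seq_len(J)), "mu_beta", "sigma_beta"), nm)
    if (ok(g_idx) && ok(b_idx)) {
      moves[[length(moves) + 1L]] <- list(type = "rescale", gamma_idx = g_idx,
                                          beta_idx = b_idx, logT0 = log(T0))
    }
  }
  moves
}

run_chain <- function(spec, layout, priors, log_post, J, fixed, free_idx,
                      log_scale, config, joint_moves = list()) {
  P <- nrow(layout)
  # initialization: prior draws, retried while the log posterior is non-finite
  lp_cur <- -Inf
  for (try in seq_len(10L)) {
    theta <- draw_init(spec, layout, priors, J)
    if (!is.null(fixed)) theta[names(fixed)] <- fixed
    lp_cur <- log_post(theta)
    if (is.finite(lp_cur)) break
  }
  if (!is.finite(lp_cur)) {
    stop("could not initialize chain: log posterior non-finite after 10 attempts")
  }

  # proposal scales: log-sd, adapted during warmup in batches
  prop_ls <- numeric(P)
  for (p in seq_len(P)) {
    prop_ls[p] <- if (log_scale[p]) log(0.5) else {
      w <- layout$upper[p] - layout$lower[p]
      if (is.finite(w)) log(w / 20) else log(10)
    }
  }
  batch_acc <- numeric(P)
  batch_n <- 0L
  batch_id <- 0L
  n_mv <- length(joint_moves)
  mv_ls <- rep(log(0.1), n_mv)
  mv_batch_acc <- numeric(n_mv)

  n_total <- config$n_warmup + config$n_samples
  out <- matrix(NA_real_, config$n_samples, P)
  out_lp <- numeric(config$n_samples)
  acc_count <- numeric(P)

  for (it in seq_len(n_total)) {
    warm <- it <= config$n_warmup
    z <- stats::rnorm(P)
    u <- log(stats::runif(P))
    for (p in free_idx) {
      prop <- theta
      if (log_scale[p]) {
        step <- exp(prop_ls[p]) * z[p]
        prop[p] <- theta[p] * exp(step)
        log_ratio_adj <- step # Jacobian: log(prop) - log(cur)
      } else {
        prop[p] <- theta[p] + exp(prop_ls[p]) * z[p]
        log_ratio_adj <- 0
      }
      lp_prop <- log_post(prop)
      if (u[p] < lp_prop - lp_cur + log_ratio_adj) {
        theta <- prop
        lp_cur <- lp_prop
        if (warm) batch_acc[p] <- batch_acc[p] + 1
        if (!warm) acc_count[p] <- acc_count[p] + 1
      }
    }
    for (mv_i in seq_len(n_mv)) {
      mv <- joint_moves[[mv_i]]
      eps <- stats::rnorm(1) * exp(mv_ls[mv_i])
      prop <- theta
      if (mv$type == "shift") {
        prop[mv$idx] <- prop[mv$idx] + eps
        log_ratio_adj <- 0
      } else if (mv$type == "funnel") {
        # scale the hierarchy SD and the children's deviations together,
        # walking along the funnel: sigma' = sigma e^eps,
        # child' = mu + (child - mu) e^eps; |Jacobian| = e^((J+1) eps)
        k <- exp(eps)
        prop[mv$sigma] <- prop[mv$sigma] * k
        prop[mv$children] <- prop[mv$mu] + (prop[mv$children] - prop[mv$mu]) * k
        log_ratio_adj <- (length(mv$children) + 1) * eps
      } else { # rescale: gamma block shifted by eps, beta block scaled to
               # keep the mean curve fixed at T0; |Jacobian| = k^n_scaled
        k <- exp(-eps * mv$logT0)
        prop[mv$gamma_idx] <- prop[mv$gamma_idx] + eps
        prop[mv$beta_idx] <- prop[mv$beta_idx] * k
        log_ratio_adj <- length(mv$beta_idx) * (-eps * mv$logT0)
      }
      lp_prop <- log_post(prop)
      if (log(stats::runif(1)) < lp_prop - lp_cur + log_ratio_adj) {
        theta <- prop
        lp_cur <- lp_prop
        if (warm) mv_batch_acc[mv_i] <- mv_batch_acc[mv_i] + 1
      }
    }
    if (warm) {
      batch_n <- batch_n + 1L
      if (batch_n == config$adapt_batch) {
        batch_id <- batch_id + 1L
        gain <- min(0.25, 1 / sqrt(batch_id))
        rate <- batch_acc / config$adapt_batch
        prop_ls <- prop_ls + gain * sign(rate - config$target_accept) *
          pmin(1, abs(rate - config$target_accept) * 4)
        batch_acc[] <- 0
        if (n_mv > 0) {
          mv_rate <- mv_batch_acc / config$adapt_batch
          mv_ls <- mv_ls + gain * sign(mv_rate - 0.30) *
            pmin(1, abs(mv_rate - 0.30) * 4)
          mv_batch_acc[] <- 0
        }
        batch_n <- 0L
      }
    } else {
      s <- it - config$n_warmup
      out[s, ] <- theta
      out_lp[s] <- lp_cur
    }
  }
  list(draws = out, lp = out_lp, accept = acc_count / config$n_samples)
}

#' @export
print.posterior_draws <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("Posterior draws for model %s: %d chains x %d iterations x %d parameters\n",
              x$spec$model_id, d[1], d[2], d[3]))
  cat("Parameters:", paste(dimnames(x$draws)[[3]], collapse = ", "), "\n")
  invisible(x)
}

#' Flatten posterior draws into a draws-by-parameters matrix
#'
#' @param x A `posterior_draws` object.
#' @return Numeric matrix with `n_chains * n_samples` rows, one column per
#'   parameter; the matching log posterior vector is in attribute `"lp"`.
#' @export
as_draws_matrix <- function(x) {
  stopifnot(inherits(x, "posterior_draws"))
  d <- dim(x$draws)
  m <- matrix(aperm(x$draws, c(2, 1, 3)), nrow = d[1] * d[2], ncol = d[3])
  colnames(m) <- dimnames(x$draws)[[3]]
  attr(m, "lp") <- as.vector(t(x$lp)) # rows are chain-major, iterations fastest
  m
}

#' Split-chain Gelman-Rubin convergence diagnostic
#'
#' Each chain is split in half and the potential scale reduction factor is
#' computed over the resulting `2m` half-chains:
#' `Rhat = sqrt(((n-1)/n * W + B/n) / W)` with `n` the half-chain length,
#' `W` the mean within-half-chain variance and `B` the between-half-chain
#' variance. Parameters with zero within-chain variance get `NaN` (with a
#' warning) and are excluded from the pass decision.
#'
#' @param draws A `posterior_draws` object (or a `[chain, iter, param]` array).
#' @param threshold Convergence threshold on the maximum Rhat (default 1.10).
#' @return An object of class `convergence_report`: data frame of `rhat` and
#'   `ess` per parameter plus a `pass` flag.
#' @export
compute_rhat <- function(draws, threshold = 1.10) {
  arr <- if (inherits(draws, "posterior_draws")) draws$draws else draws
  stopifnot(length(dim(arr)) == 3L)
  m <- dim(arr)[1]; n_iter <- dim(arr)[2]; P <- dim(arr)[3]
  if (m < 2L) stop("Rhat needs at least 2 chains")
  if (n_iter < 4L) stop("Rhat needs at least 4 iterations per chain")

  half <- n_iter %/% 2L
  rhat <- numeric(P)
  ess <- numeric(P)
  pnames <- dimnames(arr)[[3]] %||% sprintf("param%d", seq_len(P))
  zero_var <- character(0)

  for (p in seq_len(P)) {
    # 2m half-chains, each of length `half` (odd middle iteration dropped)
    halves <- matrix(NA_real_, half, 2L * m)
    for (ch in seq_len(m)) {
      halves[, 2L * ch - 1L] <- arr[ch, seq_len(half), p]
      halves[, 2L * ch] <- arr[ch, n_iter - half + seq_len(half), p]
    }
    W <- mean(apply(halves, 2L, stats::var))
    if (W == 0) {
      rhat[p] <- NaN
      ess[p] <- NaN
      zero_var <- c(zero_var, pnames[p])
      next
    }
    B <- half * stats::var(colMeans(halves))
    var_plus <- (half - 1) / half * W + B / half
    rhat[p] <- sqrt(var_plus / W)
    ess[p] <- ess_from_halves(halves, W, var_plus)
  }
  if (length(zero_var)) {
    warning("zero within-chain variance for: ", paste(zero_var, collapse = ", "),
            "; Rhat is NaN for these parameters")
  }
  finite <- is.finite(rhat)
  pass <- length(finite) > 0 && all(rhat[finite] < threshold)
  structure(list(table = data.frame(parameter = pnames, rhat = rhat, ess = ess,
                                    stringsAsFactors = FALSE),
                 threshold = threshold, pass = pass),
            class = "convergence_report")
}

# Effective sample size over half-chains: averaged within-chain
# autocovariances combined with Geyer's initial monotone positive sequence.
ess_from_halves <- function(halves, W, var_plus) {
  n <- nrow(halves); m <- ncol(halves)
  max_lag <- min(n - 1L, 250L)
  acov <- matrix(0, max_lag + 1L, m)
  for (k in seq_len(m)) {
    x <- halves[, k] - mean(halves[, k])
    full <- stats::acf(x, lag.max = max_lag, plot = FALSE,
                       type = "covariance", demean = FALSE)$acf[, 1, 1]
    acov[, k] <- full
  }
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov) / var_plus
  # pairwise sums, truncated at first negative pair, enforced non-increasing
  ess_sum <- 0
  prev <- Inf
  t <- 1L
  while (t + 1L <= length(rho)) {
    pair <- rho[t] + rho[t + 1L]
    if (pair < 0) break
    pair <- min(pair, prev)
    ess_sum <- ess_sum + pair
    prev <- pair
    t <- t + 2L
  }
  tau_int <- -1 + 2 * ess_sum # rho[1] (lag 0) is inside the pairwise sums
  max(m * n / max(tau_int, 1 / (m * n)), 1)
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("Convergence: %s (max Rhat %.4f, threshold %.2f)\n",
              if (x$pass) "PASS" else "FAIL",
              suppressWarnings(max(x$table$rhat, na.rm = TRUE)), x$threshold))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Write / read posterior draws as long-format CSV
#'
#' Columns `chain,iteration,parameter,value` plus rows with parameter
#' `"lp__"` carrying the log posterior of each draw.
#'
#' @param x A `posterior_draws` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_draws_csv <- function(x, path) {
  stopifnot(inherits(x, "posterior_draws"))
  d <- dim(x$draws)
  pnames <- dimnames(x$draws)[[3]]
  rows <- vector("list", d[1])
  for (ch in seq_len(d[1])) {
    mat <- x$draws[ch, , , drop = FALSE]
    dim(mat) <- d[2:3]
    rows[[ch]] <- data.frame(
      chain = ch,
      iteration = rep(seq_len(d[2]), times = d[3] + 1L),
      parameter = rep(c(pnames, "lp__"), each = d[2]),
      value = c(as.vector(mat), x$lp[ch, ]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$value <- sprintf("%.17g", out$value)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
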