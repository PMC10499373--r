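#' The six stimulus-torque model variants
#'
#' All variants share one mean function, a power law in the burst duration
#' \eqn{T} (seconds): \eqn{\mu(T) = \beta T^{\gamma}} with observation noise
#' \eqn{\tau \sim N(\mu(T), \sigma)}. The variants differ in whether the
#' exponent is fixed at 1 (linear models) and in which parameters carry a
#' hierarchical, per-animal level:
#'
#' \describe{
#'   \item{1-1}{linear (\eqn{\gamma \equiv 1}), shared slope \eqn{\beta}}
#'   \item{1-2}{linear, per-animal slopes \eqn{\beta_j \sim N(\mu_\beta, \sigma_\beta)}}
#'   \item{2-1}{power law, shared \eqn{\beta} and \eqn{\gamma}}
#'   \item{2-2}{power law, per-animal \eqn{\beta_j}, shared \eqn{\gamma}}
#'   \item{2-3}{power law, shared \eqn{\beta}, per-animal \eqn{\gamma_j \sim N(\mu_\gamma, \sigma_\gamma)}}
#'   \item{2-4}{power law, per-animal \eqn{\beta_j} and \eqn{\gamma_j}}
#' }
#'
#' @param model_id One of `"1-1"`, `"1-2"`, `"2-1"`, `"2-2"`, `"2-3"`, `"2-4"`.
#' @return An object of class `model_spec` with logical flags `hier_beta`,
#'   `hier_gamma` and `linear`.
#' @examples
#' model_spec("2-2")
#' @export
model_spec <- function(model_id) {
  model_id <- as.character(model_id)
  flags <- switch(model_id,
    "1-1" = list(hier_beta = FALSE, hier_gamma = FALSE, linear = TRUE),
    "1-2" = list(hier_beta = TRUE,  hier_gamma = FALSE, linear = TRUE),
    "2-1" = list(hier_beta = FALSE, hier_gamma = FALSE, linear = FALSE),
    "2-2" = list(hier_beta = TRUE,  hier_gamma = FALSE, linear = FALSE),
    "2-3" = list(hier_beta = FALSE, hier_gamma = TRUE,  linear = FALSE),
    "2-4" = list(hier_beta = TRUE,  hier_gamma = TRUE,  linear = FALSE),
    stop("unknown model id '", model_id, "'; valid ids: ",
         paste(model_ids(), collapse = ", "))
  )
  structure(c(list(model_id = model_id), flags), class = "model_spec")
}

#' @rdname model_spec
#' @export
model_ids <- function() c("1-1", "1-2", "2-1", "2-2", "2-3", "2-4")

#' @export
print.model_spec <- function(x, ...) {
  form <- if (x$linear) "tau ~ N(beta * T, sigma)" else "tau ~ N(beta * T^gamma, sigma)"
  cat("Stimulus-torque model ", x$model_id, ": ", form, "\n", sep = "")
  if (x$hier_beta)  cat("  beta_j  ~ N(mu_beta, sigma_beta)   [per animal]\n")
  if (x$hier_gamma) cat("  gamma_j ~ N(mu_gamma, sigma_gamma) [per animal]\n")
  invisible(x)
}

as_model_spec <- function(x) {
  if (inherits(x, "model_spec")) x else model_spec(x)
}

#' Uniform prior bounds for the model parameters
#'
#' Non-informative uniform priors on the top-level parameters; per-animal
#' parameters (when hierarchical) receive their normal population prior
#' instead and are not bounded. Defaults are generous relative to the torques
#' the experiment produces (tens of uNm over burst durations up to 1 s).
#'
#' @param beta,mu_beta Bounds `(low, high)` for the slope/base (uNm s^-gamma).
#' @param gamma,mu_gamma Bounds for the exponent (dimensionless).
#' @param sigma,sigma_beta Bounds for the observation / slope SDs (uNm).
#' @param sigma_gamma Bounds for the exponent SD.
#' @return An object of class `prior_spec`: a named list of length-2 bounds.
#' @export
prior_spec <- function(beta = c(0, 1000), gamma = c(0, 3),
                       sigma = c(0, 200),
                       mu_beta = c(0, 1000), sigma_beta = c(0, 200),
                       mu_gamma = c(0, 3), sigma_gamma = c(0, 3)) {
  pr <- list(beta = beta, gamma = gamma, sigma = sigma,
             mu_beta = mu_beta, sigma_beta = sigma_beta,
             mu_gamma = mu_gamma, sigma_gamma = sigma_gamma)
  for (nm in names(pr)) {
    b <- pr[[nm]]
    if (!is.numeric(b) || length(b) != 2L || !all(is.finite(b)) || b[1] >= b[2]) {
      stop("prior bounds for '", nm, "' must be a finite (low, high) pair with low < high")
    }
    if (nm %in% c("sigma", "sigma_beta", "sigma_gamma") && b[1] < 0) {
      stop("SD parameter '", nm, "' must have a non-negative lower bound")
    }
  }
  structure(pr, class = "prior_spec")
}

#' Mean torque of the power-law stimulus-torque curve
#'
#' @param beta Slope/base parameter (uNm s^-gamma); vectorized.
#' @param gamma Exponent (dimensionless); `gamma = 1` gives the linear model.
#' @param T_s Burst duration in seconds, `> 0`; vectorized.
#' @return Mean torque `beta * T_s^gamma` in uNm.
#' @examples
#' mean_torque(120, 1, 0.5)   # 60
#' mean_torque(50, 0.7, 0.5)  # 30.78
#' @export
mean_torque <- function(beta, gamma, T_s) {
  if (any(T_s <= 0)) stop("burst duration must be > 0 s")
  beta * T_s^gamma
}

# ---- parameter vectors -----------------------------------------------------

# A parameter set is a named list: beta (length J if hier_beta else 1),
# gamma (length J if hier_gamma else 1; fixed at 1 for linear models), sigma,
# and the hyperparameters present iff the corresponding hierarchy flag is set.

validate_params <- function(spec, params, n_animals = NULL) {
  spec <- as_model_spec(spec)
  need <- c("beta", "gamma", "sigma",
            if (spec$hier_beta) c("mu_beta", "sigma_beta"),
            if (spec$hier_gamma) c("mu_gamma", "sigma_gamma"))
  missing <- setdiff(need, names(params))
  if (length(missing)) {
    stop("parameter vector for model ", spec$model_id,
         " is missing: ", paste(missing, collapse = ", "))
  }
  if (params$sigma <= 0) stop("sigma must be > 0")
  if (spec$hier_beta && params$sigma_beta <= 0) stop("sigma_beta must be > 0")
  if (spec$hier_gamma && params$sigma_gamma <= 0) stop("sigma_gamma must be > 0")
  if (spec$linear && any(params$gamma != 1)) {
    stop("linear models fix gamma = 1")
  }
  if (!spec$hier_beta && length(params$beta) != 1L) {
    stop("model ", spec$model_id, " has a single shared beta")
  }
  if (!spec$hier_gamma && length(params$gamma) != 1L) {
    stop("model ", spec$model_id, " has a single shared gamma")
  }
  if (!is.null(n_animals)) {
    if (spec$hier_beta && length(params$beta) != n_animals) {
      stop("need one beta per animal (", n_animals, "), got ", length(params$beta))
    }
    if (spec$hier_gamma && length(params$gamma) != n_animals) {
      stop("need one gamma per animal (", n_animals, "), got ", length(params$gamma))
    }
  }
  invisible(params)
}

# Internal compact representation of a stimulation table for repeated
# likelihood evaluation: animals are indexed 1..J in sorted id order.
compile_data <- function(data) {
  stopifnot(all(c("animal_id", "burst_duration_s", "torque_uNm") %in% names(data)))
  if (nrow(data) == 0L) stop("empty dataset")
  if (any(data$burst_duration_s <= 0)) stop("burst durations must be > 0 s")
  animals <- sort(unique(as.character(data$animal_id)))
  list(
    tau = as.numeric(data$torque_uNm),
    T_s = as.numeric(data$burst_duration_s),
    logT = log(as.numeric(data$burst_duration_s)),
    j = match(as.character(data$animal_id), animals),
    animals = animals,
    n = nrow(data)
  )
}

#' Log-likelihood of a stimulation dataset under a model variant
#'
#' Sums, over stimulation records, the log normal density of the measured
#' torque around the model's mean curve `beta_j * T^gamma_j`, with shared
#' observation SD `sigma`. Per-animal parameters are matched to animals in
#' sorted `animal_id` order.
#'
#' @param spec A [model_spec()] or model id string.
#' @param params Named list with elements `beta`, `gamma`, `sigma` (and
#'   hyperparameters for hierarchical variants); `beta`/`gamma` have one
#'   entry per animal when hierarchical, else length 1.
#' @param data Stimulation data frame with columns `animal_id`,
#'   `burst_duration_s`, `torque_uNm`.
#' @return Log-likelihood (scalar).
#' @export
log_likelihood <- function(spec, params, data) {
  spec <- as_model_spec(spec)
  cd <- compile_data(data)
  validate_params(spec, params, n_animals = length(cd$animals))
  log_likelihood_compiled(spec, params, cd)
}

log_likelihood_compiled <- function(spec, params, cd) {
  beta <- if (length(params$beta) == 1L) rep.int(params$beta, length(cd$animals)) else params$beta
  mu <- if (spec$linear) {
    beta[cd$j] * cd$T_s
  } else {
    gamma <- if (length(params$gamma) == 1L) rep.int(params$gamma, length(cd$animals)) else params$gamma
    if (all(gamma == 1)) {
      beta[cd$j] * cd$T_s # keeps the gamma = 1 nesting identity bit-exact
    } else {
      beta[cd$j] * exp(gamma[cd$j] * cd$logT)
    }
  }
  sum(stats::dnorm(cd$tau, mean = mu, sd = params$sigma, log = TRUE))
}

#' Log prior density of a parameter vector
#'
#' Top-level parameters get independent uniform densities on their
#' [prior_spec()] bounds (`-Inf` outside); per-animal parameters of
#' hierarchical variants get their normal population density
#' `N(mu_beta, sigma_beta)` / `N(mu_gamma, sigma_gamma)`.
#'
#' @inheritParams log_likelihood
#' @param priors A [prior_spec()].
#' @return Log prior density (scalar, possibly `-Inf`).
#' @export
log_prior <- function(spec, params, priors = prior_spec()) {
  spec <- as_model_spec(spec)
  validate_params(spec, params)
  if (!inherits(priors, "prior_spec")) stop("'priors' must be a prior_spec")

  lp <- 0
  unif <- function(value, nm) {
    b <- priors[[nm]]
    if (is.null(b)) stop("prior bounds missing for '", nm, "'")
    if (value < b[1] || value > b[2]) return(-Inf)
    -log(b[2] - b[1])
  }
  # top-level uniform terms
  if (spec$hier_beta) {
    lp <- lp + unif(params$mu_beta, "mu_beta") + unif(params$sigma_beta, "sigma_beta")
  } else {
    lp <- lp + unif(params$beta, "beta")
  }
  if (!spec$linear) {
    if (spec$hier_gamma) {
      lp <- lp + unif(params$mu_gamma, "mu_gamma") + unif(params$sigma_gamma, "sigma_gamma")
    } else {
      lp <- lp + unif(params$gamma, "gamma")
    }
  }
  lp <- lp + unif(params$sigma, "sigma")
  if (!is.finite(lp)) return(-Inf)
  # hierarchical population terms
  if (spec$hier_beta) {
    if (params$sigma_beta <= 0) return(-Inf)
    lp <- lp + sum(stats::dnorm(params$beta, params$mu_beta, params$sigma_beta, log = TRUE))
  }
  if (spec$hier_gamma) {
    if (params$sigma_gamma <= 0) return(-Inf)
    lp <- lp + sum(stats::dnorm(params$gamma, params$mu_gamma, params$sigma_gamma, log = TRUE))
  }
  lp
}

# ---- flat parameter layout (used by the sampler and draw containers) -------

# Layout of the free parameters of a model as a flat named vector.
# Columns: name ("beta[1]", "sigma", ...), block, log_scale (sampled on log
# scale), lower/upper (prior bounds for top-level params, NA for hierarchical
# children whose prior is the population normal).
param_layout <- function(spec, n_animals, priors = prior_spec()) {
  spec <- as_model_spec(spec)
  rows <- list()
  add <- function(name, block, log_scale, lower, upper) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, block = block, log_scale = log_scale,
      lower = lower, upper = upper, stringsAsFactors = FALSE)
  }
  if (spec$hier_beta) {
    for (j in seq_len(n_animals)) add(sprintf("beta[%d]", j), "beta", FALSE, NA, NA)
    add("mu_beta", "mu_beta", FALSE, priors$mu_beta[1], priors$mu_beta[2])
    add("sigma_beta", "sigma_beta", TRUE, priors$sigma_beta[1], priors$sigma_beta[2])
  } else {
    add("beta", "beta", FALSE, priors$beta[1], priors$beta[2])
  }
  if (!spec$linear) {
    if (spec$hier_gamma) {
      for (j in seq_len(n_animals)) add(sprintf("gamma[%d]", j), "gamma", FALSE, NA, NA)
      add("mu_gamma", "mu_gamma", FALSE, priors$mu_gamma[1], priors$mu_gamma[2])
      add("sigma_gamma", "sigma_gamma", TRUE, priors$sigma_gamma[1], priors$sigma_gamma[2])
    } else {
      add("gamma", "gamma", FALSE, priors$gamma[1], priors$gamma[2])
    }
  }
  add("sigma", "sigma", TRUE, priors$sigma[1], priors$sigma[2])
  do.call(rbind, rows)
}

# Flat named vector -> parameter list understood by log_likelihood/log_prior.
unflatten_params <- function(spec, theta, n_animals) {
  spec <- as_model_spec(spec)
  pick <- function(nm) unname(theta[[nm]])
  params <- list(sigma = pick("sigma"))
  if (spec$hier_beta) {
    params$beta <- unname(theta[sprintf("beta[%d]", seq_len(n_animals))])
    params$mu_beta <- pick("mu_beta")
    params$sigma_beta <- pick("sigma_beta")
  } else {
    params$beta <- pick("beta")
  }
  if (spec$linear) {
    params$gamma <- 1
  } else if (spec$hier_gamma) {
    params$gamma <- unname(theta[sprintf("gamma[%d]", seq_len(n_animals))])
    params$mu_gamma <- pick("mu_gamma")
    params$sigma_gamma <- pick("sigma_gamma")
  } else {
    params$gamma <- pick("gamma")
  }
  params
}
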