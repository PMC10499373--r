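#' Ground-truth population parameters for the synthetic generator
#'
#' Describes the population from which per-animal stimulus-torque curves are
#' drawn: slopes `beta_j ~ N(mu_beta, sigma_beta)`, exponents
#' `gamma_j ~ N(mu_gamma, sigma_gamma)`, and Gaussian observation noise with
#' SD `sigma_obs` on the measured torque. The `generating_model` id fixes
#' which of these levels are active: linear models pin `mu_gamma = 1`,
#' `sigma_gamma = 0`; non-hierarchical models pin the corresponding SD at 0.
#'
#' Defaults reproduce the reference simulation conditions used throughout the
#' package's recovery tests: a linear hierarchical population with
#' `mu_beta = 100` uNm/s, `sigma_beta = 30`, `sigma_obs = 10` uNm.
#'
#' @param mu_beta Population mean slope/base (uNm s^-gamma).
#' @param sigma_beta Population SD of the slope (>= 0).
#' @param mu_gamma Population mean exponent.
#' @param sigma_gamma Population SD of the exponent (>= 0).
#' @param sigma_obs Observation noise SD in uNm (>= 0).
#' @param generating_model Model id, see [model_spec()].
#' @return An object of class `population_truth`.
#' @export
population_truth <- function(mu_beta = 100, sigma_beta = 30,
                             mu_gamma = 1, sigma_gamma = 0,
                             sigma_obs = 10, generating_model = "1-2") {
  spec <- model_spec(generating_model)
  stopifnot_scalar_number(mu_beta, "mu_beta")
  stopifnot_scalar_number(mu_gamma, "mu_gamma")
  if (sigma_beta < 0 || sigma_gamma < 0 || sigma_obs < 0) {
    stop("sigma_beta, sigma_gamma and sigma_obs must be >= 0")
  }
  if (spec$linear && !(mu_gamma == 1 && sigma_gamma == 0)) {
    stop("linear generating models require mu_gamma = 1 and sigma_gamma = 0")
  }
  if (!spec$hier_beta && sigma_beta != 0) {
    stop("model ", generating_model, " has no slope hierarchy; sigma_beta must be 0")
  }
  if (!spec$hier_gamma && sigma_gamma != 0) {
    stop("model ", generating_model, " has no exponent hierarchy; sigma_gamma must be 0")
  }
  structure(list(mu_beta = mu_beta, sigma_beta = sigma_beta,
                 mu_gamma = mu_gamma, sigma_gamma = sigma_gamma,
                 sigma_obs = sigma_obs, generating_model = generating_model),
            class = "population_truth")
}

#' @export
print.population_truth <- function(x, ...) {
  cat("Population truth (generating model ", x$generating_model, ")\n", sep = "")
  cat(sprintf("  beta_j  ~ N(%g, %g) uNm s^-gamma\n", x$mu_beta, x$sigma_beta))
  cat(sprintf("  gamma_j ~ N(%g, %g)\n", x$mu_gamma, x$sigma_gamma))
  cat(sprintf("  tau | T ~ N(beta_j T^gamma_j, %g) uNm\n", x$sigma_obs))
  invisible(x)
}

#' Design of a synthetic stimulation experiment
#'
#' Mirrors the structure of the real experiment: `n_animals` animals per
#' muscle, each stimulated some tens of times per PWM voltage with burst
#' durations varied at random over `duration_range`. When `stims_per_animal`
#' is `NULL`, per-animal counts are drawn uniformly from 37..95, the range of
#' per-animal stimulation counts observed in the experiment the generator
#' emulates.
#'
#' @param n_animals Number of animals (>= 1).
#' @param stims_per_animal Either `NULL` (draw counts from 37..95) or an
#'   integer vector of length `n_animals` giving the per-animal count used
#'   for every voltage.
#' @param duration_range `(min, max)` burst duration in seconds, with
#'   `0 < min < max <= 1`.
#' @param voltages PWM voltages (V); one sweep of stimulations per voltage.
#' @param frequency PWM frequency in Hz.
#' @param duty PWM duty ratio in percent.
#' @param muscle Stimulated muscle label.
#' @param seed Root RNG seed for the whole dataset.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(n_animals = 10, stims_per_animal = NULL,
                              duration_range = c(0.02, 1.0),
                              voltages = 2.0, frequency = 50, duty = 30,
                              muscle = c("protractor", "retractor", "levator"),
                              seed = 1L) {
  muscle <- match.arg(muscle)
  if (n_animals < 1) stop("n_animals must be >= 1")
  if (length(duration_range) != 2L || duration_range[1] <= 0 ||
      duration_range[1] >= duration_range[2] || duration_range[2] > 1.0) {
    stop("duration_range must satisfy 0 < min < max <= 1.0 s")
  }
  if (!is.null(stims_per_animal)) {
    if (length(stims_per_animal) != n_animals) {
      stop("stims_per_animal must have one count per animal")
    }
    if (any(stims_per_animal < 1)) stop("every stimulation count must be >= 1")
  }
  structure(list(n_animals = as.integer(n_animals),
                 stims_per_animal = stims_per_animal,
                 duration_range = as.numeric(duration_range),
                 voltages = as.numeric(voltages),
                 frequency = frequency, duty = duty,
                 muscle = muscle, seed = as.integer(seed)),
            class = "experiment_design")
}

# Observed range of per-animal stimulation counts in the emulated experiment.
STIM_COUNT_RANGE <- c(37L, 95L)

#' Draw per-animal slope and exponent parameters from the population
#'
#' Each animal has its own RNG stream derived from the root seed, so adding
#' animals never perturbs the parameters of earlier animals. Non-hierarchical
#' truths (SD zero) yield the population mean exactly for every animal.
#'
#' @param truth A [population_truth()].
#' @param n_animals Number of animals to draw.
#' @param seed Root seed.
#' @return Data frame with columns `animal_id`, `beta`, `gamma`.
#' @export
sample_animal_params <- function(truth, n_animals, seed) {
  stopifnot(inherits(truth, "population_truth"))
  out <- data.frame(animal_id = sprintf("animal%02d", seq_len(n_animals)),
                    beta = numeric(n_animals), gamma = numeric(n_animals))
  for (j in seq_len(n_animals)) {
    bg <- with_seed(split_seed(seed, 2L * j), {
      c(stats::rnorm(1, truth$mu_beta, truth$sigma_beta),
        stats::rnorm(1, truth$mu_gamma, truth$sigma_gamma))
    })
    out$beta[j] <- if (truth$sigma_beta > 0) bg[1] else truth$mu_beta
    out$gamma[j] <- if (truth$sigma_gamma > 0) bg[2] else truth$mu_gamma
  }
  out
}

#' Generate a synthetic stimulation dataset
#'
#' Draws per-animal curve parameters from `truth`, then for every animal and
#' voltage draws the stimulation count (unless fixed in the design), i.i.d.
#' uniform burst durations, and torques
#' `tau = beta_j * T^gamma_j + N(0, sigma_obs)`. Negative torques are
#' possible under the Gaussian noise model, as in the real measurements.
#'
#' @param truth A [population_truth()].
#' @param design An [experiment_design()].
#' @return Data frame of stimulation records with columns `animal_id`,
#'   `muscle`, `voltage_V`, `frequency_Hz`, `duty_pct`, `burst_duration_s`,
#'   `torque_uNm`, `stim_index`.
#' @examples
#' d <- generate_dataset(population_truth(), experiment_design(n_animals = 3))
#' head(d)
#' @export
generate_dataset <- function(truth, design) {
  stopifnot(inherits(truth, "population_truth"), inherits(design, "experiment_design"))
  pars <- sample_animal_params(truth, design$n_animals, design$seed)
  rows <- vector("list", design$n_animals)
  for (j in seq_len(design$n_animals)) {
    rows[[j]] <- with_seed(split_seed(design$seed, 2L * j + 1L), {
      per_v <- lapply(seq_along(design$voltages), function(v) {
        n <- if (is.null(design$stims_per_animal)) {
          sample(STIM_COUNT_RANGE[1]:STIM_COUNT_RANGE[2], 1L)
        } else {
          as.integer(design$stims_per_animal[j])
        }
        T_s <- stats::runif(n, design$duration_range[1], design$duration_range[2])
        tau <- mean_torque(pars$beta[j], pars$gamma[j], T_s) +
          stats::rnorm(n, 0, truth$sigma_obs)
        data.frame(animal_id = pars$animal_id[j],
                   muscle = design$muscle,
                   voltage_V = design$voltages[v],
                   frequency_Hz = design$frequency,
                   duty_pct = design$duty,
                   burst_duration_s = T_s,
                   torque_uNm = tau,
                   stim_index = seq_len(n),
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, per_v)
    })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- truth
  attr(out, "animal_params") <- pars
  out
}

#' Synthesize a raw force-sensor trace for a known torque
#'
#' Fixture generator for the torque-extraction pipeline: a flat zero-mean
#' baseline with a smooth half-sine deflection inside the stimulus window
#' whose noiseless peak-to-peak amplitude equals
#' `torque / (moment_arm * conversion_factor)` (unit chain:
#' uNm / (mm * mN/V) = V).
#'
#' @param torque_uNm Torque the trace should encode.
#' @param moment_arm_mm Moment arm in mm (> 0).
#' @param conversion_factor Sensor calibration in mN per V (> 0).
#' @param trace_length Number of samples over the 1 s trace; the default
#'   1001 puts the window edges and peak exactly on the sample grid so the
#'   noiseless round trip through [peak_to_peak()] is exact.
#' @param noise_sd Gaussian sensor noise SD in V.
#' @param seed RNG seed for the noise.
#' @return A [raw_trace()] with the stimulus window at 0.3--0.8 s.
#' @export
generate_force_trace <- function(torque_uNm, moment_arm_mm, conversion_factor,
                                 trace_length = 1001L, noise_sd = 0, seed = 1L) {
  stopifnot_scalar_number(moment_arm_mm, "moment_arm_mm", positive = TRUE)
  stopifnot_scalar_number(conversion_factor, "conversion_factor", positive = TRUE)
  amp <- torque_uNm / (moment_arm_mm * conversion_factor)
  time <- seq(0, 1, length.out = trace_length)
  window <- c(0.3, 0.8)
  sensor <- numeric(trace_length)
  inside <- time >= window[1] & time <= window[2]
  phase <- (time[inside] - window[1]) / diff(window)
  sensor[inside] <- amp * sin(pi * phase)
  if (noise_sd > 0) {
    sensor <- sensor + with_seed(seed, stats::rnorm(trace_length, 0, noise_sd))
  }
  raw_trace(time, sensor, window)
}

# ---- CSV schema ------------------------------------------------------------

STIM_CSV_COLUMNS <- c("animal_id", "muscle", "voltage_V", "frequency_Hz",
                      "duty_pct", "burst_duration_s", "torque_uNm", "stim_index")

#' Read / write the stimulation CSV schema
#'
#' Plain UTF-8 CSV with a fixed header
#' `animal_id,muscle,voltage_V,frequency_Hz,duty_pct,burst_duration_s,torque_uNm,stim_index`
#' and `.` as decimal separator. Numeric fields are written with full
#' precision so a write/read round trip is lossless.
#'
#' @param data Stimulation data frame (see [generate_dataset()]).
#' @param path File path.
#' @return `read_stimulation_csv` returns the data frame;
#'   `write_stimulation_csv` returns `path` invisibly.
#' @export
write_stimulation_csv <- function(data, path) {
  missing <- setdiff(STIM_CSV_COLUMNS, names(data))
  if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "))
  out <- data[STIM_CSV_COLUMNS]
  for (nm in c("voltage_V", "frequency_Hz", "duty_pct", "burst_duration_s", "torque_uNm")) {
    out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_stimulation_csv
#' @export
read_stimulation_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(STIM_CSV_COLUMNS, names(df))
  if (length(missing)) {
    stop("stimulation CSV ", path, " is missing columns: ",
         paste(missing, collapse = ", "))
  }
  bad <- which(!is.finite(df$burst_duration_s) | df$burst_duration_s <= 0)
  if (length(bad)) {
    stop("invalid burst duration in row ", bad[1], " of ", path)
  }
  df$stim_index <- as.integer(df$stim_index)
  df[STIM_CSV_COLUMNS]
}
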