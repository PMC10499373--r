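#' Build and validate a run configuration
#'
#' The configuration drives the end-to-end pipeline: simulate (or load) a
#' stimulation dataset, fit all six model variants per (muscle, voltage)
#' condition, rank them by new-animal WAIC, and export predictive outputs.
#' It can be given as a YAML/JSON file path or an equivalent nested list.
#' Keys: `mode` ("simulate" or "load"), `output_dir`, `seed`, `truth`,
#' `design`, `priors`, `chains`, `integration`, `data_path` (load mode),
#' `cutoff_s` (optional burst-duration cutoff in seconds).
#'
#' @param config File path (YAML or JSON) or nested list.
#' @return Validated object of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) stop("config must be a file path or a list")
  known <- c("mode", "output_dir", "seed", "truth", "design", "priors",
             "chains", "integration", "data_path", "cutoff_s")
  bad <- setdiff(names(config), known)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         "; valid keys: ", paste(known, collapse = ", "))
  }
  mode <- config$mode %||% "simulate"
  if (!mode %in% c("simulate", "load")) {
    stop("config key 'mode' must be \"simulate\" or \"load\", got \"", mode, "\"")
  }
  if (mode == "load" && is.null(config$data_path)) {
    stop("config key 'data_path' is required in load mode")
  }
  seed <- as.integer(config$seed %||% 1L)
  build <- function(key, fun, allowed) {
    args <- config[[key]] %||% list()
    bad <- setdiff(names(args), allowed)
    if (length(bad)) stop("unknown key(s) under config '", key, "': ",
                          paste(bad, collapse = ", "))
    tryCatch(do.call(fun, args),
             error = function(e) stop("invalid config block '", key, "': ",
                                      conditionMessage(e), call. = FALSE))
  }
  truth <- build("truth", population_truth,
                 c("mu_beta", "sigma_beta", "mu_gamma", "sigma_gamma",
                   "sigma_obs", "generating_model"))
  design_args <- config$design %||% list()
  if (is.null(design_args$seed)) design_args$seed <- seed
  design <- tryCatch(do.call(experiment_design, design_args),
                     error = function(e) stop("invalid config block 'design': ",
                                              conditionMessage(e), call. = FALSE))
  chain_args <- config$chains %||% list()
  if (is.null(chain_args$seed)) chain_args$seed <- seed
  chains <- tryCatch(do.call(chain_config, chain_args),
                     error = function(e) stop("invalid config block 'chains': ",
                                              conditionMessage(e), call. = FALSE))
  priors <- build("priors", prior_spec,
                  c("beta", "gamma", "sigma", "mu_beta", "sigma_beta",
                    "mu_gamma", "sigma_gamma"))
  integ <- build("integration", integration_config, c("n_points", "range_sd"))
  cutoff <- config$cutoff_s
  if (!is.null(cutoff) && (!is.numeric(cutoff) || cutoff <= 0)) {
    stop("config key 'cutoff_s' must be a positive duration in seconds")
  }
  structure(list(mode = mode,
                 output_dir = config$output_dir %||% ".",
                 seed = seed, truth = truth, design = design,
                 priors = priors, chains = chains, integration = integ,
                 data_path = config$data_path, cutoff_s = cutoff),
            class = "run_config")
}

st_log <- function(...) {
  message(format(Sys.time(), "%H:%M:%S"), " [stimtorque] ", ...)
}

manifest_new <- function(config) {
  cfg_json <- jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE, digits = NA)
  list(package_version = as.character(utils::packageVersion("stimtorque")),
       config_hash = md5_string(cfg_json),
       root_seed = config$seed,
       created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       stages = list(), files = list(), convergence = list())
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

md5_string <- function(x) {
  tf <- tempfile()
  writeLines(x, tf)
  on.exit(unlink(tf))
  unname(tools::md5sum(tf))
}

manifest_add_file <- function(manifest, path) {
  manifest$files[[basename(path)]] <- unname(tools::md5sum(path))
  manifest
}

manifest_write <- function(manifest, output_dir) {
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Simulate a stimulation dataset and write it to disk
#'
#' Writes `stimulations.csv` (the standard schema), a `truth.json` sidecar
#' recording the generating population parameters (for later recovery
#' scoring), and a `manifest.json` with content hashes of every output.
#'
#' @param config A [run_config()] (or anything it accepts).
#' @return Invisibly, the generated data frame.
#' @export
cmd_simulate <- function(config) {
  config <- if (inherits(config, "run_config")) config else run_config(config)
  if (config$mode != "simulate") stop("cmd_simulate requires mode = \"simulate\"")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  st_log("simulate: start (", config$design$n_animals, " animals, muscle ",
         config$design$muscle, ", seed ", config$design$seed, ")")
  t0 <- proc.time()[["elapsed"]]
  data <- generate_dataset(config$truth, config$design)
  man <- manifest_new(config)

  csv <- file.path(config$output_dir, "stimulations.csv")
  write_stimulation_csv(data, csv)
  man <- manifest_add_file(man, csv)

  truth_path <- file.path(config$output_dir, "truth.json")
  jsonlite::write_json(unclass(config$truth), truth_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  man <- manifest_add_file(man, truth_path)

  man$stages$simulate <- list(records = nrow(data),
                              elapsed_s = round(proc.time()[["elapsed"]] - t0, 3))
  manifest_write(man, config$output_dir)
  st_log("simulate: wrote ", nrow(data), " records to ", csv)
  invisible(data)
}

load_run_data <- function(config) {
  path <- if (config$mode == "load") config$data_path else {
    file.path(config$output_dir, "stimulations.csv")
  }
  if (!file.exists(path)) stop("dataset not found at ", path,
                               "; run cmd_simulate first or set data_path")
  data <- read_stimulation_csv(path)
  if (nrow(data) == 0L) stop("dataset at ", path, " is empty")
  if (!is.null(config$cutoff_s)) {
    data <- data[data$burst_duration_s <= config$cutoff_s, , drop = FALSE]
    if (nrow(data) == 0L) stop("no records survive the ", config$cutoff_s,
                               " s burst-duration cutoff")
  }
  data
}

#' Fit all six models per condition and rank them by WAIC
#'
#' Splits the dataset by (muscle, voltage), fits every model variant on each
#' condition with seeds derived from the root seed, checks convergence
#' (split Rhat < 1.10), computes the new-animal WAIC, and writes per-model
#' draw CSVs, a convergence JSON and the ranked WAIC table per condition.
#' Models failing the convergence check are flagged in the table, never
#' dropped.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list per condition with elements `data`, `fits`,
#'   `waic` (result list), `table` (ranked data frame), `convergence`.
#' @export
cmd_fit_compare <- function(config) {
  config <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  data <- load_run_data(config)
  man <- manifest_new(config)
  conditions <- unique(data[c("muscle", "voltage_V")])
  results <- list()
  for (ci in seq_len(nrow(conditions))) {
    mus <- conditions$muscle[ci]; volt <- conditions$voltage_V[ci]
    cond_data <- data[data$muscle == mus & data$voltage_V == volt, , drop = FALSE]
    cond_tag <- sprintf("%s_%gV", mus, volt)
    st_log("fit: condition ", cond_tag, " (", nrow(cond_data), " records, ",
           length(unique(cond_data$animal_id)), " animals)")
    t0 <- proc.time()[["elapsed"]]
    fits <- list(); waics <- list(); conv <- list()
    for (mi in seq_along(model_ids())) {
      id <- model_ids()[mi]
      cc <- config$chains
      cc$seed <- split_seed(config$seed, 1000L * ci + mi)
      fit <- sample_posterior(id, cond_data, config$priors, cc)
      rep_ <- compute_rhat(fit)
      fits[[id]] <- fit
      conv[[id]] <- rep_
      waics[[id]] <- waic(id, fit, cond_data, config$integration)
      draws_path <- file.path(config$output_dir,
                              sprintf("draws_%s_model%s.csv", cond_tag, id))
      write_draws_csv(fit, draws_path)
      man <- manifest_add_file(man, draws_path)
      st_log("fit: model ", id, " done (max Rhat ",
             sprintf("%.3f", suppressWarnings(max(rep_$table$rhat, na.rm = TRUE))),
             ", WAIC ", sprintf("%.4f", waics[[id]]$waic), ")")
    }
    tab <- compare_models(waics)
    tab$converged <- vapply(tab$model_id, function(id) conv[[id]]$pass, logical(1))
    tab_path <- file.path(config$output_dir, sprintf("waic_%s.csv", cond_tag))
    utils::write.csv(tab, tab_path, row.names = FALSE, quote = FALSE)
    man <- manifest_add_file(man, tab_path)
    conv_path <- file.path(config$output_dir, sprintf("convergence_%s.json", cond_tag))
    jsonlite::write_json(
      lapply(conv, function(r) list(pass = r$pass, max_rhat =
        suppressWarnings(max(r$table$rhat, na.rm = TRUE)))),
      conv_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    man <- manifest_add_file(man, conv_path)
    man$stages[[paste0("fit_", cond_tag)]] <- list(
      records = nrow(cond_data),
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 3))
    man$convergence[[cond_tag]] <- lapply(conv, function(r) r$pass)
    results[[cond_tag]] <- list(data = cond_data, fits = fits, waic = waics,
                                table = tab, convergence = conv)
    st_log("fit: condition ", cond_tag, " winner = ", tab$model_id[1])
  }
  manifest_write(man, config$output_dir)
  invisible(results)
}

#' Export predictive surface and top-density curves for one model
#'
#' Computes the new-animal predictive density surface on a (T, tau) grid
#' (the tau grid spans +/- 8 predictive SDs so each column integrates to 1)
#' and the 20 highest-posterior-density population mean curves. For
#' hierarchical models, per-animal conditional surfaces are written as well.
#'
#' @param config A [run_config()].
#' @param model_id Which model variant to use.
#' @param fit Optional `posterior_draws` from a previous [cmd_fit_compare()];
#'   if missing, the model is refitted deterministically.
#' @param k Number of top-density curves (default 20, as in the figures the
#'   pipeline emulates).
#' @param n_T,n_tau Grid resolution.
#' @return Invisibly, a list with the surface, curves, and file paths.
#' @export
cmd_predict <- function(config, model_id, fit = NULL, k = 20L,
                        n_T = 40L, n_tau = 201L) {
  config <- if (inherits(config, "run_config")) config else run_config(config)
  if (!model_id %in% model_ids()) {
    stop("unknown model id '", model_id, "'; valid ids: ",
         paste(model_ids(), collapse = ", "))
  }
  spec <- model_spec(model_id)
  data <- load_run_data(config)
  cond <- data[data$muscle == data$muscle[1] & data$voltage_V == data$voltage_V[1], ]
  if (is.null(fit)) {
    st_log("predict: refitting model ", model_id)
    cc <- config$chains
    cc$seed <- split_seed(config$seed, 1000L + match(model_id, model_ids()))
    fit <- sample_posterior(spec, cond, config$priors, cc)
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  man <- manifest_new(config)
  t0 <- proc.time()[["elapsed"]]

  T_grid <- seq(min(cond$burst_duration_s), max(cond$burst_duration_s),
                length.out = n_T)
  tau_grid <- default_tau_grid(spec, fit, T_grid, n_tau)
  surf <- predictive_surface(spec, fit, T_grid, tau_grid, config$integration)
  surf_path <- file.path(config$output_dir,
                         sprintf("surface_model%s.csv", model_id))
  utils::write.csv(surface_to_df(surf), surf_path, row.names = FALSE, quote = FALSE)
  man <- manifest_add_file(man, surf_path)

  curves <- top_density_curves(spec, fit, k = k, T_grid = T_grid)
  curves_path <- file.path(config$output_dir,
                           sprintf("curves_model%s.csv", model_id))
  utils::write.csv(curves, curves_path, row.names = FALSE, quote = FALSE)
  man <- manifest_add_file(man, curves_path)

  animal_surfaces <- list()
  if (spec$hier_beta || spec$hier_gamma) {
    for (a in fit$animals) {
      asurf <- predictive_surface(spec, fit, T_grid, tau_grid,
                                  config$integration, animal = a)
      ap <- file.path(config$output_dir,
                      sprintf("surface_model%s_%s.csv", model_id, a))
      utils::write.csv(surface_to_df(asurf), ap, row.names = FALSE, quote = FALSE)
      man <- manifest_add_file(man, ap)
      animal_surfaces[[a]] <- asurf
    }
  }
  man$stages[[paste0("predict_model", model_id)]] <- list(
    elapsed_s = round(proc.time()[["elapsed"]] - t0, 3))
  manifest_write(man, config$output_dir)
  st_log("predict: wrote surface and ", k, " curves for model ", model_id)
  invisible(list(surface = surf, curves = curves,
                 animal_surfaces = animal_surfaces,
                 paths = c(surf_path, curves_path)))
}

# tau grid spanning the predictive mass: population mean curve +/- 8
# predictive SDs at the extreme durations, pooled over draws.
default_tau_grid <- function(spec, fit, T_grid, n_tau) {
  m <- as_draws_matrix(fit)
  cols <- marginal_columns(spec, m)
  Tr <- range(T_grid)
  mu_c <- if (spec$hier_beta) cols$mu_beta else cols$beta
  gam_c <- if (spec$hier_gamma) cols$mu_gamma else cols$gamma
  lo <- Inf; hi <- -Inf
  for (T_s in Tr) {
    mu <- mu_c * T_s^gam_c
    extra_b <- if (spec$hier_beta) (cols$sigma_beta * T_s^gam_c)^2 else 0
    extra_g <- if (spec$hier_gamma) {
      (mu_c * T_s^gam_c * abs(log(T_s)) * cols$sigma_gamma)^2
    } else 0
    sd <- sqrt(cols$sigma^2 + extra_b + extra_g)
    lo <- min(lo, mu - 8 * sd); hi <- max(hi, mu + 8 * sd)
  }
  seq(lo, hi, length.out = n_tau)
}
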