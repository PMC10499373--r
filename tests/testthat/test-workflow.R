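# Small end-to-end configuration used across the workflow tests: 4 animals,
# fixed counts, short chains. Everything derives from one root seed.
tiny_config <- function(dir, seed = 5, extra = list()) {
  base <- list(
    mode = "simulate",
    output_dir = dir,
    seed = seed,
    truth = list(mu_beta = 100, sigma_beta = 30, sigma_obs = 10,
                 generating_model = "1-2"),
    design = list(n_animals = 4, stims_per_animal = rep(20L, 4)),
    chains = list(n_chains = 2, n_warmup = 250, n_samples = 150),
    integration = list(n_points = 51, range_sd = 6))
  utils::modifyList(base, extra)
}

test_that("cmd_simulate writes the dataset, truth sidecar and manifest", {
  dir <- withr::local_tempdir()
  d <- suppressMessages(cmd_simulate(tiny_config(dir)))
  expect_true(file.exists(file.path(dir, "stimulations.csv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  expect_true(file.exists(file.path(dir, "manifest.json")))

  back <- read_stimulation_csv(file.path(dir, "stimulations.csv"))
  expect_equal(nrow(back), nrow(d))
  expect_true(all(back$burst_duration_s > 0 & back$burst_duration_s <= 1))

  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_equal(truth$mu_beta, 100)

  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  expect_true(all(c("stimulations.csv", "truth.json") %in% names(man$files)))
  expect_equal(unname(tools::md5sum(file.path(dir, "stimulations.csv"))),
               man$files[["stimulations.csv"]])
})

test_that("identical config and seed give identical simulated files", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  suppressMessages(cmd_simulate(tiny_config(d1)))
  suppressMessages(cmd_simulate(tiny_config(d2)))
  expect_identical(readLines(file.path(d1, "stimulations.csv")),
                   readLines(file.path(d2, "stimulations.csv")))
})

test_that("malformed configuration fails with a structured error naming the key", {
  dir <- withr::local_tempdir()
  expect_error(run_config(tiny_config(dir, extra = list(bogus_key = 1))),
               "bogus_key")
  expect_error(run_config(tiny_config(dir, extra = list(mode = "teleport"))),
               "mode")
  expect_error(run_config(tiny_config(dir, extra = list(
    truth = list(mu_beta = 100, nonsense = 2)))), "nonsense")
  expect_error(run_config(tiny_config(dir, extra = list(cutoff_s = -0.5))),
               "cutoff_s")
  cfg <- tiny_config(dir); cfg$mode <- "load"; cfg$data_path <- NULL
  expect_error(run_config(cfg), "data_path")
})

test_that("configs round-trip through YAML", {
  dir <- withr::local_tempdir()
  cfg_path <- file.path(dir, "run.yaml")
  yaml::write_yaml(tiny_config(dir), cfg_path)
  cfg <- run_config(cfg_path)
  expect_s3_class(cfg, "run_config")
  expect_equal(cfg$truth$mu_beta, 100)
  expect_equal(cfg$design$n_animals, 4)
  expect_equal(cfg$chains$n_samples, 150)
})

test_that("cmd_fit_compare fits all six models and writes a ranked table", {
  dir <- withr::local_tempdir()
  cfg <- run_config(tiny_config(dir))
  suppressMessages(cmd_simulate(cfg))
  res <- suppressMessages(cmd_fit_compare(cfg))
  cond <- res[[1]]
  expect_length(cond$fits, 6)
  expect_setequal(cond$table$model_id, model_ids())
  expect_equal(cond$table$rank, 1:6)
  expect_true(all(diff(cond$table$waic) >= 0)) # ascending
  expect_true(is.logical(cond$table$converged))

  tab_files <- list.files(dir, pattern = "^waic_.*\\.csv$")
  expect_length(tab_files, 1)
  draw_files <- list.files(dir, pattern = "^draws_.*\\.csv$")
  expect_length(draw_files, 6)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  expect_true(all(c(tab_files, draw_files) %in% names(man$files)))
})

test_that("end-to-end WAIC tables are deterministic given the config", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  for (dir in c(d1, d2)) {
    cfg <- run_config(tiny_config(dir))
    suppressMessages(cmd_simulate(cfg))
    suppressMessages(cmd_fit_compare(cfg))
  }
  f <- function(dir) list.files(dir, pattern = "^waic_", full.names = TRUE)
  expect_identical(readLines(f(d1)), readLines(f(d2)))
})

test_that("the burst-duration cutoff filters records before fitting", {
  dir <- withr::local_tempdir()
  cfg <- run_config(tiny_config(dir))
  suppressMessages(cmd_simulate(cfg))
  full <- read_stimulation_csv(file.path(dir, "stimulations.csv"))

  cfg_cut <- run_config(tiny_config(dir, extra = list(cutoff_s = 0.5)))
  res <- suppressMessages(cmd_fit_compare(cfg_cut))
  n_kept <- sum(full$burst_duration_s <= 0.5)
  expect_equal(nrow(res[[1]]$data), n_kept)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  fit_stage <- man$stages[[grep("^fit_", names(man$stages))[1]]]
  expect_equal(fit_stage$records, n_kept)
})

test_that("an empty dataset is an error with no outputs", {
  dir <- withr::local_tempdir()
  writeLines(paste(c("animal_id,muscle,voltage_V,frequency_Hz,duty_pct",
                     "burst_duration_s,torque_uNm,stim_index"), collapse = ","),
             file.path(dir, "stimulations.csv"))
  cfg <- run_config(tiny_config(dir))
  expect_error(suppressMessages(cmd_fit_compare(cfg)), "empty")
  expect_length(list.files(dir, pattern = "^waic_"), 0)
})

test_that("cmd_predict writes surface and curves with k = 20 by default", {
  dir <- withr::local_tempdir()
  cfg <- run_config(tiny_config(dir))
  suppressMessages(cmd_simulate(cfg))
  res <- suppressMessages(cmd_fit_compare(cfg))
  fit <- res[[1]]$fits[["1-2"]]
  out <- suppressMessages(cmd_predict(cfg, "1-2", fit = fit,
                                      n_T = 6, n_tau = 301))
  expect_equal(length(unique(out$curves$curve)), 20)
  expect_true(file.exists(file.path(dir, "surface_model1-2.csv")))
  expect_true(file.exists(file.path(dir, "curves_model1-2.csv")))
  # hierarchical model: one conditional surface per animal
  expect_length(out$animal_surfaces, 4)

  # every tau column of the marginal surface integrates to ~1
  sdf <- out$surface
  dt <- diff(sdf$tau_grid)[1]
  ints <- colSums(sdf$density) * dt -
    dt * (sdf$density[1, ] + sdf$density[nrow(sdf$density), ]) / 2
  expect_true(all(abs(ints - 1) < 1e-3))

  expect_error(suppressMessages(cmd_predict(cfg, "7-7")), "valid ids")
})
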