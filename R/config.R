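## Run configuration, YAML/CSV serialization, run records and the
## command-level entry points backing the CLI script (inst/cli/promcm.R).

#' Run configuration
#'
#' A flat, human-editable set of keys covering the reference curves, dose
#' grid, simulation constants, optimizer settings and output location.
#' Defaults reproduce the reference study conditions (alpha = 2.0,
#' gamma = 0.2, dt = 1, t_end = 200, 10,000 cells, 34 doses, activity map
#' 0/1/10, reference Hill coefficients 1.6 and 1.8).  Round-trips
#' losslessly through YAML via [write_run_config()] / [read_run_config()].
#'
#' @param chain one of [chain_kinds()].
#' @param H_act,K_act,H_rep,K_rep reference Hill parameters of the
#'   observed activator-only / repressor-only curves (`K` values are
#'   configurable; they are not printed in the reference data).
#' @param n_doses,dox_min,dox_max,include_zero dose-grid specification.
#' @param alpha,gamma,dt,t_end,n_cells,deg_noise_sd,bl_noise_sd,activity,update_mode
#'   simulation constants, see [sim_config()].
#' @param seed master seed.
#' @param budget optimizer evaluation budget.
#' @param output_dir directory for command outputs.
#' @return Object of class `"run_config"`.
#' @export
run_config <- function(chain = "three_state",
                       H_act = 1.6, K_act = 0.6, H_rep = 1.8, K_rep = 0.6,
                       n_doses = 34L, dox_min = 0.01, dox_max = 10,
                       include_zero = TRUE,
                       alpha = 2.0, gamma = 0.2, dt = 1, t_end = 200L,
                       n_cells = 10000L, deg_noise_sd = 0.5,
                       bl_noise_sd = 0.5,
                       activity = c(repressor_bound = 0, unbound = 1,
                                    activator_bound = 10),
                       update_mode = "two_jump",
                       seed = 1L, budget = 50000L,
                       output_dir = "promcm-out") {
  chain <- match.arg(chain, chain_kinds())
  update_mode <- match.arg(update_mode, c("two_jump", "single_jump"))
  stopifnot(H_act > 0, K_act > 0, H_rep > 0, K_rep > 0,
            n_doses >= 7L, dox_min > 0, dox_max > dox_min,
            is.logical(include_zero), budget >= 1000L)
  cfg <- sim_config(alpha = alpha, gamma = gamma, dt = dt, t_end = t_end,
                    n_cells = n_cells, deg_noise_sd = deg_noise_sd,
                    bl_noise_sd = bl_noise_sd, activity = activity,
                    update_mode = update_mode, seed = seed)
  structure(list(chain = chain,
                 H_act = as.numeric(H_act), K_act = as.numeric(K_act),
                 H_rep = as.numeric(H_rep), K_rep = as.numeric(K_rep),
                 n_doses = as.integer(n_doses),
                 dox_min = as.numeric(dox_min),
                 dox_max = as.numeric(dox_max),
                 include_zero = isTRUE(include_zero),
                 alpha = as.numeric(alpha), gamma = as.numeric(gamma),
                 dt = as.numeric(dt), t_end = as.integer(t_end),
                 n_cells = as.integer(n_cells),
                 deg_noise_sd = as.numeric(deg_noise_sd),
                 bl_noise_sd = as.numeric(bl_noise_sd),
                 activity = vapply(cfg$activity, as.numeric, numeric(1)),
                 update_mode = update_mode,
                 seed = as.integer(seed), budget = as.integer(budget),
                 output_dir = output_dir),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("promcm run configuration\n")
  for (nm in names(unclass(x))) {
    v <- x[[nm]]
    cat(sprintf("  %-13s %s\n", nm,
                paste(format(v, digits = 10), collapse = " ")))
  }
  invisible(x)
}

#' Write / read a run configuration (YAML)
#'
#' @param config a [run_config()] object.
#' @param path file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   a [run_config()].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  raw <- unclass(config)
  raw$activity <- as.list(raw$activity)   # keep state names in the YAML map
  yaml::write_yaml(raw, path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$activity <- unlist(raw$activity)
  do.call(run_config, raw)
}

## Derived pieces of a run configuration.
config_sim <- function(config) {
  sim_config(alpha = config$alpha, gamma = config$gamma, dt = config$dt,
             t_end = config$t_end, n_cells = config$n_cells,
             deg_noise_sd = config$deg_noise_sd,
             bl_noise_sd = config$bl_noise_sd,
             activity = config$activity,
             update_mode = config$update_mode, seed = config$seed)
}
config_doses <- function(config) {
  dose_grid(config$n_doses, config$dox_min, config$dox_max,
            config$include_zero)
}
config_curves <- function(config) {
  observed_curves(hill(config$K_act, config$H_act),
                  hill(config$K_rep, config$H_rep),
                  dox = config_doses(config))
}

.full_num <- function(x) sprintf("%.17g", x)

#' Write / read an estimated switching model (CSV)
#'
#' One row per Hill function with columns `name`, `K`, `H`, written at
#' full double precision so equal seeds give byte-identical files.
#'
#' @param model a `switching_model` or fitted `mcm` object.
#' @param path file path.
#' @return `write_switching_csv` returns `path` invisibly;
#'   `read_switching_csv` a `switching_model`.
#' @export
write_switching_csv <- function(model, path) {
  if (inherits(model, "mcm")) model <- model$model
  stopifnot(inherits(model, "switching_model"))
  df <- data.frame(name = names(model),
                   K = .full_num(vapply(model, `[[`, numeric(1), "K")),
                   H = .full_num(vapply(model, `[[`, numeric(1), "H")))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_switching_csv
#' @param chain chain kind of a 2-state model CSV (the file itself only
#'   names the Hill functions); ignored for 3-state files.
#' @export
read_switching_csv <- function(path, chain = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "K", "H") %in% names(df)))
    stop("malformed switching-model CSV: need columns name, K, H")
  hp <- list()
  for (i in seq_len(nrow(df))) {
    K <- suppressWarnings(as.numeric(df$K[i]))
    H <- suppressWarnings(as.numeric(df$H[i]))
    if (!is.finite(K) || !is.finite(H) || K <= 0 || H <= 0)
      stop("malformed switching-model CSV at row ", i, " (name = '",
           df$name[i], "'): K and H must be positive numbers")
    hp[[df$name[i]]] <- hill(K, H)
  }
  if (setequal(names(hp), c("A1", "A2", "R1", "R2")))
    return(do.call(switching_model, c(hp, list(chain = "three_state"))))
  dependent <- setequal(names(hp), "p1")
  if (!dependent && !setequal(names(hp), c("p1", "p2")))
    stop("malformed switching-model CSV: unexpected Hill function names: ",
         paste(names(hp), collapse = ", "))
  if (is.null(chain) || !chain %in% c("activator", "repressor"))
    stop("2-state switching CSV does not identify its chain; ",
         "pass chain = \"activator\" or \"repressor\"")
  do.call(switching_model,
          c(hp, list(chain = chain, dependent = dependent)))
}

#' Write a population sample (CSV)
#'
#' Columns `dox`, `cell_index`, `X_final`, full double precision.
#'
#' @param sample a `"population_sample"`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_population_csv <- function(sample, path) {
  stopifnot(inherits(sample, "population_sample"))
  df <- data.frame(dox = .full_num(rep(sample$dox, length(sample$values))),
                   cell_index = seq_along(sample$values),
                   X_final = .full_num(sample$values))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a dose-response table (CSV)
#'
#' @param table a `"dose_response"` table.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_dose_response_csv <- function(table, path) {
  df <- data.frame(dox = .full_num(table$dox),
                   mean_X = .full_num(table$mean_X),
                   sd_X = .full_num(table$sd_X),
                   norm_mean = .full_num(table$norm_mean))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run record
#'
#' A reproducibility manifest: config snapshot, seeds, package version,
#' timestamp and the MD5 checksum of every output file.  A run is
#' reproducible from its record alone.
#'
#' @param config the [run_config()] used.
#' @param seeds named list/vector of seeds used by each stage.
#' @param files character vector of output file paths.
#' @param path where to write the YAML record.
#' @return The record (list), invisibly.
#' @export
write_run_record <- function(config, seeds, files, path) {
  stopifnot(inherits(config, "run_config"))
  sums <- tools::md5sum(files)
  scaled <- config$n_cells < 10000L || config$n_doses < 34L
  rec <- list(config = unclass(config),
              seeds = as.list(seeds),
              version = as.character(utils::packageVersion("promcm")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              scaled = scaled,
              manifest = lapply(seq_along(files), function(i)
                list(file = basename(files[i]), md5 = unname(sums[i]))))
  yaml::write_yaml(rec, path, precision = 15)
  invisible(rec)
}

.log <- function(...) message(sprintf(...))

.warn_nondefault <- function(config) {
  if (config$n_cells != 10000L || config$n_doses != 34L ||
      config$t_end != 200L)
    .log("note: config departs from reference defaults (n_cells=%d, n_doses=%d, t_end=%d)",
         config$n_cells, config$n_doses, config$t_end)
}

#' Command: estimate a switching model
#'
#' Estimates the switching model for `config$chain` and writes
#' `switching_model.csv` plus `run_record.yaml` to the output directory.
#'
#' @param config a [run_config()].
#' @param dir output directory (default `config$output_dir`).
#' @return The fitted `mcm` object, invisibly.
#' @export
cmd_estimate <- function(config, dir = config$output_dir) {
  stopifnot(inherits(config, "run_config"))
  .warn_nondefault(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fit <- estimate_switching(config_curves(config), chain = config$chain,
                            seed = config$seed, budget = config$budget)
  f_model <- file.path(dir, "switching_model.csv")
  write_switching_csv(fit, f_model)
  .log("estimate [%s]: objective = %.6g, contingency %s, seed %d",
       config$chain, fit$objective_value,
       if (fit$constraint_satisfied) "satisfied" else "violated",
       config$seed)
  write_run_record(config, list(estimate = config$seed), f_model,
                   file.path(dir, "run_record.yaml"))
  invisible(fit)
}

#' Command: simulate populations at given doses
#'
#' Reads a switching model from CSV and writes one population CSV per dox
#' plus a mean/sd summary CSV.
#'
#' @param config a [run_config()].
#' @param model_file path to a switching-model CSV
#'   ([write_switching_csv()]).
#' @param dox vector of dox levels.
#' @param dir output directory.
#' @return Data frame of per-dox means/sds, invisibly.
#' @export
cmd_simulate <- function(config, model_file, dox,
                         dir = config$output_dir) {
  stopifnot(inherits(config, "run_config"))
  if (!file.exists(model_file))
    stop("model file not found: ", model_file)
  model <- read_switching_csv(model_file, chain = config$chain)
  .warn_nondefault(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- config_sim(config)
  files <- character(0)
  summ <- data.frame(dox = numeric(0), mean_X = numeric(0),
                     sd_X = numeric(0))
  for (i in seq_along(dox)) {
    s <- simulate_population(config$chain, model, dox[i], cfg,
                             seed = config$seed + i)
    f <- file.path(dir, sprintf("population_dox_%02d.csv", i))
    write_population_csv(s, f)
    files <- c(files, f)
    summ <- rbind(summ, data.frame(dox = dox[i], mean_X = s$mean,
                                   sd_X = s$sd))
    .log("simulate [%s] dox = %g: mean = %.4g, sd = %.4g",
         config$chain, dox[i], s$mean, s$sd)
  }
  f_sum <- file.path(dir, "population_summary.csv")
  utils::write.csv(summ, f_sum, row.names = FALSE)
  write_run_record(config, list(simulate = config$seed),
                   c(files, f_sum), file.path(dir, "run_record.yaml"))
  invisible(summ)
}

#' Command: estimate + simulate a dose-response table
#'
#' @param config a [run_config()].
#' @param dir output directory.
#' @return The `"dose_response"` table, invisibly.
#' @export
cmd_dose_response <- function(config, dir = config$output_dir) {
  stopifnot(inherits(config, "run_config"))
  .warn_nondefault(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fit <- estimate_switching(config_curves(config), chain = config$chain,
                            seed = config$seed, budget = config$budget)
  tab <- run_dose_response(config$chain, fit,
                           dox_grid = config_doses(config),
                           cfg = config_sim(config),
                           seed = config$seed + 1000L)
  f <- file.path(dir, sprintf("dose_response_%s.csv", config$chain))
  write_dose_response_csv(tab, f)
  hf <- predict_hill(tab)
  .log("dose-response [%s]: fitted H = %.4f (SE %.3g), K = %.4f",
       config$chain, hf$params$H, hf$se_H, hf$params$K)
  write_run_record(config,
                   list(estimate = config$seed,
                        simulate = config$seed + 1000L),
                   f, file.path(dir, "run_record.yaml"))
  invisible(tab)
}

#' Command: full three-chain prediction report
#'
#' Runs estimation, simulation and Hill refits for all three chains and
#' writes the per-chain dose-response CSVs, a `prediction_report.csv` and
#' a plain-text report mirroring the headline comparison table.
#'
#' @param config a [run_config()].
#' @param dir output directory.
#' @return The `"mcm_report"`, invisibly.
#' @export
cmd_predict <- function(config, dir = config$output_dir) {
  stopifnot(inherits(config, "run_config"))
  .warn_nondefault(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rep_ <- mcm_report(hill(config$K_act, config$H_act),
                     hill(config$K_rep, config$H_rep),
                     dox = config_doses(config),
                     cfg = config_sim(config),
                     seed = config$seed, budget = config$budget)
  files <- character(0)
  for (ch in chain_kinds()) {
    f <- file.path(dir, sprintf("dose_response_%s.csv", ch))
    write_dose_response_csv(rep_$tables[[ch]], f)
    files <- c(files, f)
    .log("predict [%s]: fitted H = %.4f (SE %.3g)",
         ch, rep_$hill[[ch]]$params$H, rep_$hill[[ch]]$se_H)
  }
  h <- function(f) f$params$H
  df <- data.frame(
    quantity = c("H_activator", "H_repressor", "H_combined",
                 "se_H_combined", "K_combined", "calc_add", "calc_mult",
                 "observed_act", "observed_rep", "observed_combined"),
    value = .full_num(c(h(rep_$hill$activator), h(rep_$hill$repressor),
                        h(rep_$hill$three_state),
                        rep_$hill$three_state$se_H,
                        rep_$hill$three_state$params$K,
                        rep_$calc_add, rep_$calc_mult,
                        rep_$observed_reference$act,
                        rep_$observed_reference$rep,
                        rep_$observed_reference$combined)))
  f_rep <- file.path(dir, "prediction_report.csv")
  utils::write.csv(df, f_rep, row.names = FALSE, quote = FALSE)
  f_txt <- file.path(dir, "prediction_report.txt")
  utils::capture.output(print(rep_), file = f_txt)
  files <- c(files, f_rep, f_txt)
  write_run_record(config, list(master = config$seed), files,
                   file.path(dir, "run_record.yaml"))
  invisible(rep_)
}
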