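# known flat configuration keys and their defaults (NULL = use constructor
# default); the single documented schema shared by read_config() and
# run_pipeline()
config_schema <- function() {
  list(
    k_foldase = 0.1, Km = 1, Kd = 2, monomers_per_unit = 1,
    k_NU = 1, client_conc = 100,
    foldase_size_kDa = 70, holdase_size_kDa = 40,
    atp_per_residue = 5, da_per_residue = 100,
    atp_per_cycle = 1, cycle_rate = 0.1, idle_activity_fraction = 1,
    aa_cost_per_residue = 0,
    requirement_mode = "proportional", u_o = 0.1, u_fixed = 0.1,
    variant = "constant_run",
    sweep_min = 1e-3, sweep_max = 1e3, sweep_n = 61, sweep_mode = "exact",
    gen_n_samples = 6, gen_true_slope = -1, gen_intercept_log10 = 1,
    gen_noise_sigma_log10 = 0.3, gen_rate_min = 1, gen_rate_decades = 3,
    aging_n_timepoints = 8, aging_synthesis_fold_drop = 20,
    aging_k_syn_start = 0.25, aging_noise_sigma_log10 = 0.2
  )
}

#' Read and validate a pipeline configuration file
#'
#' Configuration files are flat YAML key-value maps; any subset of the
#' schema keys may be given (an empty file yields all defaults) and
#' unknown keys are rejected. Values are validated through the parameter
#' constructors, so violations produce field-level messages. The `variant`
#' key applies one of the named sensitivity variants (see
#' [apply_variant()]) after the explicit keys, so e.g. `variant: Kd_tight`
#' overrides `Kd` to 0.01 uM.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`: list with `model` (a [chap_config()]),
#'   `sweep` (grid spec), `generator` and `aging` sub-lists, plus
#'   provenance (`path`, `md5`) in attributes.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) abort("config must be a YAML mapping of key: value.")
  schema <- config_schema()
  unknown <- setdiff(names(raw), names(schema))
  if (length(unknown))
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  cfg <- build_pipeline_config(modifyList(schema, raw))
  attr(cfg, "path") <- path
  attr(cfg, "md5") <- unname(tools::md5sum(path))
  cfg
}

# assemble a validated pipeline_config from a full flat key list
build_pipeline_config <- function(kv) {
  check_field <- function(expr, field) {
    tryCatch(expr, error = function(e)
      abort(sprintf("invalid config field `%s`: %s", field,
                    conditionMessage(e))))
  }
  fkin <- check_field(foldase_kinetics(kv$k_foldase, kv$Km), "k_foldase/Km")
  hkin <- check_field(holdase_kinetics(kv$Kd, kv$monomers_per_unit), "Kd")
  cost_f <- check_field(
    cost_params(kv$foldase_size_kDa, kv$atp_per_residue, kv$da_per_residue,
                kv$atp_per_cycle, kv$cycle_rate, kv$idle_activity_fraction,
                kv$aa_cost_per_residue), "foldase cost")
  cost_h <- check_field(
    holdase_cost_params(kv$holdase_size_kDa, kv$atp_per_residue,
                        kv$da_per_residue, kv$aa_cost_per_residue),
    "holdase cost")
  req <- check_field(requirement(kv$requirement_mode, kv$u_o, kv$u_fixed),
                     "requirement")
  model <- chap_config(fkin, hkin, cost_f, cost_h, req,
                       k_NU = kv$k_NU, client_conc = kv$client_conc)
  model <- apply_variant(model, kv$variant)
  if (kv$sweep_min <= 0 || kv$sweep_max <= kv$sweep_min || kv$sweep_n < 2)
    abort("invalid config field `sweep_min/sweep_max/sweep_n`.")
  structure(
    list(
      model = model,
      sweep = list(min = kv$sweep_min, max = kv$sweep_max,
                   n = as.integer(kv$sweep_n), mode = kv$sweep_mode),
      generator = list(n_samples = kv$gen_n_samples,
                       true_slope = kv$gen_true_slope,
                       intercept_log10 = kv$gen_intercept_log10,
                       noise_sigma_log10 = kv$gen_noise_sigma_log10,
                       rate_min = kv$gen_rate_min,
                       rate_decades = kv$gen_rate_decades),
      aging = list(n_timepoints = kv$aging_n_timepoints,
                   synthesis_fold_drop = kv$aging_synthesis_fold_drop,
                   k_syn_start = kv$aging_k_syn_start,
                   noise_sigma_log10 = kv$aging_noise_sigma_log10)
    ),
    class = "pipeline_config"
  )
}

#' Default pipeline configuration
#'
#' @return The `pipeline_config` produced by the schema defaults.
#' @export
default_pipeline_config <- function() build_pipeline_config(config_schema())

#' Read a tidy abundance table from CSV/TSV
#'
#' Enforces the tidy schema (`sample_id`, `rate`, `chaperone_class`,
#' `abundance`, optional `outlier_flag`); extra columns are preserved
#' untouched. Errors name the offending column.
#'
#' @param path CSV (or TSV, by extension) file path.
#' @return A validated tibble.
#' @export
read_abundance_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  reader <- if (grepl("\\.tsv$", path)) readr::read_tsv else readr::read_csv
  data <- reader(path, show_col_types = FALSE, progress = FALSE)
  validate_abundance_table(data)
}

#' Write a table to CSV at full precision
#'
#' @param table A data frame.
#' @param path Output path (directory created if needed).
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(table, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the stages end-to-end: optimal-allocation sweep, asymptotic
#' slope table, synthetic abundance table plus its scaling fit, synthetic
#' aging trajectory, and a run manifest. All outputs are tidy CSVs under
#' `out_dir`; the manifest (JSON) records the configuration hash, seed,
#' variant and package version so a run can be reproduced exactly. Two
#' runs with the same configuration and seed produce identical CSVs.
#'
#' @param config A `pipeline_config` from [read_config()], or `NULL` for
#'   the defaults.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed driving all synthetic-data stages.
#' @return Invisibly, a named list of the files written.
#' @export
run_pipeline <- function(config = NULL, out_dir, seed = 1) {
  config <- config %||% default_pipeline_config()
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e))))
  }

  sw <- stage("sweep", {
    grid <- log_spaced(config$sweep$min, config$sweep$max, config$sweep$n)
    sweep_synthesis_rates(config$model, grid, mode = config$sweep$mode)
  })
  files$sweep <- write_table_csv(
    dplyr::select(sw, "k_syn", "foldase_conc", "holdase_conc",
                  "total_conc", "total_cost", "ratio", "U_free",
                  "marginal_residual", "mode", "variant", "feasible"),
    file.path(out_dir, "sweep.csv"))

  slopes <- stage("slopes", {
    tidyr::expand_grid(which = c("holdase", "foldase", "total"),
                       regime = c("slow", "fast")) |>
      dplyr::mutate(slope = purrr::map2_dbl(
                      .data$which, .data$regime,
                      ~ tryCatch(asymptotic_slope(sw, .x, .y),
                                 error = function(e) NA_real_)),
                    variant = config$model$variant)
  })
  files$slopes <- write_table_csv(slopes, file.path(out_dir, "slopes.csv"))

  abund <- stage("synthetic-abundance", {
    g <- config$generator
    gen_abundance_table(generator_config(
      n_samples = g$n_samples, true_slope = g$true_slope,
      intercept_log10 = g$intercept_log10,
      noise_sigma_log10 = g$noise_sigma_log10, rate_min = g$rate_min,
      rate_decades = g$rate_decades, seed = seed))
  })
  files$abundance <- write_table_csv(abund,
                                     file.path(out_dir, "abundance.csv"))
  files$scaling_fits <- write_table_csv(
    stage("fit-scaling", fit_scaling(abund)),
    file.path(out_dir, "scaling_fits.csv"))

  aging <- stage("synthetic-aging", {
    a <- config$aging
    gen_aging_trajectory(aging_config(
      n_timepoints = a$n_timepoints,
      synthesis_fold_drop = a$synthesis_fold_drop,
      k_syn_start = a$k_syn_start,
      noise_sigma_log10 = a$noise_sigma_log10, seed = seed), sw)
  })
  files$aging <- write_table_csv(aging, file.path(out_dir, "aging.csv"))

  manifest <- list(
    package = "proteocost",
    version = as.character(utils::packageVersion("proteocost")),
    seed = seed,
    variant = config$model$variant,
    config_path = attr(config, "path") %||% NA,
    config_md5 = attr(config, "md5") %||% NA,
    files = lapply(files, basename)
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  files$manifest <- manifest_path
  invisible(files)
}
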