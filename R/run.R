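# Config-driven entry points tying the modules into reproducible runs.
# Every run directory receives the resolved configuration, a log with
# per-stage timings, and the artifact files.

read_run_config <- function(config) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config))
      stop("config file not found: ", config)
    yaml::read_yaml(config)
  } else config
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$outdir <- cfg$outdir %||% "."
  cfg
}

start_run <- function(cfg, name) {
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(cfg$outdir, paste0(name, ".log"))
  cat(sprintf("[%s] %s started, seed %d\n",
              format(Sys.time()), name, cfg$seed), file = logfile)
  yaml::write_yaml(cfg, file.path(cfg$outdir, paste0(name, "_config.yaml")))
  logfile
}

log_stage <- function(logfile, msg, t0) {
  cat(sprintf("[%s] %s (%.1fs)\n", format(Sys.time()), msg,
              as.numeric(Sys.time()) - t0), file = logfile, append = TRUE)
}

load_inputs <- function(cfg, need_st = TRUE) {
  sc <- read_sc_data(cfg$sc_counts, cfg$sc_labels)
  st <- if (need_st) read_st_data(cfg$st_counts, cfg$st_coordinates) else NULL
  list(sc = sc, st = st)
}

pipeline_config <- function(cfg) {
  keys <- names(spotgcn_config())
  cfg[intersect(names(cfg), keys)]
}

#' Run the deconvolution pipeline from a configuration
#'
#' Reads the inputs named in the configuration (YAML file or list with keys
#' `sc_counts`, `sc_labels`, `st_counts`, optional `st_coordinates`,
#' `truth`, `outdir`, `seed` plus any [spotgcn_config()] override), runs
#' [deconvolve()], and writes the mapping matrix (`mapping_matrix.csv`), the
#' per-spot metrics against the truth when given (`metrics.csv`), the
#' resolved config and a log into `outdir`. Re-running the same
#' configuration reproduces the artifacts bitwise.
#'
#' @param config path to a YAML file or a named list.
#' @return the `spot_deconv` fit, invisibly.
#' @export
run_deconvolve <- function(config) {
  cfg <- read_run_config(config)
  logfile <- start_run(cfg, "deconvolve")
  t0 <- as.numeric(Sys.time())
  inp <- load_inputs(cfg)
  log_stage(logfile, "inputs loaded", t0)
  fit <- deconvolve(inp$sc, inp$st, config = pipeline_config(cfg))
  log_stage(logfile, "pipeline finished", t0)
  write_matrix_csv(fit, file.path(cfg$outdir, "mapping_matrix.csv"))
  if (!is.null(cfg$truth)) {
    truth <- read_dense_matrix(cfg$truth)
    mt <- evaluate_deconvolution(fit, truth)
    utils::write.csv(mt, file.path(cfg$outdir, "metrics.csv"),
                     row.names = FALSE)
  }
  log_stage(logfile, "artifacts written", t0)
  invisible(fit)
}

#' Run a spot simulation from a configuration
#'
#' Dispatches on `cfg$simulator`: `"regular"` ([simulate_regular()], keys
#' `n_spots`, `cells_range`, `types_range`, `max_col`) or `"spatial"`
#' ([simulate_spatial()], keys `hex_size`, `aggregation`, plus the reference
#' slide inputs). Writes the CSV trio `simulated_{counts,coordinates,
#' proportions}.csv`.
#'
#' @param config path to a YAML file or a named list.
#' @return the `simulated_st` object, invisibly.
#' @export
run_simulate <- function(config) {
  cfg <- read_run_config(config)
  logfile <- start_run(cfg, "simulate")
  t0 <- as.numeric(Sys.time())
  sim_kind <- cfg$simulator %||% "regular"
  inp <- load_inputs(cfg, need_st = identical(sim_kind, "spatial"))
  sim <- if (identical(sim_kind, "spatial")) {
    simulate_spatial(inp$sc, inp$st, hex_size = cfg$hex_size %||% 1,
                     seed = cfg$seed,
                     aggregation = cfg$aggregation %||% "average")
  } else {
    simulate_regular(inp$sc, n_spots = cfg$n_spots %||% 200L,
                     seed = cfg$seed)
  }
  log_stage(logfile, paste(sim_kind, "simulation finished"), t0)
  write_simulated_csv(sim, file.path(cfg$outdir, "simulated"))
  invisible(sim)
}

#' Add neighbour-diffusion noise to a simulated slide (config entry point)
#'
#' Keys: `st_counts`, `st_coordinates`, `fraction`, `alpha`, `seed`.
#' Writes `noisy_counts.csv`.
#'
#' @param config path to a YAML file or a named list.
#' @return the noisy dataset, invisibly.
#' @export
run_add_noise <- function(config) {
  cfg <- read_run_config(config)
  logfile <- start_run(cfg, "add_noise")
  t0 <- as.numeric(Sys.time())
  st <- read_st_data(cfg$st_counts, cfg$st_coordinates)
  out <- add_neighbor_noise(st, fraction = cfg$fraction %||% 0.25,
                            alpha = cfg$alpha %||% 0.1, seed = cfg$seed)
  log_stage(logfile, "noise added", t0)
  write_matrix_csv(out$counts, file.path(cfg$outdir, "noisy_counts.csv"))
  invisible(out)
}

#' Blur a high-resolution slide into square bins (config entry point)
#'
#' Keys: `st_counts`, `st_coordinates`, optional `cell_labels`, `bin_x`,
#' `bin_y`. Writes the blurred CSV trio.
#'
#' @param config path to a YAML file or a named list.
#' @return the `simulated_st`, invisibly.
#' @export
run_blur <- function(config) {
  cfg <- read_run_config(config)
  logfile <- start_run(cfg, "blur")
  t0 <- as.numeric(Sys.time())
  st <- read_st_data(cfg$st_counts, cfg$st_coordinates)
  labels <- NULL
  if (!is.null(cfg$cell_labels)) {
    lab <- utils::read.table(cfg$cell_labels, header = TRUE, sep = ",",
                             check.names = FALSE)
    labels <- as.character(lab[[ncol(lab)]])
  }
  sim <- blur_bins(st, bin_x = cfg$bin_x %||% 1,
                   bin_y = cfg$bin_y %||% cfg$bin_x %||% 1,
                   cell_types = labels)
  log_stage(logfile, "blurring finished", t0)
  write_simulated_csv(sim, file.path(cfg$outdir, "blurred"))
  invisible(sim)
}

#' Evaluate predicted proportions against a truth table (config entry point)
#'
#' Keys: `predicted` (CSV), `truth` (CSV). Writes `metrics.csv`.
#'
#' @param config path to a YAML file or a named list.
#' @return the `metric_table`, invisibly.
#' @export
run_evaluate <- function(config) {
  cfg <- read_run_config(config)
  logfile <- start_run(cfg, "evaluate")
  t0 <- as.numeric(Sys.time())
  pred <- read_dense_matrix(cfg$predicted)
  truth <- read_dense_matrix(cfg$truth)
  mt <- evaluate_deconvolution(pred, truth)
  log_stage(logfile, "evaluation finished", t0)
  utils::write.csv(mt, file.path(cfg$outdir, "metrics.csv"), row.names = FALSE)
  invisible(mt)
}

#' Cross-validated gene recovery (config entry point)
#'
#' Keys: the deconvolution inputs plus `folds`. Writes the aggregated
#' predictions and the per-gene metric table.
#'
#' @param config path to a YAML file or a named list.
#' @return the [crossval_gene_recovery()] result, invisibly.
#' @export
run_recover_genes <- function(config) {
  cfg <- read_run_config(config)
  logfile <- start_run(cfg, "recover_genes")
  t0 <- as.numeric(Sys.time())
  inp <- load_inputs(cfg)
  cv <- crossval_gene_recovery(inp$sc, inp$st, folds = cfg$folds %||% 10L,
                               seed = cfg$seed,
                               config = pipeline_config(cfg))
  log_stage(logfile, "cross-validation finished", t0)
  write_matrix_csv(cv$predicted,
                   file.path(cfg$outdir, "recovered_expression.csv"))
  utils::write.csv(cv$metrics, file.path(cfg$outdir, "gene_metrics.csv"),
                   row.names = FALSE)
  invisible(cv)
}

#' Generate synthetic inputs (config entry point)
#'
#' Accepts any [synthetic_config()] field; writes the single-cell counts and
#' labels, and the zoned reference slide trio.
#'
#' @param config path to a YAML file or a named list.
#' @return list with the generated `sc` and `st`, invisibly.
#' @export
run_make_synthetic <- function(config) {
  cfg <- read_run_config(config)
  logfile <- start_run(cfg, "make_synthetic")
  t0 <- as.numeric(Sys.time())
  sargs <- cfg[intersect(names(cfg), names(formals(synthetic_config)))]
  scfg <- do.call(synthetic_config, sargs)
  sc <- make_synthetic_scrna(scfg)
  ref <- make_synthetic_spatial_reference(scfg, sc)
  log_stage(logfile, "generation finished", t0)
  write_matrix_csv(sc$counts, file.path(cfg$outdir, "sc_counts.csv"))
  utils::write.csv(data.frame(cell_id = sc$cell_ids,
                              cell_type = sc$cell_types),
                   file.path(cfg$outdir, "sc_labels.csv"), row.names = FALSE)
  write_matrix_csv(ref$counts, file.path(cfg$outdir, "ref_counts.csv"))
  write_matrix_csv(ref$coordinates,
                   file.path(cfg$outdir, "ref_coordinates.csv"))
  invisible(list(sc = sc, st = ref))
}
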