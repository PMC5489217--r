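# Configuration-driven pipeline.
#
# Ties the stages together behind one function: network construction or
# SBML loading, PhPP + sensitivity map, synthetic culture generation,
# kinetic fitting, sensitivity trajectories, and the inhibition
# flux-change report.  Outputs are TSV/JSON under an output directory
# together with a JSON run manifest (config hash, package version,
# seed, per-stage status).

.default_config <- function() {
  list(stages = c("phpp", "sens_map", "fit", "trajectory", "fcs_report"),
       network = list(source = "toy"),
       grid = list(carbon_max = 20, o2_max = 25, n = 21),
       culture = list(kLa = 25, Cstar = 0.0075, S0 = 15, x0 = 0.5,
                      t_end = 48, n_samples = 25,
                      noise_sd = c(x = 0.07, S = 0.3, P = 0.08)),
       inhibition = list(reaction_id = "CINADH", fraction = 0.8,
                         start_time = 12),
       fit = list(n_starts = 6),
       output_dir = "arcfba_run",
       seed = 1L)
}

#' Run the analysis pipeline
#'
#' @param config a nested list, or the path to a YAML/JSON file holding
#'   one; missing entries fall back to the defaults (a toy network,
#'   21x21 grid over 0-20 x 0-25 mmol/gDW/h, a kLa = 25 1/h synthetic
#'   culture with CINADH inhibition from 12 h).  Set
#'   `stages` to any subset of `"phpp"`, `"sens_map"`, `"fit"`,
#'   `"trajectory"`, `"fcs_report"`.
#' @param demo if `TRUE`, run the full default pipeline (all stages,
#'   default toy network and synthetic culture).
#' @return invisibly, the manifest list (also written as
#'   `manifest.json`); stage outputs land in `config$output_dir`.
#' @export
run_pipeline <- function(config = list(), demo = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  cfg <- utils::modifyList(.default_config(), config)
  if (demo) cfg$stages <- .default_config()$stages
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("arcfba")),
                   seed = cfg$seed, config = cfg, stages = list(),
                   outputs = character())
  t_start <- Sys.time()
  log_stage <- function(name, status, secs) {
    message(sprintf("[%s] %s (%.1f s)", name, status, secs))
    manifest$stages[[name]] <<- list(status = status,
                                     wall_seconds = round(secs, 2))
  }
  emit <- function(file) manifest$outputs <<- c(manifest$outputs, file)

  network <- if (identical(cfg$network$source, "toy")) {
    opts <- cfg$network$options
    if (is.null(opts)) make_core_network()
    else make_core_network(do.call(toy_network_options, opts))
  } else {
    load_sbml(cfg$network$source, objective_id = cfg$network$objective_id)
  }

  grid <- NULL
  if (any(c("phpp", "sens_map") %in% cfg$stages)) {
    t0 <- Sys.time()
    axes_c <- seq(0, cfg$grid$carbon_max, length.out = cfg$grid$n)
    axes_o <- seq(0, cfg$grid$o2_max, length.out = cfg$grid$n)
    grid <- compute_phpp(network, carbon_axis = axes_c, o2_axis = axes_o)
    write_phpp(grid, cfg$output_dir)
    emit("phpp_*.tsv")
    log_stage("phpp", "ok", as.numeric(Sys.time() - t0, units = "secs"))
    if ("sens_map" %in% cfg$stages) {
      f <- file.path(cfg$output_dir, "sens_map.tsv")
      df <- data.frame(carbon = rep(grid$carbon_axis, times = ncol(grid$arc_surface)),
                       o2 = rep(grid$o2_axis, each = nrow(grid$arc_surface)),
                       lambda_arc_etoh = as.vector(grid$arc_surface),
                       lambda_arc_etoh_mito = as.vector(grid$arc_surface_m))
      utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
      emit(basename(f))
      log_stage("sens_map", "ok", 0)
    }
  }

  fitres <- NULL; dataset <- NULL
  if (any(c("fit", "trajectory", "fcs_report") %in% cfg$stages)) {
    cc <- cfg$culture
    params <- culture_params(kLa = cc$kLa, Cstar = cc$Cstar)
    dataset <- make_culture_dataset(
      params, initial_state = c(x = cc$x0, S = cc$S0, P = 0),
      sample_times = seq(0, cc$t_end, length.out = cc$n_samples),
      noise_sd = cc$noise_sd, seed = cfg$seed)
    write_culture_tsv(dataset, file.path(cfg$output_dir, "culture_data.tsv"))
    emit("culture_data.tsv")
  }
  if ("fit" %in% cfg$stages) {
    t0 <- Sys.time()
    fitres <- fit_parameters(dataset,
                             fixed = list(kLa = cfg$culture$kLa,
                                          Cstar = cfg$culture$Cstar),
                             n_starts = cfg$fit$n_starts, seed = cfg$seed)
    writeLines(jsonlite::toJSON(
      list(params = unclass(fitres$params), k = fitres$k,
           residual_report = fitres$residual_report),
      auto_unbox = TRUE, digits = NA, pretty = TRUE),
      file.path(cfg$output_dir, "fit_params.json"))
    emit("fit_params.json")
    log_stage("fit", "ok", as.numeric(Sys.time() - t0, units = "secs"))
  }

  if (any(c("trajectory", "fcs_report") %in% cfg$stages)) {
    t0 <- Sys.time()
    params_use <- if (!is.null(fitres)) fitres$params
                  else culture_params(kLa = cfg$culture$kLa,
                                      Cstar = cfg$culture$Cstar)
    tr <- simulate_culture(params_use,
                           c(x = cfg$culture$x0, S = cfg$culture$S0, P = 0),
                           seq(1, cfg$culture$t_end, by = 1))
    rates <- culture_rate_points(tr)
    inh <- do.call(inhibition_spec, cfg$inhibition)
    if ("trajectory" %in% cfg$stages) {
      st0 <- sensitivity_trajectory(network, rates)
      st1 <- sensitivity_trajectory(network, rates, inh)
      st0$arm <- "control"; st1$arm <- "inhibited"
      out <- rbind(st0, st1)
      f <- file.path(cfg$output_dir, "sensitivity_trajectory.tsv")
      utils::write.table(out, f, sep = "\t", quote = FALSE, row.names = FALSE)
      emit(basename(f))
      log_stage("trajectory", "ok",
                as.numeric(Sys.time() - t0, units = "secs"))
    }
    if ("fcs_report" %in% cfg$stages) {
      t0 <- Sys.time()
      rep <- inhibition_flux_report(network, rates, inh)
      f <- file.path(cfg$output_dir, "fcs_report.tsv")
      utils::write.table(rep$table, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      emit(basename(f))
      log_stage("fcs_report", "ok",
                as.numeric(Sys.time() - t0, units = "secs"))
    }
  }

  manifest$wall_seconds <- round(
    as.numeric(Sys.time() - t_start, units = "secs"), 2)
  cfg_for_hash <- cfg
  hash_file <- tempfile()
  writeLines(jsonlite::toJSON(cfg_for_hash, auto_unbox = TRUE), hash_file)
  manifest$config_md5 <- unname(tools::md5sum(hash_file))
  unlink(hash_file)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(cfg$output_dir, "manifest.json"))
  invisible(manifest)
}
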