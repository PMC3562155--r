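# End-to-end pipeline: synthesize or read measurements, fit the relay,
# predict held-out conditions, run FBA/FVA on the toy network, fit the
# power-law node kinetics, and decompose the branch fluxes.

#' Pipeline configuration
#'
#' A validated list of paths, stage switches, seeds and tolerances.  A
#' configuration can also be read from a YAML file with the same field
#' names ([read_pipeline_config()]).  All defaults mirror the fitted
#' constants and the shipped calibration.
#'
#' @param out_dir output directory (created if missing).
#' @param measurements optional path to a measurement TSV; when `NULL` the
#'   synthetic generator supplies the data.
#' @param flux_table optional path to a node flux TSV; defaults to the
#'   published values.
#' @param network optional path to a network TSV; defaults to the toy
#'   network.
#' @param stages character vector of stages to run, a subset of
#'   `c("synth", "fit", "predict", "fba", "fva", "powerlaw", "fluxes")`.
#' @param seed integer seed for all stochastic stages.
#' @param rel_error relative noise of synthetic measurements.
#' @param r_fru scaled fructose uptake rate of the fructose condition.
#' @param growth_rate,uptake_measured FBA stage constraints (growth fixed,
#'   measured substrate uptake for NGAM calibration).
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir = tempfile("ptsflux_run_"),
                            measurements = NULL, flux_table = NULL,
                            network = NULL,
                            stages = c("synth", "fit", "predict", "fba",
                                       "fva", "powerlaw", "fluxes"),
                            seed = 1, rel_error = 0.05,
                            r_fru = PTS_DEFAULT_RFRU,
                            growth_rate = 0.2, uptake_measured = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  for (p in c(measurements, flux_table, network)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("configured path does not exist: ", p, call. = FALSE)
    }
  }
  if (seed != round(seed)) stop("seed must be an integer", call. = FALSE)
  if (rel_error < 0) stop("rel_error must be >= 0", call. = FALSE)
  structure(list(out_dir = out_dir, measurements = measurements,
                 flux_table = flux_table, network = network,
                 stages = stages, seed = as.integer(seed),
                 rel_error = rel_error, r_fru = r_fru,
                 growth_rate = growth_rate,
                 uptake_measured = uptake_measured),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with configuration fields.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0) {
    stop("unknown configuration field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(pipeline_config, raw)
}

#' Run the analysis pipeline
#'
#' Executes the selected stages in order (generate/read data, fit, predict,
#' FBA, FVA, power law, branch fluxes), writing each stage's tables to the
#' configured output directory together with a run log recording the seed
#' and package version.  Deterministic given the seed; a stage failure
#' halts with an error naming the stage, keeping earlier outputs.
#'
#' @param config a [pipeline_config()].
#' @return A result bundle (named list per stage), invisibly also written
#'   to `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  logline <- function(...) {
    msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }
  logline("ptsflux ", as.character(utils::packageVersion("ptsflux")),
          " seed=", config$seed)
  bundle <- list()
  stage <- function(name, expr) {
    if (!(name %in% config$stages)) return(invisible(NULL))
    logline("stage ", name, " started")
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    logline("stage ", name, " done")
    res
  }

  design <- default_design(r_fru = config$r_fru)
  bundle$measurements <- if (!is.null(config$measurements)) {
    read_measurements(config$measurements)
  } else {
    stage("synth", {
      dat <- generate_phospho_dataset(synthetic_design(
        design = design, rel_error = config$rel_error, seed = config$seed,
        allow_any_noise = config$rel_error == 0))
      write_measurements(dat,
                         file.path(config$out_dir, "measurements.tsv"))
      dat
    })
  }

  bundle$fit <- stage("fit", {
    fit <- fit_equilibrium_constants(bundle$measurements, design = design)
    write_parameters_json(fit, file.path(config$out_dir, "fit.json"))
    utils::write.table(fit$diagnostics$residual_table,
                       file.path(config$out_dir, "fit_residuals.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    fit
  })

  bundle$predictions <- stage("predict", {
    est <- if (!is.null(bundle$fit)) bundle$fit else
      list(Keq = PTS_DEFAULT_KEQ, K5 = PTS_DEFAULT_K5,
           k4 = PTS_CALIBRATED_K4)
    grid <- expand.grid(strain = c("WT", "delta_ptsP", "delta_ptsO",
                                   "delta_fruB"),
                        condition = PTS_CONDITIONS,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid$predicted <- vapply(seq_len(nrow(grid)), function(i) {
      cond <- growth_condition(grid$condition[i])
      predict_ptsN(est, grid$strain[i], cond)
    }, numeric(1))
    utils::write.table(grid, file.path(config$out_dir, "predictions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    grid
  })

  net <- if (!is.null(config$network)) read_network_tsv(config$network)
         else make_toy_network()
  bundle$fba <- stage("fba", {
    if (!is.null(config$uptake_measured)) {
      ngam <- calibrate_ngam(net, config$growth_rate,
                             config$uptake_measured)
      net <- set_ngam(net, as.numeric(ngam))
    }
    minimize_substrate_uptake(net, config$growth_rate)
  })

  bundle$fva <- stage("fva", {
    sol <- if (!is.null(bundle$fba) && bundle$fba$status == "optimal")
      bundle$fba else minimize_substrate_uptake(net, config$growth_rate)
    res <- fva(net, sol)
    utils::write.table(res, file.path(config$out_dir, "fva_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res
  })

  flux_tab <- if (!is.null(config$flux_table))
    read_flux_table(config$flux_table) else node_flux_table()
  bundle$powerlaw <- stage("powerlaw", {
    k <- slope_k_from_conditions(flux_tab)
    rc <- function(cond) flux_tab$nominal[flux_tab$condition == cond &
                                            flux_tab$reaction == "pyr_to_pep"]
    pp_fit <- if (!is.null(bundle$fit)) bundle$fit$pp else
      c(CAA = 1.0, CAA_fructose = 0.49)
    fit <- fit_powerlaw_two_points(
      c(rc("CAA"), unname(pp_fit["CAA"])),
      c(rc("CAA_fructose"), unname(pp_fit["CAA_fructose"])))
    k_band <- slope_k_extremes(flux_tab)
    curve <- characteristic_curve(fit, k, k_band,
                                  ra_grid = seq(1, 10, by = 0.25))
    utils::write.table(curve,
                       file.path(config$out_dir, "characteristic_curve.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(kc = fit$kc, nc = fit$nc, kd = fit$kd,
                              nd = fit$nd, alpha = fit$alpha,
                              n_prime = fit$n_prime, slope_k = k,
                              slope_k_range = k_band),
                         file.path(config$out_dir, "powerlaw.json"),
                         auto_unbox = TRUE, digits = NA)
    list(fit = fit, slope_k = k, slope_k_range = k_band, curve = curve)
  })

  bundle$branch_fluxes <- stage("fluxes", {
    est <- if (!is.null(bundle$fit)) bundle$fit else
      list(Keq = PTS_DEFAULT_KEQ, K5 = PTS_DEFAULT_K5,
           k4 = PTS_CALIBRATED_K4,
           pp = c(CAA_fructose = 0.49))
    params <- pts_parameters_from_constants(Keq = est$Keq, K5 = est$K5,
                                            k4 = est$k4)
    res <- steady_branch_fluxes(params,
                                pp = unname(est$pp["CAA_fructose"]),
                                r_fru = config$r_fru)
    tab <- data.frame(reaction = names(res$rates),
                      net_rate = as.numeric(res$rates))
    tab$share <- NA_real_
    tab$share[tab$reaction == "r3"] <- res$ntr_share
    tab$share[tab$reaction == "r4"] <- res$c_share
    utils::write.table(tab,
                       file.path(config$out_dir, "branch_fluxes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res
  })

  logline("pipeline finished")
  invisible(bundle)
}
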