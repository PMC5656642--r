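# End-to-end pipeline: read (or simulate) inputs, fit the transport model,
# analyze the recapture experiment, downscale prevalence, compute flux
# aggregates, and write summary tables plus a reproducibility manifest.

#' Default pipeline configuration
#'
#' @param ... Overrides for any configuration field. Key fields:
#'   \code{seed}, \code{L} (flux samples per municipality-day, default
#'   400), \code{n_prev_draws} (municipal prevalence sample size),
#'   \code{season} (day-of-year window, default March through December),
#'   \code{mask} (apply the confirmed-presence mask), \code{adjusted}
#'   (rescale by recapture efficiency), \code{chains}/\code{iter}/
#'   \code{warmup} (sampler), \code{prior_location}/\code{prior_scale},
#'   \code{inputs} (named list of CSV paths; when \code{NULL} a synthetic
#'   world is generated), \code{synthetic} (overrides passed to
#'   \code{\link{synthetic_config}}).
#' @return A named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    L = 400L,
    n_prev_draws = 500L,
    season = c(60L, 365L),       # March through December
    mask = TRUE,
    adjusted = FALSE,
    chains = 4L, iter = 2000L, warmup = 1000L,
    prior_location = 0, prior_scale = 2.5,
    daily_trips = NULL,
    rounding_decimals = 4L,
    inputs = NULL,
    synthetic = list(),
    out_dir = NULL
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg
}

read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, cfg)
}

load_inputs <- function(cfg) {
  if (is.null(cfg$inputs)) {
    sc <- do.call(synthetic_config,
                  c(list(seed = cfg$seed), cfg$synthetic))
    world <- gen_world(sc, n_prev_draws = cfg$n_prev_draws)
    return(world)
  }
  paths <- cfg$inputs
  for (p in unlist(paths)) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  geo <- geography_from_tables(
    read_table(paths$municipalities, "municipalities"),
    read_table(paths$overlaps, "overlaps")
  )
  cells <- cells_from_long(read_table(paths$cell_posteriors,
                                      "cell_posteriors"))
  prev <- resample_to_municipalities(cells, geo,
                                     n_draws = cfg$n_prev_draws,
                                     seed = derive_seed(cfg$seed, 127L))
  list(
    geography = geo,
    cells = cells,
    prevalence = prev,
    car_stops = read_table(paths$car_stops, "car_stops"),
    recapture = read_table(paths$recapture, "recapture"),
    od = od_from_long(read_table(paths$od, "od"),
                      provinces = geo$provinces)
  )
}

#' Run the full inference pipeline
#'
#' Chains every stage: input loading (or synthetic generation), Bayesian
#' transport-model fit (with the alert-probability covariate when the car
#' stops carry one), recapture-efficiency estimation, optional efficiency
#' adjustment, prevalence masking, commuter-flow downscaling, flux
#' computation over the season window with L aligned samples, and
#' aggregation to province pairs/months and province-year out/in/net
#' flows. Writes all summary tables and a manifest when \code{out_dir}
#' is set; outputs are byte-identical for identical config and seed.
#'
#' @param config A \code{\link{pipeline_config}} list, or a path to a JSON
#'   file of overrides.
#' @return Invisibly, a list with the fitted objects and summary tables.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- do.call(pipeline_config, config[!vapply(config, is.null, TRUE)])
  t_start <- Sys.time()
  stage <- function(name) {
    message(sprintf("[tigerflux %s] stage: %s",
                    format(round(difftime(Sys.time(), t_start, units = "secs"),
                                 1)), name))
  }

  stage("load inputs")
  world <- load_inputs(cfg)
  geo <- world$geography

  stage("fit transport model")
  stops <- world$car_stops
  prior <- logistic_prior(cfg$prior_location, cfg$prior_scale)
  has_cov <- "alert_prob" %in% names(stops) &&
    !all(is.na(stops$alert_prob)) &&
    stats::sd(stops$alert_prob, na.rm = TRUE) > 0
  X <- if (has_cov) cbind(alert_prob = stops$alert_prob) else NULL
  fit <- fit_bayes_logistic(X, stops$detected, prior = prior,
                            chains = cfg$chains, iter = cfg$iter,
                            warmup = cfg$warmup,
                            seed = derive_seed(cfg$seed, 201L))

  stage("fit efficiency")
  eff <- recapture_summary(world$recapture)

  stage("prevalence mask")
  prev <- world$prevalence
  if (isTRUE(cfg$mask)) prev <- apply_confirmation_mask(prev, geo)

  stage("downscale commuter flows")
  mun_od <- downscale_od(world$od, geo)

  stage("flux")
  days <- seq.int(cfg$season[1], cfg$season[2])
  field <- suppressWarnings(transport_field(
    prev, fit, days, L = cfg$L,
    seed = derive_seed(cfg$seed, 211L),
    efficiency = if (isTRUE(cfg$adjusted)) eff$r else NULL
  ))
  mflux <- municipal_flux(mun_od, field)
  pair_day <- aggregate_flows(mflux, level = "province_pair")
  pair_month <- aggregate_flows(pair_day, time = "month")
  out_year <- aggregate_flows(pair_day, level = "out", time = "year")
  in_year <- aggregate_flows(pair_day, level = "in", time = "year")
  net_year <- aggregate_flows(pair_day, level = "net", time = "year")

  stage("report")
  theta <- posterior_predictive(fit,
                                x = if (has_cov) {
                                  stats::median(stops$alert_prob, na.rm = TRUE)
                                } else NULL)
  theta_adj <- adjust_for_efficiency(theta, eff$r)
  theta_tab <- data.frame(
    model = c("fitted", "efficiency_adjusted"),
    median = c(summarize_draws(theta)$median, summarize_draws(theta_adj)$median),
    q05 = c(summarize_draws(theta)$q05, summarize_draws(theta_adj)$q05),
    q95 = c(summarize_draws(theta)$q95, summarize_draws(theta_adj)$q95)
  )
  results <- list(
    config = cfg,
    geography = geo,
    fit = fit,
    efficiency = eff,
    theta_summary = theta_tab,
    flow_pair_month = summarize_flows(pair_month),
    flow_out_year = summarize_flows(out_year),
    flow_in_year = summarize_flows(in_year),
    flow_net_year = summarize_flows(net_year)
  )
  if (!is.null(cfg$daily_trips)) {
    results$trips <- trips_with_mosquitoes(
      cfg$daily_trips,
      summarize_draws(if (isTRUE(cfg$adjusted)) theta_adj else theta),
      decimals = cfg$rounding_decimals
    )
  }

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    wp <- function(df, name) write_table(df, file.path(cfg$out_dir, name))
    wp(theta_tab, "theta_summary.csv")
    wp(eff$per_condition, "efficiency.csv")
    wp(results$flow_pair_month, "flow_province_pair_month.csv")
    wp(results$flow_out_year, "flow_out_year.csv")
    wp(results$flow_in_year, "flow_in_year.csv")
    wp(results$flow_net_year, "flow_net_year.csv")
    cfg_serial <- cfg[c("seed", "L", "n_prev_draws", "season", "mask",
                        "adjusted", "chains", "iter", "warmup",
                        "prior_location", "prior_scale")]
    manifest <- list(
      seed = cfg$seed,
      L = cfg$L,
      config_hash = fnv1a_hash(jsonlite::toJSON(cfg_serial,
                                                auto_unbox = TRUE)),
      tables = c("theta_summary.csv", "efficiency.csv",
                 "flow_province_pair_month.csv", "flow_out_year.csv",
                 "flow_in_year.csv", "flow_net_year.csv")
    )
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(results)
}

#' Command-line entry point
#'
#' Exposes the pipeline stages as a CLI:
#' \code{--stage} one of \code{simulate}, \code{fit-transport},
#' \code{fit-efficiency}, \code{adjust}, \code{downscale-prevalence},
#' \code{flux}, \code{report}, or \code{all} (default). \code{simulate}
#' writes the synthetic input tables; other stages run the pipeline
#' through the requested point and write that stage's outputs. Returns
#' (invisibly) exit code 0 on success and 2 on a validation error.
#'
#' @param args Character vector of command-line arguments (default: the
#'   calling process's).
#' @return Integer exit status, invisibly.
#' @export
flux_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  spec <- list(
    optparse::make_option("--config", type = "character", default = NULL,
                          help = "JSON config file"),
    optparse::make_option("--seed", type = "integer", default = NULL,
                          help = "master seed"),
    optparse::make_option("--out", type = "character", default = "tigerflux-out",
                          help = "output directory"),
    optparse::make_option("--stage", type = "character", default = "all",
                          help = "pipeline stage to run"),
    optparse::make_option("--no-mask", action = "store_true", default = FALSE,
                          dest = "no_mask",
                          help = "skip the confirmed-presence mask"),
    optparse::make_option("--adjusted", action = "store_true", default = FALSE,
                          help = "apply the recapture-efficiency adjustment"),
    optparse::make_option("--draws", type = "integer", default = NULL,
                          dest = "draws", help = "flux samples L")
  )
  opt <- tryCatch(
    optparse::parse_args(optparse::OptionParser(option_list = spec),
                         args = args),
    error = function(e) e
  )
  if (inherits(opt, "error")) {
    message("argument error: ", conditionMessage(opt))
    return(invisible(2L))
  }
  status <- tryCatch({
    cfg <- if (!is.null(opt$config)) {
      read_pipeline_config(opt$config)
    } else {
      pipeline_config()
    }
    if (!is.null(opt$seed)) cfg$seed <- opt$seed
    if (!is.null(opt$draws)) cfg$L <- opt$draws
    if (isTRUE(opt$no_mask)) cfg$mask <- FALSE
    if (isTRUE(opt$adjusted)) cfg$adjusted <- TRUE
    cfg$out_dir <- opt$out
    run_stage(cfg, opt$stage)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  invisible(status)
}

run_stage <- function(cfg, stage_name) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (stage_name == "simulate") {
    sc <- do.call(synthetic_config, c(list(seed = cfg$seed), cfg$synthetic))
    world <- gen_world(sc, n_prev_draws = cfg$n_prev_draws)
    write_table(world$car_stops, file.path(cfg$out_dir, "car_stops.csv"))
    write_table(world$recapture, file.path(cfg$out_dir, "recapture.csv"))
    write_table(world$geography$municipalities,
                file.path(cfg$out_dir, "municipalities.csv"))
    write_table(world$geography$overlaps,
                file.path(cfg$out_dir, "overlaps.csv"))
    write_table(cells_to_long(world$cells),
                file.path(cfg$out_dir, "cell_posteriors.csv"))
    write_table(od_to_long(world$od), file.path(cfg$out_dir, "od.csv"))
    return(invisible(NULL))
  }
  if (stage_name %in% c("fit-transport", "fit-efficiency", "adjust")) {
    world <- load_inputs(cfg)
    if (stage_name == "fit-efficiency") {
      eff <- recapture_summary(world$recapture)
      write_table(eff$per_condition, file.path(cfg$out_dir, "efficiency.csv"))
      return(invisible(NULL))
    }
    prior <- logistic_prior(cfg$prior_location, cfg$prior_scale)
    stops <- world$car_stops
    has_cov <- "alert_prob" %in% names(stops) &&
      stats::sd(stops$alert_prob, na.rm = TRUE) > 0
    fit <- fit_bayes_logistic(
      if (has_cov) cbind(alert_prob = stops$alert_prob) else NULL,
      stops$detected, prior = prior, chains = cfg$chains,
      iter = cfg$iter, warmup = cfg$warmup,
      seed = derive_seed(cfg$seed, 201L)
    )
    theta <- posterior_predictive(
      fit, x = if (has_cov) stats::median(stops$alert_prob) else NULL)
    if (stage_name == "adjust") {
      eff <- recapture_summary(world$recapture)
      theta <- adjust_for_efficiency(theta, eff$r)
    }
    s <- summarize_draws(theta)
    write_table(data.frame(median = s$median, q05 = s$q05, q95 = s$q95,
                           adjusted = isTRUE(attr(theta, "adjusted"))),
                file.path(cfg$out_dir, "theta_summary.csv"))
    return(invisible(NULL))
  }
  if (stage_name == "downscale-prevalence") {
    world <- load_inputs(cfg)
    prev <- world$prevalence
    if (isTRUE(cfg$mask)) prev <- apply_confirmation_mask(prev, world$geography)
    means <- apply(prev, c(1, 2), mean)
    df <- data.frame(
      municipality_id = rep(rownames(means), ncol(means)),
      period = rep(seq_len(ncol(means)), each = nrow(means)),
      mean_alert_prob = as.vector(means)
    )
    write_table(df, file.path(cfg$out_dir, "municipal_prevalence_mean.csv"))
    return(invisible(NULL))
  }
  if (stage_name %in% c("flux", "report", "all")) {
    run_pipeline(cfg)
    return(invisible(NULL))
  }
  stop("unknown stage: ", stage_name, call. = FALSE)
}
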