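#' Pipeline configuration
#'
#' Collects all stage parameters of the end-to-end analysis: city/event
#' generation, grid size, survival preset, exceedance threshold, MCLP
#' parameters, and output directory. Any field can be supplied via a
#' flat key=value file (see [read_config_file()]).
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param n_calls number of calls to simulate.
#' @param cell_size_m demand-grid cell side (metres).
#' @param survival_preset \code{"test"} or \code{"paper"} chain scale.
#' @param threshold_s exceedance/censoring threshold (seconds).
#' @param p number of AEDs to place.
#' @param cutoff_s bystander walking cut-off (seconds).
#' @param curve_by increment of the coverage curve.
#' @param city a \code{city_config} (defaults to [city_config()] with
#'   \code{seed}).
#' @param out_dir output directory.
#' @param overwrite allow overwriting existing outputs (default FALSE).
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(seed = 1L, n_calls = 476L, cell_size_m = 500,
                            survival_preset = c("test", "paper"),
                            threshold_s = 300, p = 100L, cutoff_s = 150,
                            curve_by = 20L, city = NULL,
                            out_dir = "ohca-run", overwrite = FALSE) {
  survival_preset <- match.arg(survival_preset)
  if (is.null(city)) city <- city_config(seed = seed)
  structure(list(seed = as.integer(seed), n_calls = as.integer(n_calls),
                 cell_size_m = cell_size_m,
                 survival_preset = survival_preset,
                 threshold_s = threshold_s, p = as.integer(p),
                 cutoff_s = cutoff_s, curve_by = as.integer(curve_by),
                 city = city, out_dir = out_dir, overwrite = overwrite),
            class = "pipeline_config")
}

#' Run the five-step analysis end-to-end
#'
#' Executes simulate -> filter/describe -> isochrones -> spatial
#' survival (PEP + diurnal relative risk) -> MCLP (+ coverage curve) ->
#' paired comparison, writing each stage's artifact to disk and a final
#' run manifest (parameters, seeds, package version, MD5 hash of every
#' output). Fully reproducible under a fixed seed; any stage failure
#' aborts with the stage name while earlier artifacts persist.
#'
#' @param config a \code{pipeline_config}.
#' @param events optional pre-existing event table (skips simulation).
#' @return the manifest list, invisibly; artifacts under
#'   \code{config$out_dir}.
#' @export
run_pipeline <- function(config = pipeline_config(), events = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  art <- function(f) file.path(config$out_dir, f)
  guard <- function(f) {
    if (file.exists(f) && !config$overwrite)
      stop("output exists and overwrite = FALSE: ", f)
    f
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  t0 <- Sys.time()

  # 1. simulate city + events
  city <- stage("simulate", generate_city(config$city))
  if (is.null(events))
    events <- stage("simulate",
                    simulate_events(city, config$n_calls,
                                    seed = config$seed))
  stage("simulate", {
    write_city_geojson(city, guard(art("city.geojson")))
    write_events_csv(events, guard(art("events.csv")))
  })

  # 2. filter + describe
  cohort <- stage("describe", filter_ohca(events))
  summ <- stage("describe", cohort_summary(cohort))
  stage("describe", write_summary_json(summ, guard(art("summary.json"))))

  # 3. isochrones
  grid <- stage("isochrone", make_grid(city$bbox, config$cell_size_m))
  field <- stage("isochrone", travel_time_field(city, grid))
  stage("isochrone", {
    cells <- field$cells[, c("ix", "iy", "cell_id", "minutes", "band")]
    write_grid_geojson(cells, config$cell_size_m, city$bbox,
                       guard(art("isochrones.geojson")))
  })

  # 4. spatial survival: PEP surface + diurnal relative risk
  demand <- stage("survival",
                  aggregate_demand(cohort, config$cell_size_m,
                                   bbox = city$bbox, all_cells = TRUE))
  fit <- stage("survival", {
    sdat <- build_survival_data(cohort, threshold_s = config$threshold_s)
    spatial_delay_model(sdat, demand,
                        mcmc = mcmc_control(preset = config$survival_preset,
                                            seed = config$seed))
  })
  pep <- stage("survival", compute_pep(fit))
  rr <- stage("survival", relative_risk_curve(fit))
  stage("survival", {
    write_grid_geojson(pep[, c("ix", "iy", "cell_id", "event_count", "pep")],
                       config$cell_size_m, city$bbox,
                       guard(art("pep.geojson")))
    utils::write.csv(rr, guard(art("rr_curve.csv")), row.names = FALSE)
    jsonlite::write_json(
      list(beta_mean = as.list(coef(fit)),
           eta_median = stats::median(fit$samples$eta),
           acceptance = as.list(fit$acceptance)),
      guard(art("posterior.json")), auto_unbox = TRUE, digits = NA)
  })

  # 5. MCLP + coverage curve
  if (is.null(city$candidates) || nrow(city$candidates) == 0)
    stop("pipeline stage 'mclp' failed: no candidate layer", call. = FALSE)
  mclp_out <- stage("mclp", {
    dem <- aggregate_demand(cohort, config$cell_size_m, bbox = city$bbox)
    cov <- build_coverage(dem, city$candidates, config$cutoff_s,
                          city$pedestrian_speed)
    sol <- solve_greedy(cov, config$p)
    crv <- coverage_curve(cov, by = config$curve_by)
    list(cov = cov, sol = sol, crv = crv)
  })
  stage("mclp", {
    sel <- mclp_out$cov$candidates
    sel$selected <- sel$site_id %in% mclp_out$sol$selected
    write_points_geojson(sel, guard(art("aed_sites.geojson")))
    jsonlite::write_json(
      list(p = mclp_out$sol$p,
           covered_cells = mclp_out$sol$n_covered_cells,
           active_cells = mclp_out$sol$n_active_cells,
           coverage_fraction_cells = mclp_out$sol$coverage_fraction_cells,
           coverage_fraction_demand = mclp_out$sol$coverage_fraction_demand,
           curve = mclp_out$crv$table,
           saturation_p = mclp_out$crv$saturation_p),
      guard(art("mclp.json")), auto_unbox = TRUE, digits = NA)
  })

  # 6. compare AED vs ambulance times
  cmp <- stage("compare", {
    aed <- aed_travel_times(mclp_out$sol, cohort, city$candidates,
                            speed = city$pedestrian_speed)
    test <- wilcoxon_signed_rank(aed, cohort$response_time_s)
    list(aed = aed, test = test)
  })
  stage("compare", {
    jsonlite::write_json(
      list(n_pairs = cmp$test$n_pairs, W = cmp$test$W, z = cmp$test$z,
           p_value = cmp$test$p_value, method = cmp$test$method,
           summary = summarize_pair(cmp$aed, cohort$response_time_s)),
      guard(art("compare.json")), auto_unbox = TRUE, digits = NA)
    utils::write.csv(pair_quantiles(cmp$aed, cohort$response_time_s),
                     guard(art("violin_quantiles.csv")), row.names = FALSE)
  })

  # manifest
  outputs <- c("city.geojson", "events.csv", "summary.json",
               "isochrones.geojson", "pep.geojson", "rr_curve.csv",
               "posterior.json", "aed_sites.geojson", "mclp.json",
               "compare.json", "violin_quantiles.csv")
  hashes <- as.list(tools::md5sum(vapply(outputs, art, character(1))))
  names(hashes) <- outputs
  manifest <- list(
    package_version = as.character(utils::packageVersion("ohcacover")),
    seed = config$seed,
    parameters = list(n_calls = config$n_calls,
                      cell_size_m = config$cell_size_m,
                      survival_preset = config$survival_preset,
                      threshold_s = config$threshold_s, p = config$p,
                      cutoff_s = config$cutoff_s,
                      curve_by = config$curve_by),
    n_events = nrow(events), n_cohort = nrow(cohort),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    output_md5 = hashes
  )
  jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(manifest)
}
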