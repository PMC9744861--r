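# End-to-end orchestration: simulate -> prepare records -> fit
# occupancy models -> derive trends -> compute drivers and traits ->
# trend regression -> scenario decomposition.  All stage outputs are
# plain CSV/JSON under the output directory; the manifest records the
# seed and a configuration hash.

#' Recompute driver-change variables from emitted data
#'
#' Mirrors what an analyst does with the raw series: annual bioclim
#' variables per zone from monthly climate, 10-year-window regression
#' changes per interval; gap-filled land-use series, intensity
#' variables, endpoint-difference changes; then standardization over
#' zone x interval replicates.
#'
#' @param climate data.frame zone, year, month, temp, precip.
#' @param landuse data.frame zone, year, variable, value (NA = gap),
#'   with variables `agri_area`, `grassland_area`, `lsu`, `crop_*`.
#' @param study_area named vector: area per zone (same unit as
#'   `agri_area`).
#' @param crop_rates named insecticide application rates per crop.
#' @param intervals data.frame from [interval_windows()].
#' @return standardized DriverTable with `"scaling"` attribute.
#' @export
compute_driver_table <- function(climate, landuse, study_area, crop_rates,
                                 intervals) {
  rows <- list()
  for (z in unique(climate$zone)) {
    cz <- climate[climate$zone == z, ]
    ann <- do.call(rbind, lapply(split(cz, cz$year), function(d) {
      d <- d[order(d$month), ]
      as.data.frame(t(compute_bioclim(d$temp, d$precip)))
    }))
    ann$year <- as.integer(rownames(ann))
    luz <- landuse[landuse$zone == z & !is.na(landuse$value), ]
    out_years <- seq(min(intervals$from), max(intervals$to))
    filled <- lapply(split(luz, luz$variable), function(d) {
      gapfill_landuse(d$year, d$value, out_years)$value
    })
    crops <- do.call(cbind, filled[grep("^crop_", names(filled))])
    if (!is.null(crops)) colnames(crops) <- sub("^crop_", "", grep("^crop_", names(filled), value = TRUE))
    lv <- landuse_variables(filled$agri_area, filled$grassland_area,
                            filled$lsu, crops, crop_rates, study_area[[z]])
    lv$year <- out_years
    for (k in seq_len(nrow(intervals))) {
      int <- c(intervals$from[k], intervals$to[k])
      rows[[length(rows) + 1L]] <- data.frame(
        zone = z, interval = k,
        bio1 = climate_change(ann$bio1, ann$year, int),
        bio4 = climate_change(ann$bio4, ann$year, int),
        bio18 = climate_change(ann$bio18, ann$year, int),
        agri_prop = landuse_change(lv$agri_prop, lv$year, int),
        grass_intensity = landuse_change(lv$grass_intensity, lv$year, int),
        crop_intensity = landuse_change(lv$crop_intensity, lv$year, int))
    }
  }
  standardize_changes(do.call(rbind, rows))
}

#' Run the full analysis pipeline on a synthetic dataset
#'
#' Executes every stage in sequence and writes all summary artifacts to
#' `outdir`.  MCMC problem sizes are controlled by `occ_mcmc` /
#' `reg_mcmc`; the defaults are sized for a small demonstration system.
#'
#' @param config a `sim_config` describing the study system.
#' @param outdir output directory.
#' @param interval_length trend interval length in years (5 or 10).
#' @param model_version regression version reported (1, 2 or 3);
#'   scenarios always use the agri-species-only version 2 fit.
#' @param occ_mcmc list of occupancy MCMC settings (chains, adapt,
#'   burnin, iter).
#' @param reg_mcmc list of regression MCMC settings (chains, iter,
#'   warmup).
#' @param occ_terms model terms of the occupancy fit (see
#'   [fit_occupancy_model()]).
#' @param seed master seed for model fitting (data generation uses
#'   `config$rng_seed`).
#' @param n_boot bootstrap replicates for the trend sign-change interval.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with all stage results.
#' @export
run_pipeline <- function(config = sim_config(), outdir = tempfile("occutrends"),
                         interval_length = config$interval_length,
                         model_version = 1L,
                         occ_mcmc = list(chains = 2L, adapt = 150L,
                                         burnin = 150L, iter = 300L),
                         reg_mcmc = list(chains = 2L, iter = 500L,
                                         warmup = 500L),
                         occ_terms = c("elev", "region", "square", "rw",
                                       "det_covs", "det_year"),
                         seed = 1L, n_boot = 9999L, quiet = FALSE) {
  config <- validate_sim_config(config)
  config$interval_length <- interval_length
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()

  say("stage 1/7: simulating study system")
  sim <- simulate_dataset(config)
  write_sim_data(sim, file.path(outdir, "data"))
  years <- config$years
  intervals <- interval_windows(min(years), max(years), interval_length)

  say("stage 2/7: preparing records (%d raw records)", nrow(sim$records))
  recs <- filter_records(sim$records, min(years), max(years), quiet = quiet)
  bv <- build_visits(recs)
  experts <- classify_observers(bv$visits, recs)
  species_sel <- select_species(recs, years)
  if (!length(species_sel)) stopf("no species passes the year-coverage filter")
  say("  %d visits, %d species selected, %d expert observer(s)",
      nrow(bv$visits), length(species_sel), sum(experts$expert))

  say("stage 3/7: driver variables and species traits")
  drivers <- compute_driver_table(sim$drivers$climate, sim$drivers$landuse,
                                  sim$drivers$study_area, config$crop_rates,
                                  intervals)
  sti <- species_temperature_index(sim$species$grid$records,
                                   sim$species$grid$cell_temps)
  spdf <- sim$species$species
  hs <- habitat_specialisation(
    data.frame(species_id = spdf$species_id, group = spdf$group,
               n_habitats = spdf$n_habitats),
    config$habitat_universe)
  traits <- data.frame(
    species_id = spdf$species_id, group = spdf$group,
    niche = sti$sti[match(spdf$species_id, sti$species_id)],
    specialisation = hs$specialisation[match(spdf$species_id, hs$species_id)],
    agri_associated = spdf$agri_associated,
    flag_excluded = spdf$flag_excluded)
  utils::write.csv(drivers, file.path(outdir, "drivers.csv"), row.names = FALSE)
  utils::write.csv(traits, file.path(outdir, "traits.csv"), row.names = FALSE)

  say("stage 4/7: occupancy-detection models (%d species)", length(species_sel))
  zone_of <- stats::setNames(sim$frame$zone, sim$frame$square_id)
  series_list <- list()
  conv_list <- list()
  for (sp in species_sel) {
    hist <- build_detection_histories(sp, bv$visits, bv$visit_species, recs,
                                      sim$frame, experts, sim$projects)
    if (is.null(hist)) next
    grp <- recs$group[match(sp, recs$species_id)]
    group_squares <- unique(recs$square_id[recs$group == grp])
    design <- occu_design(hist, sim$frame, years = years,
                          group_squares = group_squares)
    fit <- fit_occupancy_model(design, chains = occ_mcmc$chains,
                               adapt = occ_mcmc$adapt, burnin = occ_mcmc$burnin,
                               iter = occ_mcmc$iter,
                               seed = seed + match(sp, species_sel),
                               terms = occ_terms)
    ser <- derive_mean_occupancy(fit)
    series_list[[sp]] <- ser
    conv_list[[sp]] <- check_convergence(ser)$fraction_ok
    say("  %s: %d sites, %d visits, Rhat<1.1 fraction %.2f", sp,
        nrow(design$sites), nrow(design$visits), conv_list[[sp]])
  }
  if (!length(series_list)) stopf("no species could be fitted")

  say("stage 5/7: trend estimation")
  sp_fit <- names(series_list)
  nd <- nrow(series_list[[1]]$country)
  change_draws <- t(vapply(sp_fit, function(sp) {
    fit_window_trend(series_list[[sp]]$country, years)
  }, numeric(nd)))
  mean_occ_draws <- t(vapply(sp_fit, function(sp) {
    rowMeans(series_list[[sp]]$country)
  }, numeric(nd)))
  trend_summary <- summarize_trends(change_draws, mean_occ_draws,
                                    n_boot = n_boot)
  trend_rows <- list()
  for (sp in sp_fit) {
    ser <- series_list[[sp]]
    for (z in dimnames(ser$zone)[[2]]) {
      for (k in seq_len(nrow(intervals))) {
        d <- fit_window_trend(ser$zone[, z, ], years,
                              c(intervals$from[k], intervals$to[k]))
        trend_rows[[length(trend_rows) + 1L]] <- data.frame(
          species_id = sp, zone = z, interval = k,
          change_mean = mean(d),
          response = mean(signed_sqrt(d)))
      }
    }
  }
  trends <- do.call(rbind, trend_rows)
  utils::write.csv(trends, file.path(outdir, "trends_zone_interval.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(species_id = sp_fit, change_mean = rowMeans(change_draws),
               change_lower = apply(change_draws, 1, function(d) hdi(d)[1]),
               change_upper = apply(change_draws, 1, function(d) hdi(d)[2])),
    file.path(outdir, "trends_country.csv"), row.names = FALSE)

  say("stage 6/7: trend regression (version %d)", model_version)
  zone_weights <- table(sim$frame$zone)
  zone_elev <- stats::setNames(
    sim$frame$elev_class[!duplicated(sim$frame$zone)],
    sim$frame$zone[!duplicated(sim$frame$zone)])
  tr_in <- trends[, c("species_id", "zone", "interval")]
  tr_in$response <- trends$response
  design <- build_design(tr_in, drivers, traits, version = model_version,
                         zone_elev = zone_elev,
                         zone_weights = as.numeric(zone_weights[names(zone_weights)]) |>
                           stats::setNames(names(zone_weights)))
  fit <- fit_trend_regression(design, iter = reg_mcmc$iter,
                              warmup = reg_mcmc$warmup,
                              chains = reg_mcmc$chains, seed = seed)
  reg_summary <- data.frame(
    term = colnames(fit$beta),
    mean = colMeans(fit$beta),
    t(apply(fit$beta, 2, hdi)),
    rhat = fit$rhat)
  utils::write.csv(reg_summary, file.path(outdir, "regression_effects.csv"),
                   row.names = FALSE)

  say("stage 7/7: scenario decomposition")
  if (model_version == 2L) {
    design2 <- design; fit2 <- fit
  } else {
    design2 <- build_design(tr_in, drivers, traits, version = 2L,
                            zone_elev = zone_elev,
                            zone_weights = as.numeric(zone_weights[names(zone_weights)]) |>
                              stats::setNames(names(zone_weights)))
    fit2 <- fit_trend_regression(design2, iter = reg_mcmc$iter,
                                 warmup = reg_mcmc$warmup,
                                 chains = reg_mcmc$chains, seed = seed + 1L)
  }
  observed <- aggregate_longterm(design2, design2$y)
  scen <- run_scenarios(fit2, observed)
  utils::write.csv(scen, file.path(outdir, "scenarios.csv"), row.names = FALSE)

  manifest <- list(
    seed = seed, config_seed = config$rng_seed,
    config_hash = .config_hash(unclass(config)),
    interval_length = interval_length, model_version = model_version,
    n_species_fitted = length(sp_fit),
    n_visits = nrow(bv$visits), n_records = nrow(recs),
    convergence_fraction = mean(unlist(conv_list), na.rm = TRUE),
    runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(
    list(counts = trend_summary$counts,
         quarters = trend_summary$quarters,
         percent = trend_summary$percent,
         sign_change = trend_summary$sign_change),
    file.path(outdir, "trend_summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")
  say("pipeline complete in %.1f min", manifest$runtime_s / 60)
  invisible(list(sim = sim, records = recs, visits = bv, experts = experts,
                 drivers = drivers, traits = traits, series = series_list,
                 change_draws = change_draws, trend_summary = trend_summary,
                 trends = trends, design = design, fit = fit,
                 design2 = design2, fit2 = fit2,
                 observed_longterm = observed, scenarios = scen,
                 manifest = manifest, outdir = outdir))
}

#' Deterministic micro-datasets for tests and examples
#'
#' @param kind one of `"tiny-occupancy"` (3 sites, 2 years, enumerable
#'   latent states), `"toy-trend"` (8 species with known point trends),
#'   `"driver-grid"` (2 zones x 8 intervals with closed-form changes).
#' @return the fixture object (see details of each kind in the source).
#' @export
make_fixtures <- function(kind = c("tiny-occupancy", "toy-trend", "driver-grid")) {
  kind <- match.arg(kind)
  if (kind == "tiny-occupancy") {
    frame <- data.frame(square_id = c("sqA", "sqB", "sqC"),
                        zone = "Jura_low", region = "Jura",
                        elev_class = "low", fine_region = c("J1", "J1", "J2"),
                        elevation = c(400, 600, 800))
    hist <- data.frame(
      visit_id = sprintf("v%02d", 1:5),
      square_id = c("sqA", "sqA", "sqB", "sqC", "sqC"),
      zone = "Jura_low",
      year = c(2000L, 2001L, 2000L, 2000L, 2001L),
      y = c(1L, 0L, 1L, 0L, 0L),
      yday_s = c(-1, 0, 0.5, 1, -0.5),
      list_class = list_length_class(c(1, 2, 4, 1, 3)),
      source_class = factor(c("naturalist", "expert", "project",
                              "naturalist", "redlist"),
                            levels = source_levels()))
    attr(hist, "species_id") <- "toy"
    return(occu_design(hist, frame, years = 2000:2001))
  }
  if (kind == "toy-trend") {
    pm <- c(-0.08, -0.05, -0.01, 0.005, 0.01, 0.03, 0.06, 0.09)
    change <- matrix(rep(pm, 200), nrow = 8,
                     dimnames = list(paste0("sp", 1:8), NULL))
    mean_occ <- matrix(rep(c(0.1, 0.15, 0.2, 0.25, 0.2, 0.15, 0.12, 0.18), 200),
                       nrow = 8, dimnames = dimnames(change))
    return(list(change_draws = change, mean_occ_draws = mean_occ,
                point_trends = pm))
  }
  # driver-grid: linear trajectories with closed-form interval changes
  g <- expand.grid(zone = c("Jura_low", "Jura_high"), interval = 1:8)
  g$bio1 <- 0.05 * 5 * ifelse(g$zone == "Jura_low", 1, 2)
  g$bio4 <- 0.01 * 5
  g$bio18 <- -2 * 5
  g$agri_prop <- -0.004 * 5
  g$grass_intensity <- 0.002 * 5 * g$interval
  g$crop_intensity <- 0.001 * 5
  g
}
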