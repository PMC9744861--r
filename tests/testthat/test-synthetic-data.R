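test_that("configuration is validated", {
  expect_error(sim_config(n_squares_per_zone = 0L), "n_squares_per_zone")
  expect_error(sim_config(n_zones = 12L), "n_zones")
  expect_error(sim_config(occupancy_coefs = list(intercept = 0, elev = 0,
                                                 elev2 = 0, sd_species = -1,
                                                 sd_region = 0.1, sd_square = 0.1,
                                                 sd_rw = 0.1)), "SD")
  expect_error(sim_config(nonsense = 1), "unknown")
})

test_that("landscape generation fills every zone and is deterministic", {
  cfg <- sim_config(n_zones = 9L, n_squares_per_zone = 50L)
  frame <- generate_landscape(cfg)
  expect_equal(nrow(frame), 450)
  expect_equal(length(unique(frame$zone)), 9)
  expect_true(all(table(frame$zone) == 50))
  # the 1000 m rule ties class to continuous elevation
  expect_true(all(frame$elev_class == elevation_class(frame$elevation)))
  expect_identical(elevation_class(999), "low")
  expect_identical(elevation_class(1001), "high")
  expect_identical(frame, generate_landscape(cfg))
  frame2 <- generate_landscape(sim_config(rng_seed = 2L))
  expect_false(identical(frame$elevation, frame2$elevation))
})

test_that("driver trajectories carry the configured climate trends", {
  cfg <- sim_config(n_zones = 2L, n_squares_per_zone = 5L,
                    climate = list(temp_trend = 0.05, amp_trend = 0,
                                   precip_trend = 0, temp_noise_sd = 0,
                                   precip_noise_sd = 0, amp = 9,
                                   zone_multipliers = c(1, 1)),
                    landuse = list(agri_start = c(low = 0.45, high = 0.30),
                                   agri_loss = 0, grass_share = c(low = 0.55, high = 0.9),
                                   lsu_per_grass = c(low = 1.3, high = 0.7),
                                   lsu_rise = 0, crop_share = c(low = 0.25, high = 0),
                                   noise_sd = 0, observed_years_step = 5L,
                                   gap_fraction = 0))
  drv <- generate_driver_trajectories(cfg)
  z <- unique(drv$climate$zone)[1]
  cz <- drv$climate[drv$climate$zone == z, ]
  ann <- tapply(cz$temp, cz$year, mean)
  sl <- unname(ols_slope(as.numeric(ann), as.numeric(names(ann))))
  expect_equal(sl, 0.05, tolerance = 1e-10)
  # zero-trend, zero-noise land use is constant
  agri <- drv$truth[drv$truth$zone == z & drv$truth$variable == "agri_area", ]
  expect_equal(stats::sd(agri$value), 0)
  # gaps flagged as configured
  cfg2 <- sim_config(n_zones = 1L, n_squares_per_zone = 5L,
                     landuse = utils::modifyList(cfg$landuse, list(gap_fraction = 0.5)))
  drv2 <- generate_driver_trajectories(cfg2)
  expect_true(all(is.na(drv2$landuse$value[!drv2$landuse$observed])))
  expect_gt(sum(!drv2$landuse$observed), 0.3 * nrow(drv2$landuse))
})

test_that("latent dynamics honour the configured structure", {
  cfg <- sim_config(n_zones = 3L, n_squares_per_zone = 10L, n_years = 11L,
                    n_species_per_group = c(butterfly = 2L, grasshopper = 1L,
                                            dragonfly = 1L),
                    driver_effect_sizes = c(bio1 = 0, bio4 = 0, bio18 = 0,
                                            agri_prop = 0, grass_intensity = 0,
                                            crop_intensity = 0),
                    occupancy_coefs = list(intercept = 0, elev = 0, elev2 = 0,
                                           sd_species = 0, sd_region = 0,
                                           sd_square = 0, sd_rw = 0))
  frame <- generate_landscape(cfg)
  drv <- generate_driver_trajectories(cfg)
  pool <- generate_species_pool(cfg)
  ts <- simulate_occupancy_dynamics(frame, drv, pool, cfg)
  # all coefficients zero: psi exactly 0.5 everywhere
  expect_true(all(ts$psi == 0.5))
  expect_true(all(ts$z %in% 0:1))
  # zero effects: true trends indistinguishable from zero
  mc_se <- stats::sd(ts$true_trends$true_trend) / sqrt(nrow(ts$true_trends))
  expect_lt(abs(mean(ts$true_trends$true_trend)), 3 * max(mc_se, 1e-12))
})

test_that("a positive warming effect orders species trends by zone warming", {
  cfg <- sim_config(n_zones = 5L, n_squares_per_zone = 10L, n_years = 21L,
                    n_species_per_group = c(butterfly = 4L, grasshopper = 2L,
                                            dragonfly = 2L),
                    driver_effect_sizes = c(bio1 = 0.8, bio4 = 0, bio18 = 0,
                                            agri_prop = 0, grass_intensity = 0,
                                            crop_intensity = 0),
                    trait_interactions = c(niche = 0, specialisation = 0),
                    occupancy_coefs = list(intercept = -0.5, elev = 0, elev2 = 0,
                                           sd_species = 0.2, sd_region = 0,
                                           sd_square = 0.2, sd_rw = 0.01),
                    rng_seed = 21L)
  frame <- generate_landscape(cfg)
  drv <- generate_driver_trajectories(cfg)
  pool <- generate_species_pool(cfg)
  ts <- simulate_occupancy_dynamics(frame, drv, pool, cfg)
  # per zone: mean true trend over species vs mean standardized warming
  tt <- ts$true_trends
  mean_trend <- tapply(tt$true_trend, tt$zone, mean)
  dc <- ts$driver_changes
  warming <- tapply(dc$bio1, dc$zone, mean)
  expect_gt(stats::cor(mean_trend[names(warming)], warming,
                       method = "spearman"), 0)
})

test_that("the observation process emits records only for detections", {
  cfg <- sim_config(n_zones = 2L, n_squares_per_zone = 8L, n_years = 6L,
                    n_species_per_group = c(butterfly = 2L, grasshopper = 1L,
                                            dragonfly = 1L),
                    visit_intensity = 2, p_nonadult = 0, rng_seed = 3L)
  frame <- generate_landscape(cfg)
  drv <- generate_driver_trajectories(cfg)
  pool <- generate_species_pool(cfg)
  ts <- simulate_occupancy_dynamics(frame, drv, pool, cfg)
  # z = 0 everywhere: zero records
  ts0 <- ts
  ts0$z[] <- 0L
  obs0 <- simulate_visits_and_records(ts0, frame, pool, cfg)
  expect_equal(nrow(obs0$records), 0)
  # every record matches a latent presence
  obs <- simulate_visits_and_records(ts, frame, pool, cfg)
  r <- obs$records
  zi <- ts$z[cbind(match(r$species_id, rownames(ts$z)),
                   match(r$square_id, colnames(ts$z)),
                   match(as.character(r$year), dimnames(ts$z)[[3]]))]
  expect_true(all(zi == 1L))
  # determinism
  obs2 <- simulate_visits_and_records(ts, frame, pool, cfg)
  expect_identical(obs$records, obs2$records)
})

test_that("lowering the detection intercept strictly reduces records", {
  cfg <- sim_config(n_zones = 2L, n_squares_per_zone = 10L, n_years = 8L,
                    n_species_per_group = c(butterfly = 2L, grasshopper = 1L,
                                            dragonfly = 1L),
                    visit_intensity = 2, rng_seed = 5L)
  frame <- generate_landscape(cfg)
  drv <- generate_driver_trajectories(cfg)
  pool <- generate_species_pool(cfg)
  ts <- simulate_occupancy_dynamics(frame, drv, pool, cfg)
  hi <- simulate_visits_and_records(ts, frame, pool, cfg)
  cfg_lo <- cfg
  cfg_lo$detection_coefs$intercept <- cfg$detection_coefs$intercept - 2
  lo <- simulate_visits_and_records(ts, frame, pool, cfg_lo)
  expect_lt(nrow(lo$records), nrow(hi$records))
  # naive occupancy cannot exceed true occupancy of visited squares
  naive <- length(unique(hi$records$square_id)) / nrow(frame)
  true_occ <- mean(apply(ts$z, 2, max))
  expect_lte(naive, true_occ + 1e-12)
})

test_that("a seeded dataset round-trips to disk with a manifest", {
  cfg <- sim_config(n_zones = 2L, n_squares_per_zone = 6L, n_years = 6L,
                    n_species_per_group = c(butterfly = 1L, grasshopper = 1L,
                                            dragonfly = 1L),
                    visit_intensity = 1, rng_seed = 11L)
  sim <- simulate_dataset(cfg)
  dir <- tempfile("simout")
  write_sim_data(sim, dir)
  expect_true(all(file.exists(file.path(
    dir, c("frame.csv", "records.csv", "climate.csv", "landuse.csv",
           "species.csv", "true_trends.csv", "manifest.yaml")))))
  mf <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  expect_equal(mf$seed, 11L)
  expect_equal(mf$n_records, nrow(sim$records))
  unlink(dir, recursive = TRUE)
})
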