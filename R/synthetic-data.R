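# Virtual study system with known ground truth.
#
# The generator emulates the statistical structure the downstream
# analysis assumes: a landscape of 1x1 km squares stratified into
# bioclimatic zones (coarse region x elevation class), zone-specific
# climate and land-use trajectories, species with temperature niches and
# habitat specialisation, latent occupancy following a logistic model
# with zone-year effects whose drift is a linear combination of
# standardized driver changes and trait interactions, and an
# opportunistic observation process (heterogeneous observers, sources,
# list-length effects) that emits records only for detections.

# region template: 5 coarse regions, 12 fine regions, 9 zones
.zone_template <- function() {
  regions <- data.frame(
    region = c("Jura", "Plateau", "NorthernAlps", "CentralAlps", "SouthernAlps"),
    has_high = c(TRUE, FALSE, TRUE, TRUE, TRUE),
    base_temp_low = c(9.4, 9.5, 9.2, 9.5, 10.4))
  fine <- list(Jura = c("J1", "J2"), Plateau = c("P1", "P2", "P3"),
               NorthernAlps = c("N1", "N2", "N3"), CentralAlps = c("C1", "C2"),
               SouthernAlps = c("S1", "S2"))
  zones <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
    ec <- if (regions$has_high[i]) c("low", "high") else "low"
    data.frame(region = regions$region[i], elev_class = ec,
               base_temp = regions$base_temp_low[i] - ifelse(ec == "high", 4.5, 0))
  }))
  # order: low-elevation zones first within region, demo subsets stay sensible
  zones$zone <- paste(zones$region, zones$elev_class, sep = "_")
  zones$fine_regions <- fine[zones$region]
  rownames(zones) <- NULL
  zones
}

#' Configuration of the synthetic study system
#'
#' Returns a validated configuration list.  Defaults describe a
#' desk-scale version of a 41-year (1980-2020), nine-zone opportunistic
#' recording system for three insect groups; every default can be
#' overridden by name.
#'
#' @param n_squares_per_zone squares per bioclimatic zone (default 50).
#' @param n_zones number of zones, 1-9, taken from the fixed
#'   region x elevation template (default 9).
#' @param n_years study years (default 41, labelled from `start_year`).
#' @param start_year first study year (default 1980).
#' @param interval_length length of the trend intervals in years (default 5).
#' @param n_species_per_group named counts for the groups
#'   butterfly / grasshopper / dragonfly.
#' @param driver_effect_sizes named vector: logit-scale drift of the
#'   zone-year occupancy effect per 1 SD of driver change per interval,
#'   for `bio1`, `bio4`, `bio18`, `agri_prop`, `grass_intensity`,
#'   `crop_intensity`.
#' @param trait_interactions named vector: multiplicative modulation of
#'   climate effects by the standardized temperature niche (`niche`) and
#'   of land-use effects by standardized specialisation
#'   (`specialisation`).
#' @param occupancy_coefs list: `intercept`, `elev`, `elev2` (on scaled
#'   elevation), `sd_species`, `sd_region`, `sd_square`, `sd_rw`
#'   (random-walk innovation SD of the zone-year effect).
#' @param detection_coefs list: `intercept` (single-species list,
#'   plain-naturalist visit at mid-season), `yday`, `yday2`,
#'   `shortlist`, `longlist` (effort classes 2-3 and >3), `expert`,
#'   `project`, `targeted_project`, `redlist`, `sd_year`.
#' @param visit_intensity expected visits per square and year (over all
#'   groups; default 3).
#' @param n_observers observer pool size (default 100).
#' @param zipf_alpha exponent of the discrete power-law observer
#'   activity distribution (default 1.5); guarantees a heavy expert tail.
#' @param source_probs probabilities of a visit's source:
#'   `person`, `project`, `targeted_project`, `redlist`.
#' @param effort_probs probabilities of the latent effort classes that
#'   generate list lengths (1 species; 2-3; >3).
#' @param season named list of `c(first_day, last_day)` activity windows
#'   per group.
#' @param p_nonadult fraction of records flagged as non-adult stages.
#' @param climate list: `temp_trend` (deg C/yr, zone-multiplied),
#'   `amp_trend` (seasonal-amplitude trend), `precip_trend`
#'   (mm/month/yr), `temp_noise_sd`, `precip_noise_sd`, `amp` (seasonal
#'   amplitude), `zone_multipliers` (length `n_zones` contrast of trend
#'   strengths).
#' @param landuse list: trajectory anchors and noise for agricultural
#'   area, grassland share, livestock units and crops, plus
#'   `observed_years_step` (pre-1996 census spacing) and `gap_fraction`
#'   (additional random gaps).
#' @param crop_rates named insecticide application rates per crop type.
#' @param habitat_universe named habitat-universe sizes per group.
#' @param p_agri_associated probability that a butterfly / grasshopper
#'   species is associated to agriculturally influenced habitats
#'   (dragonflies never are).
#' @param rng_seed integer master seed; equal seeds give byte-identical
#'   outputs.
#' @param ... overrides for any of the above, validated by name.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_squares_per_zone = 50L,
                       n_zones = 9L,
                       n_years = 41L,
                       start_year = 1980L,
                       interval_length = 5L,
                       n_species_per_group = c(butterfly = 11L, grasshopper = 5L, dragonfly = 4L),
                       driver_effect_sizes = c(bio1 = -0.3, bio4 = -0.1, bio18 = -0.1,
                                               agri_prop = 0.15, grass_intensity = -0.15,
                                               crop_intensity = -0.1),
                       trait_interactions = c(niche = 0.5, specialisation = 0.5),
                       occupancy_coefs = list(intercept = -0.8, elev = -0.4, elev2 = -0.3,
                                              sd_species = 0.6, sd_region = 0.3,
                                              sd_square = 0.6, sd_rw = 0.03),
                       detection_coefs = list(intercept = -0.9, yday = 0.2, yday2 = -0.4,
                                              shortlist = 0.7, longlist = 1.3,
                                              expert = 0.8, project = 0.3,
                                              targeted_project = 1.2, redlist = 0.5,
                                              sd_year = 0.25),
                       visit_intensity = 3,
                       n_observers = 100L,
                       zipf_alpha = 1.5,
                       source_probs = c(person = 0.70, project = 0.15,
                                        targeted_project = 0.05, redlist = 0.10),
                       effort_probs = c(0.35, 0.40, 0.25),
                       season = list(butterfly = c(100L, 280L),
                                     grasshopper = c(140L, 290L),
                                     dragonfly = c(120L, 260L)),
                       p_nonadult = 0.03,
                       climate = list(temp_trend = 0.05, amp_trend = 0.01,
                                      precip_trend = -0.4, temp_noise_sd = 0.5,
                                      precip_noise_sd = 12, amp = 9,
                                      zone_multipliers = NULL),
                       landuse = list(agri_start = c(low = 0.45, high = 0.30),
                                      agri_loss = 0.10, grass_share = c(low = 0.55, high = 0.90),
                                      lsu_per_grass = c(low = 1.3, high = 0.7),
                                      lsu_rise = 0.25, crop_share = c(low = 0.25, high = 0),
                                      noise_sd = 0.01, observed_years_step = 5L,
                                      gap_fraction = 0),
                       crop_rates = c(cereal = 0.6, orchard = 2.4),
                       habitat_universe = c(butterfly = 18L, grasshopper = 12L, dragonfly = 10L),
                       p_agri_associated = 0.85,
                       rng_seed = 1L,
                       ...) {
  cfg <- c(as.list(environment()))
  cfg$... <- NULL
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stopf("unknown sim_config field(s): %s", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param config a `sim_config` object to validate.
#' @export
validate_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with(config, {
    if (n_squares_per_zone < 1L) stopf("n_squares_per_zone must be >= 1")
    if (n_zones < 1L || n_zones > 9L) stopf("n_zones must be in 1..9")
    if (n_years < 2L) stopf("n_years must be >= 2")
    if (any(n_species_per_group < 0L) || sum(n_species_per_group) < 1L) {
      stopf("need at least one species")
    }
    sds <- c(occupancy_coefs$sd_species, occupancy_coefs$sd_region,
             occupancy_coefs$sd_square, occupancy_coefs$sd_rw,
             detection_coefs$sd_year)
    if (any(sds < 0)) stopf("all random-effect SDs must be >= 0")
    if (visit_intensity < 0) stopf("visit_intensity must be >= 0")
  })
  if (is.null(config$climate$zone_multipliers)) {
    config$climate$zone_multipliers <-
      if (config$n_zones == 1L) 1 else seq(0.5, 1.5, length.out = config$n_zones)
  }
  config$years <- seq(config$start_year, length.out = config$n_years)
  config
}

#' Generate the study landscape
#'
#' Assigns `n_squares_per_zone` squares to each of the first `n_zones`
#' zones of the region x elevation template.  Each square gets a
#' continuous mean elevation consistent with its elevation class (the
#' 1000 m a.s.l. rule: below 1000 m = low), and a fine biogeographic
#' region nested in its coarse region.
#'
#' @param config a `sim_config`.
#' @return data.frame (`StudyFrame`): `square_id`, `zone`, `region`,
#'   `elev_class`, `fine_region`, `elevation`.
#' @export
generate_landscape <- function(config) {
  config <- validate_sim_config(config)
  zt <- .zone_template()[seq_len(config$n_zones), ]
  set.seed(config$rng_seed + 101L)
  n <- config$n_squares_per_zone
  out <- do.call(rbind, lapply(seq_len(nrow(zt)), function(i) {
    elev <- if (zt$elev_class[i] == "low") stats::runif(n, 300, 999.9)
            else stats::runif(n, 1000, 2500)
    data.frame(zone = zt$zone[i], region = zt$region[i],
               elev_class = zt$elev_class[i],
               fine_region = sample(zt$fine_regions[[i]], n, replace = TRUE),
               elevation = elev)
  }))
  out$square_id <- sprintf("sq%05d", seq_len(nrow(out)))
  out[, c("square_id", "zone", "region", "elev_class", "fine_region", "elevation")]
}

#' Elevation class of a square
#'
#' Squares with mean elevation below 1000 m a.s.l. are "low", at or
#' above 1000 m "high".
#' @param elevation mean elevation in m a.s.l.
#' @return character vector "low"/"high".
#' @export
elevation_class <- function(elevation) ifelse(elevation < 1000, "low", "high")

#' Generate zone-wise driver trajectories
#'
#' Monthly temperature and precipitation series per zone and year (with
#' zone-specific linear trends in mean, seasonal amplitude and summer
#' precipitation, plus noise), and smooth multi-decadal land-use series
#' (agricultural area, grassland area, livestock units, per-crop areas)
#' observed on a census-like schedule with configurable gaps.  Climate
#' series include the 5 years preceding the study range, as needed by
#' the 10-year climate-change windows.
#'
#' @param config a `sim_config`.
#' @return list with `climate` (data.frame: zone, year, month, temp,
#'   precip), `landuse` (data.frame: zone, year, variable, value,
#'   observed), `study_area` (named: squares per zone), and `truth`
#'   (complete land-use series before gapping).
#' @export
generate_driver_trajectories <- function(config) {
  config <- validate_sim_config(config)
  zt <- .zone_template()[seq_len(config$n_zones), ]
  set.seed(config$rng_seed + 202L)
  cyears <- seq(config$start_year - 5L, max(config$years))
  cl <- config$climate
  clim <- do.call(rbind, lapply(seq_len(nrow(zt)), function(i) {
    m <- cl$zone_multipliers[i]
    g <- expand.grid(month = 1:12, year = cyears)
    dt <- g$year - config$start_year
    seas <- (cl$amp + m * cl$amp_trend * dt) * cos(2 * pi * (g$month - 7) / 12)
    temp <- zt$base_temp[i] + m * cl$temp_trend * dt + seas +
      stats::rnorm(nrow(g), 0, cl$temp_noise_sd)
    base_p <- 90 + 40 * exp(-((g$month - 7) / 3)^2)      # summer-peaked precip
    precip <- pmax(0, base_p + m * cl$precip_trend * dt *
                     (g$month %in% 5:9) + stats::rnorm(nrow(g), 0, cl$precip_noise_sd))
    data.frame(zone = zt$zone[i], year = g$year, month = g$month,
               temp = temp, precip = precip)
  }))

  lu <- config$landuse
  area <- config$n_squares_per_zone * 100          # ha per zone (1 km2 squares)
  ramp <- function(t, frac) 1 - frac * stats::plogis((t - 20) / 6)
  lu_truth <- do.call(rbind, lapply(seq_len(nrow(zt)), function(i) {
    ec <- zt$elev_class[i]
    dt <- config$years - config$start_year
    agri <- area * lu$agri_start[[ec]] * ramp(dt, lu$agri_loss)
    grass <- agri * lu$grass_share[[ec]]
    lsu <- grass * lu$lsu_per_grass[[ec]] * (1 + lu$lsu_rise * stats::plogis((dt - 15) / 5))
    crop <- (agri - grass) * lu$crop_share[[ec]]
    rbind(
      data.frame(zone = zt$zone[i], year = config$years, variable = "agri_area", value = agri),
      data.frame(zone = zt$zone[i], year = config$years, variable = "grassland_area", value = grass),
      data.frame(zone = zt$zone[i], year = config$years, variable = "lsu", value = lsu),
      data.frame(zone = zt$zone[i], year = config$years, variable = "crop_cereal", value = crop * 0.7),
      data.frame(zone = zt$zone[i], year = config$years, variable = "crop_orchard", value = crop * 0.3))
  }))
  lu_truth$value <- lu_truth$value * exp(stats::rnorm(nrow(lu_truth), 0, lu$noise_sd))

  # census schedule: yearly from 1996, every `observed_years_step` before
  dense_from <- min(max(config$years) - 24L, 1996L)
  sched <- config$years >= dense_from |
    (config$years - config$start_year) %% lu$observed_years_step == 0L
  observed <- sched[match(lu_truth$year, config$years)]
  if (lu$gap_fraction > 0) {
    drop <- stats::runif(nrow(lu_truth)) < lu$gap_fraction
    observed <- observed & !drop
  }
  landuse <- lu_truth
  landuse$observed <- observed
  landuse$value[!observed] <- NA_real_

  study_area <- stats::setNames(rep(area, nrow(zt)), zt$zone)
  list(climate = clim, landuse = landuse, study_area = study_area,
       truth = lu_truth)
}

#' Generate the species pool with traits
#'
#' Species in three groups with a temperature niche (deg C), a habitat
#' preference count (from which specialisation follows), an
#' agri-association flag (no dragonfly is agri-associated), and the
#' exclusion flags used by sensitivity analyses.  Also emits synthetic
#' continental grid records and cell temperatures from which the
#' species temperature index can be recomputed.
#'
#' @param config a `sim_config`.
#' @return list with `species` (data.frame of traits and truth) and
#'   `grid` (list: `records`, `cell_temps`).
#' @export
generate_species_pool <- function(config) {
  config <- validate_sim_config(config)
  set.seed(config$rng_seed + 303L)
  groups <- rep(names(config$n_species_per_group), config$n_species_per_group)
  ns <- length(groups)
  niche_mean <- c(butterfly = 8.5, grasshopper = 10, dragonfly = 10.5)
  niche <- stats::rnorm(ns, niche_mean[groups], 2)
  n_hab <- integer(ns)
  agri <- logical(ns)
  for (g in unique(groups)) {
    i <- groups == g
    N <- config$habitat_universe[[g]]
    n_hab[i] <- sample.int(N, sum(i), replace = TRUE)
    agri[i] <- if (g == "dragonfly") FALSE else
      stats::runif(sum(i)) < config$p_agri_associated
  }
  sp <- data.frame(
    species_id = sprintf("%s%03d", substr(groups, 1, 2), stats::ave(seq_len(ns), groups, FUN = seq_along)),
    group = groups, niche = niche, n_habitats = n_hab,
    agri_associated = agri,
    flag_excluded = stats::runif(ns) < 0.05)     # migratory/introduced/taxonomic
  hs <- habitat_specialisation(
    data.frame(species_id = sp$species_id, group = sp$group, n_habitats = sp$n_habitats),
    config$habitat_universe)
  sp$specialisation <- hs$specialisation[match(sp$species_id, hs$species_id)]

  # continental grid: 60 cells spanning 2..16 degC; occupied cells cluster
  # around the species' niche so the recomputed STI tracks it
  n_cells <- 60L
  cell_temps <- data.frame(cell_id = sprintf("cell%02d", seq_len(n_cells)),
                           temp = seq(2, 16, length.out = n_cells))
  grid_records <- do.call(rbind, lapply(seq_len(ns), function(s) {
    w <- stats::dnorm(cell_temps$temp, sp$niche[s], 1.5)
    k <- 5L + stats::rpois(1, 10)
    cells <- sample(cell_temps$cell_id, k, replace = TRUE, prob = w)
    data.frame(species_id = sp$species_id[s], cell_id = cells)
  }))
  list(species = sp, grid = list(records = grid_records, cell_temps = cell_temps))
}

# trend intervals of a simulated system; years beyond the last complete
# interval reuse the final interval's drift
.sim_intervals <- function(config) {
  n_int <- (config$n_years - 1L) %/% config$interval_length
  if (n_int < 1L) {
    stopf("n_years (%d) must span at least one %d-year interval",
          config$n_years, config$interval_length)
  }
  interval_windows(config$start_year,
                   config$start_year + n_int * config$interval_length,
                   config$interval_length)
}

# standardized driver changes per zone x interval, from the generator's
# own (noise-free-ish) truth; reused by simulate_occupancy_dynamics
.true_driver_changes <- function(config, drivers) {
  iv <- .sim_intervals(config)
  clim <- drivers$climate
  zones <- unique(clim$zone)
  rows <- list()
  for (z in zones) {
    cz <- clim[clim$zone == z, ]
    ann <- do.call(rbind, lapply(split(cz, cz$year), function(d) {
      d <- d[order(d$month), ]
      as.data.frame(t(compute_bioclim(d$temp, d$precip)))
    }))
    ann$year <- as.integer(rownames(ann))
    luz <- drivers$truth[drivers$truth$zone == z, ]
    luw <- stats::reshape(luz, idvar = "year", timevar = "variable", direction = "wide")
    names(luw) <- sub("^value\\.", "", names(luw))
    crops <- as.matrix(luw[, grep("^crop_", names(luw)), drop = FALSE])
    colnames(crops) <- sub("^crop_", "", colnames(crops))
    lv <- landuse_variables(luw$agri_area, luw$grassland_area, luw$lsu,
                            crops, config$crop_rates, drivers$study_area[[z]])
    lv$year <- luw$year
    for (k in seq_len(nrow(iv))) {
      int <- c(iv$from[k], iv$to[k])
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

#' Simulate latent occupancy dynamics
#'
#' Builds per-species occupancy probabilities on the logit scale:
#' species intercept + elevation (linear + quadratic, scaled) + fine
#' region and square random effects + a zone-year effect.  The zone-year
#' effect is a random walk whose per-year drift is the configured linear
#' combination of standardized driver changes, modulated by species
#' traits (temperature niche for climate drivers, specialisation for
#' land-use drivers; agricultural drivers act only on agri-associated
#' species).  Latent presence is drawn Bernoulli(psi).  True trends are
#' the OLS changes of the generated mean-psi series.
#'
#' @param frame StudyFrame from [generate_landscape()].
#' @param drivers output of [generate_driver_trajectories()].
#' @param species species pool from [generate_species_pool()].
#' @param config a `sim_config`.
#' @return list (`TrueState`): `psi` and `z` (species x squares x years
#'   arrays), `true_trends` (zone x interval, data.frame),
#'   `true_trends_country` (named per species), `driver_changes`
#'   (standardized zone x interval table used for the drift).
#' @export
simulate_occupancy_dynamics <- function(frame, drivers, species, config) {
  config <- validate_sim_config(config)
  sp <- species$species
  ns <- nrow(sp); nsq <- nrow(frame); ny <- config$n_years
  dc <- .true_driver_changes(config, drivers)
  iv <- .sim_intervals(config)

  set.seed(config$rng_seed + 404L)
  oc <- config$occupancy_coefs
  elev_s <- as.numeric(scale(frame$elevation))
  regions <- sort(unique(frame$fine_region))
  a_region <- stats::setNames(stats::rnorm(length(regions), 0, oc$sd_region), regions)
  a_square <- stats::rnorm(nsq, 0, oc$sd_square)
  a_species <- stats::rnorm(ns, 0, oc$sd_species)

  niche_std <- as.numeric(scale(sp$niche))
  spec_std <- if (stats::sd(sp$specialisation) > 0)
    as.numeric(scale(sp$specialisation)) else rep(0, ns)
  eff <- config$driver_effect_sizes
  ti <- config$trait_interactions
  climate_drivers <- c("bio1", "bio4", "bio18")
  landuse_drivers <- c("agri_prop", "grass_intensity", "crop_intensity")

  base <- oc$intercept + oc$elev * elev_s + oc$elev2 * elev_s^2 +
    a_region[frame$fine_region] + a_square
  zones <- unique(frame$zone)
  year_of <- config$years
  interval_of_year <- findInterval(year_of, iv$from, rightmost.closed = TRUE)
  interval_of_year <- pmin(pmax(interval_of_year, 1L), nrow(iv))

  psi <- array(NA_real_, c(ns, nsq, ny),
               dimnames = list(sp$species_id, frame$square_id, year_of))
  z <- array(NA_integer_, dim(psi), dimnames = dimnames(psi))
  gam <- array(0, c(ns, length(zones), ny), dimnames = list(sp$species_id, zones, year_of))
  for (s in seq_len(ns)) {
    bsp <- stats::setNames(numeric(6), c(climate_drivers, landuse_drivers))
    bsp[climate_drivers] <- eff[climate_drivers] * (1 + ti[["niche"]] * niche_std[s])
    bsp[landuse_drivers] <- eff[landuse_drivers] * (1 + ti[["specialisation"]] * spec_std[s])
    bsp[c("agri_prop", "grass_intensity")] <-
      bsp[c("agri_prop", "grass_intensity")] * sp$agri_associated[s]
    for (zi in seq_along(zones)) {
      dcz <- dc[dc$zone == zones[zi], ]
      drift <- drop(as.matrix(dcz[order(dcz$interval), names(bsp)]) %*% bsp) /
        config$interval_length
      g <- numeric(ny)
      for (t in 2:ny) {
        g[t] <- g[t - 1] + drift[interval_of_year[t - 1]] +
          stats::rnorm(1, 0, oc$sd_rw)
      }
      gam[s, zi, ] <- g
    }
  }
  for (s in seq_len(ns)) {
    zi <- match(frame$zone, zones)
    lp <- outer(base + a_species[s], rep(1, ny)) + gam[s, , ][zi, , drop = FALSE]
    if (any(!is.finite(lp))) stopf("non-finite occupancy linear predictor (species %s)", sp$species_id[s])
    psi[s, , ] <- ilogit(lp)
    z[s, , ] <- stats::rbinom(length(lp), 1L, as.vector(psi[s, , ]))
  }

  # ground-truth trends from the generated mean-psi series
  tt <- list()
  for (s in seq_len(ns)) {
    for (zn in zones) {
      msk <- frame$zone == zn
      series <- colMeans(psi[s, msk, , drop = FALSE][1, , ])
      for (k in seq_len(nrow(iv))) {
        tt[[length(tt) + 1L]] <- data.frame(
          species_id = sp$species_id[s], zone = zn, interval = k,
          true_trend = fit_window_trend(series, year_of, c(iv$from[k], iv$to[k])))
      }
    }
  }
  country <- vapply(seq_len(ns), function(s) {
    fit_window_trend(colMeans(psi[s, , , drop = FALSE][1, , ]), year_of)
  }, numeric(1))
  list(psi = psi, z = z,
       true_trends = do.call(rbind, tt),
       true_trends_country = stats::setNames(country, sp$species_id),
       driver_changes = dc, gamma = gam)
}

#' Simulate visits and emit the opportunistic record table
#'
#' Places visits on squares and days (Poisson number per square-year,
#' day uniform in the visiting group's season window), assigns observers
#' from a discrete power-law activity distribution and a source class
#' (person / project / species-targeted project / Red-List inventory),
#' draws per-species detections Bernoulli(z * p) with the configured
#' detection model (latent effort class standing in for list length),
#' and emits records only for detections.  Realized list lengths are
#' whatever the emitted records imply.
#'
#' @param true_state output of [simulate_occupancy_dynamics()].
#' @param frame StudyFrame.
#' @param species species pool from [generate_species_pool()].
#' @param config a `sim_config`.
#' @return list: `records` (RecordTable), `projects` (project metadata
#'   incl. species coverage), `visits_truth` (all placed visits incl.
#'   recordless ones).
#' @export
simulate_visits_and_records <- function(true_state, frame, species, config) {
  config <- validate_sim_config(config)
  sp <- species$species
  set.seed(config$rng_seed + 505L)

  groups <- names(config$n_species_per_group)[config$n_species_per_group > 0]
  gprob <- config$n_species_per_group[groups] / sum(config$n_species_per_group[groups])
  nsq <- nrow(frame); ny <- config$n_years

  nv_sqyr <- stats::rpois(nsq * ny, config$visit_intensity)
  sq_idx <- rep(rep(seq_len(nsq), ny), nv_sqyr)
  yr_idx <- rep(rep(seq_len(ny), each = nsq), nv_sqyr)
  nv <- length(sq_idx)
  if (nv == 0L) {
    return(list(records = .empty_records(), projects = NULL, visits_truth = NULL))
  }
  grp <- sample(groups, nv, replace = TRUE, prob = gprob)
  doy <- integer(nv)
  for (g in groups) {
    i <- grp == g
    doy[i] <- sample(seq(config$season[[g]][1], config$season[[g]][2]), sum(i), replace = TRUE)
  }
  w <- (seq_len(config$n_observers))^(-config$zipf_alpha)
  observer <- sprintf("obs%04d", sample.int(config$n_observers, nv, replace = TRUE, prob = w))
  src <- sample(names(config$source_probs), nv, replace = TRUE, prob = config$source_probs)
  effort <- sample(1:3, nv, replace = TRUE, prob = config$effort_probs)

  # project pool: per group a generic project and a Red-List inventory
  # (full group coverage) plus targeted projects covering one species
  projects <- do.call(rbind, lapply(groups, function(g) {
    targets <- sp$species_id[sp$group == g]
    rbind(data.frame(project_id = paste0("proj_", g), type = "project",
                     group = g, target_species = NA_character_),
          data.frame(project_id = paste0("rl_", g), type = "redlist",
                     group = g, target_species = NA_character_),
          data.frame(project_id = paste0("tp_", g), type = "targeted_project",
                     group = g,
                     target_species = targets[1]))
  }))
  project_id <- rep(NA_character_, nv)
  pidx <- src != "person"
  for (g in groups) {
    for (ty in c("project", "targeted_project", "redlist")) {
      i <- pidx & grp == g & src == ty
      project_id[i] <- projects$project_id[projects$group == g & projects$type == ty][1]
    }
  }
  # expert status used for generation: heavy-tail observers
  top_obs <- sprintf("obs%04d", seq_len(max(1L, ceiling(0.025 * config$n_observers))))
  expert_gen <- observer %in% top_obs & src == "person"

  dcf <- config$detection_coefs
  a_year <- stats::rnorm(ny, 0, dcf$sd_year)

  rec <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    vis <- which(grp == g)
    spg <- which(sp$group == g)
    if (!length(vis) || !length(spg)) next
    season <- config$season[[g]]
    mid <- mean(season); sc <- diff(season) / 4
    yds <- (doy[vis] - mid) / sc
    lp_vis <- dcf$intercept + dcf$yday * yds + dcf$yday2 * yds^2 +
      dcf$shortlist * (effort[vis] == 2) + dcf$longlist * (effort[vis] == 3) +
      dcf$expert * expert_gen[vis] +
      dcf$project * (src[vis] == "project") +
      dcf$redlist * (src[vis] == "redlist") +
      a_year[yr_idx[vis]]
    pr <- projects[match(project_id[vis], projects$project_id), ]
    for (s in spg) {
      zz <- true_state$z[s, , ][cbind(sq_idx[vis], yr_idx[vis])]
      lp <- lp_vis + dcf$targeted_project *
        (!is.na(pr$target_species) & pr$target_species == sp$species_id[s])
      det <- zz == 1L & stats::runif(length(vis)) < ilogit(lp)
      if (!any(det)) next
      vi <- vis[det]
      rec[[gi]] <- rbind(rec[[gi]], data.frame(
        species_id = sp$species_id[s], group = g,
        square_id = frame$square_id[sq_idx[vi]],
        year = config$years[yr_idx[vi]], doy = doy[vi],
        observer_id = observer[vi], project_id = project_id[vi],
        source_hint = src[vi],
        life_stage = "adult"))
    }
  }
  records <- do.call(rbind, rec)
  if (is.null(records)) records <- .empty_records()
  rownames(records) <- NULL
  if (nrow(records) && config$p_nonadult > 0) {
    records$life_stage[stats::runif(nrow(records)) < config$p_nonadult] <- "larva"
  }
  visits_truth <- data.frame(square_id = frame$square_id[sq_idx],
                             year = config$years[yr_idx], doy = doy,
                             group = grp, observer_id = observer,
                             project_id = project_id, source_hint = src,
                             effort_class = effort)
  list(records = records, projects = projects, visits_truth = visits_truth)
}

.empty_records <- function() {
  data.frame(species_id = character(), group = character(),
             square_id = character(), year = integer(), doy = integer(),
             observer_id = character(), project_id = character(),
             source_hint = character(), life_stage = character())
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running landscape, drivers, species pool, latent
#' dynamics and the observation process in sequence from one
#' configuration.
#'
#' @param config a `sim_config`.
#' @return list of class `sim_data`: `config`, `frame`, `drivers`,
#'   `species`, `truth`, `records`, `projects`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  config <- validate_sim_config(config)
  frame <- generate_landscape(config)
  drivers <- generate_driver_trajectories(config)
  pool <- generate_species_pool(config)
  truth <- simulate_occupancy_dynamics(frame, drivers, pool, config)
  obs <- simulate_visits_and_records(truth, frame, pool, config)
  structure(list(config = config, frame = frame, drivers = drivers,
                 species = pool, truth = truth, records = obs$records,
                 projects = obs$projects, visits_truth = obs$visits_truth),
            class = "sim_data")
}

#' Write a synthetic dataset to CSV files plus a YAML manifest
#'
#' @param sim a `sim_data` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_sim_data <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sim$frame, file.path(dir, "frame.csv"), row.names = FALSE)
  utils::write.csv(sim$records, file.path(dir, "records.csv"), row.names = FALSE)
  utils::write.csv(sim$drivers$climate, file.path(dir, "climate.csv"), row.names = FALSE)
  utils::write.csv(sim$drivers$landuse, file.path(dir, "landuse.csv"), row.names = FALSE)
  utils::write.csv(sim$species$species, file.path(dir, "species.csv"), row.names = FALSE)
  utils::write.csv(sim$truth$true_trends, file.path(dir, "true_trends.csv"), row.names = FALSE)
  cfg <- sim$config
  class(cfg) <- NULL
  manifest <- list(
    seed = cfg$rng_seed,
    config_hash = .config_hash(cfg),
    n_records = nrow(sim$records),
    n_squares = nrow(sim$frame),
    n_species = nrow(sim$species$species))
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

.config_hash <- function(cfg) {
  # stable content hash without extra dependencies
  s <- paste(utils::capture.output(utils::str(cfg, digits.d = 12)), collapse = "\n")
  sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 977)) %% 2147483647
}
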