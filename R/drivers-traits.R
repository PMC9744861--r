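# Climate-change and land-use-change covariates per bioclimatic zone and
# 5-year interval, plus the two species traits (temperature niche,
# habitat specialisation).

#' Bioclimatic summaries of a monthly climate year
#'
#' From 12 monthly mean temperatures and 12 monthly precipitation sums,
#' computes: BIO1, the annual mean temperature (mean of monthly means);
#' BIO4, temperature seasonality (standard deviation of the monthly
#' means, not multiplied by 100); and BIO18, precipitation of the
#' warmest quarter (precipitation sum of the consecutive 3-month window
#' with the highest mean temperature, December-January wrap-around
#' allowed).
#'
#' @param monthly_temp 12 monthly mean temperatures (deg C), Jan..Dec.
#' @param monthly_precip 12 monthly precipitation sums (mm), Jan..Dec.
#' @return named numeric vector `c(bio1, bio4, bio18)`.
#' @export
compute_bioclim <- function(monthly_temp, monthly_precip) {
  if (length(monthly_temp) != 12L || anyNA(monthly_temp)) {
    stopf("monthly_temp must be 12 non-missing values")
  }
  if (length(monthly_precip) != 12L || anyNA(monthly_precip)) {
    stopf("monthly_precip must be 12 non-missing values")
  }
  bio1 <- mean(monthly_temp)
  bio4 <- stats::sd(monthly_temp)
  # all 12 wrap-around 3-month windows
  idx <- vapply(1:12, function(m) as.integer(((m - 1):(m + 1)) %% 12 + 1), integer(3))
  tmean <- colMeans(matrix(monthly_temp[idx], nrow = 3))
  psum <- colSums(matrix(monthly_precip[idx], nrow = 3))
  bio18 <- psum[which.max(tmean)]
  c(bio1 = bio1, bio4 = bio4, bio18 = unname(bio18))
}

#' Climate change attributed to a 5-year interval
#'
#' OLS slope of the annual series over a 10-year window (the interval
#' plus the 5 preceding years, so the first 1980-1985 interval uses
#' 1975-1985), multiplied by the interval length.  The widened window
#' buffers single extreme years and accounts for lagged climate effects.
#'
#' @param values annual values of the climate variable.
#' @param years calendar years labelling `values`.
#' @param interval length-2 vector `c(from, to)` of the focal interval.
#' @param lead years prepended to the window (default 5).
#' @return the change (slope x interval length) in the variable's units.
#' @export
climate_change <- function(values, years, interval, lead = 5L) {
  want <- seq(interval[1] - lead, interval[2])
  sel <- match(want, years)
  if (anyNA(sel)) {
    stopf("climate window %d-%d incomplete; missing years: %s",
          interval[1] - lead, interval[2],
          paste(want[is.na(sel)], collapse = ", "))
  }
  v <- values[sel]
  if (anyNA(v)) stopf("climate series has NA inside window %d-%d", want[1], interval[2])
  ols_slope(v, want) * (interval[2] - interval[1])
}

#' Gap-fill an irregular land-use series
#'
#' Agricultural statistics change gradually but are recorded at irregular
#' (5-10 year) resolution before 1996.  A thin-plate spline smooth of
#' value against year (mgcv::gam) predicts a complete annual series.
#' With fewer than 4 observed years the fit falls back to linear
#' interpolation (constant-extrapolated at the ends) with a warning.
#'
#' @param years observed years (numeric, possibly irregular).
#' @param values observed values.
#' @param out_years years at which to predict (default `min:max` of
#'   `years`).
#' @return data.frame with columns `year`, `value`, `observed`.
#' @export
gapfill_landuse <- function(years, values, out_years = NULL) {
  keep <- is.finite(years) & is.finite(values)
  years <- years[keep]; values <- values[keep]
  if (is.null(out_years)) out_years <- seq(min(years), max(years))
  n <- length(years)
  if (n < 2L) stopf("gapfill_landuse needs at least 2 observed years")
  if (stats::sd(values) == 0) {
    return(data.frame(year = out_years, value = rep(values[1], length(out_years)),
                      observed = out_years %in% years))
  }
  if (n < 4L) {
    warnf("only %d observed years: falling back to linear interpolation", n)
    pred <- stats::approx(years, values, xout = out_years, rule = 2)$y
  } else {
    # basis dimension capped so sparse series stay smooth; REML can
    # degenerate on (near-)noise-free series, so fall back to GCV and
    # finally to an interpolating natural spline
    k <- max(4L, min(n - 1L, 10L))
    df <- data.frame(years = years, values = values)
    nd <- data.frame(years = out_years)
    pred <- tryCatch(
      as.numeric(stats::predict(
        mgcv::gam(values ~ s(years, k = k), data = df, method = "REML"), nd)),
      error = function(e) tryCatch(
        as.numeric(stats::predict(
          mgcv::gam(values ~ s(years, k = k), data = df, method = "GCV.Cp"), nd)),
        error = function(e2)
          stats::spline(years, values, xout = out_years, method = "natural")$y))
  }
  data.frame(year = out_years, value = pred, observed = out_years %in% years)
}

#' Land-use intensity variables for one bioclimatic zone
#'
#' From gap-filled annual series of total agricultural area, grassland
#' area, livestock units (LSU) and per-crop areas, derives the three
#' annual land-use variables: proportion of agricultural area (relative
#' to the zone's study area), grassland-use intensity (LSU per grassland
#' area) and crop-use intensity (area-weighted mean insecticide
#' application rate over the zone's study area).
#'
#' @param agri_area annual total agricultural area (same unit as
#'   `study_area`).
#' @param grassland_area annual grassland area.
#' @param lsu annual livestock units.
#' @param crop_areas matrix years x crops of cropped areas (may be NULL
#'   or zero columns for zones without crops).
#' @param crop_rates named vector of per-crop insecticide application
#'   rates (kg/ha-equivalent), aligned with `colnames(crop_areas)`.
#' @param study_area total study area of the zone (scalar).
#' @return data.frame with columns `agri_prop`, `grass_intensity`,
#'   `crop_intensity`, one row per year.
#' @export
landuse_variables <- function(agri_area, grassland_area, lsu, crop_areas,
                              crop_rates, study_area) {
  if (any(grassland_area <= 0)) {
    stopf("grassland-use intensity undefined: grassland area <= 0 in %d year(s)",
          sum(grassland_area <= 0))
  }
  if (study_area <= 0) stopf("study_area must be positive")
  if (is.null(crop_areas) || NCOL(crop_areas) == 0L) {
    crop_load <- rep(0, length(agri_area))
  } else {
    crop_areas <- as.matrix(crop_areas)
    rates <- crop_rates[colnames(crop_areas)]
    if (anyNA(rates)) {
      stopf("no application rate for crop(s): %s",
            paste(colnames(crop_areas)[is.na(rates)], collapse = ", "))
    }
    crop_load <- drop(crop_areas %*% rates)
  }
  data.frame(
    agri_prop = agri_area / study_area,
    grass_intensity = lsu / grassland_area,
    crop_intensity = crop_load / study_area)
}

#' Change of an annual land-use variable over an interval
#'
#' Endpoint difference of the (gap-filled) series across the interval;
#' an OLS-slope variant over the same window is available for
#' sensitivity checks.
#'
#' @param values annual values.
#' @param years calendar years labelling `values`.
#' @param interval length-2 vector `c(from, to)`.
#' @param method "difference" (default) or "slope".
#' @return the change across the interval in the variable's units.
#' @export
landuse_change <- function(values, years, interval,
                           method = c("difference", "slope")) {
  method <- match.arg(method)
  sel <- match(seq(interval[1], interval[2]), years)
  if (anyNA(sel)) stopf("land-use window %d-%d incomplete", interval[1], interval[2])
  v <- values[sel]
  if (method == "difference") {
    v[length(v)] - v[1]
  } else {
    ols_slope(v, seq(interval[1], interval[2])) * (interval[2] - interval[1])
  }
}

#' Standardize driver-change variables over their recording replicates
#'
#' Each change variable is centred to mean 0 and scaled to standard
#' deviation 1 over its zone x interval replicates.  The scaling
#' constants are attached as the `"scaling"` attribute so that
#' counterfactual scenarios can map an uncentred "absolute 0" change
#' into standardized space (`-mean/sd`).
#'
#' @param drivers data.frame with columns `zone`, `interval` and one
#'   column per raw change variable.
#' @param vars which columns to standardize (default: all numeric
#'   columns except `zone`/`interval`).
#' @return data.frame of the same shape with standardized columns and a
#'   `"scaling"` attribute (data.frame `variable`, `center`, `scale`).
#' @export
standardize_changes <- function(drivers, vars = NULL) {
  if (is.null(vars)) {
    vars <- setdiff(names(drivers)[vapply(drivers, is.numeric, logical(1))],
                    c("zone", "interval"))
  }
  sc <- data.frame(variable = vars, center = NA_real_, scale = NA_real_)
  for (i in seq_along(vars)) {
    v <- drivers[[vars[i]]]
    if (anyNA(v)) stopf("variable '%s' has missing values", vars[i])
    m <- mean(v); s <- stats::sd(v)
    if (!is.finite(s) || s == 0) stopf("variable '%s' has zero variance", vars[i])
    drivers[[vars[i]]] <- (v - m) / s
    sc$center[i] <- m; sc$scale[i] <- s
  }
  attr(drivers, "scaling") <- sc
  drivers
}

#' Species temperature index
#'
#' The temperature niche of a species estimated as the unweighted mean
#' annual temperature of the grid cells in which it was recorded at
#' least once (each occupied cell counted once, regardless of record
#' numbers).
#'
#' @param grid_records data.frame with columns `species_id`, `cell_id`.
#' @param cell_temps data.frame with columns `cell_id`, `temp` (deg C).
#' @return data.frame `species_id`, `sti`, `n_cells`; species with no
#'   matching cells get `NA` and a warning.
#' @export
species_temperature_index <- function(grid_records, cell_temps) {
  recs <- unique(grid_records[, c("species_id", "cell_id")])
  recs$temp <- cell_temps$temp[match(recs$cell_id, cell_temps$cell_id)]
  miss <- is.na(recs$temp)
  if (any(miss)) {
    warnf("%d record cell(s) missing from cell_temps; dropped", sum(miss))
    recs <- recs[!miss, ]
  }
  out <- aggregate(temp ~ species_id, data = recs,
                   FUN = mean)
  names(out)[2] <- "sti"
  out$n_cells <- aggregate(cell_id ~ species_id, data = recs, FUN = length)$cell_id
  absent <- setdiff(unique(grid_records$species_id), out$species_id)
  if (length(absent)) {
    warnf("species without any temperature cell: %s",
          paste(absent, collapse = ", "))
    out <- rbind(out, data.frame(species_id = absent, sti = NA_real_, n_cells = 0L))
  }
  out[order(out$species_id), , drop = FALSE]
}

#' Habitat specialisation index
#'
#' The raw index is `1 - n_i / N_group`, where `n_i` is the number of
#' preferred habitats of species `i` and `N_group` the size of the
#' group's habitat universe; it is then min-max rescaled within each
#' insect group so the least specialised species scores 0 and the most
#' specialised scores 1.
#'
#' @param habitats data.frame with columns `species_id`, `group`,
#'   `n_habitats`.
#' @param group_totals named vector: habitat-universe size per group.
#' @return data.frame `species_id`, `group`, `raw`, `specialisation`.
#' @export
habitat_specialisation <- function(habitats, group_totals) {
  N <- group_totals[as.character(habitats$group)]
  if (anyNA(N)) {
    stopf("no habitat-universe size for group(s): %s",
          paste(unique(habitats$group[is.na(N)]), collapse = ", "))
  }
  if (any(N <= 0)) stopf("habitat-universe size must be positive")
  n <- habitats$n_habitats
  if (any(n < 1 | n > N)) stopf("n_habitats must be in [1, N_group] for every species")
  raw <- 1 - n / N
  out <- data.frame(species_id = habitats$species_id, group = habitats$group,
                    raw = as.numeric(raw), specialisation = NA_real_)
  for (g in unique(out$group)) {
    i <- out$group == g
    r <- out$raw[i]
    out$specialisation[i] <- if (length(unique(r)) >= 2L) {
      (r - min(r)) / (max(r) - min(r))
    } else r                                      # degenerate group kept raw
  }
  out
}
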