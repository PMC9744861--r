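# Counterfactual driver scenarios and explained variance of long-term
# trends.
#
# A scenario switches each of the six driver-change variables either to
# its measured trajectory or to "no change": the uncentred change 0,
# which maps to -center/scale in standardized space via the scaling
# constants stored at standardization time.  Predictions are made at
# the replication unit (species x zone x interval) with random effects
# kept at their posterior draw values, back-transformed by
# sign-preserving squaring, summed over the intervals per species and
# zone, and averaged over zones weighted by the number of squares per
# zone, giving a country-wide 40-year occupancy change per species.

#' Enumerate the 17 driver scenarios
#'
#' One null scenario (all six drivers zeroed), six single-driver
#' scenarios, nine climate x land-use pairs, and the full scenario with
#' every driver at its measured trajectory.
#'
#' @param climate,landuse driver names (defaults: the three climate and
#'   three land-use change variables).
#' @return named list of scenarios; each scenario is a list `name`,
#'   `observed` (character vector of drivers following their measured
#'   trajectory).
#' @export
make_scenarios <- function(climate = c("bio1", "bio4", "bio18"),
                           landuse = c("agri_prop", "grass_intensity",
                                       "crop_intensity")) {
  if (length(climate) != 3L || length(landuse) != 3L) {
    stopf("expected 3 climate and 3 land-use drivers")
  }
  sc <- list(list(name = "null", observed = character()))
  for (d in c(climate, landuse)) {
    sc[[length(sc) + 1L]] <- list(name = d, observed = d)
  }
  for (a in climate) for (b in landuse) {
    sc[[length(sc) + 1L]] <- list(name = paste(a, b, sep = "+"),
                                  observed = c(a, b))
  }
  sc[[length(sc) + 1L]] <- list(name = "full", observed = c(climate, landuse))
  stats::setNames(sc, vapply(sc, `[[`, character(1), "name"))
}

# driver table under a scenario: zeroed drivers replaced by the
# standardized image of an uncentred zero change
.scenario_drivers <- function(design, scenario) {
  drv <- design$drivers
  sc <- design$scaling
  all_d <- c(.climate_vars, .landuse_vars)
  unknown <- setdiff(scenario$observed, all_d)
  if (length(unknown)) stopf("unknown driver(s) in scenario: %s",
                             paste(unknown, collapse = ", "))
  for (d in setdiff(all_d, scenario$observed)) {
    i <- match(d, sc$variable)
    if (is.na(i)) stopf("no scaling constants stored for driver '%s'", d)
    drv[[d]] <- rep((0 - sc$center[i]) / sc$scale[i], nrow(drv))
  }
  drv
}

#' Aggregate interval-level values to country-wide long-term changes
#'
#' Back-transforms sign-root scale values (sign-preserving square), sums
#' them over the intervals within each species x zone, and averages over
#' zones weighted by the number of squares per zone.
#'
#' @param design a `trend_design`.
#' @param values vector (one per design row) or rows x draws matrix on
#'   the sign-root scale.
#' @return named vector (or species x draws matrix) of long-term
#'   country-wide occupancy changes.
#' @export
aggregate_longterm <- function(design, values) {
  v <- signed_square(as.matrix(values))
  key <- paste(design$rows$species_id, design$rows$zone, sep = "\r")
  by_sz <- rowsum(v, key, reorder = TRUE)
  sz <- do.call(rbind, strsplit(rownames(by_sz), "\r"))
  w <- design$zone_weights[sz[, 2]]
  num <- rowsum(by_sz * w, sz[, 1], reorder = TRUE)
  den <- rowsum(as.numeric(w), sz[, 1], reorder = TRUE)
  out <- num / as.vector(den)
  if (is.null(dim(values))) stats::setNames(out[, 1], rownames(out)) else out
}

#' Predict long-term species trends under a scenario
#'
#' For each posterior draw of the regression fit, the linear predictor
#' is evaluated at every (species, zone, interval) row with the
#' scenario's driver values (fixed-effect and random-slope driver
#' columns rebuilt; traits, elevation, interval and group terms and all
#' random effects kept at their fitted values), back-transformed and
#' aggregated to a country-wide 40-year change per species.
#'
#' @param fit a `trend_fit` (the agri-associated-species model version
#'   is the intended input for the headline decomposition).
#' @param scenario one element of [make_scenarios()].
#' @param draws optional subset of draw indices (default: all).
#' @return species x draws matrix of predicted long-term changes.
#' @export
predict_scenario <- function(fit, scenario, draws = NULL) {
  design <- fit$design
  drv <- .scenario_drivers(design, scenario)
  ti <- design$traits
  si <- design$species_idx
  elev <- design$Xf[, "elev"]
  dc <- .driver_columns(design$rows, drv, ti$niche_s[si], ti$spec_s[si], elev)
  Xs <- design$Xf
  repl <- intersect(colnames(dc), colnames(Xs))
  Xs[, repl] <- dc[, repl]
  Zs <- dc[, colnames(design$Zs), drop = FALSE]
  if (design$version == 1L) {
    nonagri <- !ti$agri_associated[si]
    Xs[nonagri, grepl("agri_prop|grass_intensity", colnames(Xs))] <- 0
    Zs[nonagri, grepl("agri_prop|grass_intensity", colnames(Zs))] <- 0
  }
  if (is.null(draws)) draws <- seq_len(nrow(fit$beta))
  eta <- Xs %*% t(fit$beta[draws, , drop = FALSE]) +
    t(fit$u_zone[draws, design$zone_idx, drop = FALSE])
  Zfull <- cbind(1, Zs)
  for (k in seq_len(ncol(Zfull))) {
    bk <- matrix(fit$b[draws, si, k], nrow = length(draws), ncol = length(si))
    eta <- eta + Zfull[, k] * t(bk)
  }
  aggregate_longterm(design, eta)
}

#' Per-draw explained variance of a scenario
#'
#' Squared Pearson correlation between predicted and observed long-term
#' species changes, per posterior draw.  Draws in which the predictions
#' have zero variance get R-squared 0 (with a warning).
#'
#' @param predicted species x draws matrix from [predict_scenario()].
#' @param observed named vector of observed long-term changes (same
#'   species order).
#' @param level HDI levels for the summary (default c(0.8, 0.95)).
#' @return list: `r2` (per-draw vector), `mean`, `hdi80`, `hdi95`.
#' @export
scenario_r2 <- function(predicted, observed, level = c(0.8, 0.95)) {
  predicted <- as.matrix(predicted)
  if (nrow(predicted) < 3L) stopf("scenario R2 needs at least 3 species")
  if (!is.null(names(observed)) && !is.null(rownames(predicted))) {
    observed <- observed[rownames(predicted)]
  }
  if (anyNA(observed)) stopf("observed changes missing for some species")
  sdp <- apply(predicted, 2, stats::sd)
  r2 <- rep(0, ncol(predicted))
  ok <- is.finite(sdp) & sdp > 0
  if (!all(ok)) warnf("%d draw(s) with zero prediction variance: R2 set to 0", sum(!ok))
  if (stats::sd(observed) == 0) {
    warnf("observed changes have zero variance: R2 set to 0")
  } else if (any(ok)) {
    r2[ok] <- drop(stats::cor(observed, predicted[, ok, drop = FALSE]))^2
  }
  out <- list(r2 = r2, mean = mean(r2))
  if (length(r2) >= 100) {
    out$hdi80 <- hdi(r2, level[1])
    out$hdi95 <- hdi(r2, level[2])
  }
  out
}

#' Run all scenarios against observed long-term trends
#'
#' @param fit a `trend_fit`.
#' @param observed named vector of observed long-term species changes
#'   (e.g. `aggregate_longterm(design, design$y)`).
#' @param scenarios from [make_scenarios()] (default: all 17).
#' @param draws optional draw subset passed to [predict_scenario()].
#' @return data.frame: scenario, mean R2, HDI bounds.
#' @export
run_scenarios <- function(fit, observed, scenarios = make_scenarios(),
                          draws = NULL) {
  rows <- lapply(scenarios, function(sc) {
    pred <- predict_scenario(fit, sc, draws = draws)
    r2 <- scenario_r2(pred, observed)
    data.frame(scenario = sc$name, mean_r2 = r2$mean,
               hdi80_lower = if (!is.null(r2$hdi80)) r2$hdi80[1] else NA_real_,
               hdi80_upper = if (!is.null(r2$hdi80)) r2$hdi80[2] else NA_real_,
               hdi95_lower = if (!is.null(r2$hdi95)) r2$hdi95[1] else NA_real_,
               hdi95_upper = if (!is.null(r2$hdi95)) r2$hdi95[2] else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
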