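test_that("the design matrix has the enumerated column structure", {
  drv <- make_driver_table(1, zones = c("A_low", "A_high", "B_low"), n_intervals = 8)
  traits <- make_traits(2, 12, groups = c("butterfly", "grasshopper", "dragonfly"))
  traits$agri_associated[traits$group == "dragonfly"] <- FALSE
  trends <- expand.grid(species_id = traits$species_id,
                        zone = c("A_low", "A_high", "B_low"),
                        interval = 1:8, stringsAsFactors = FALSE)
  trends$response <- stats::rnorm(nrow(trends), 0, 0.1)
  d <- build_design(trends, drv, traits, version = 3)
  # hand enumeration: intercept (1) + drivers (6) + traits (2) + elev (1)
  # + elev x climate/agri/grass (5) + elev x traits (2) + climate x landuse (9)
  # + niche x climate (3) + specialisation x landuse (3)
  # + interval contrasts (7) + group contrasts (2) = 41
  expect_equal(ncol(d$Xf), 41)
  expect_false("elev:crop_intensity" %in% colnames(d$Xf))
  expect_equal(ncol(d$Zs), 15)       # 6 drivers + 9 driver x driver
  # sum-to-zero coding: contrast columns sum to zero over a balanced factor
  expect_equal(unname(colSums(d$Xf[, grep("^interval_s", colnames(d$Xf))])),
               rep(0, 7))
  # pinned coding values: first interval level is +1 on its own contrast
  r1 <- d$rows$interval == 1
  expect_true(all(d$Xf[r1, "interval_s1"] == 1))
  r8 <- d$rows$interval == 8
  expect_true(all(d$Xf[r8, "interval_s1"] == -1))
  # elevation is coded -0.5 / +0.5
  expect_setequal(unique(d$Xf[, "elev"]), c(-0.5, 0.5))
})

test_that("model versions restrict agricultural parameters as specified", {
  drv <- make_driver_table(3, zones = c("A_low", "B_high"), n_intervals = 4)
  traits <- make_traits(4, 10, groups = c("butterfly", "dragonfly"))
  traits$agri_associated <- traits$group == "butterfly"
  trends <- expand.grid(species_id = traits$species_id,
                        zone = c("A_low", "B_high"), interval = 1:4,
                        stringsAsFactors = FALSE)
  trends$response <- 0
  d1 <- build_design(trends, drv, traits, version = 1)
  nonagri <- !traits$agri_associated[match(d1$rows$species_id, traits$species_id)]
  agri_cols <- grep("agri_prop|grass_intensity", colnames(d1$Xf))
  expect_true(all(d1$Xf[nonagri, agri_cols] == 0))
  # crop-intensity columns stay active for everyone
  expect_gt(min(abs(d1$Xf[nonagri, "crop_intensity"])), 0)
  expect_true(all(d1$Zs[nonagri, grep("agri_prop|grass_intensity",
                                      colnames(d1$Zs))] == 0))
  # version 2 drops non-agri rows entirely
  d2 <- build_design(trends, drv, traits, version = 2)
  n_agri <- sum(traits$agri_associated)
  expect_equal(length(d2$y), n_agri * 2 * 4)
  # version 3 keeps everything active
  d3 <- build_design(trends, drv, traits, version = 3)
  expect_equal(length(d3$y), nrow(trends))
  expect_gt(min(abs(d3$Xf[, "agri_prop"])), 0)
  # orphan keys are reported
  bad <- trends; bad$species_id[1] <- "ghost"
  expect_error(build_design(bad, drv, traits, version = 3), "ghost")
})

test_that("identical standardized covariates give identical designs", {
  # doubling a covariate's raw scale before standardization changes nothing
  zones <- c("A_low", "B_high")
  set.seed(5)
  raw <- expand.grid(zone = zones, interval = 1:4, stringsAsFactors = FALSE)
  for (v in c("bio1", "bio4", "bio18", "agri_prop", "grass_intensity",
              "crop_intensity")) raw[[v]] <- stats::rnorm(nrow(raw))
  raw2 <- raw
  raw2$bio1 <- raw$bio1 * 2
  traits <- make_traits(6, 5)
  trends <- expand.grid(species_id = traits$species_id, zone = zones,
                        interval = 1:4, stringsAsFactors = FALSE)
  trends$response <- stats::rnorm(nrow(trends))
  d1 <- build_design(trends, standardize_changes(raw), traits, version = 3)
  d2 <- build_design(trends, standardize_changes(raw2), traits, version = 3)
  expect_equal(d1$Xf, d2$Xf, tolerance = 1e-12)
  expect_equal(d1$Zs, d2$Zs, tolerance = 1e-12)
})

test_that("the regression recovers known coefficients on simulated data", {
  drv <- make_driver_table(11, zones = paste0(c("A", "B", "C", "D"),
                                              rep(c("_low", "_high"), 2)),
                           n_intervals = 8)
  ns <- 40
  traits <- make_traits(12, ns, agri = TRUE)
  trends <- expand.grid(species_id = traits$species_id,
                        zone = unique(drv$zone), interval = 1:8,
                        stringsAsFactors = FALSE)
  trends$response <- 0
  design <- build_design(trends, drv, traits, version = 3)
  set.seed(13)
  beta <- stats::setNames(numeric(ncol(design$Xf)), colnames(design$Xf))
  beta["bio1"] <- -0.5
  beta["elev:grass_intensity"] <- -0.3
  b <- cbind(stats::rnorm(ns, 0, 0.05), matrix(0, ns, 15))
  design$y <- drop(design$Xf %*% beta) +
    rowSums(cbind(1, design$Zs) * b[design$species_idx, ]) +
    stats::rnorm(length(design$y), 0, 0.1)
  fit <- fit_trend_regression(design, iter = 300, warmup = 200, chains = 2,
                              seed = 17)
  ci_bio1 <- hdi(fit$beta[, "bio1"])
  expect_true(ci_bio1[1] <= -0.5 && -0.5 <= ci_bio1[2])
  ci_eg <- hdi(fit$beta[, "elev:grass_intensity"])
  expect_true(ci_eg[1] <= -0.3 && -0.3 <= ci_eg[2])
  zero_terms <- setdiff(colnames(fit$beta),
                        c("bio1", "elev:grass_intensity", "(Intercept)"))
  expect_lt(max(abs(colMeans(fit$beta[, zero_terms]))), 0.1)
})

test_that("an all-zero response concentrates every effect near zero", {
  # enough zone x interval combinations that the driver columns are not
  # collinear, otherwise null-space directions just follow the prior
  zones <- paste0(c("A", "B", "C", "D", "E", "F", "G", "H", "I"), "_low")
  drv <- make_driver_table(14, zones = zones, n_intervals = 8)
  traits <- make_traits(15, 8)
  trends <- expand.grid(species_id = traits$species_id,
                        zone = zones, interval = 1:8,
                        stringsAsFactors = FALSE)
  trends$response <- 0
  design <- build_design(trends, drv, traits, version = 3)
  fit <- fit_trend_regression(design, iter = 300, warmup = 300, chains = 1,
                              seed = 19)
  # the intercept trades off against the zone and species random
  # intercepts along a prior-regularized ridge, so it is excluded here
  slopes <- setdiff(colnames(fit$beta), "(Intercept)")
  expect_lt(max(abs(colMeans(fit$beta[, slopes]))), 0.1)
  expect_lt(mean(fit$sigma[, "sigma_e"]), 0.05)
})

test_that("sensitivity filters remove the specified rows", {
  drv <- make_driver_table(21, zones = c("A_low", "B_high"), n_intervals = 4)
  traits <- make_traits(22, 10, groups = "butterfly")
  traits$flag_excluded <- c(TRUE, rep(FALSE, 9))
  trends <- expand.grid(species_id = traits$species_id,
                        zone = c("A_low", "B_high"), interval = 1:4,
                        stringsAsFactors = FALSE)
  trends$response <- stats::rnorm(nrow(trends))
  design <- build_design(trends, drv, traits, version = 3)
  counts <- expand.grid(species_id = traits$species_id,
                        zone = c("A_low", "B_high"), stringsAsFactors = FALSE)
  counts$n_records <- c(40L, rep(100L, 9), rep(120L, 10))
  # species mode: the flagged species and the 20% with fewest records
  fs <- sensitivity_filter(design, "species", counts)
  gone_sp <- setdiff(traits$species_id, unique(fs$rows$species_id))
  expect_true(traits$species_id[1] %in% gone_sp)       # flagged
  expect_equal(length(gone_sp), 2)                      # flagged + 2 lowest overlap
  # species-zone mode: the 40-record combination drops below threshold 41
  fz <- sensitivity_filter(design, "species_zone", counts)
  expect_false(any(fz$rows$species_id == traits$species_id[1] &
                     fz$rows$zone == "A_low"))
  expect_true(any(fz$rows$species_id == traits$species_id[1] &
                    fz$rows$zone == "B_high"))
  expect_equal(length(fz$y), nrow(trends) - 4)
  counts$n_records <- 0L
  expect_error(sensitivity_filter(design, "species_zone", counts), "every row")
})
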