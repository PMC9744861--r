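test_that("marginal likelihood has its closed forms on one site-year", {
  frame <- data.frame(square_id = "s1", zone = "A_low", region = "A",
                      elev_class = "low", fine_region = "a1", elevation = 500)
  mk <- function(y) {
    hist <- data.frame(visit_id = c("v1", "v2"), square_id = "s1",
                       zone = "A_low", year = 2000L, y = y, yday_s = 0,
                       list_class = list_length_class(c(1, 1)),
                       source_class = factor("naturalist", levels = source_levels()))
    attr(hist, "species_id") <- "t"
    occu_design(hist, frame, years = 2000:2001)
  }
  params <- list(mu_o = 0, mu_d = 0)          # psi = p = 0.5
  # y = (0,0): 0.5 * 0.25 + 0.5 = 0.625
  expect_equal(marginal_loglik(mk(c(0L, 0L)), params), log(0.625), tolerance = 1e-12)
  # y = (1,0): 0.5 * 0.25 = 0.125
  expect_equal(marginal_loglik(mk(c(1L, 0L)), params), log(0.125), tolerance = 1e-12)
  # non-finite predictors are rejected with a location
  expect_error(marginal_loglik(mk(c(0L, 0L)), list(mu_o = Inf, mu_d = 0)),
               "non-finite")
})

test_that("marginal likelihood equals the enumeration oracle on tiny instances", {
  checked <- 0
  for (seed in 1:100) {
    inst <- make_tiny_instance(seed)
    if (is.null(inst)) next
    checked <- checked + 1
    expect_equal(marginal_loglik(inst$design, inst$params),
                 enumerate_loglik(inst$design, inst$params),
                 tolerance = 1e-12)
  }
  expect_gt(checked, 80)
})

test_that("marginal likelihood is invariant to visit order within site-years", {
  inst <- make_tiny_instance(7)
  d <- inst$design
  perm <- sample(nrow(d$visits))
  d2 <- d
  d2$visits <- d$visits[perm, ]
  d2$X <- d$X[perm, , drop = FALSE]
  expect_equal(marginal_loglik(d, inst$params), marginal_loglik(d2, inst$params),
               tolerance = 1e-12)
})

test_that("occupancy fits are reproducible and saturate on all-ones data", {
  cd <- make_const_history(1, S = 15, T = 3, J = 2)
  d <- occu_design(cd$hist, cd$frame, years = 2000:2002)
  f1 <- fit_occupancy_model(d, chains = 2, adapt = 100, burnin = 50, iter = 100,
                            seed = 4, terms = character(0))
  f2 <- fit_occupancy_model(d, chains = 2, adapt = 100, burnin = 50, iter = 100,
                            seed = 4, terms = character(0))
  expect_identical(as.matrix(f1$samples), as.matrix(f2$samples))
  # every visit a detection: derived occupancy concentrates near 1
  cd1 <- cd
  cd1$hist$y <- 1L
  d1 <- occu_design(cd1$hist, cd1$frame, years = 2000:2002)
  fs <- fit_occupancy_model(d1, chains = 2, adapt = 100, burnin = 100, iter = 200,
                            seed = 5, terms = character(0))
  ser <- derive_mean_occupancy(fs)
  expect_gt(mean(ser$country > 0.95), 0.5)
})

test_that("derived mean occupancy equals the hand-computed weighted mean", {
  # 2 zones, 4 squares (3 in A, 1 in B), known constant parameters
  frame <- data.frame(square_id = paste0("s", 1:4),
                      zone = c("A_low", "A_low", "A_low", "B_high"),
                      region = "A", elev_class = c("low", "low", "low", "high"),
                      fine_region = "a1", elevation = c(400, 600, 800, 1200))
  hist <- data.frame(visit_id = c("v1", "v2"), square_id = c("s1", "s4"),
                     zone = c("A_low", "B_high"), year = 2000L, y = c(1L, 1L),
                     yday_s = 0, list_class = list_length_class(c(1, 1)),
                     source_class = factor("naturalist", levels = source_levels()))
  attr(hist, "species_id") <- "t"
  design <- occu_design(hist, frame, years = 2000:2001)
  # fabricate a two-chain posterior of constant draws
  draws <- cbind("mu_o" = rep(0.4, 50), "b_o1" = 0.3, "b_o2" = -0.2,
                 "gam[1,1]" = 0.1, "gam[1,2]" = -0.1,
                 "gam[2,1]" = 0.2, "gam[2,2]" = 0, "mu_d" = 0)
  fit <- structure(list(
    samples = coda::mcmc.list(coda::mcmc(draws[1:25, ]), coda::mcmc(draws[26:50, ])),
    design = design, terms = c("elev", "rw")), class = "occu_fit")
  ser <- derive_mean_occupancy(fit)
  e <- design$sites$elev_s
  lp <- 0.4 + 0.3 * e - 0.2 * e^2
  zi <- match(design$sites$zone, design$zones)
  gam <- rbind(c(0.1, -0.1), c(0.2, 0))
  psi <- plogis(outer(lp, rep(1, 2)) + gam[zi, ])
  expect_equal(unname(ser$zone[1, "A_low", ]), unname(colMeans(psi[1:3, ])),
               tolerance = 1e-12)
  expect_equal(unname(ser$zone[1, "B_high", ]), unname(psi[4, ]), tolerance = 1e-12)
  expect_equal(unname(ser$country[1, ]), unname(colSums(psi) / 4), tolerance = 1e-12)
  # all psi forced to ~1: series identically ~1
  draws1 <- draws; draws1[, "mu_o"] <- 50; draws1[, c("b_o1", "b_o2")] <- 0
  fit1 <- fit
  fit1$samples <- coda::mcmc.list(coda::mcmc(draws1[1:25, ]), coda::mcmc(draws1[26:50, ]))
  expect_equal(unname(derive_mean_occupancy(fit1)$country[1, ]), c(1, 1),
               tolerance = 1e-10)
})

test_that("a species confined to a quarter of the landscape scores 0.25", {
  frame <- data.frame(square_id = paste0("s", 1:8),
                      zone = rep(c("A_low", "B_low", "C_low", "D_low"), each = 2),
                      region = "R", elev_class = "low", fine_region = "r1",
                      elevation = 500)
  hist <- data.frame(visit_id = "v1", square_id = "s1", zone = "A_low",
                     year = 2000L, y = 1L, yday_s = 0,
                     list_class = list_length_class(1),
                     source_class = factor("naturalist", levels = source_levels()))
  attr(hist, "species_id") <- "t"
  design <- occu_design(hist, frame, years = 2000:2001)
  expect_equal(nrow(design$sites), 2)          # only the occupied zone
  expect_equal(design$n_group_squares, 8)
  draws <- cbind("mu_o" = rep(50, 50), "mu_d" = 0)
  fit <- structure(list(samples = coda::mcmc.list(coda::mcmc(draws)),
                        design = design, terms = character(0)),
                   class = "occu_fit")
  ser <- derive_mean_occupancy(fit)
  expect_equal(unname(ser$country[1, ]), c(0.25, 0.25), tolerance = 1e-10)
})

test_that("split R-hat separates mixed from shifted chains", {
  set.seed(12)
  same <- matrix(stats::rnorm(2000), 1000, 2)
  expect_lt(split_rhat(same), 1.05)
  shifted <- cbind(stats::rnorm(1000), stats::rnorm(1000, 3))
  expect_gt(split_rhat(shifted), 1.1)
  # constant chains are perfectly converged
  expect_equal(split_rhat(matrix(1, 100, 2)), 1)
})

test_that("convergence report counts the sub-threshold fraction", {
  set.seed(13)
  nz <- 2; Tn <- 3
  mk_series <- function(shift_zone1) {
    zone <- array(stats::rnorm(400 * nz * Tn), c(400, nz, Tn),
                  dimnames = list(NULL, c("A", "B"), 2000:2002))
    if (shift_zone1) zone[201:400, 1, ] <- zone[201:400, 1, ] + 5
    structure(list(zone = zone,
                   country = matrix(stats::rnorm(400 * Tn), 400, Tn,
                                    dimnames = list(NULL, 2000:2002)),
                   chain = rep(1:2, each = 200), years = 2000:2002),
              class = "occu_series")
  }
  good <- check_convergence(mk_series(FALSE))
  expect_true(good$available)
  expect_equal(good$fraction_ok, 1)
  bad <- check_convergence(mk_series(TRUE))
  # zone A rows (3 of 9 diagnostics) fail
  expect_equal(bad$fraction_ok, 6 / 9, tolerance = 1e-12)
  one <- mk_series(FALSE); one$chain <- rep(1L, 400)
  expect_false(check_convergence(one)$available)
})

test_that("the fitted model corrects naive occupancy upward", {
  cd <- make_const_history(3, S = 60, T = 6, J = 2, psi = 0.6, p = 0.5)
  d <- occu_design(cd$hist, cd$frame, years = 2000:2005)
  fit <- fit_occupancy_model(d, chains = 2, adapt = 100, burnin = 100,
                             iter = 300, seed = 6, terms = character(0))
  ser <- derive_mean_occupancy(fit)
  est <- mean(ser$country)
  expect_gt(est, cd$naive)
  expect_lt(abs(est - 0.6), 0.08)
})
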