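# Shared fixture builders for the test suite.

# detection history with constant occupancy/detection on a 1-zone frame
make_const_history <- function(seed, S = 100, T = 10, J = 3, psi = 0.7, p = 0.8) {
  set.seed(seed)
  frame <- data.frame(square_id = sprintf("sq%03d", seq_len(S)), zone = "Z_low",
                      region = "Z", elev_class = "low", fine_region = "Z1",
                      elevation = stats::runif(S, 300, 900))
  z <- matrix(stats::rbinom(S * T, 1, psi), S, T)
  g <- expand.grid(i = seq_len(S), t = seq_len(T), j = seq_len(J))
  y <- stats::rbinom(nrow(g), 1, z[cbind(g$i, g$t)] * p)
  hist <- data.frame(visit_id = sprintf("v%05d", seq_len(nrow(g))),
                     square_id = frame$square_id[g$i], zone = "Z_low",
                     year = 1999L + g$t, y = y, yday_s = 0,
                     list_class = list_length_class(rep(1, nrow(g))),
                     source_class = factor("naturalist", levels = source_levels()))
  attr(hist, "species_id") <- "const"
  list(frame = frame, hist = hist, z = z,
       naive = mean(tapply(y, paste(g$i, g$t), max)))
}

# random tiny occupancy instance for the enumeration oracle
make_tiny_instance <- function(seed) {
  set.seed(seed)
  S <- sample(1:3, 1); T <- sample(1:3, 1)
  frame <- data.frame(square_id = sprintf("s%d", seq_len(S)),
                      zone = sample(c("A_low", "B_high"), S, replace = TRUE),
                      region = "R", elev_class = "low",
                      fine_region = sample(c("r1", "r2"), S, replace = TRUE),
                      elevation = stats::runif(S, 300, 1500))
  rows <- list()
  vid <- 0
  for (i in seq_len(S)) for (t in seq_len(T)) {
    nv <- sample(0:3, 1)
    if (nv == 0) next
    for (j in seq_len(nv)) {
      vid <- vid + 1
      rows[[vid]] <- data.frame(
        visit_id = sprintf("v%03d", vid), square_id = frame$square_id[i],
        zone = frame$zone[i], year = 2000L + t,
        y = stats::rbinom(1, 1, 0.4), yday_s = stats::rnorm(1),
        list_class = list_length_class(sample(1:5, 1)),
        source_class = factor(sample(source_levels(), 1),
                              levels = source_levels()))
    }
  }
  if (!length(rows)) return(NULL)
  hist <- do.call(rbind, rows)
  attr(hist, "species_id") <- "tiny"
  design <- occu_design(hist, frame, years = 2001:(2000 + T))
  params <- list(
    mu_o = stats::rnorm(1), b_o1 = stats::rnorm(1, 0, 0.5),
    b_o2 = stats::rnorm(1, 0, 0.5),
    a_region = stats::setNames(stats::rnorm(2, 0, 0.5), c("r1", "r2")),
    a_square = stats::setNames(stats::rnorm(S, 0, 0.5), frame$square_id),
    gamma = matrix(stats::rnorm(length(design$zones) * T, 0, 0.5),
                   length(design$zones), T),
    mu_d = stats::rnorm(1),
    b_d = stats::rnorm(8, 0, 0.5),
    a_d1 = stats::rnorm(T, 0, 0.5))
  list(design = design, params = params)
}

# brute-force marginal likelihood: sum over every latent configuration
enumerate_loglik <- function(design, params) {
  s <- design$sites
  zidx <- match(s$zone, design$zones)
  lp_occ <- params$mu_o + params$b_o1 * s$elev_s + params$b_o2 * s$elev_s^2 +
    params$a_region[s$fine_region] + params$a_square[s$square_id]
  v <- design$visits
  p_det <- plogis(params$mu_d + drop(design$X %*% params$b_d) + params$a_d1[v$t])
  key <- unique(data.frame(site = v$site, t = v$t))
  Q <- nrow(key)
  total <- 0
  for (q in seq_len(Q)) {
    rows <- v$site == key$site[q] & v$t == key$t[q]
    psi <- plogis(lp_occ[key$site[q]] + params$gamma[zidx[key$site[q]], key$t[q]])
    lik <- 0
    for (z in 0:1) {
      obs <- if (z == 1) prod(ifelse(v$y[rows] == 1, p_det[rows], 1 - p_det[rows]))
             else as.numeric(all(v$y[rows] == 0))
      lik <- lik + (if (z == 1) psi else 1 - psi) * obs
    }
    total <- total + log(unname(lik))
  }
  total
}

# small driver table with standardized changes over zones x intervals
make_driver_table <- function(seed, zones = c("A_low", "A_high", "B_low"),
                              n_intervals = 8) {
  set.seed(seed)
  drv <- expand.grid(zone = zones, interval = seq_len(n_intervals),
                     stringsAsFactors = FALSE)
  for (v in c("bio1", "bio4", "bio18", "agri_prop", "grass_intensity",
              "crop_intensity")) {
    drv[[v]] <- stats::rnorm(nrow(drv))
  }
  standardize_changes(drv)
}

make_traits <- function(seed, ns, groups = c("butterfly", "grasshopper"),
                        agri = NULL) {
  set.seed(seed)
  data.frame(species_id = sprintf("sp%03d", seq_len(ns)),
             group = sample(groups, ns, replace = TRUE),
             niche = stats::rnorm(ns, 9, 2),
             specialisation = stats::runif(ns),
             agri_associated = if (is.null(agri)) stats::runif(ns) < 0.7 else agri,
             flag_excluded = FALSE)
}
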