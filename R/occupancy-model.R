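# Per-species hierarchical occupancy-detection model.
#
# Ecological process: latent presence z[i,t] ~ Bern(psi[i,t]) with
# logit(psi) = intercept + elevation (linear + quadratic) + fine-region
# and square random effects + a zone-year effect following independent
# random walks per bioclimatic zone.  Observation process: detection
# y[i,t,j] | z ~ Bern(z * p[i,t,j]) with logit(p) = intercept + day of
# year (linear + quadratic) + list-length class + five-level source
# class + a year random effect.  Fitting is by Gibbs sampling in JAGS;
# presence is fixed at 1 (as data) for site-years with a detection and
# sampled for the remaining visited site-years.  Occupancy is derived
# from the parameter draws for every included square-year, so unvisited
# square-years never enter the likelihood but are predicted.

#' Detection design matrix of a detection history
#'
#' Fixed 8-column layout: scaled day of year, its square, list-length
#' dummies (2-3, >3) and source dummies (expert, project,
#' targeted_project, redlist).
#'
#' @param hist DetectionHistory from [build_detection_histories()].
#' @return numeric matrix with one row per visit.
#' @export
detection_matrix <- function(hist) {
  cbind(yday = hist$yday_s,
        yday2 = hist$yday_s^2,
        shortlist = as.numeric(hist$list_class == "2-3"),
        longlist = as.numeric(hist$list_class == ">3"),
        expert = as.numeric(hist$source_class == "expert"),
        project = as.numeric(hist$source_class == "project"),
        targeted_project = as.numeric(hist$source_class == "targeted_project"),
        redlist = as.numeric(hist$source_class == "redlist"))
}

#' Assemble the occupancy model design for one species
#'
#' Sites are the group-dataset squares within the species' occupied
#' zones; elevation is scaled to mean 0, SD 1 over those squares.  Years
#' span the supplied range (including any warm-up years present in the
#' history).  Visits index into sites and years.
#'
#' @param hist DetectionHistory.
#' @param frame StudyFrame.
#' @param years calendar years of the model (default: range of the
#'   history's years).
#' @param group_squares square ids making up the group dataset (for the
#'   country-wide denominator; default: all squares in `frame`).
#' @return list of class `occu_design`.
#' @export
occu_design <- function(hist, frame, years = NULL, group_squares = NULL) {
  if (is.null(years)) years <- seq(min(hist$year), max(hist$year))
  if (is.null(group_squares)) group_squares <- frame$square_id
  zones <- sort(unique(hist$zone))
  sites <- frame[frame$zone %in% zones & frame$square_id %in% group_squares, ,
                 drop = FALSE]
  sites <- sites[order(sites$square_id), ]
  sites$elev_s <- if (nrow(sites) > 1L && stats::sd(sites$elevation) > 0) {
    as.numeric(scale(sites$elevation))
  } else {
    rep(0, nrow(sites))
  }
  sites$site <- seq_len(nrow(sites))
  site_of <- stats::setNames(sites$site, sites$square_id)
  t_of <- match(hist$year, years)
  if (anyNA(t_of)) stopf("detection history has years outside the design range")
  s_of <- site_of[hist$square_id]
  if (anyNA(s_of)) stopf("detection history references squares outside the design sites")
  visits <- data.frame(site = as.integer(s_of), t = t_of, y = hist$y)
  structure(list(
    species_id = attr(hist, "species_id"),
    sites = sites, years = years, T = length(years),
    zones = zones, regions = sort(unique(sites$fine_region)),
    visits = visits, X = detection_matrix(hist),
    n_group_squares = length(unique(group_squares))),
    class = "occu_design")
}

#' Default priors of the occupancy-detection model
#'
#' Intercepts and slopes Normal(0, 1.5^2) (an SD of 1.5 avoids
#' overweighting extreme probabilities through the logit link);
#' hierarchical SDs half-Normal(0, 1) except the random-walk innovation
#' SDs, which are half-Cauchy(0, 1); first-year zone effects
#' Normal(0, 1.5^2).
#'
#' @param sd_intercept,sd_slope,sd_sd,sd_gamma1,cauchy_scale prior
#'   scales, all configurable.
#' @return named list of prior scales.
#' @export
occu_priors <- function(sd_intercept = 1.5, sd_slope = 1.5, sd_sd = 1,
                        sd_gamma1 = 1.5, cauchy_scale = 1) {
  list(sd_intercept = sd_intercept, sd_slope = sd_slope, sd_sd = sd_sd,
       sd_gamma1 = sd_gamma1, cauchy_scale = cauchy_scale)
}

#' Exact marginal log-likelihood of the occupancy-detection model
#'
#' The latent presence state is summed out analytically: each visited
#' site-year contributes
#' `log(psi * prod_j Bern(y_j | p_j) + (1 - psi) * 1(all y_j = 0))`;
#' site-years with no visits contribute 0.
#'
#' @param design an `occu_design`.
#' @param params named list: `mu_o`, `b_o1`, `b_o2`, `a_region` (named
#'   by fine region), `a_square` (named by square id), `gamma` (zones x
#'   years matrix), `mu_d`, `b_d` (length-8 detection slopes), `a_d1`
#'   (per-year detection effects).  Missing components default to zero.
#' @return the marginal log-likelihood (scalar).
#' @export
marginal_loglik <- function(design, params) {
  gv <- function(x, default) if (is.null(x)) default else x
  s <- design$sites
  p <- params
  lp_occ <- gv(p$mu_o, 0) +
    gv(p$b_o1, 0) * s$elev_s + gv(p$b_o2, 0) * s$elev_s^2
  if (!is.null(p$a_region)) lp_occ <- lp_occ + p$a_region[s$fine_region]
  if (!is.null(p$a_square)) lp_occ <- lp_occ + p$a_square[s$square_id]
  zidx <- match(s$zone, design$zones)
  v <- design$visits
  lp_psi_vis <- lp_occ[v$site] +
    if (!is.null(p$gamma)) p$gamma[cbind(zidx[v$site], v$t)] else 0
  lp_det <- gv(p$mu_d, 0) +
    (if (!is.null(p$b_d)) drop(design$X %*% p$b_d) else 0) +
    (if (!is.null(p$a_d1)) p$a_d1[v$t] else 0)
  if (any(!is.finite(lp_psi_vis))) {
    stopf("non-finite occupancy linear predictor at visit %d",
          which(!is.finite(lp_psi_vis))[1])
  }
  if (any(!is.finite(lp_det))) {
    stopf("non-finite detection linear predictor at visit %d",
          which(!is.finite(lp_det))[1])
  }
  # per site-year: log(psi * prod(Bern) + (1 - psi) * all-zero)
  key <- paste(v$site, v$t)
  grp <- match(key, unique(key))
  log_p_terms <- stats::dbinom(v$y, 1, ilogit(lp_det), log = TRUE)
  sum_log_p <- as.numeric(tapply(log_p_terms, grp, sum))
  any_det <- as.numeric(tapply(v$y, grp, max)) > 0
  first <- !duplicated(grp)
  psi_q <- ilogit(lp_psi_vis[first])
  ll_q <- ifelse(any_det,
                 log(psi_q) + sum_log_p,
                 log(psi_q * exp(sum_log_p) + (1 - psi_q)))
  sum(ll_q)
}

# build the JAGS model string for the requested term set
.jags_occu_model <- function(terms, priors) {
  pi <- 1 / priors$sd_intercept^2
  ps <- 1 / priors$sd_slope^2
  pv <- 1 / priors$sd_sd^2
  pg1 <- 1 / priors$sd_gamma1^2
  pc <- 1 / priors$cauchy_scale^2
  occ <- "mu_o"
  det <- "mu_d"
  blocks <- c(
    sprintf("  mu_o ~ dnorm(0, %g)", pi),
    sprintf("  mu_d ~ dnorm(0, %g)", pi))
  if ("elev" %in% terms) {
    blocks <- c(blocks,
      sprintf("  b_o1 ~ dnorm(0, %g)", ps),
      sprintf("  b_o2 ~ dnorm(0, %g)", ps))
    occ <- paste(occ, "+ b_o1*elev[qsite[q]] + b_o2*elev2[qsite[q]]")
  }
  if ("region" %in% terms) {
    blocks <- c(blocks,
      sprintf("  sig_o1 ~ dnorm(0, %g) T(0,)", pv),
      "  for (g in 1:Nreg) { a_o1[g] ~ dnorm(0, 1/sig_o1^2) }")
    occ <- paste(occ, "+ a_o1[reg[qsite[q]]]")
  }
  if ("square" %in% terms) {
    blocks <- c(blocks,
      sprintf("  sig_o2 ~ dnorm(0, %g) T(0,)", pv),
      "  for (i in 1:S) { a_o2[i] ~ dnorm(0, 1/sig_o2^2) }")
    occ <- paste(occ, "+ a_o2[qsite[q]]")
  }
  if ("rw" %in% terms) {
    blocks <- c(blocks,
      "  for (r in 1:R) {",
      sprintf("    sig_g[r] ~ dt(0, %g, 1) T(0,)", pc),
      sprintf("    gam[r,1] ~ dnorm(0, %g)", pg1),
      "    for (t in 2:T) { gam[r,t] ~ dnorm(gam[r,t-1], 1/sig_g[r]^2) }",
      "  }")
    occ <- paste(occ, "+ gam[qzone[q], qyear[q]]")
  }
  if ("det_covs" %in% terms) {
    blocks <- c(blocks,
      sprintf("  for (k in 1:K) { b_d[k] ~ dnorm(0, %g) }", ps))
    det <- paste(det, "+ inprod(X[v,], b_d)")
  }
  if ("det_year" %in% terms) {
    blocks <- c(blocks,
      sprintf("  sig_d1 ~ dnorm(0, %g) T(0,)", pv),
      "  for (t in 1:T) { a_d1[t] ~ dnorm(0, 1/sig_d1^2) }")
    det <- paste(det, "+ a_d1[vyear[v]]")
  }
  paste(c("model {", blocks,
          "  for (q in 1:Q) {",
          sprintf("    logit(psi[q]) <- %s", occ),
          "    z[q] ~ dbern(psi[q])",
          "  }",
          "  for (v in 1:V) {",
          sprintf("    logit(p[v]) <- %s", det),
          "    y[v] ~ dbern(z[qv[v]] * p[v])",
          "  }",
          "}"), collapse = "\n")
}

#' Fit the occupancy-detection model
#'
#' Gibbs sampling via JAGS.  Latent presence is supplied as data (1)
#' for site-years with at least one detection and sampled elsewhere.
#' Model terms can be switched off individually (e.g. for reduced
#' intercept-only fits on small simulations); by default the full
#' structure is fitted.
#'
#' @param design an `occu_design`.
#' @param priors from [occu_priors()].
#' @param chains,adapt,burnin,iter,thin MCMC settings (defaults 4
#'   chains, 2000 iterations of which 1000 warm-up: `adapt` 500 +
#'   `burnin` 500, `iter` 1000 retained).
#' @param seed integer seed; chain RNGs are derived deterministically
#'   from it, so equal seeds give identical draws.
#' @param terms character subset of `c("elev", "region", "square",
#'   "rw", "det_covs", "det_year")`.
#' @param quiet suppress JAGS progress output.
#' @return list of class `occu_fit`: `samples` (a coda `mcmc.list`),
#'   `design`, `terms`, `mcmc` settings.
#' @export
fit_occupancy_model <- function(design, priors = occu_priors(),
                                chains = 4L, adapt = 500L, burnin = 500L,
                                iter = 1000L, thin = 1L, seed = 1L,
                                terms = c("elev", "region", "square", "rw",
                                          "det_covs", "det_year"),
                                quiet = TRUE) {
  stopifnot(inherits(design, "occu_design"))
  if (design$T < 2L) stopf("design must span at least 2 years")
  if (sum(design$visits$y) < 1L) stopf("design has no detection")
  if (length(terms)) {
    terms <- match.arg(terms, several.ok = TRUE)
  }
  v <- design$visits
  key <- paste(v$site, v$t)
  qid <- match(key, unique(key))
  first <- !duplicated(qid)
  qsite <- v$site[first]
  qyear <- v$t[first]
  zdat <- as.integer(tapply(v$y, qid, max))
  zdat[zdat == 0L] <- NA_integer_
  zinit <- ifelse(is.na(zdat), 1L, NA_integer_)
  zidx <- match(design$sites$zone, design$zones)
  dat <- list(Q = length(qsite), V = nrow(v), S = nrow(design$sites),
              T = design$T, qsite = qsite, qyear = qyear,
              qv = qid, y = v$y, z = zdat)
  if ("elev" %in% terms) {
    dat$elev <- design$sites$elev_s
    dat$elev2 <- design$sites$elev_s^2
  }
  if ("region" %in% terms) {
    dat$Nreg <- length(design$regions)
    dat$reg <- match(design$sites$fine_region, design$regions)
  }
  if ("rw" %in% terms) {
    dat$R <- length(design$zones)
    dat$qzone <- zidx[qsite]
  }
  if ("det_covs" %in% terms) {
    X <- design$X
    keep <- apply(X, 2, function(col) stats::sd(col) > 0)
    X <- X[, keep, drop = FALSE]
    if (ncol(X) == 0L) {
      terms <- setdiff(terms, "det_covs")
    } else {
      dat$X <- X; dat$K <- ncol(X)
    }
  }
  if ("det_year" %in% terms) dat$vyear <- v$t
  model_str <- .jags_occu_model(terms, priors)
  inits <- lapply(seq_len(chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer(seed) * 1000L + ch, z = zinit)
  })
  monitors <- c("mu_o", "mu_d",
                if ("elev" %in% terms) c("b_o1", "b_o2"),
                if ("region" %in% terms) c("a_o1", "sig_o1"),
                if ("square" %in% terms) c("a_o2", "sig_o2"),
                if ("rw" %in% terms) c("gam", "sig_g"),
                if ("det_covs" %in% terms) "b_d",
                if ("det_year" %in% terms) c("a_d1", "sig_d1"))
  run <- function() {
    jm <- rjags::jags.model(textConnection(model_str), data = dat,
                            inits = inits, n.chains = chains,
                            n.adapt = adapt, quiet = TRUE)
    stats::update(jm, burnin, progress.bar = "none")
    rjags::coda.samples(jm, monitors, n.iter = iter, thin = thin,
                        progress.bar = "none")
  }
  samples <- if (quiet) suppressWarnings(run()) else run()
  structure(list(samples = samples, design = design, terms = terms,
                 det_cols = if (!is.null(dat$X)) colnames(dat$X) else NULL,
                 mcmc = list(chains = chains, adapt = adapt, burnin = burnin,
                             iter = iter, thin = thin, seed = seed)),
            class = "occu_fit")
}

#' Derive annual mean occupancy from an occupancy fit
#'
#' For each posterior draw, the occupancy probability is computed for
#' every included square-year; the zone series is the mean over the
#' zone's squares and the country-wide series the sum over all included
#' squares divided by the number of squares in the group dataset (zones
#' without any record of the species thus contribute 0 occupancy).
#'
#' @param fit an `occu_fit`.
#' @return list of class `occu_series`: `zone` (array draw x zone x
#'   year), `country` (matrix draw x year), `chain` (chain index per
#'   draw), `years`.
#' @export
derive_mean_occupancy <- function(fit) {
  design <- fit$design
  draws <- as.matrix(fit$samples)
  nch <- length(fit$samples)
  chain <- rep(seq_len(nch), each = nrow(draws) / nch)
  s <- design$sites
  Tn <- design$T
  zidx <- match(s$zone, design$zones)
  nz <- length(design$zones)
  nsq_zone <- tabulate(zidx, nz)
  cn <- colnames(draws)
  get1 <- function(nm) if (nm %in% cn) draws[, nm] else numeric(nrow(draws))
  getvec <- function(prefix, n) {
    nms <- paste0(prefix, "[", seq_len(n), "]")
    if (all(nms %in% cn)) draws[, nms, drop = FALSE] else
      matrix(0, nrow(draws), n)
  }
  mu <- get1("mu_o")
  b1 <- get1("b_o1"); b2 <- get1("b_o2")
  areg <- getvec("a_o1", length(design$regions))
  asq <- getvec("a_o2", nrow(s))
  has_gam <- any(grepl("^gam\\[", cn))
  regi <- match(s$fine_region, design$regions)
  nd <- nrow(draws)
  zone_arr <- array(NA_real_, c(nd, nz, Tn),
                    dimnames = list(NULL, design$zones, design$years))
  country <- matrix(NA_real_, nd, Tn, dimnames = list(NULL, design$years))
  gam_cols <- if (has_gam)
    outer(seq_len(nz), seq_len(Tn),
          function(r, t) paste0("gam[", r, ",", t, "]")) else NULL
  zsum <- function(x) rowsum(x, zidx, reorder = TRUE)
  for (d in seq_len(nd)) {
    base <- mu[d] + b1[d] * s$elev_s + b2[d] * s$elev_s^2 +
      areg[d, regi] + asq[d, ]
    gam <- if (has_gam) matrix(draws[d, gam_cols], nz, Tn) else matrix(0, nz, Tn)
    lp <- outer(base, rep(1, Tn)) + gam[zidx, , drop = FALSE]
    psi <- ilogit(lp)
    zs <- zsum(psi)
    zone_arr[d, , ] <- zs / nsq_zone
    country[d, ] <- colSums(zs) / design$n_group_squares
  }
  structure(list(zone = zone_arr, country = country, chain = chain,
                 years = design$years),
            class = "occu_series")
}

#' Split-R-hat of chains
#'
#' Potential scale reduction factor with each chain split in half
#' (Gelman-Rubin on 2m half-chains).
#'
#' @param x iterations x chains matrix of draws of one quantity.
#' @return R-hat (NA if fewer than 2 chains or constant draws).
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (ncol(x) < 1L || n < 4L) return(NA_real_)
  h <- floor(n / 2)
  halves <- cbind(x[seq_len(h), , drop = FALSE],
                  x[seq.int(n - h + 1L, n), , drop = FALSE])
  if (ncol(halves) < 2L) return(NA_real_)
  m <- ncol(halves); nn <- nrow(halves)
  W <- mean(apply(halves, 2, stats::var))
  B <- nn * stats::var(colMeans(halves))
  if (!is.finite(W) || W == 0) return(if (B == 0 || !is.finite(B)) 1 else Inf)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Convergence diagnostics of derived mean-occupancy series
#'
#' Split-R-hat for every derived zone-year and country-year mean
#' occupancy value, with the fraction below the standard 1.1 threshold.
#'
#' @param series an `occu_series` from [derive_mean_occupancy()].
#' @param threshold R-hat threshold (default 1.1).
#' @return list: `table` (data.frame scope, zone, year, rhat),
#'   `fraction_ok`, `available`.
#' @export
check_convergence <- function(series, threshold = 1.1) {
  nch <- length(unique(series$chain))
  if (nch < 2L) {
    return(list(table = NULL, fraction_ok = NA_real_, available = FALSE))
  }
  rows <- list()
  for (t in seq_along(series$years)) {
    rows[[length(rows) + 1L]] <- data.frame(
      scope = "country", zone = NA_character_, year = series$years[t],
      rhat = split_rhat(matrix(series$country[, t], ncol = nch)))
    for (z in seq_len(dim(series$zone)[2])) {
      rows[[length(rows) + 1L]] <- data.frame(
        scope = "zone", zone = dimnames(series$zone)[[2]][z],
        year = series$years[t],
        rhat = split_rhat(matrix(series$zone[, z, t], ncol = nch)))
    }
  }
  tab <- do.call(rbind, rows)
  list(table = tab,
       fraction_ok = mean(tab$rhat < threshold, na.rm = TRUE),
       available = TRUE)
}
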