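# Hierarchical regression of sign-root transformed 5-year occupancy
# trends on climate-change and land-use-change covariates, species
# traits and their interactions.
#
# y ~ Normal(Xf %*% beta + u_zone + Z_species %*% b_species, sigma_e^2)
# with independent species random intercepts and random slopes for the
# six drivers and the nine climate x land-use interactions.  Fitting is
# by a blocked Gibbs sampler: fixed effects and each random-effect block
# have conjugate Gaussian full conditionals; standard deviations are
# updated by univariate slice sampling under half-Normal priors.

.climate_vars <- c("bio1", "bio4", "bio18")
.landuse_vars <- c("agri_prop", "grass_intensity", "crop_intensity")
.agri_vars <- c("agri_prop", "grass_intensity")

# sum-to-zero contrast columns of a factor, named lev1..lev(K-1)
.sum_contrasts <- function(f, prefix) {
  f <- droplevels(factor(f))
  K <- nlevels(f)
  if (K < 2L) return(matrix(numeric(0), length(f), 0))
  C <- stats::contr.sum(K)
  M <- C[as.integer(f), , drop = FALSE]
  colnames(M) <- paste0(prefix, "_s", seq_len(K - 1L))
  M
}

# driver-dependent columns for given standardized driver values
# rows: data.frame with zone, interval, species_id; drv: zone x interval
# table of standardized changes; sp: per-row trait/elevation values
.driver_columns <- function(rows, drv, sp_niche, sp_spec, elev) {
  key <- paste(rows$zone, rows$interval)
  dkey <- paste(drv$zone, drv$interval)
  idx <- match(key, dkey)
  if (anyNA(idx)) {
    orphans <- unique(key[is.na(idx)])
    stopf("no driver values for zone x interval: %s",
          paste(utils::head(orphans, 5), collapse = "; "))
  }
  D <- as.matrix(drv[idx, c(.climate_vars, .landuse_vars)])
  main <- D
  colnames(main) <- c(.climate_vars, .landuse_vars)
  ed <- D[, c(.climate_vars, .agri_vars)] * elev
  colnames(ed) <- paste0("elev:", c(.climate_vars, .agri_vars))
  cl <- matrix(NA_real_, nrow(rows), 9)
  cn <- character(9); k <- 0
  for (a in .climate_vars) for (b in .landuse_vars) {
    k <- k + 1
    cl[, k] <- D[, a] * D[, b]
    cn[k] <- paste0(a, ":", b)
  }
  colnames(cl) <- cn
  nc <- D[, .climate_vars] * sp_niche
  colnames(nc) <- paste0("niche:", .climate_vars)
  sl <- D[, .landuse_vars] * sp_spec
  colnames(sl) <- paste0("specialisation:", .landuse_vars)
  cbind(main, ed, cl, nc, sl)
}

#' Build the trend-regression design
#'
#' Assembles response, fixed-effect matrix and random-slope covariates
#' for one of the three model versions: (1) all species, but columns
#' involving agricultural area or grassland-use intensity zeroed for
#' species not associated to agriculturally influenced habitats, so
#' those parameters learn from agri-associated species only; (2) only
#' agri-associated species; (3) all species, all columns active.
#'
#' Fixed effects: intercept; 3 climate + 3 land-use changes; the two
#' traits; elevation class (coded -0.5 low / +0.5 high); elevation
#' interactions with climate, agricultural area, grassland intensity
#' (no elevation x crop intensity: crops are essentially absent at high
#' elevation) and with the traits; the 9 climate x land-use products;
#' temperature niche x climate (3); specialisation x land use (3);
#' sum-to-zero-coded interval factor and group intercept contrasts.
#' Traits are standardized over the species of the input trend table.
#'
#' @param trends data.frame `species_id`, `zone`, `interval`,
#'   `response` (sign-root transformed 5-year occupancy change).
#' @param drivers standardized DriverTable (from
#'   [standardize_changes()]): `zone`, `interval` and the six change
#'   variables, with the `"scaling"` attribute.
#' @param traits data.frame `species_id`, `group`, `niche`,
#'   `specialisation`, `agri_associated` (plus optional flags used by
#'   [sensitivity_filter()]).
#' @param version model version 1, 2 or 3.
#' @param zone_elev named character vector zone -> "low"/"high";
#'   default parses the `_low`/`_high` suffix of the zone label.
#' @param zone_weights named vector of squares per zone, used for the
#'   country-wide aggregation of scenario predictions (default equal).
#' @return list of class `trend_design`.
#' @export
build_design <- function(trends, drivers, traits, version = 1L,
                         zone_elev = NULL, zone_weights = NULL) {
  if (!version %in% 1:3) stopf("version must be 1, 2 or 3")
  orphan <- setdiff(trends$species_id, traits$species_id)
  if (length(orphan)) {
    stopf("species without traits: %s", paste(utils::head(orphan, 5), collapse = ", "))
  }
  ti <- traits[match(unique(trends$species_id), traits$species_id), , drop = FALSE]
  ti$niche_s <- as.numeric(scale(ti$niche))
  ti$spec_s <- if (stats::sd(ti$specialisation) > 0)
    as.numeric(scale(ti$specialisation)) else 0
  rows <- trends
  if (version == 2L) {
    # trait scaling is computed over the full species pool first, so the
    # covariate scale is comparable across model versions
    keep_sp <- ti$species_id[ti$agri_associated]
    rows <- rows[rows$species_id %in% keep_sp, , drop = FALSE]
    if (!nrow(rows)) stopf("version 2 removed every row (no agri-associated species)")
    ti <- ti[ti$agri_associated, , drop = FALSE]
  }
  si <- match(rows$species_id, ti$species_id)
  zones <- sort(unique(rows$zone))
  if (is.null(zone_elev)) {
    zone_elev <- stats::setNames(
      ifelse(grepl("_high$", zones), "high", "low"), zones)
  }
  if (is.null(zone_weights)) zone_weights <- stats::setNames(rep(1, length(zones)), zones)
  elev <- ifelse(zone_elev[rows$zone] == "high", 0.5, -0.5)

  dc <- .driver_columns(rows, drivers, ti$niche_s[si], ti$spec_s[si], elev)
  et <- cbind("elev:niche" = elev * ti$niche_s[si],
              "elev:specialisation" = elev * ti$spec_s[si])
  inter_cols <- dc[, setdiff(colnames(dc),
                             c(.climate_vars, .landuse_vars,
                               paste0("elev:", c(.climate_vars, .agri_vars)))),
                   drop = FALSE]
  Xf <- cbind("(Intercept)" = 1,
              dc[, c(.climate_vars, .landuse_vars), drop = FALSE],
              niche = ti$niche_s[si], specialisation = ti$spec_s[si],
              elev = elev,
              dc[, paste0("elev:", c(.climate_vars, .agri_vars)), drop = FALSE],
              et, inter_cols,
              .sum_contrasts(rows$interval, "interval"),
              .sum_contrasts(ti$group[si], "group"))

  # species random-slope covariates: 6 drivers + 9 driver x driver
  slope_cols <- c(.climate_vars, .landuse_vars,
                  as.vector(outer(.climate_vars, .landuse_vars, paste, sep = ":")))
  Zs <- dc[, slope_cols, drop = FALSE]

  if (version == 1L) {
    nonagri <- !ti$agri_associated[si]
    zero_cols <- grepl("agri_prop|grass_intensity", colnames(Xf))
    Xf[nonagri, zero_cols] <- 0
    zero_z <- grepl("agri_prop|grass_intensity", colnames(Zs))
    Zs[nonagri, zero_z] <- 0
  }

  structure(list(
    y = rows$response, Xf = Xf, Zs = Zs,
    rows = rows[, c("species_id", "zone", "interval")],
    species = ti$species_id, species_idx = si,
    zones = zones, zone_idx = match(rows$zone, zones),
    zone_elev = zone_elev, zone_weights = zone_weights[zones],
    traits = ti, version = version,
    scaling = attr(drivers, "scaling"),
    drivers = drivers),
    class = "trend_design")
}

# univariate slice sampler (stepping out), Neal (2003)
.slice <- function(x0, logf, w = 0.5, max_steps = 30L, lower = -Inf, upper = Inf) {
  f0 <- logf(x0)
  if (!is.finite(f0)) stopf("slice sampler started at zero density")
  logy <- f0 + log(stats::runif(1))
  L <- x0 - w * stats::runif(1)
  R <- L + w
  for (i in seq_len(max_steps)) {
    if (L <= lower || logf(max(L, lower)) <= logy) break
    L <- L - w
  }
  for (i in seq_len(max_steps)) {
    if (R >= upper || logf(min(R, upper)) <= logy) break
    R <- R + w
  }
  L <- max(L, lower); R <- min(R, upper)
  repeat {
    x1 <- stats::runif(1, L, R)
    if (logf(x1) >= logy) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}

# log density of a half-Normal(0, scale) prior at sd > 0
.lp_halfnormal <- function(sd, scale) {
  if (sd <= 0) return(-Inf)
  -0.5 * (sd / scale)^2
}

#' Fit the trend regression by blocked Gibbs sampling
#'
#' Priors: Normal(0, `prior_beta`) on fixed effects (covariates are
#' standardized), half-Normal(0, `prior_sd`) on every standard
#' deviation.  Random slopes are modelled independent (diagonal
#' covariance).  Two or more chains are run from dispersed starts;
#' non-convergence (split R-hat > 1.1 on any fixed effect) is flagged
#' with a warning, never silently accepted.
#'
#' @param design a `trend_design`.
#' @param iter retained iterations per chain (default 1000).
#' @param warmup discarded iterations per chain (default 1000).
#' @param chains number of chains (default 4).
#' @param seed integer seed.
#' @param prior_beta,prior_sd prior scales.
#' @param quiet suppress progress notes.
#' @return list of class `trend_fit`: `beta` (draw x coef), `u_zone`
#'   (draw x zone), `b` (draw x species x 16 array), `sigma` (draw x
#'   component), `chain`, `design`, `rhat` (per fixed effect).
#' @export
fit_trend_regression <- function(design, iter = 1000L, warmup = 1000L,
                                 chains = 4L, seed = 1L, prior_beta = 1,
                                 prior_sd = 1, quiet = TRUE) {
  stopifnot(inherits(design, "trend_design"))
  y <- design$y
  Xf <- design$Xf
  n <- length(y)
  p <- ncol(Xf)
  ns <- length(design$species)
  Zs <- design$Zs                       # species random slopes (15 columns)
  q <- ncol(Zs)
  sidx <- design$species_idx
  zidx <- design$zone_idx
  nz <- length(design$zones)
  # intercept-like effects (fixed effects, zone intercepts, species
  # intercepts) are heavily confounded; sampling them in one joint
  # conjugate block keeps the chain mixing
  Uz <- matrix(0, n, nz); Uz[cbind(seq_len(n), zidx)] <- 1
  Us <- matrix(0, n, ns); Us[cbind(seq_len(n), sidx)] <- 1
  W <- cbind(Xf, Uz, Us)
  pw <- ncol(W)
  i_beta <- seq_len(p)
  i_zone <- p + seq_len(nz)
  i_sint <- p + nz + seq_len(ns)
  WtW <- crossprod(W)
  # per-species slope cross products (q x q), fixed across iterations
  ZtZ <- array(0, c(q, q, ns))
  sp_rows <- split(seq_len(n), sidx)
  for (s in seq_along(sp_rows)) {
    Zi <- Zs[sp_rows[[s]], , drop = FALSE]
    ZtZ[, , as.integer(names(sp_rows)[s])] <- crossprod(Zi)
  }

  slope_to_fixed <- match(colnames(Zs), colnames(Xf))
  if (anyNA(slope_to_fixed)) stopf("random-slope column without fixed counterpart")

  sig_names <- c("sigma_e", "sigma_zone", "sigma_b_icpt",
                 paste0("sigma_b_", colnames(Zs)))
  run_chain <- function(ch) {
    set.seed(as.integer(seed) * 100L + ch)
    theta <- stats::rnorm(pw, 0, 0.1)
    b <- matrix(stats::rnorm(ns * q, 0, 0.1), ns, q)
    sig_e <- stats::runif(1, 0.3, 1)
    sig_z <- stats::runif(1, 0.1, 0.5)
    sig_i <- stats::runif(1, 0.1, 0.5)
    sig_b <- stats::runif(q, 0.1, 0.5)
    keep_beta <- matrix(NA_real_, iter, p)
    keep_u <- matrix(NA_real_, iter, nz)
    keep_b <- array(NA_real_, c(iter, ns, q + 1L))
    keep_sig <- matrix(NA_real_, iter, 3L + q)
    Zb_row <- rowSums(Zs * b[sidx, , drop = FALSE])
    for (it in seq_len(warmup + iter)) {
      # joint block: fixed effects + zone intercepts + species intercepts
      r <- y - Zb_row
      prior_prec <- c(rep(1 / prior_beta^2, p), rep(1 / sig_z^2, nz),
                      rep(1 / sig_i^2, ns))
      A <- WtW / sig_e^2
      diag(A) <- diag(A) + prior_prec
      m <- crossprod(W, r) / sig_e^2
      ch_A <- chol(A)
      theta <- drop(backsolve(ch_A, backsolve(ch_A, m, transpose = TRUE) +
                                stats::rnorm(pw)))
      wtheta <- drop(W %*% theta)
      # per-species slope blocks (conditionally independent)
      r <- y - wtheta
      Ztr <- rowsum((Zs * r), sidx, reorder = TRUE) / sig_e^2
      Dinv <- diag(1 / sig_b^2, q)
      for (s in seq_len(ns)) {
        As <- ZtZ[, , s] / sig_e^2 + Dinv
        cs <- chol(As)
        b[s, ] <- backsolve(cs, backsolve(cs, Ztr[s, ], transpose = TRUE) +
                              stats::rnorm(q))
      }
      Zb_row <- rowSums(Zs * b[sidx, , drop = FALSE])
      # translation group move along beta_k -> beta_k + delta,
      # b[, k] -> b[, k] - delta: the slope columns equal their fixed
      # counterparts, so the likelihood is invariant and delta has a
      # Gaussian conditional; this decouples fixed driver effects from
      # the mean of the species random slopes
      for (k in seq_len(q)) {
        j <- slope_to_fixed[k]
        prec <- 1 / prior_beta^2 + ns / sig_b[k]^2
        mu_d <- (sum(b[, k]) / sig_b[k]^2 - theta[j] / prior_beta^2) / prec
        delta <- stats::rnorm(1, mu_d, sqrt(1 / prec))
        theta[j] <- theta[j] + delta
        b[, k] <- b[, k] - delta
        wtheta <- wtheta + delta * W[, j]
        Zb_row <- Zb_row - delta * Zs[, k]
      }
      # variance components by slice sampling (half-Normal priors)
      res <- y - wtheta - Zb_row
      rss <- sum(res^2)
      sig_e <- .slice(sig_e, function(s) {
        if (s <= 0) return(-Inf)
        -n * log(s) - rss / (2 * s^2) + .lp_halfnormal(s, prior_sd)
      }, lower = 1e-6)
      ssz <- sum(theta[i_zone]^2)
      sig_z <- .slice(sig_z, function(s) {
        if (s <= 0) return(-Inf)
        -nz * log(s) - ssz / (2 * s^2) + .lp_halfnormal(s, prior_sd)
      }, lower = 1e-6)
      ssi <- sum(theta[i_sint]^2)
      sig_i <- .slice(sig_i, function(s) {
        if (s <= 0) return(-Inf)
        -ns * log(s) - ssi / (2 * s^2) + .lp_halfnormal(s, prior_sd)
      }, lower = 1e-6)
      ssb <- colSums(b^2)
      for (k in seq_len(q)) {
        sig_b[k] <- .slice(sig_b[k], function(s) {
          if (s <= 0) return(-Inf)
          -ns * log(s) - ssb[k] / (2 * s^2) + .lp_halfnormal(s, prior_sd)
        }, lower = 1e-6)
      }
      if (it > warmup) {
        j <- it - warmup
        keep_beta[j, ] <- theta[i_beta]
        keep_u[j, ] <- theta[i_zone]
        keep_b[j, , 1L] <- theta[i_sint]
        keep_b[j, , 1L + seq_len(q)] <- b
        keep_sig[j, ] <- c(sig_e, sig_z, sig_i, sig_b)
      }
    }
    list(beta = keep_beta, u = keep_u, b = keep_b, sig = keep_sig)
  }
  res <- lapply(seq_len(chains), run_chain)
  beta <- do.call(rbind, lapply(res, `[[`, "beta"))
  colnames(beta) <- colnames(Xf)
  u <- do.call(rbind, lapply(res, `[[`, "u"))
  colnames(u) <- design$zones
  b <- do.call(abind_first, lapply(res, `[[`, "b"))
  sig <- do.call(rbind, lapply(res, `[[`, "sig"))
  colnames(sig) <- sig_names
  chain <- rep(seq_len(chains), each = iter)
  rhat <- vapply(seq_len(p), function(j) {
    split_rhat(matrix(beta[, j], ncol = chains))
  }, numeric(1))
  names(rhat) <- colnames(Xf)
  if (chains >= 2L && any(rhat > 1.1, na.rm = TRUE)) {
    warnf("trend regression not converged: R-hat > 1.1 for %s",
          paste(names(rhat)[which(rhat > 1.1)], collapse = ", "))
  }
  structure(list(beta = beta, u_zone = u, b = b, sigma = sig,
                 chain = chain, design = design, rhat = rhat,
                 b_cols = c("icpt", colnames(Zs))),
            class = "trend_fit")
}

# rbind along the first dimension of 3-d arrays
abind_first <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  out <- array(NA_real_, c(sum(vapply(parts, function(x) dim(x)[1], numeric(1))),
                           d[2], d[3]))
  at <- 0L
  for (x in parts) {
    out[at + seq_len(dim(x)[1]), , ] <- x
    at <- at + dim(x)[1]
  }
  out
}

#' Residual diagnostics of a trend-regression fit
#'
#' Residuals at posterior-mean parameters: Shapiro-Wilk normality test
#' (on a subsample if n > 4000) and lag-1 autocorrelation of residuals
#' within species x zone series ordered by interval.
#'
#' @param fit a `trend_fit`.
#' @return list: `shapiro_p`, `lag1`, `residuals`.
#' @export
regression_diagnostics <- function(fit) {
  d <- fit$design
  eta <- drop(d$Xf %*% colMeans(fit$beta)) +
    colMeans(fit$u_zone)[d$zone_idx] +
    rowSums(cbind(1, d$Zs) * apply(fit$b, c(2, 3), mean)[d$species_idx, ])
  res <- d$y - eta
  sub <- if (length(res) > 4000) sample(res, 4000) else res
  sh <- stats::shapiro.test(sub)$p.value
  key <- paste(d$rows$species_id, d$rows$zone)
  lag1 <- unlist(lapply(split(seq_along(res), key), function(i) {
    i <- i[order(d$rows$interval[i])]
    if (length(i) < 3) return(NULL)
    r <- res[i]
    stats::cor(r[-1], r[-length(r)])
  }))
  list(shapiro_p = sh, lag1 = mean(lag1, na.rm = TRUE), residuals = res)
}

#' Sensitivity filters on a trend-regression design
#'
#' Mode `"species"` removes flagged species (migratory, (re)introduced,
#' uncertain taxonomy; `flag_excluded` in the trait table) plus the 20%
#' of species with the lowest record numbers per group.  Mode
#' `"species_zone"` removes species x zone combinations with fewer than
#' `min_records` records (default 41: less than one record per year on
#' average).
#'
#' @param design a `trend_design`.
#' @param mode `"species"` or `"species_zone"`.
#' @param record_counts data.frame `species_id`, `zone`, `n_records`
#'   (per species x zone; species totals are their sum).
#' @param min_records threshold for mode `"species_zone"`.
#' @param lowest_fraction fraction of lowest-record species removed per
#'   group in mode `"species"` (default 0.2).
#' @return the filtered `trend_design`.
#' @export
sensitivity_filter <- function(design, mode = c("species", "species_zone"),
                               record_counts, min_records = 41L,
                               lowest_fraction = 0.2) {
  mode <- match.arg(mode)
  rows <- design$rows
  if (mode == "species") {
    ti <- design$traits
    tot <- tapply(record_counts$n_records, record_counts$species_id, sum)
    ti$n_records <- as.numeric(tot[ti$species_id])
    ti$n_records[is.na(ti$n_records)] <- 0
    drop_sp <- character()
    if ("flag_excluded" %in% names(ti)) {
      drop_sp <- ti$species_id[ti$flag_excluded]
    }
    for (g in unique(ti$group)) {
      tg <- ti[ti$group == g, ]
      k <- floor(nrow(tg) * lowest_fraction)
      if (k > 0) {
        drop_sp <- union(drop_sp, tg$species_id[order(tg$n_records)][seq_len(k)])
      }
    }
    keep <- !(rows$species_id %in% drop_sp)
  } else {
    key <- paste(rows$species_id, rows$zone)
    ck <- paste(record_counts$species_id, record_counts$zone)
    nrec <- record_counts$n_records[match(key, ck)]
    nrec[is.na(nrec)] <- 0
    keep <- nrec >= min_records
  }
  if (!any(keep)) stopf("sensitivity filter removed every row")
  .subset_design(design, keep)
}

.subset_design <- function(design, keep) {
  d <- design
  d$y <- d$y[keep]
  d$Xf <- d$Xf[keep, , drop = FALSE]
  d$Zs <- d$Zs[keep, , drop = FALSE]
  d$rows <- d$rows[keep, , drop = FALSE]
  sp_left <- unique(d$rows$species_id)
  d$traits <- d$traits[d$traits$species_id %in% sp_left, , drop = FALSE]
  d$species <- d$traits$species_id
  d$species_idx <- match(d$rows$species_id, d$species)
  zones_left <- sort(unique(d$rows$zone))
  d$zone_weights <- d$zone_weights[zones_left]
  d$zones <- zones_left
  d$zone_idx <- match(d$rows$zone, d$zones)
  d
}
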