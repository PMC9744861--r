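# Window-based trends of mean occupancy and their posterior summaries.
#
# Mean-occupancy series come in as draws x years matrices (one row per
# posterior draw).  A "trend" is always expressed as the change in mean
# occupancy over the window: OLS slope of the series against calendar
# year, multiplied by the window length in years.

#' Sign-preserving square root and its inverse
#'
#' `signed_sqrt(x)` returns `sign(x) * sqrt(|x|)`; `signed_square(x)`
#' returns `sign(x) * x^2`.  The pair is used to normalise trend
#' residuals before regression and to back-transform predictions;
#' `signed_square(signed_sqrt(x)) == x` exactly.
#'
#' @param x numeric vector.
#' @return numeric vector of the same length.
#' @export
signed_sqrt <- function(x) sign(x) * sqrt(abs(x))

#' @rdname signed_sqrt
#' @export
signed_square <- function(x) sign(x) * x^2

#' Highest density interval of a sample
#'
#' The shortest contiguous interval containing `level` posterior mass,
#' computed from the empirical draws (sliding window over the order
#' statistics).
#'
#' @param draws numeric vector of posterior draws (>= 100).
#' @param level coverage level in (0, 1); default 0.95.
#' @return named numeric vector `c(lower, upper)`.
#' @export
hdi <- function(draws, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1L || is.na(level) ||
      level <= 0 || level >= 1) {
    stopf("hdi level must be a single number in (0, 1)")
  }
  draws <- draws[is.finite(draws)]
  n <- length(draws)
  if (n < 100L) stopf("hdi needs at least 100 draws, got %d", n)
  sorted <- sort(draws)
  k <- ceiling(level * n)
  m <- n - k + 1L                       # candidate window starts
  widths <- sorted[k:n] - sorted[seq_len(m)]
  i <- which.min(widths)
  c(lower = sorted[i], upper = sorted[i + k - 1L])
}

#' Consecutive year windows of fixed length
#'
#' Enumerates the consecutive intervals of `length` years spanning
#' `start`..`end`, e.g. 1980-2020 in 5-year steps gives the 8 intervals
#' 1980-1985, 1985-1990, ..., 2015-2020 (endpoints shared).
#'
#' @param start,end first and last calendar year.
#' @param length interval length in years (default 5).
#' @return data.frame with columns `interval` (1-based index), `from`, `to`.
#' @export
interval_windows <- function(start, end, length = 5L) {
  if ((end - start) %% length != 0) {
    stopf("range %d-%d is not divisible into %d-year intervals", start, end, length)
  }
  from <- seq(start, end - length, by = length)
  data.frame(interval = seq_along(from), from = from, to = from + length)
}

#' Occupancy change over a year window, per posterior draw
#'
#' For each draw (row of `series`), fits an OLS line of mean occupancy
#' against year over the window and returns slope x window length, i.e.
#' the modelled change in mean occupancy across the window.
#'
#' @param series draws x years matrix (or single series vector) of mean
#'   occupancy.
#' @param years calendar years labelling the columns of `series`.
#' @param window length-2 vector `c(from, to)`; defaults to the full range.
#' @return numeric vector of per-draw changes.
#' @export
fit_window_trend <- function(series, years, window = range(years)) {
  if (is.null(dim(series))) series <- matrix(series, nrow = 1L)
  if (ncol(series) != length(years)) stopf("series has %d columns but %d years given", ncol(series), length(years))
  sel <- years >= window[1] & years <= window[2]
  got <- years[sel]
  want <- seq(window[1], window[2])
  if (!identical(as.integer(got), as.integer(want))) {
    stopf("window %d-%d requires every year present; missing: %s",
          window[1], window[2], paste(setdiff(want, got), collapse = ", "))
  }
  if (sum(sel) < 2L) stopf("window must span at least 2 years")
  ols_slope(series[, sel, drop = FALSE], years[sel]) * diff(window)
}

#' Summarise a set of 40-year species trends
#'
#' Computes the headline distribution-trend summaries from per-species
#' posterior draws of the long-term occupancy change:
#' counts of species with positive / negative trends (per draw, with
#' HDIs); the declining and increasing quarters (25% of species with the
#' strongest negative / positive posterior-mean trends) and their average
#' absolute and percent changes; a bootstrap confidence interval for the
#' rank position at which trends change sign; and the comparison of
#' 40-year mean occupancy between increasing and decreasing species.
#'
#' Quarter membership is fixed by posterior-mean ranking; uncertainty is
#' then propagated by averaging over the fixed sets per draw.  Species
#' with an exactly zero change in a draw are counted as negative (ties
#' are broken deterministically towards "negative").
#'
#' @param change_draws species x draws matrix of occupancy change over
#'   the window (rownames = species ids).
#' @param mean_occ_draws species x draws matrix of window-mean occupancy,
#'   aligned with `change_draws`.
#' @param level HDI level for all interval summaries (default 0.95).
#' @param n_boot bootstrap replicates for the sign-change position
#'   (default 9999).
#' @return list with elements `counts`, `quarters`, `percent`,
#'   `sign_change`, `occupancy_comparison` (each a small data.frame or
#'   named list; see the package vignette).
#' @export
summarize_trends <- function(change_draws, mean_occ_draws, level = 0.95,
                             n_boot = 9999L) {
  if (is.null(dim(change_draws))) stopf("change_draws must be a species x draws matrix")
  ns <- nrow(change_draws)
  if (ns < 4L) stopf("trend quarters undefined for fewer than 4 species (got %d)", ns)
  if (!all(dim(change_draws) == dim(mean_occ_draws))) {
    stopf("change_draws and mean_occ_draws must have identical dimensions")
  }
  sp <- rownames(change_draws)
  if (is.null(sp)) sp <- paste0("sp", seq_len(ns))

  # (i) per-draw counts; zero counted as negative
  n_pos <- colSums(change_draws > 0)
  n_neg <- ns - n_pos
  counts <- data.frame(
    direction = c("positive", "negative"),
    mean = c(mean(n_pos), mean(n_neg)),
    rbind(hdi(n_pos, level), hdi(n_neg, level)))

  # (ii) quarters fixed by posterior-mean rank
  pm <- rowMeans(change_draws)
  q <- floor(ns / 4)
  ord <- order(pm)
  declining <- sp[ord[seq_len(q)]]
  increasing <- sp[ord[seq.int(ns - q + 1L, ns)]]
  dec_draws <- colMeans(change_draws[ord[seq_len(q)], , drop = FALSE])
  inc_draws <- colMeans(change_draws[ord[seq.int(ns - q + 1L, ns)], , drop = FALSE])
  quarters <- data.frame(
    quarter = c("declining", "increasing"),
    n = q,
    mean_change = c(mean(dec_draws), mean(inc_draws)),
    rbind(hdi(dec_draws, level), hdi(inc_draws, level)))

  # (iii) percent change relative to window-mean occupancy
  pct <- 100 * change_draws / mean_occ_draws
  dec_pct <- colMeans(pct[ord[seq_len(q)], , drop = FALSE])
  inc_pct <- colMeans(pct[ord[seq.int(ns - q + 1L, ns)], , drop = FALSE])
  percent <- data.frame(
    quarter = c("declining", "increasing"),
    mean_percent = c(mean(dec_pct), mean(inc_pct)),
    rbind(hdi(dec_pct, level), hdi(inc_pct, level)))

  # (iv) bootstrap of the sign-change rank position (resampling species
  # point estimates and recounting negatives; zero counts as negative)
  boot_neg <- vapply(seq_len(n_boot), function(b) {
    sum(sample(pm, ns, replace = TRUE) <= 0)
  }, numeric(1))
  sign_change <- list(
    position = sum(pm <= 0),
    ci = stats::quantile(boot_neg, c((1 - level) / 2, 1 - (1 - level) / 2),
                         names = FALSE),
    n_boot = n_boot)

  # (v) mean occupancy of increasing vs decreasing species
  inc_set <- pm > 0
  if (any(inc_set) && any(!inc_set)) {
    occ_inc <- colMeans(mean_occ_draws[inc_set, , drop = FALSE])
    occ_dec <- colMeans(mean_occ_draws[!inc_set, , drop = FALSE])
    diff_draws <- occ_inc - occ_dec
    occ_cmp <- data.frame(
      set = c("increasing", "decreasing", "difference"),
      mean = c(mean(occ_inc), mean(occ_dec), mean(diff_draws)),
      rbind(hdi(occ_inc, level), hdi(occ_dec, level), hdi(diff_draws, level)))
  } else {
    occ_cmp <- NULL
  }

  list(counts = counts,
       quarters = quarters,
       percent = percent,
       sign_change = sign_change,
       occupancy_comparison = occ_cmp,
       membership = list(declining = declining, increasing = increasing))
}
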