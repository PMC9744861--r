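#' @keywords internal
#' @importFrom mgcv gam s
#' @importFrom coda as.mcmc
"_PACKAGE"

# inverse logit on the full real line
ilogit <- function(x) stats::plogis(x)

logit <- function(p) stats::qlogis(p)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Closed-form OLS slope of y against x
#'
#' Vectorized over the rows of `y`: each row is one series (e.g. one
#' posterior draw) regressed on the common predictor `x`.
#'
#' @param y numeric vector, or matrix with one series per row.
#' @param x numeric predictor (e.g. calendar years).
#' @return numeric vector of slopes, one per row of `y`.
#' @export
ols_slope <- function(y, x) {
  if (is.null(dim(y))) y <- matrix(y, nrow = 1L)
  if (ncol(y) != length(x)) stopf("series length %d != predictor length %d", ncol(y), length(x))
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx == 0) stopf("predictor has zero variance")
  drop(y %*% xc) / sxx
}
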