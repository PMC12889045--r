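#' Carryover contamination rate
#'
#' The contamination rate after a wash is the ratio of the leftover-cell
#' detection rate to the original (pre-wash) cell density, both in cells
#' detected per minute.
#'
#' @param leftover leftover cells/min after the wash (>= 0).
#' @param original original cell density in cells/min (> 0).
#' @return \code{leftover / original}, vectorized.
#' @examples
#' contaminationRate(2, 1000)
#' @export
contaminationRate <- function(leftover, original) {
  if (any(original <= 0)) stop("original rate must be > 0")
  if (any(leftover < 0)) stop("leftover rate must be >= 0")
  leftover / original
}

#' Fit geometric decay to a wash series
#'
#' Ordinary least squares of log leftover rate on the (1-based) wash
#' index; the per-wash retention factor is \code{exp(slope)}. Zero rates
#' carry no log information and are excluded with a warning ("no cell
#' detected" endpoints). A non-decreasing series yields retention >= 1 and
#' is flagged non-decaying.
#'
#' @param series a \code{\link{WashSeries}}.
#' @return A \code{WashDecayFit} object.
#' @examples
#' fitDecay(WashSeries(1000, c(100, 10, 1)))
#' @export
fitDecay <- function(series) {
  stopifnot(is(series, "WashSeries"))
  rate <- series@leftoverRates
  idx <- seq_along(rate)
  pos <- rate > 0
  if (any(!pos))
    warning(sum(!pos), " zero leftover rate(s) excluded from the log fit")
  if (sum(pos) < 2)
    stop("need >= 2 strictly positive leftover rates to fit a decay")
  y <- log(rate[pos])
  x <- idx[pos]
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  res <- stats::residuals(fit)
  tss <- sum((y - mean(y))^2)
  rss <- sum(res^2)
  r2 <- if (tss < 1e-24) {
    if (rss < 1e-24) 1 else 0  # constant series: a flat line fits exactly
  } else {
    1 - rss / tss
  }
  ret <- exp(co[["x"]])
  if (abs(ret - 1) < 1e-12) ret <- 1  # constant series, up to lm round-off
  new("WashDecayFit", logIntercept = co[["(Intercept)"]], retention = ret,
      rSquared = r2, nonDecaying = ret >= 1, nUsed = as.integer(sum(pos)))
}

#' Washes needed to reach a target contamination rate
#'
#' Smallest integer \code{n} with
#' \code{currentRate * retention^n <= target} under the fitted geometric
#' decay.
#'
#' @param fit a \code{\link[=fitDecay]{WashDecayFit}}.
#' @param currentRate current contamination rate (fraction).
#' @param target target contamination rate (fraction), > 0.
#' @return Integer number of additional washes (0 when already at or below
#'   target).
#' @examples
#' fit <- fitDecay(WashSeries(1000, c(100, 10, 1)))
#' washesToTarget(fit, currentRate = 0.02, target = 0.001)
#' @export
washesToTarget <- function(fit, currentRate, target) {
  stopifnot(is(fit, "WashDecayFit"), currentRate > 0, target > 0)
  if (target >= currentRate) return(0L)
  r <- retention(fit)
  if (r >= 1 - 1e-12)
    stop("non-decaying series (retention >= 1): target is unreachable")
  n <- max(0, ceiling(log(target / currentRate) / log(r) - 1e-9))
  ## guard against floating-point off-by-one
  if (currentRate * r^n > target) n <- n + 1
  if (n > 0 && currentRate * r^(n - 1) <= target) n <- n - 1
  as.integer(n)
}
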