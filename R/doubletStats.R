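#' Fluorophore proportion from single-signal tallies
#'
#' Estimates the proportion of green-fluorescent cells from the
#' single-signal well counts: \code{p = n_green_only / (n_green_only +
#' n_red_only)}. Same-color multi-cell wells are counted as single-signal
#' by a two-color assay, which leaves a small bias that is ignored here
#' (negligible when the multi-cell fraction is modest).
#'
#' @param counts a \code{\link{SignalCounts}} object.
#' @return Estimated green-cell proportion in [0, 1].
#' @examples
#' estimateColorProportion(SignalCounts(300, 100, 10, 5))
#' @export
estimateColorProportion <- function(counts) {
  stopifnot(is(counts, "SignalCounts"))
  nSingle <- counts@nGreenOnly + counts@nRedOnly
  if (nSingle == 0)
    stop("no single-signal wells: color proportion is inestimable")
  counts@nGreenOnly / nSingle
}

dualFraction <- function(counts, denominator) {
  ne <- nNonEmpty(counts)
  if (ne == 0) stop("no non-empty wells")
  denom <- if (denominator == "nonempty") ne else ne + counts@nEmpty
  counts@nDual / denom
}

#' Multi-cell fraction via the two-color collision model
#'
#' A two-color assay only reveals multi-cell wells whose cells carry
#' different fluorophores. Under the exactly-two-cell model of multi-cell
#' wells, a multi-cell well is dual-signal with probability
#' \code{2 p (1 - p)} where \code{p} is the green-cell proportion, so the
#' total multi-cell fraction is the observed dual-signal fraction divided
#' by that collision probability (capped at 1). The single-cell dispensing
#' frequency is \code{100 (1 - m)} percent.
#'
#' @param counts a \code{\link{SignalCounts}} object.
#' @param pHat green-cell proportion; estimated from \code{counts} via
#'   \code{\link{estimateColorProportion}} when \code{NULL}.
#' @param denominator \code{"nonempty"} (default) expresses fractions
#'   relative to non-empty wells; \code{"dispensed"} relative to all
#'   dispensed wells.
#' @return A \code{DoubletEstimate} object.
#' @examples
#' ## the six-plate dual-fluorophore benchmark tallies
#' est <- estimateMultiFractionPairwise(SignalCounts(225, 225, 27, 51))
#' singleCellFreq(est)
#' @export
estimateMultiFractionPairwise <- function(counts, pHat = NULL,
                                          denominator = c("nonempty",
                                                          "dispensed")) {
  stopifnot(is(counts, "SignalCounts"))
  denominator <- match.arg(denominator)
  if (is.null(pHat)) pHat <- estimateColorProportion(counts)
  d <- dualFraction(counts, denominator)
  coll <- 2 * pHat * (1 - pHat)
  if (coll == 0)
    stop("color proportion is 0 or 1: collision probability vanishes, ",
         "the multi-cell fraction is unidentifiable")
  m <- min(1, d / coll)
  new("DoubletEstimate", dHat = d, pHat = pHat, mHat = m,
      singleCellFreq = 100 * (1 - m), ciLow = NA_real_, ciHigh = NA_real_,
      model = "pairwise", lambdaHat = NA_real_, denominator = denominator)
}

## P(dual | >= 1 cell) under cells ~ Poisson(lambda) truncated to >= 1:
## a well is single-colored iff all its cells share a color;
## A(x) = P(all cells green-ish with per-cell prob x | k >= 1)
##      = (exp(lambda (x - 1)) - exp(-lambda)) / (1 - exp(-lambda))
truncPoisDualProb <- function(lambda, p) {
  A <- function(x) {
    (exp(lambda * (x - 1)) - exp(-lambda)) / (1 - exp(-lambda))
  }
  1 - (A(p) + A(1 - p))
}

#' Multi-cell fraction via a truncated-Poisson model
#'
#' Sensitivity variant of \code{\link{estimateMultiFractionPairwise}}: the
#' number of cells in a non-empty well is modeled as Poisson(lambda)
#' truncated to k >= 1. The rate is solved by bisection (bracket
#' \code{[1e-8, 10]}, tolerance 1e-10) so that the model's dual-signal
#' probability matches the observed dual fraction; the multi-cell fraction
#' is then \code{P(k >= 2 | k >= 1)}. Agrees with the pairwise model in
#' the small-dual-fraction limit.
#'
#' @inheritParams estimateMultiFractionPairwise
#' @return A \code{DoubletEstimate} with slot \code{lambdaHat} filled.
#' @examples
#' estimateMultiFractionPoisson(SignalCounts(225, 225, 27, 51))
#' @export
estimateMultiFractionPoisson <- function(counts, pHat = NULL,
                                         denominator = c("nonempty",
                                                         "dispensed")) {
  stopifnot(is(counts, "SignalCounts"))
  denominator <- match.arg(denominator)
  if (is.null(pHat)) pHat <- estimateColorProportion(counts)
  if (pHat <= 0 || pHat >= 1)
    stop("color proportion is 0 or 1: dual probability vanishes")
  d <- dualFraction(counts, denominator)
  if (d == 0) {
    return(new("DoubletEstimate", dHat = 0, pHat = pHat, mHat = 0,
               singleCellFreq = 100, ciLow = NA_real_, ciHigh = NA_real_,
               model = "truncated_poisson", lambdaHat = 0,
               denominator = denominator))
  }
  f <- function(lam) truncPoisDualProb(lam, pHat) - d
  lo <- 1e-8
  hi <- 10
  if (f(lo) > 0 || f(hi) < 0)
    stop("observed dual fraction has no root in the bracket: ",
         "truncated-Poisson model mismatch")
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  lambda <- (lo + hi) / 2
  m <- 1 - lambda * exp(-lambda) / (1 - exp(-lambda))
  new("DoubletEstimate", dHat = d, pHat = pHat, mHat = m,
      singleCellFreq = 100 * (1 - m), ciLow = NA_real_, ciHigh = NA_real_,
      model = "truncated_poisson", lambdaHat = lambda,
      denominator = denominator)
}

#' Bootstrap confidence interval for the single-cell frequency
#'
#' Nonparametric bootstrap over wells: the four-class tally is resampled
#' as a multinomial of the same total, the estimator re-run on each
#' replicate, and a percentile interval taken on the single-cell
#' dispensing frequency. Replicates where the estimator is undefined (a
#' color absent among single-signal wells while dual wells are present)
#' are dropped; more than 50\% failures is an error.
#'
#' @inheritParams estimateMultiFractionPairwise
#' @param B number of bootstrap replicates.
#' @param level confidence level.
#' @param seed integer seed (the interval is deterministic given it).
#' @param model \code{"pairwise"} or \code{"poisson"}.
#' @return Named numeric vector \code{c(ciLow, ciHigh)} in percent.
#' @examples
#' bootstrapCI(SignalCounts(225, 225, 27, 51), B = 200, seed = 1)
#' @export
bootstrapCI <- function(counts, B = 1000, level = 0.95, seed = 1,
                        model = c("pairwise", "poisson"),
                        denominator = c("nonempty", "dispensed")) {
  stopifnot(is(counts, "SignalCounts"), B >= 1, level > 0, level < 1)
  model <- match.arg(model)
  denominator <- match.arg(denominator)
  n <- signalCounts(counts)
  N <- sum(n)
  if (nNonEmpty(counts) == 0) stop("no non-empty wells")
  set.seed(seed)
  reps <- stats::rmultinom(B, N, n / N)
  ngo <- reps["green_only", ]
  nro <- reps["red_only", ]
  nd <- reps["dual", ]
  ne <- ngo + nro + nd
  denom <- if (denominator == "nonempty") ne else rep(N, B)
  if (model == "pairwise") {
    ## closed form, vectorized over replicates
    p <- ngo / (ngo + nro)
    coll <- 2 * p * (1 - p)
    scf <- rep(NA_real_, B)
    scf[nd == 0 & ne > 0] <- 100  # no dual wells: multi-cell estimate is 0
    est <- nd > 0 & coll > 0
    scf[est] <- 100 * (1 - pmin(1, (nd[est] / denom[est]) / coll[est]))
  } else {
    scf <- vapply(seq_len(B), function(b) {
      sc <- SignalCounts(ngo[b], nro[b], nd[b], reps["empty", b])
      tryCatch(
        singleCellFreq(estimateMultiFractionPoisson(
          sc, denominator = denominator)),
        error = function(e) NA_real_)
    }, numeric(1))
  }
  ok <- !is.na(scf)
  if (mean(ok) < 0.5)
    stop("estimator failed in more than half of the bootstrap replicates")
  alpha <- (1 - level) / 2
  q <- stats::quantile(scf[ok], c(alpha, 1 - alpha), names = FALSE)
  c(ciLow = q[1], ciHigh = q[2])
}

#' Full doublet analysis of a tally
#'
#' Convenience wrapper: point estimate under the chosen model plus a
#' bootstrap percentile interval, returned as one
#' \code{\link[=estimateMultiFractionPairwise]{DoubletEstimate}}.
#'
#' @inheritParams bootstrapCI
#' @return A \code{DoubletEstimate} with confidence bounds filled.
#' @export
estimateDoublets <- function(counts, model = c("pairwise", "poisson"),
                             B = 1000, level = 0.95, seed = 1,
                             denominator = c("nonempty", "dispensed")) {
  model <- match.arg(model)
  denominator <- match.arg(denominator)
  est <- if (model == "pairwise") {
    estimateMultiFractionPairwise(counts, denominator = denominator)
  } else {
    estimateMultiFractionPoisson(counts, denominator = denominator)
  }
  ci <- bootstrapCI(counts, B = B, level = level, seed = seed,
                    model = model, denominator = denominator)
  est@ciLow <- min(ci[["ciLow"]], singleCellFreq(est))
  est@ciHigh <- max(ci[["ciHigh"]], singleCellFreq(est))
  validObject(est)
  est
}
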