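#' Parameters of a dispensing simulation
#'
#' Bundles the generative model of a single-cell dispensing run: a dispensed
#' well is empty with probability \code{emptyFraction}; otherwise it holds
#' two or more cells with probability \code{multiFraction} (cell count
#' \code{2 + Poisson(extraCellMean)}) or exactly one cell. Each cell is
#' green-fluorescent with probability \code{colorProp}, red otherwise. A
#' channel reading is \code{Normal(bgMean, bgSd) + nCells_color *
#' Normal(signalMean, signalSd)}, truncated at zero.
#'
#' The default \code{extraCellMean = 0} gives the exactly-two-cell model of
#' multi-cell wells, the regime the pairwise collision estimator assumes.
#'
#' @param emptyFraction probability a dispensed well receives no cell.
#' @param multiFraction probability a non-empty well holds >= 2 cells.
#' @param extraCellMean Poisson mean of cells beyond two in a multi-cell
#'   well.
#' @param colorProp probability a cell is green (red = 1 - colorProp).
#' @param bgMean,bgSd background intensity mean and sd per channel.
#' @param signalMean,signalSd per-cell signal intensity mean and sd.
#' @return A validated parameter list of class \code{"dispensingParams"}.
#' @examples
#' dispensingParams(multiFraction = 0.115)
#' @export
dispensingParams <- function(emptyFraction = 0.1, multiFraction = 0.115,
                             extraCellMean = 0, colorProp = 0.5,
                             bgMean = 100, bgSd = 2,
                             signalMean = 1000, signalSd = 20) {
  p <- list(emptyFraction = emptyFraction, multiFraction = multiFraction,
            extraCellMean = extraCellMean, colorProp = colorProp,
            bgMean = bgMean, bgSd = bgSd, signalMean = signalMean,
            signalSd = signalSd)
  for (nm in c("emptyFraction", "multiFraction", "colorProp")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(nm, " must be a probability in [0, 1]")
  }
  if (p$extraCellMean < 0) stop("extraCellMean must be >= 0")
  if (p$bgSd < 0 || p$signalSd < 0) stop("sds must be >= 0")
  if (p$signalMean <= 0) stop("signalMean must be > 0")
  structure(p, class = "dispensingParams")
}

#' @export
print.dispensingParams <- function(x, ...) {
  cat("dispensingParams:\n")
  cat(sprintf(
    "  empty %.3f, multi %.3f (+Pois(%.2f) cells), green prop %.3f\n",
    x$emptyFraction, x$multiFraction, x$extraCellMean, x$colorProp))
  cat(sprintf("  background N(%g, %g), per-cell signal N(%g, %g)\n",
              x$bgMean, x$bgSd, x$signalMean, x$signalSd))
  invisible(x)
}

## draw per-well cell counts and colors for n dispensed wells (vectorized)
drawWellTruth <- function(n, params) {
  empty <- stats::runif(n) < params$emptyFraction
  multi <- !empty & stats::runif(n) < params$multiFraction
  nCells <- integer(n)
  nCells[!empty] <- 1L
  nCells[multi] <- 2L + stats::rpois(sum(multi), params$extraCellMean)
  nGreen <- stats::rbinom(n, nCells, params$colorProp)
  data.frame(n_cells = nCells, n_green = nGreen, n_red = nCells - nGreen)
}

## intensity model: background + (cells of the color) x one per-cell signal
## draw, truncated at 0
drawIntensity <- function(nColor, params) {
  pmax(0, stats::rnorm(length(nColor), params$bgMean, params$bgSd) +
         nColor * stats::rnorm(length(nColor), params$signalMean,
                               params$signalSd))
}

#' Simulate fluorescence plates from a dispensing run
#'
#' Generates per-well, per-channel plate-reader intensities together with
#' the ground-truth cell content of every well, under the generative model
#' of \code{\link{dispensingParams}}. Blank and NTC wells receive
#' background only; the positive-control well receives a 400-droplet
#' dispense. Sub-streams are derived deterministically per plate from the
#' one \code{seed}, so the output is bit-reproducible.
#'
#' @param params a \code{\link{dispensingParams}} object.
#' @param nPlates number of 96-well plates to simulate.
#' @param layout a \code{\link{PlateLayout}}.
#' @param seed integer seed.
#' @return A list with \code{readings} (data.frame: plate_id, well, channel,
#'   intensity) and \code{truth} (data.frame: plate_id, well, n_cells,
#'   n_green, n_red).
#' @examples
#' sim <- simulatePlate(dispensingParams(), nPlates = 1, seed = 7)
#' head(sim$readings)
#' @export
simulatePlate <- function(params, nPlates = 1, layout = PlateLayout(),
                          seed = 1) {
  stopifnot(inherits(params, "dispensingParams"), nPlates >= 1)
  readings <- vector("list", nPlates)
  truth <- vector("list", nPlates)
  for (i in seq_len(nPlates)) {
    set.seed(seed + i - 1L)
    plateId <- sprintf("plate%02d", i)
    disp <- wellsWithRole(layout, "dispensed")
    ctrl <- wellsWithRole(layout, c("blank", "ntc"))
    pos <- wellsWithRole(layout, "positive")

    tr <- drawWellTruth(length(disp), params)
    tr <- cbind(plate_id = plateId, well = disp, tr)
    if (length(pos)) {
      nGreen <- stats::rbinom(length(pos), 400L, params$colorProp)
      tr <- rbind(tr, data.frame(plate_id = plateId, well = pos,
                                 n_cells = 400L, n_green = nGreen,
                                 n_red = 400L - nGreen))
    }
    tr <- rbind(tr, data.frame(plate_id = plateId, well = ctrl,
                               n_cells = 0L, n_green = 0L, n_red = 0L))
    readings[[i]] <- data.frame(
      plate_id = plateId,
      well = rep(tr$well, 2),
      channel = rep(c("green", "red"), each = nrow(tr)),
      intensity = c(drawIntensity(tr$n_green, params),
                    drawIntensity(tr$n_red, params)))
    truth[[i]] <- tr
  }
  list(readings = do.call(rbind, readings), truth = do.call(rbind, truth))
}

#' Simulate well-class tallies directly
#'
#' Fast path for estimator studies: draws the ground-truth cell content of
#' \code{nWells} dispensed wells and tallies the well classes an ideal
#' (noise-free) two-color assay would report -- a well is dual-signal iff it
#' holds at least one green and at least one red cell.
#'
#' @param nWells number of dispensed wells.
#' @param params a \code{\link{dispensingParams}} object (intensity
#'   parameters are unused).
#' @param seed integer seed.
#' @return A \code{\link{SignalCounts}} object.
#' @examples
#' simulateSignalCounts(1e4, dispensingParams(multiFraction = 0.2), seed = 1)
#' @export
simulateSignalCounts <- function(nWells, params, seed = 1) {
  stopifnot(inherits(params, "dispensingParams"), nWells >= 1)
  set.seed(seed)
  tr <- drawWellTruth(nWells, params)
  SignalCounts(
    nGreenOnly = sum(tr$n_green > 0 & tr$n_red == 0),
    nRedOnly = sum(tr$n_red > 0 & tr$n_green == 0),
    nDual = sum(tr$n_green > 0 & tr$n_red > 0),
    nEmpty = sum(tr$n_cells == 0))
}

#' Deterministic dual-fluorophore benchmark experiment
#'
#' Constructs the packaged six-plate benchmark of a two-fluorophore
#' dispensing run: across the 528 dispensed wells, exactly 225 wells hold
#' one green cell, 225 one red cell, 27 one cell of each color, and 51 are
#' empty, with class positions shuffled reproducibly. The equal green/red
#' split is a convention of the benchmark (recorded in \code{metadata}).
#'
#' So that the classifier's output is known exactly in advance for every
#' seed, the benchmark's noise is bounded: backgrounds vary uniformly
#' within \code{bgHalfWidth} of \code{bgMean} and per-cell signals within
#' \code{signalHalfWidth} of \code{signalMean}, while the NTC wells take a
#' fixed symmetric spread of values about the background mean whose
#' 2-standard-deviation threshold provably exceeds every background
#' reading yet sits far below every one-cell signal. Class tallies from
#' the normalize/threshold/classify path therefore equal the constructed
#' composition by design, not by chance.
#'
#' @param seed integer seed for well placement and noise draws.
#' @param bgMean,bgHalfWidth background intensity mean and uniform noise
#'   half-width.
#' @param signalMean,signalHalfWidth per-cell signal mean and uniform
#'   noise half-width.
#' @return A list with \code{readings}, \code{truth}, \code{layout} and
#'   \code{metadata} (the exact class composition).
#' @examples
#' fx <- fixtureExperiment(seed = 1)
#' fx$metadata$composition
#' @export
fixtureExperiment <- function(seed = 1, bgMean = 100, bgHalfWidth = 2,
                              signalMean = 1000, signalHalfWidth = 20) {
  stopifnot(bgHalfWidth > 0,
            signalMean - signalHalfWidth > 4 * bgHalfWidth)
  layout <- PlateLayout()
  composition <- c(green_only = 225L, red_only = 225L, dual = 27L,
                   empty = 51L)
  set.seed(seed)
  classes <- sample(rep(names(composition), composition))
  nGreen <- as.integer(classes %in% c("green_only", "dual"))
  nRed <- as.integer(classes %in% c("red_only", "dual"))
  ## fixed NTC spread: sample sd of the 24 values is ~1.14 * bgHalfWidth,
  ## so mean + 2 sd clears the bgMean + bgHalfWidth background maximum
  ntcOffsets <- bgHalfWidth * c(-1.5, -0.5, 0.5, 1.5)
  unif <- function(n, half) stats::runif(n, -half, half)
  intensity <- function(nColor) {
    bgMean + unif(length(nColor), bgHalfWidth) +
      nColor * (signalMean + unif(length(nColor), signalHalfWidth))
  }
  disp <- wellsWithRole(layout, "dispensed")
  blank <- wellsWithRole(layout, "blank")
  ntc <- wellsWithRole(layout, "ntc")
  pos <- wellsWithRole(layout, "positive")
  readings <- vector("list", 6L)
  truth <- vector("list", 6L)
  for (i in 1:6) {
    plateId <- sprintf("plate%02d", i)
    idx <- (i - 1L) * 88L + seq_len(88L)
    tr <- rbind(
      data.frame(plate_id = plateId, well = disp,
                 n_cells = nGreen[idx] + nRed[idx],
                 n_green = nGreen[idx], n_red = nRed[idx]),
      data.frame(plate_id = plateId, well = pos, n_cells = 400L,
                 n_green = 200L, n_red = 200L),
      data.frame(plate_id = plateId, well = c(blank, ntc), n_cells = 0L,
                 n_green = 0L, n_red = 0L))
    rd <- data.frame(
      plate_id = plateId,
      well = rep(tr$well, 2),
      channel = rep(c("green", "red"), each = nrow(tr)),
      intensity = c(intensity(tr$n_green), intensity(tr$n_red)))
    rd$intensity[rd$well %in% ntc] <- rep(bgMean + ntcOffsets, 2)
    readings[[i]] <- rd
    truth[[i]] <- tr
  }
  list(readings = do.call(rbind, readings),
       truth = do.call(rbind, truth),
       layout = layout,
       metadata = list(composition = composition,
                       color_split = "equal green/red by convention",
                       n_plates = 6L, seed = seed))
}

#' Simulate dispensing of a mock community
#'
#' Models species-biased droplet dispensing of a mixed community: the
#' post-dispensing draw is multinomial with probabilities proportional to
#' \code{inputProportions * biasWeights} (bias emulating, e.g., cell-shape
#' dependent recognition by the dispenser), then thinned per species by its
#' viability; surviving droplet counts are renormalized to relative
#' abundances.
#'
#' @param species character vector of species names.
#' @param inputProportions pre-dispensing relative abundances (sum to 1).
#' @param biasWeights positive per-species dispensing bias multipliers.
#' @param nDroplets number of droplets dispensed.
#' @param viability per-species probability a dispensed droplet yields a
#'   viable culture (scalar or vector).
#' @param seed integer seed.
#' @return data.frame with columns species, pre, post (relative
#'   abundances).
#' @examples
#' simulateMockDispense(letters[1:3], c(0.5, 0.3, 0.2), seed = 1)
#' @export
simulateMockDispense <- function(species, inputProportions,
                                 biasWeights = rep(1, length(species)),
                                 nDroplets = 1e4,
                                 viability = rep(1, length(species)),
                                 seed = 1) {
  k <- length(species)
  viability <- rep_len(viability, k)
  stopifnot(length(inputProportions) == k, length(biasWeights) == k,
            all(biasWeights > 0), all(viability >= 0 & viability <= 1),
            nDroplets >= 1)
  if (abs(sum(inputProportions) - 1) > 1e-9)
    stop("inputProportions must sum to 1")
  set.seed(seed)
  w <- inputProportions * biasWeights
  dispensed <- stats::rmultinom(1, nDroplets, w / sum(w))[, 1]
  surviving <- stats::rbinom(k, dispensed, viability)
  if (sum(surviving) == 0)
    stop("degenerate sample: no surviving droplets")
  data.frame(species = species, pre = inputProportions,
             post = surviving / sum(surviving))
}

#' Simulate a cartridge wash series
#'
#' Leftover-cell detection rates after successive cartridge washes, under
#' geometric carryover decay with multiplicative log-normal noise:
#' \code{leftover_i = originalRate * retention^i * exp(N(0, noiseSd))}.
#'
#' @param originalRate pre-wash cell density (cells/min), > 0.
#' @param retentionTrue per-wash carryover retention, in (0, 1).
#' @param nWashes number of washes.
#' @param noiseSd sd of the multiplicative log-scale noise.
#' @param seed integer seed.
#' @return A \code{\link{WashSeries}}.
#' @examples
#' simulateWashSeries(1000, 0.1, nWashes = 3, noiseSd = 0, seed = 1)
#' @export
simulateWashSeries <- function(originalRate, retentionTrue, nWashes = 5,
                               noiseSd = 0, seed = 1) {
  if (!is.numeric(retentionTrue) || retentionTrue <= 0 || retentionTrue >= 1)
    stop("retention must lie strictly inside (0, 1)")
  stopifnot(originalRate > 0, nWashes >= 1, noiseSd >= 0)
  set.seed(seed)
  i <- seq_len(nWashes)
  rates <- originalRate * retentionTrue^i *
    exp(stats::rnorm(nWashes, 0, noiseSd))
  WashSeries(originalRate, rates)
}

#' Simulate a block-structured ANI matrix
#'
#' Generates the pairwise ANI / aligned-fraction input of strain and
#' lineage clustering with known lineage labels: genomes of the same
#' lineage share ANI drawn in \code{[withinAniLow, 100]} (default floor
#' 99.9), genomes of different lineages share ANI around
#' \code{betweenAni}, always strictly below \code{withinAniLow}. A small
#' asymmetric jitter emulates direction-dependent whole-genome alignment
#' output. Diagonal ANI is 100.
#'
#' @param nLineages number of lineages.
#' @param genomesPerLineage genomes per lineage (scalar or vector of length
#'   \code{nLineages}).
#' @param withinAniLow lower bound of within-lineage ANI (percent).
#' @param betweenAni scalar, or \code{nLineages x nLineages} matrix, of
#'   between-lineage ANI levels (percent); values at or above
#'   \code{withinAniLow} are rejected.
#' @param alignedFraction scalar aligned-fraction percentage for all pairs,
#'   or a full genome-level matrix (use values below the filter threshold
#'   to create unlinked pairs).
#' @param jitter half-width of the uniform directional jitter (percent).
#' @param seed integer seed.
#' @return A list with \code{ani} (an \code{\link{ANIMatrix}}) and
#'   \code{lineage} (named integer vector of true lineage labels).
#' @examples
#' sim <- simulateAniMatrix(3, 3, betweenAni = 97, seed = 1)
#' sim$lineage
#' @export
simulateAniMatrix <- function(nLineages, genomesPerLineage,
                              withinAniLow = 99.9, betweenAni = 97,
                              alignedFraction = 85, jitter = 0.02,
                              seed = 1) {
  if (nLineages < 1 || any(genomesPerLineage < 1))
    stop("lineage and genome counts must be positive")
  sizes <- rep_len(genomesPerLineage, nLineages)
  if (is.matrix(betweenAni)) {
    stopifnot(all(dim(betweenAni) == nLineages))
  } else {
    betweenAni <- matrix(betweenAni, nLineages, nLineages)
  }
  if (nLineages > 1 &&
      any(betweenAni[upper.tri(betweenAni)] >= withinAniLow))
    stop("betweenAni must be strictly below withinAniLow")
  set.seed(seed)
  n <- sum(sizes)
  lineage <- rep(seq_len(nLineages), sizes)
  ids <- sprintf("g%02d", seq_len(n))
  names(lineage) <- ids
  ani <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(ani) <- 100
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      if (lineage[i] == lineage[j]) {
        base <- stats::runif(1, withinAniLow + jitter, 100 - jitter)
      } else {
        base <- betweenAni[lineage[i], lineage[j]]
      }
      ani[i, j] <- base + stats::runif(1, -jitter, jitter)
      ani[j, i] <- base + stats::runif(1, -jitter, jitter)
    }
  }
  if (is.matrix(alignedFraction)) {
    stopifnot(all(dim(alignedFraction) == n))
    af <- alignedFraction
    dimnames(af) <- list(ids, ids)
  } else {
    af <- matrix(alignedFraction, n, n, dimnames = list(ids, ids))
  }
  diag(af) <- 100
  list(ani = ANIMatrix(ani, af), lineage = lineage)
}
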