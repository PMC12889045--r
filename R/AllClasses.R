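#' @import methods
NULL

WELL_ROLES <- c("dispensed", "blank", "ntc", "positive")
WELL_CLASSES <- c("empty", "green_only", "red_only", "dual")
CHANNELS <- c("green", "red")

#' Well identifiers of a rectangular plate
#'
#' @param rows row letters (default A-H).
#' @param cols 1-based column indices (default 1-12).
#' @return Character vector of well ids such as \code{"A1"}, in row-major
#'   order.
#' @examples
#' head(wellIds())
#' @export
wellIds <- function(rows = LETTERS[1:8], cols = 1:12) {
  as.vector(t(outer(rows, cols, paste0)))
}

## "A01" / "a1" -> "A1"; used by all readers so user tables can be sloppy
normalizeWellId <- function(x) {
  x <- toupper(trimws(x))
  row <- substr(x, 1, 1)
  col <- sub("^0+", "", substring(x, 2))
  bad <- !grepl("^[A-P][0-9]+$", paste0(row, col))
  if (any(bad)) {
    stop("malformed well id(s): ", paste(unique(x[bad]), collapse = ", "))
  }
  paste0(row, col)
}

wellColumn <- function(well) as.integer(substring(well, 2))
wellRow <- function(well) substr(well, 1, 1)

# ---------------------------------------------------------------------------
# PlateLayout
# ---------------------------------------------------------------------------

#' @rdname PlateLayout
#' @export
setClass("PlateLayout",
  representation(nRows = "integer", nCols = "integer", roleMap = "character"))

setValidity("PlateLayout", function(object) {
  wells <- wellIds(LETTERS[seq_len(object@nRows)], seq_len(object@nCols))
  msgs <- character()
  if (!setequal(names(object@roleMap), wells) ||
      length(object@roleMap) != length(wells)) {
    msgs <- c(msgs, "roleMap must assign exactly one role to every well")
  }
  if (!all(object@roleMap %in% WELL_ROLES)) {
    msgs <- c(msgs, paste("roles must be one of:",
                          paste(WELL_ROLES, collapse = ", ")))
  }
  disp <- names(object@roleMap)[object@roleMap == "dispensed"]
  if (length(disp) != 88 || any(wellColumn(disp) > 11)) {
    msgs <- c(msgs,
      "exactly the 88 wells of columns 1-11 must carry role 'dispensed'")
  }
  if (!setequal(names(object@roleMap)[object@roleMap == "blank"],
                c("A12", "B12", "C12"))) {
    msgs <- c(msgs, "blank wells must be A12-C12")
  }
  if (!setequal(names(object@roleMap)[object@roleMap == "ntc"],
                c("D12", "E12", "F12", "G12"))) {
    msgs <- c(msgs, "NTC wells must be D12-G12")
  }
  if (!identical(names(object@roleMap)[object@roleMap == "positive"], "H12")) {
    msgs <- c(msgs, "positive-control well must be H12")
  }
  if (length(msgs)) msgs else TRUE
})

#' Plate layout of a dispensing run
#'
#' The standard 96-well dispensing layout: single cells are dispensed into
#' the first 11 columns (A1-H11, 88 wells), the last column holds blanks
#' (A12-C12, never dispensed into), non-template controls (NTCs, D12-G12:
#' droplets verified empty of cells, used as fluorescence background) and a
#' multi-droplet positive control (H12).
#'
#' @param roleMap optional named character vector (well id -> role) to
#'   override the default; roles are \code{"dispensed"}, \code{"blank"},
#'   \code{"ntc"}, \code{"positive"}.
#' @return A \code{PlateLayout} object.
#' @examples
#' layout <- PlateLayout()
#' table(roles(layout))
#' @export
PlateLayout <- function(roleMap = NULL) {
  if (is.null(roleMap)) {
    wells <- wellIds()
    roleMap <- stats::setNames(rep("dispensed", length(wells)), wells)
    roleMap[c("A12", "B12", "C12")] <- "blank"
    roleMap[c("D12", "E12", "F12", "G12")] <- "ntc"
    roleMap["H12"] <- "positive"
  }
  names(roleMap) <- normalizeWellId(names(roleMap))
  new("PlateLayout", nRows = 8L, nCols = 12L, roleMap = roleMap)
}

#' @describeIn PlateLayout role of every well (named character vector).
#' @param object,x a \code{PlateLayout}.
#' @export
setGeneric("roles", function(x) standardGeneric("roles"))

#' @rdname PlateLayout
#' @export
setMethod("roles", "PlateLayout", function(x) x@roleMap)

#' Wells of a layout carrying given roles
#'
#' @param layout a \code{PlateLayout}.
#' @param role character vector of roles.
#' @return Character vector of well ids, in row-major plate order.
#' @export
wellsWithRole <- function(layout, role) {
  stopifnot(is(layout, "PlateLayout"), all(role %in% WELL_ROLES))
  names(roles(layout))[roles(layout) %in% role]
}

setMethod("show", "PlateLayout", function(object) {
  tab <- table(factor(roles(object), levels = WELL_ROLES))
  cat("PlateLayout:", object@nRows, "x", object@nCols, "wells (",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), ")\n")
})

# ---------------------------------------------------------------------------
# FluorThresholds
# ---------------------------------------------------------------------------

#' @rdname computeThresholds
#' @export
setClass("FluorThresholds",
  representation(bgMean = "numeric", bgSd = "numeric", threshold = "numeric"))

setValidity("FluorThresholds", function(object) {
  if (!setequal(names(object@threshold), CHANNELS))
    return("thresholds must be named by channel (green, red)")
  if (any(object@bgSd < 0)) return("bgSd must be >= 0")
  if (any(object@threshold < object@bgMean - 1e-12))
    return("threshold must be >= bgMean")
  TRUE
})

#' @describeIn computeThresholds per-channel positive threshold (named
#'   numeric vector).
#' @export
setGeneric("threshold", function(x) standardGeneric("threshold"))

#' @rdname computeThresholds
#' @export
setMethod("threshold", "FluorThresholds", function(x) x@threshold)

setMethod("show", "FluorThresholds", function(object) {
  cat("FluorThresholds (normalized scale, mean + 2 sd of background):\n")
  for (ch in CHANNELS) {
    cat(sprintf("  %-5s bg %.4g +/- %.4g -> threshold %.4g\n",
                ch, object@bgMean[ch], object@bgSd[ch], object@threshold[ch]))
  }
})

# ---------------------------------------------------------------------------
# SignalCounts
# ---------------------------------------------------------------------------

#' @rdname tallyClasses
#' @export
setClass("SignalCounts",
  representation(nGreenOnly = "integer", nRedOnly = "integer",
                 nDual = "integer", nEmpty = "integer"))

setValidity("SignalCounts", function(object) {
  v <- c(object@nGreenOnly, object@nRedOnly, object@nDual, object@nEmpty)
  if (length(v) != 4L || any(is.na(v)) || any(v < 0))
    return("all four counts must be single non-negative integers")
  TRUE
})

#' Tallies of classified wells
#'
#' @param nGreenOnly,nRedOnly,nDual,nEmpty well counts per class.
#' @return A \code{SignalCounts} object.
#' @examples
#' sc <- SignalCounts(225, 225, 27, 51)
#' nNonEmpty(sc)
#' @export
SignalCounts <- function(nGreenOnly = 0, nRedOnly = 0, nDual = 0, nEmpty = 0) {
  new("SignalCounts", nGreenOnly = as.integer(nGreenOnly),
      nRedOnly = as.integer(nRedOnly), nDual = as.integer(nDual),
      nEmpty = as.integer(nEmpty))
}

#' @describeIn tallyClasses number of non-empty (signal-positive) wells.
#' @export
setGeneric("nNonEmpty", function(x) standardGeneric("nNonEmpty"))

#' @rdname tallyClasses
#' @export
setMethod("nNonEmpty", "SignalCounts",
  function(x) x@nGreenOnly + x@nRedOnly + x@nDual)

#' @describeIn tallyClasses counts as a named vector
#'   (green_only, red_only, dual, empty).
#' @export
setGeneric("signalCounts", function(x) standardGeneric("signalCounts"))

#' @rdname tallyClasses
#' @export
setMethod("signalCounts", "SignalCounts", function(x) {
  c(green_only = x@nGreenOnly, red_only = x@nRedOnly,
    dual = x@nDual, empty = x@nEmpty)
})

setMethod("show", "SignalCounts", function(object) {
  ne <- nNonEmpty(object)
  cat("SignalCounts:", ne + object@nEmpty, "dispensed wells\n")
  cat(sprintf("  green_only %d, red_only %d, dual %d, empty %d\n",
              object@nGreenOnly, object@nRedOnly, object@nDual,
              object@nEmpty))
  if (ne > 0) {
    cat(sprintf("  non-empty %d (%.1f%% single-signal, %.2f%% dual)\n", ne,
                100 * (object@nGreenOnly + object@nRedOnly) / ne,
                100 * object@nDual / ne))
  }
})

# ---------------------------------------------------------------------------
# DoubletEstimate
# ---------------------------------------------------------------------------

#' @rdname estimateMultiFractionPairwise
#' @export
setClass("DoubletEstimate",
  representation(dHat = "numeric", pHat = "numeric", mHat = "numeric",
                 singleCellFreq = "numeric", ciLow = "numeric",
                 ciHigh = "numeric", model = "character",
                 lambdaHat = "numeric", denominator = "character"))

setValidity("DoubletEstimate", function(object) {
  tol <- 1e-9
  if (object@dHat < -tol || object@dHat > object@mHat + tol ||
      object@mHat > 1 + tol)
    return("must satisfy 0 <= dHat <= mHat <= 1")
  if (abs(object@singleCellFreq - 100 * (1 - object@mHat)) > 1e-6)
    return("singleCellFreq must equal 100 * (1 - mHat)")
  if (!object@model %in% c("pairwise", "truncated_poisson"))
    return("model must be 'pairwise' or 'truncated_poisson'")
  if (!is.na(object@ciLow) && !is.na(object@ciHigh) &&
      (object@ciLow > object@singleCellFreq + tol ||
       object@ciHigh < object@singleCellFreq - tol))
    return("confidence interval must contain the point estimate")
  TRUE
})

#' @describeIn estimateMultiFractionPairwise estimated single-cell dispensing
#'   frequency in percent.
#' @export
setGeneric("singleCellFreq", function(x) standardGeneric("singleCellFreq"))

#' @rdname estimateMultiFractionPairwise
#' @export
setMethod("singleCellFreq", "DoubletEstimate", function(x) x@singleCellFreq)

#' @describeIn estimateMultiFractionPairwise estimated fraction of non-empty
#'   wells holding two or more cells.
#' @export
setGeneric("multiFraction", function(x) standardGeneric("multiFraction"))

#' @rdname estimateMultiFractionPairwise
#' @export
setMethod("multiFraction", "DoubletEstimate", function(x) x@mHat)

setMethod("show", "DoubletEstimate", function(object) {
  cat(sprintf("DoubletEstimate (%s model, denominator: %s wells)\n",
              object@model, object@denominator))
  cat(sprintf("  dual-signal fraction d = %.2f%%, color proportion p = %.3f\n",
              100 * object@dHat, object@pHat))
  cat(sprintf("  multi-cell fraction   = %.1f%%\n", 100 * object@mHat))
  cat(sprintf("  single-cell frequency = %.1f%%\n", object@singleCellFreq))
  if (!is.na(object@ciLow)) {
    cat(sprintf("  95%% bootstrap CI      = [%.1f, %.1f]%%\n",
                object@ciLow, object@ciHigh))
  }
  if (!is.na(object@lambdaHat)) {
    cat(sprintf("  lambda (cells/well | >=1) = %.4f\n", object@lambdaHat))
  }
})

# ---------------------------------------------------------------------------
# Wash kinetics
# ---------------------------------------------------------------------------

#' @rdname simulateWashSeries
#' @export
setClass("WashSeries",
  representation(originalRate = "numeric", leftoverRates = "numeric"))

setValidity("WashSeries", function(object) {
  if (length(object@originalRate) != 1L || object@originalRate <= 0)
    return("originalRate must be a single positive number")
  if (any(object@leftoverRates < 0))
    return("leftoverRates must be >= 0")
  TRUE
})

#' @rdname simulateWashSeries
#' @param originalRate pre-wash cell density (cells detected per minute).
#' @param leftoverRates cells/min detected after wash 1, 2, ...
#' @export
WashSeries <- function(originalRate, leftoverRates) {
  new("WashSeries", originalRate = as.numeric(originalRate),
      leftoverRates = as.numeric(leftoverRates))
}

setMethod("show", "WashSeries", function(object) {
  cat("WashSeries:", length(object@leftoverRates), "washes, original",
      object@originalRate, "cells/min\n")
  cat("  leftover:", paste(signif(object@leftoverRates, 4), collapse = ", "),
      "\n")
})

#' @rdname fitDecay
#' @export
setClass("WashDecayFit",
  representation(logIntercept = "numeric", retention = "numeric",
                 rSquared = "numeric", nonDecaying = "logical",
                 nUsed = "integer"))

#' @describeIn fitDecay fitted per-wash retention (carryover) factor.
#' @export
setGeneric("retention", function(x) standardGeneric("retention"))

#' @rdname fitDecay
#' @export
setMethod("retention", "WashDecayFit", function(x) x@retention)

setMethod("show", "WashDecayFit", function(object) {
  cat(sprintf(
    "WashDecayFit: retention %.4g per wash (r^2 = %.4f, n = %d)%s\n",
    object@retention, object@rSquared, object@nUsed,
    if (object@nonDecaying) " [non-decaying]" else ""))
})

# ---------------------------------------------------------------------------
# ANIMatrix
# ---------------------------------------------------------------------------

#' @rdname ANIMatrix
#' @export
setClass("ANIMatrix",
  representation(ids = "character", ani = "matrix",
                 alignedFraction = "matrix"))

setValidity("ANIMatrix", function(object) {
  n <- length(object@ids)
  msgs <- character()
  for (nm in c("ani", "alignedFraction")) {
    m <- slot(object, nm)
    if (!all(dim(m) == c(n, n)))
      msgs <- c(msgs, paste(nm, "must be", n, "x", n))
    v <- m[!is.na(m)]
    if (any(v < 0 | v > 100))
      msgs <- c(msgs, paste(nm, "values must lie in [0, 100]"))
  }
  if (anyDuplicated(object@ids)) msgs <- c(msgs, "duplicate genome ids")
  d <- diag(object@ani)
  if (any(is.na(d)) || any(abs(d - 100) > 1e-9))
    msgs <- c(msgs, "diagonal ANI must be 100")
  if (length(msgs)) msgs else TRUE
})

#' Pairwise ANI matrix with aligned fractions
#'
#' Container for genome-by-genome average nucleotide identity (ANI, percent)
#' and the aligned fraction (percent of the genome covered by the alignment
#' behind each ANI value), as produced upstream by whole-genome aligners.
#' Matrices may be asymmetric as read (query vs reference direction);
#' \code{\link{buildDistance}} symmetrizes them. Missing comparisons are
#' \code{NA}.
#'
#' @param ani square numeric matrix of ANI percentages with genome ids as
#'   dimnames; diagonal must be 100.
#' @param alignedFraction square numeric matrix of aligned-fraction
#'   percentages, same dimnames.
#' @return An \code{ANIMatrix} object.
#' @seealso \code{\link{simulateAniMatrix}}, \code{\link{readAniTables}}
#' @export
ANIMatrix <- function(ani, alignedFraction) {
  ids <- rownames(ani)
  stopifnot(!is.null(ids), identical(ids, colnames(ani)),
            identical(ids, rownames(alignedFraction)),
            identical(ids, colnames(alignedFraction)))
  new("ANIMatrix", ids = ids, ani = ani, alignedFraction = alignedFraction)
}

#' @describeIn ANIMatrix genome identifiers.
#' @param x,object an \code{ANIMatrix}.
#' @export
setGeneric("genomeIds", function(x) standardGeneric("genomeIds"))

#' @rdname ANIMatrix
#' @export
setMethod("genomeIds", "ANIMatrix", function(x) x@ids)

#' @describeIn ANIMatrix the ANI percentage matrix.
#' @export
setGeneric("aniValues", function(x) standardGeneric("aniValues"))

#' @rdname ANIMatrix
#' @export
setMethod("aniValues", "ANIMatrix", function(x) x@ani)

#' @describeIn ANIMatrix the aligned-fraction percentage matrix.
#' @export
setGeneric("alignedFractions", function(x) standardGeneric("alignedFractions"))

#' @rdname ANIMatrix
#' @export
setMethod("alignedFractions", "ANIMatrix", function(x) x@alignedFraction)

setMethod("show", "ANIMatrix", function(object) {
  off <- object@ani[upper.tri(object@ani)]
  cat("ANIMatrix:", length(object@ids), "genomes;",
      sum(!is.na(off)), "of", length(off), "pairs observed\n")
  if (any(!is.na(off))) {
    cat(sprintf("  off-diagonal ANI range: %.2f - %.2f\n",
                min(off, na.rm = TRUE), max(off, na.rm = TRUE)))
  }
})

# ---------------------------------------------------------------------------
# ClusterAssignment
# ---------------------------------------------------------------------------

#' @rdname strainAndLineage
#' @export
setClass("ClusterAssignment",
  representation(assignments = "data.frame", nStrains = "integer",
                 nLineages = "integer"))

setValidity("ClusterAssignment", function(object) {
  a <- object@assignments
  need <- c("genome_id", "strain_id", "lineage_id")
  if (!all(need %in% names(a)))
    return("assignments must have genome_id, strain_id, lineage_id")
  ## the lineage partition must refine the strain partition
  if (nrow(a) &&
      any(tapply(a$strain_id, a$lineage_id,
                 function(s) length(unique(s))) > 1L))
    return("each lineage must lie within a single strain")
  if (object@nLineages < object@nStrains)
    return("lineage count must be >= strain count")
  TRUE
})

#' @describeIn strainAndLineage per-genome assignment table (data.frame with
#'   genome_id, strain_id, lineage_id).
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))

#' @rdname strainAndLineage
#' @export
setMethod("assignments", "ClusterAssignment", function(x) x@assignments)

#' @describeIn strainAndLineage number of strain-level clusters.
#' @export
setGeneric("nStrains", function(x) standardGeneric("nStrains"))

#' @rdname strainAndLineage
#' @export
setMethod("nStrains", "ClusterAssignment", function(x) x@nStrains)

#' @describeIn strainAndLineage number of lineage-level clusters.
#' @export
setGeneric("nLineages", function(x) standardGeneric("nLineages"))

#' @rdname strainAndLineage
#' @export
setMethod("nLineages", "ClusterAssignment", function(x) x@nLineages)

setMethod("show", "ClusterAssignment", function(object) {
  cat("ClusterAssignment:", nrow(object@assignments), "genomes ->",
      object@nStrains, "strains,", object@nLineages, "lineages\n")
})
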