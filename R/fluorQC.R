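checkReadings <- function(readings) {
  need <- c("plate_id", "well", "channel", "intensity")
  if (!all(need %in% names(readings)))
    stop("readings must have columns: ", paste(need, collapse = ", "))
  if (!all(readings$channel %in% CHANNELS))
    stop("channel must be one of: ", paste(CHANNELS, collapse = ", "))
  readings$well <- normalizeWellId(readings$well)
  readings
}

#' Normalize plate-reader fluorescence
#'
#' Two-step normalization of raw dual-channel intensities: each reading is
#' first divided by the mean intensity of the NTC (background) wells of its
#' own plate and channel, then each channel is min-max standardized to
#' [0, 1] across all plates of the experiment, putting the two fluorophores
#' on a common scale. Per-plate min-max is available via
#' \code{scope = "plate"}.
#'
#' @param readings data.frame with columns plate_id, well, channel,
#'   intensity.
#' @param layout a \code{\link{PlateLayout}}.
#' @param scope \code{"experiment"} (default) computes the min-max range
#'   per channel across all plates; \code{"plate"} computes it per plate.
#' @return The input data.frame with an added column \code{norm}.
#' @examples
#' sim <- simulatePlate(dispensingParams(), seed = 1)
#' norm <- normalizeReadings(sim$readings, PlateLayout())
#' range(norm$norm)
#' @export
normalizeReadings <- function(readings, layout = PlateLayout(),
                              scope = c("experiment", "plate")) {
  scope <- match.arg(scope)
  readings <- checkReadings(readings)
  ntc <- wellsWithRole(layout, "ntc")
  key <- interaction(readings$plate_id, readings$channel, drop = TRUE)
  isNtc <- readings$well %in% ntc
  for (k in levels(key)) {
    if (!any(isNtc & key == k))
      stop("no NTC wells found for ", k,
           "; background normalization is undefined")
  }
  ntcMean <- tapply(readings$intensity[isNtc], key[isNtc], mean)
  if (any(ntcMean <= 0)) stop("non-positive NTC mean intensity")
  norm1 <- as.numeric(readings$intensity / ntcMean[as.character(key)])
  mmKey <- if (scope == "experiment") readings$channel else key
  rngLo <- tapply(norm1, mmKey, min)
  rngHi <- tapply(norm1, mmKey, max)
  span <- rngHi - rngLo
  if (any(span <= 0))
    stop("degenerate scale: a channel is constant, min-max undefined")
  readings$norm <- as.numeric((norm1 - rngLo[as.character(mmKey)]) /
                                span[as.character(mmKey)])
  readings
}

#' Positive-signal thresholds from background wells
#'
#' The per-channel positive threshold is the mean plus two standard
#' deviations (n-1 denominator) of the normalized background-well
#' fluorescence. Background wells are the NTCs by default; blanks can be
#' pooled in via \code{backgroundRoles = c("ntc", "blank")}.
#'
#' @param normalized output of \code{\link{normalizeReadings}}.
#' @param layout a \code{\link{PlateLayout}}.
#' @param backgroundRoles roles treated as background.
#' @return A \code{FluorThresholds} object.
#' @examples
#' sim <- simulatePlate(dispensingParams(), seed = 1)
#' norm <- normalizeReadings(sim$readings)
#' computeThresholds(norm, PlateLayout())
#' @export
computeThresholds <- function(normalized, layout = PlateLayout(),
                              backgroundRoles = "ntc") {
  stopifnot("norm" %in% names(normalized),
            all(backgroundRoles %in% c("ntc", "blank")))
  bgWells <- wellsWithRole(layout, backgroundRoles)
  bg <- normalized[normalized$well %in% bgWells, ]
  bgMean <- bgSd <- numeric(0)
  for (ch in CHANNELS) {
    v <- bg$norm[bg$channel == ch]
    if (length(v) < 2)
      stop("need >= 2 background wells per channel to define a threshold")
    bgMean[ch] <- mean(v)
    bgSd[ch] <- stats::sd(v)
  }
  new("FluorThresholds", bgMean = bgMean, bgSd = bgSd,
      threshold = bgMean + 2 * bgSd)
}

#' Classify dispensed wells by dual-channel fluorescence
#'
#' A channel is positive when its normalized reading strictly exceeds the
#' channel threshold (ties count as negative). Dispensed wells are classed
#' \code{green_only}, \code{red_only}, \code{dual} (both positive) or
#' \code{empty} (neither); control wells keep their layout roles and are
#' not classified.
#'
#' @param normalized output of \code{\link{normalizeReadings}}.
#' @param thresholds a \code{FluorThresholds} computed on the same
#'   normalization.
#' @param layout a \code{\link{PlateLayout}}.
#' @return data.frame with columns plate_id, well, green_norm, red_norm,
#'   class.
#' @seealso \code{\link{tallyClasses}}
#' @export
classifyWells <- function(normalized, thresholds, layout = PlateLayout()) {
  stopifnot(is(thresholds, "FluorThresholds"),
            "norm" %in% names(normalized))
  disp <- wellsWithRole(layout, "dispensed")
  d <- normalized[normalized$well %in% disp, ]
  wide <- merge(
    stats::setNames(d[d$channel == "green",
                      c("plate_id", "well", "norm")],
                    c("plate_id", "well", "green_norm")),
    stats::setNames(d[d$channel == "red", c("plate_id", "well", "norm")],
                    c("plate_id", "well", "red_norm")),
    by = c("plate_id", "well"), all = TRUE)
  grid <- expand.grid(well = disp,
                      plate_id = unique(normalized$plate_id),
                      stringsAsFactors = FALSE)
  have <- paste(wide$plate_id[!is.na(wide$green_norm) &
                                !is.na(wide$red_norm)],
                wide$well[!is.na(wide$green_norm) & !is.na(wide$red_norm)])
  miss <- setdiff(paste(grid$plate_id, grid$well), have)
  if (length(miss)) {
    stop("dispensed wells missing a channel reading: ",
         paste(utils::head(miss, 10), collapse = ", "),
         if (length(miss) > 10) sprintf(" (and %d more)", length(miss) - 10))
  }
  thr <- threshold(thresholds)
  g <- wide$green_norm > thr["green"]
  r <- wide$red_norm > thr["red"]
  wide$class <- ifelse(g & r, "dual",
                ifelse(g, "green_only",
                ifelse(r, "red_only", "empty")))
  wide <- wide[order(wide$plate_id, wellRow(wide$well),
                     wellColumn(wide$well)), ]
  rownames(wide) <- NULL
  wide
}

#' Tally classified wells
#'
#' @param classes character vector of well classes, or the data.frame
#'   returned by \code{\link{classifyWells}}.
#' @return A \code{\link{SignalCounts}} object; its non-empty total is the
#'   denominator of the dual-signal fraction used downstream.
#' @examples
#' tallyClasses(c("green_only", "dual", "empty"))
#' @export
tallyClasses <- function(classes) {
  if (is.data.frame(classes)) classes <- classes$class
  if (!all(classes %in% WELL_CLASSES))
    stop("unknown well class: ",
         paste(setdiff(classes, WELL_CLASSES), collapse = ", "))
  tab <- table(factor(classes, levels = WELL_CLASSES))
  SignalCounts(nGreenOnly = tab[["green_only"]],
               nRedOnly = tab[["red_only"]],
               nDual = tab[["dual"]], nEmpty = tab[["empty"]])
}
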