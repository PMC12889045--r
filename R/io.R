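#' Read a plate-reader fluorescence table
#'
#' Reads per-well fluorescence in either the long dialect (columns
#' plate_id, well, channel, intensity) or a wide Tecan-style dialect (one
#' row per well with two intensity columns named green/red, or gfp/mapple
#' aliases). The dialect is auto-detected from the header. Well ids are
#' normalized to the \code{A1..H12} form and the presence of both channels
#' for every dispensed well is validated.
#'
#' @param path CSV file path.
#' @param layout a \code{\link{PlateLayout}} used for validation.
#' @param dialect \code{"auto"} (default), \code{"long"} or \code{"wide"}.
#' @return Long-format data.frame: plate_id, well, channel, intensity.
#' @seealso \code{\link{writePlateTable}}
#' @export
readPlateTable <- function(path, layout = PlateLayout(),
                           dialect = c("auto", "long", "wide")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  aliases <- c(gfp = "green", sfgfp = "green", mapple = "red", rfp = "red")
  for (a in names(aliases)) {
    names(tab)[names(tab) == a] <- aliases[[a]]
  }
  if (dialect == "auto") {
    dialect <- if (all(c("channel", "intensity") %in% names(tab))) {
      "long"
    } else if (all(c("green", "red") %in% names(tab))) {
      "wide"
    } else {
      stop("unknown plate-table header: ",
           paste(names(tab), collapse = ", "))
    }
  }
  if (is.null(tab$plate_id)) tab$plate_id <- "plate01"
  if (dialect == "wide") {
    tab <- data.frame(
      plate_id = rep(tab$plate_id, 2),
      well = rep(tab$well, 2),
      channel = rep(c("green", "red"), each = nrow(tab)),
      intensity = c(tab$green, tab$red))
  }
  tab <- checkReadings(tab[c("plate_id", "well", "channel", "intensity")])
  disp <- wellsWithRole(layout, "dispensed")
  want <- expand.grid(channel = CHANNELS, well = disp,
                      plate_id = unique(tab$plate_id),
                      stringsAsFactors = FALSE)
  have <- paste(tab$plate_id, tab$well, tab$channel)
  miss <- setdiff(paste(want$plate_id, want$well, want$channel), have)
  if (length(miss))
    stop("missing dispensed-well readings: ",
         paste(utils::head(miss, 8), collapse = ", "),
         if (length(miss) > 8) sprintf(" (and %d more)", length(miss) - 8))
  tab
}

#' Write a plate-reader fluorescence table
#'
#' Writes long-format readings as CSV, the dialect
#' \code{\link{readPlateTable}} round-trips.
#'
#' @param readings long-format readings data.frame.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writePlateTable <- function(readings, path) {
  readings <- checkReadings(readings)
  utils::write.csv(readings[c("plate_id", "well", "channel", "intensity")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a plate layout from a YAML or JSON plate map
#'
#' The file maps well ids to roles (\code{dispensed}, \code{blank},
#' \code{ntc}, \code{positive}); wells omitted from the map default to the
#' standard layout's role.
#'
#' @param path YAML or JSON file of well: role pairs (top-level key
#'   \code{roles} optional).
#' @return A \code{\link{PlateLayout}}.
#' @export
readPlateLayout <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(spec$roles)) spec <- spec$roles
  roleMap <- roles(PlateLayout())
  if (length(spec)) {
    spec <- unlist(spec)
    roleMap[normalizeWellId(names(spec))] <- unname(spec)
  }
  PlateLayout(roleMap)
}

readPercentTable <- function(path, percentCols) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (cc in intersect(percentCols, names(tab))) {
    v <- tab[[cc]]
    if (any(!is.na(v) & (v < 0 | v > 100)))
      stop("values of ", cc, " in ", basename(path),
           " outside [0, 100]")
  }
  tab
}

#' Read ANI, genome-quality and reference-comparison tables
#'
#' Reads the tab-separated outputs of an upstream whole-genome comparison
#' pipeline: pairwise self-comparisons (query, reference, ani_pct,
#' aligned_fraction_pct), a genome-quality table (genome_id, completeness,
#' contamination) and optionally reference comparisons (genome_id or
#' lineage_id, ref_id, ani_pct, aligned_fraction_pct). Percent fields are
#' range-checked; duplicate (query, reference) rows resolve last-wins with
#' a warning; genomes present in the ANI table but absent from the quality
#' table produce a warning and pass through.
#'
#' @param aniPath pairwise ANI TSV path.
#' @param qualityPath genome-quality TSV path.
#' @param refsPath optional reference-comparison TSV path.
#' @return A list with \code{ani} (an \code{\link{ANIMatrix}}),
#'   \code{quality} (data.frame) and \code{refs} (data.frame or NULL).
#' @seealso \code{\link{writeAniTable}}
#' @export
readAniTables <- function(aniPath, qualityPath, refsPath = NULL) {
  pair <- readPercentTable(aniPath, c("ani_pct", "aligned_fraction_pct"))
  need <- c("query", "reference", "ani_pct", "aligned_fraction_pct")
  if (!all(need %in% names(pair)))
    stop("ANI table must have columns: ", paste(need, collapse = ", "))
  key <- paste(pair$query, pair$reference)
  if (anyDuplicated(key)) {
    warning("duplicate (query, reference) rows in ", basename(aniPath),
            ": keeping the last occurrence")
    pair <- pair[!duplicated(key, fromLast = TRUE), ]
  }
  ids <- sort(unique(c(pair$query, pair$reference)))
  ani <- af <- matrix(NA_real_, length(ids), length(ids),
                      dimnames = list(ids, ids))
  ani[cbind(pair$query, pair$reference)] <- pair$ani_pct
  af[cbind(pair$query, pair$reference)] <- pair$aligned_fraction_pct
  diag(ani) <- 100
  diag(af) <- 100
  quality <- readPercentTable(qualityPath, c("completeness"))
  if (!all(c("genome_id", "completeness", "contamination") %in%
             names(quality)))
    stop("quality table must have genome_id, completeness, contamination")
  orphan <- setdiff(ids, quality$genome_id)
  if (length(orphan))
    warning("genomes in ANI table but not in quality table: ",
            paste(orphan, collapse = ", "))
  refs <- if (!is.null(refsPath)) {
    readPercentTable(refsPath, c("ani_pct", "aligned_fraction_pct"))
  }
  list(ani = ANIMatrix(ani, af), quality = quality, refs = refs)
}

#' Write an ANI matrix as a pairwise TSV
#'
#' One row per ordered genome pair with an observed comparison; the
#' dialect \code{\link{readAniTables}} round-trips.
#'
#' @param ani an \code{\link{ANIMatrix}}.
#' @param path output TSV path.
#' @return The path, invisibly.
#' @export
writeAniTable <- function(ani, path) {
  stopifnot(is(ani, "ANIMatrix"))
  a <- aniValues(ani)
  af <- alignedFractions(ani)
  idx <- which(!is.na(a) & row(a) != col(a), arr.ind = TRUE)
  tab <- data.frame(query = rownames(a)[idx[, 1]],
                    reference = colnames(a)[idx[, 2]],
                    ani_pct = a[idx],
                    aligned_fraction_pct = af[idx])
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Run the dispensing-QC pipeline from a configuration
#'
#' Executes the stages named by the configuration -- well classification
#' plus doublet estimation when \code{readings} is set, genome clustering
#' plus novelty calling when \code{ani} and \code{quality} are set -- and
#' writes a versioned JSON report embedding the fully resolved
#' configuration, so a report identifies its own inputs, parameters and
#' seeds.
#'
#' Configuration fields (YAML file path or list): \code{readings},
#' \code{layout} (optional plate-map path), \code{background}
#' (\code{"ntc"} or \code{"ntc+blank"}), \code{model} (\code{"pairwise"}
#' or \code{"poisson"}), \code{bootstrapB}, \code{seed}, \code{ani},
#' \code{quality}, \code{refs}, \code{selfMinAF}, \code{refMinAF},
#' \code{outDir}.
#'
#' @param config path to a YAML configuration or an equivalent list.
#' @param quiet suppress progress messages.
#' @return The report, invisibly (also written to
#'   \code{<outDir>/report.json}, alongside per-stage TSV outputs).
#' @export
runPipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("no such config file: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || length(config) == 0)
    stop("usage: runPipeline(config) with a non-empty configuration ",
         "naming at least one stage input ('readings' or 'ani')")
  if (is.null(config$readings) && is.null(config$ani))
    stop("configuration names no stage: set 'readings' and/or 'ani'")
  defaults <- list(background = "ntc", model = "pairwise",
                   bootstrapB = 1000L, seed = 1L, selfMinAF = 75,
                   refMinAF = 50, strainThreshold = 99,
                   lineageThreshold = 99.9, outDir = ".")
  config <- utils::modifyList(defaults, config)
  note <- function(...) if (!quiet) message("[dispenseQC] ", ...)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  report <- list(package = "dispenseQC",
                 version = as.character(utils::packageVersion("dispenseQC")),
                 config = config)

  if (!is.null(config$readings)) {
    note("classify: ", config$readings)
    layout <- if (is.null(config$layout)) PlateLayout() else
      readPlateLayout(config$layout)
    readings <- readPlateTable(config$readings, layout)
    norm <- normalizeReadings(readings, layout)
    bgRoles <- if (identical(config$background, "ntc+blank"))
      c("ntc", "blank") else "ntc"
    thr <- computeThresholds(norm, layout, backgroundRoles = bgRoles)
    classes <- classifyWells(norm, thr, layout)
    counts <- tallyClasses(classes)
    utils::write.table(classes,
                       file.path(config$outDir, "classified_wells.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    note("doublets: ", config$model, " model, B = ", config$bootstrapB)
    est <- estimateDoublets(counts, model = config$model,
                            B = config$bootstrapB, seed = config$seed)
    report$classification <- list(
      thresholds = as.list(threshold(thr)),
      counts = as.list(signalCounts(counts)),
      n_nonempty = nNonEmpty(counts))
    report$doublets <- list(
      dual_fraction = est@dHat, color_proportion = est@pHat,
      multi_cell_fraction = est@mHat,
      single_cell_freq_pct = singleCellFreq(est),
      ci_low_pct = est@ciLow, ci_high_pct = est@ciHigh,
      model = est@model)
  }

  if (!is.null(config$ani)) {
    note("cluster: ", config$ani)
    tabs <- readAniTables(config$ani, config$quality, config$refs)
    qc <- qcFilter(tabs$quality)
    keep <- intersect(genomeIds(tabs$ani), qc$kept)
    a <- aniValues(tabs$ani)[keep, keep, drop = FALSE]
    af <- alignedFractions(tabs$ani)[keep, keep, drop = FALSE]
    assign <- strainAndLineage(ANIMatrix(a, af),
                               minAlignedFraction = config$selfMinAF,
                               strainThreshold = config$strainThreshold,
                               lineageThreshold = config$lineageThreshold)
    out <- assignments(assign)
    novelty <- NULL
    if (!is.null(tabs$refs)) {
      refs <- tabs$refs
      if (!"lineage_id" %in% names(refs)) {
        refs <- merge(refs, out[c("genome_id", "lineage_id")],
                      by = "genome_id")
      }
      novelty <- noveltyCall(refs, minAlignedFraction = config$refMinAF)
      out <- merge(out, novelty, by = "lineage_id", all.x = TRUE,
                   sort = FALSE)[c("genome_id", "strain_id", "lineage_id",
                                   "best_ref_ani", "status")]
    }
    utils::write.table(out, file.path(config$outDir, "assignments.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    report$clustering <- list(
      n_genomes_in = nrow(tabs$quality),
      n_dropped_qc = length(qc$dropped), dropped = qc$dropped,
      n_strains = nStrains(assign), n_lineages = nLineages(assign),
      n_novel = if (is.null(novelty)) NA_integer_ else
        sum(novelty$status == "novel"))
  }

  report$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(report, file.path(config$outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  note("report: ", file.path(config$outDir, "report.json"))
  invisible(report)
}
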