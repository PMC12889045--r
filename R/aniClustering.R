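#' Genome assembly quality filter
#'
#' Drops assemblies whose quality metrics indicate impure or partial
#' cultures: contamination strictly above 90 percent or completeness
#' strictly below 50 percent (boundary values are kept).
#'
#' @param quality data.frame with columns genome_id, completeness,
#'   contamination (percent, as reported by an assembly QC tool).
#' @return A list with \code{kept} and \code{dropped} genome-id character
#'   vectors.
#' @examples
#' q <- data.frame(genome_id = c("a", "b"), completeness = c(98, 30),
#'                 contamination = c(1, 2))
#' qcFilter(q)
#' @export
qcFilter <- function(quality) {
  need <- c("genome_id", "completeness", "contamination")
  if (!all(need %in% names(quality)))
    stop("quality table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(quality$genome_id))
    stop("duplicate genome ids: ",
         paste(unique(quality$genome_id[duplicated(quality$genome_id)]),
               collapse = ", "))
  if (nrow(quality) == 0)
    return(list(kept = character(0), dropped = character(0)))
  bad <- quality$contamination > 90 | quality$completeness < 50
  list(kept = quality$genome_id[!bad], dropped = quality$genome_id[bad])
}

#' Symmetric clustering distance from an ANI matrix
#'
#' Symmetrizes ANI and aligned fraction by averaging the two comparison
#' directions, then converts to a distance \code{100 - ANI}. Pairs whose
#' mean aligned fraction falls below \code{minAlignedFraction} are marked
#' unlinked (\code{NA}): their ANI is considered spurious and the pair can
#' never be merged, at any threshold.
#'
#' @param ani an \code{\link{ANIMatrix}}.
#' @param minAlignedFraction minimum mean aligned fraction (percent) for a
#'   pair to be usable; the self-comparison default is 75.
#' @return Symmetric numeric distance matrix with genome-id dimnames;
#'   \code{NA} marks unlinked pairs, the diagonal is 0.
#' @seealso \code{\link{clusterGenomes}}
#' @export
buildDistance <- function(ani, minAlignedFraction = 75) {
  stopifnot(is(ani, "ANIMatrix"))
  a <- aniValues(ani)
  af <- alignedFractions(ani)
  aSym <- (a + t(a)) / 2
  afSym <- (af + t(af)) / 2
  linked <- !is.na(afSym) & afSym >= minAlignedFraction
  missing <- is.na(aSym) & linked
  diag(missing) <- FALSE
  if (any(missing)) {
    idx <- which(missing, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    stop("missing ANI for unfiltered pair(s): ",
         paste(utils::head(paste(rownames(aSym)[idx[, 1]],
                                 rownames(aSym)[idx[, 2]], sep = "-"), 5),
               collapse = ", "))
  }
  d <- 100 - aSym
  d[!linked] <- NA_real_
  diag(d) <- 0
  d
}

#' Constrained average-linkage clustering at an ANI threshold
#'
#' Agglomerative average-linkage clustering of genomes: clusters keep
#' merging while the average pairwise distance between them is at most
#' \code{100 - aniThreshold} (so a pair at exactly the threshold ANI is
#' merged). A candidate merge is forbidden outright if any member pair is
#' unlinked (\code{NA} distance) -- unlinked pairs never average into a
#' merge, rather than entering as an arbitrary large distance. Ties are
#' broken deterministically by the lexicographically smallest member ids,
#' making the partition invariant to genome input order.
#'
#' Cluster-pair averages are maintained by Lance-Williams size-weighted
#' updates, with \code{NA} propagating through them.
#'
#' @param d distance matrix from \code{\link{buildDistance}}.
#' @param aniThreshold ANI threshold in percent (99 for strains, 99.9 for
#'   lineages).
#' @return Named integer vector mapping each genome id to a cluster label;
#'   clusters are numbered by their lexicographically smallest member.
#' @examples
#' sim <- simulateAniMatrix(3, 3, betweenAni = 97, seed = 1)
#' clusterGenomes(buildDistance(sim$ani), 99)
#' @export
clusterGenomes <- function(d, aniThreshold) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d),
            aniThreshold >= 0, aniThreshold <= 100)
  ids <- rownames(d)
  stopifnot(!is.null(ids))
  n <- length(ids)
  cutoff <- (100 - aniThreshold) + 1e-9
  cd <- (d + t(d)) / 2  # guards against asymmetric float noise
  diag(cd) <- NA_real_
  sizes <- rep(1L, n)
  reps <- ids            # lexicographic minimum member id per cluster
  members <- as.list(seq_len(n))
  active <- rep(TRUE, n)
  while (sum(active) > 1L) {
    idx <- which(active)
    sub <- cd[idx, idx, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- NA_real_
    if (all(is.na(sub))) break
    best <- min(sub, na.rm = TRUE)
    if (best > cutoff) break
    cand <- which(!is.na(sub) & sub <= best + 1e-12, arr.ind = TRUE)
    pairReps <- cbind(pmin(reps[idx[cand[, 1]]], reps[idx[cand[, 2]]]),
                      pmax(reps[idx[cand[, 1]]], reps[idx[cand[, 2]]]))
    pick <- order(pairReps[, 1], pairReps[, 2])[1]
    i <- idx[min(cand[pick, ])]
    j <- idx[max(cand[pick, ])]
    ## Lance-Williams average-linkage update; NA (unlinked) propagates
    for (k in setdiff(which(active), c(i, j))) {
      v <- if (is.na(cd[i, k]) || is.na(cd[j, k])) NA_real_ else
        (sizes[i] * cd[i, k] + sizes[j] * cd[j, k]) / (sizes[i] + sizes[j])
      cd[i, k] <- cd[k, i] <- v
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    reps[i] <- min(reps[i], reps[j])
    active[j] <- FALSE
  }
  live <- which(active)
  live <- live[order(reps[live])]
  part <- integer(n)
  for (ci in seq_along(live)) part[members[[live[ci]]]] <- ci
  stats::setNames(part, ids)
}

#' Strain- and lineage-level genome clustering
#'
#' Clusters genomes at the strain (99 percent ANI) and lineage (99.9
#' percent ANI) thresholds with \code{\link{clusterGenomes}} and returns
#' nested labels. A lineage is by construction at least as fine as a
#' strain; if average-linkage heights ever invert that nesting, the
#' offending lineage is split along strain boundaries (logged via
#' \code{message}).
#'
#' @param ani an \code{\link{ANIMatrix}} of the genomes that passed
#'   \code{\link{qcFilter}}.
#' @param minAlignedFraction aligned-fraction filter for self comparisons
#'   (default 75).
#' @param strainThreshold,lineageThreshold ANI thresholds in percent.
#' @return A \code{ClusterAssignment}: per-genome strain_id (\code{"S1"},
#'   ...) and lineage_id (\code{"L1"}, ...), plus cluster counts.
#' @examples
#' sim <- simulateAniMatrix(3, 2, betweenAni = 97, seed = 4)
#' strainAndLineage(sim$ani)
#' @export
strainAndLineage <- function(ani, minAlignedFraction = 75,
                             strainThreshold = 99,
                             lineageThreshold = 99.9) {
  d <- buildDistance(ani, minAlignedFraction)
  strain <- clusterGenomes(d, strainThreshold)
  lineage <- clusterGenomes(d, lineageThreshold)
  ## enforce nesting: split any lineage that straddles strains
  crossing <- tapply(strain, lineage, function(s) length(unique(s)))
  if (any(crossing > 1L)) {
    message("split ", sum(crossing > 1L),
            " lineage(s) straddling strain boundaries")
    lineage <- as.integer(factor(paste(strain, lineage)))
    names(lineage) <- names(strain)
  }
  ids <- genomeIds(ani)
  relabel <- function(part, prefix) {
    first <- tapply(ids, part, min)
    ord <- rank(first)  # stable labels: by smallest member id
    paste0(prefix, ord[as.character(part)])
  }
  out <- data.frame(genome_id = ids,
                    strain_id = relabel(strain, "S"),
                    lineage_id = relabel(lineage, "L"))
  new("ClusterAssignment", assignments = out,
      nStrains = length(unique(out$strain_id)),
      nLineages = length(unique(out$lineage_id)))
}

#' Novelty call against reference genomes
#'
#' A lineage is novel when its best qualifying reference comparison --
#' aligned fraction at least \code{minAlignedFraction} (the looser
#' reference-comparison filter, default 50 percent) -- has ANI strictly
#' below \code{threshold}; a best reference ANI of exactly the threshold
#' is not novel. Lineages with no qualifying reference comparison are
#' flagged \code{"no_reference"} rather than novel.
#'
#' @param refs data.frame of reference comparisons with columns lineage_id
#'   (or genome_id), ref_id, ani_pct, aligned_fraction_pct.
#' @param threshold novelty ANI threshold in percent (default 99).
#' @param minAlignedFraction aligned-fraction filter for reference
#'   comparisons (default 50).
#' @return data.frame with columns lineage_id, best_ref_ani, status
#'   (\code{"novel"}, \code{"known"} or \code{"no_reference"}).
#' @examples
#' refs <- data.frame(lineage_id = c("L1", "L1", "L2"),
#'                    ref_id = c("r1", "r2", "r1"),
#'                    ani_pct = c(98.7, 97, 99.4),
#'                    aligned_fraction_pct = c(80, 90, 70))
#' noveltyCall(refs)
#' @export
noveltyCall <- function(refs, threshold = 99, minAlignedFraction = 50) {
  if ("lineage_id" %in% names(refs)) {
    unit <- "lineage_id"
  } else if ("genome_id" %in% names(refs)) {
    unit <- "genome_id"
  } else {
    stop("refs must have a lineage_id or genome_id column")
  }
  need <- c("ani_pct", "aligned_fraction_pct")
  if (!all(need %in% names(refs)))
    stop("refs must have columns: ", paste(need, collapse = ", "))
  units <- sort(unique(refs[[unit]]))
  out <- lapply(units, function(u) {
    r <- refs[refs[[unit]] == u &
                refs$aligned_fraction_pct >= minAlignedFraction, ]
    if (nrow(r) == 0) {
      data.frame(lineage_id = u, best_ref_ani = NA_real_,
                 status = "no_reference")
    } else {
      best <- max(r$ani_pct)
      data.frame(lineage_id = u, best_ref_ani = best,
                 status = if (best < threshold) "novel" else "known")
    }
  })
  do.call(rbind, out)
}
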