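#' Per-plate culture success rate
#'
#' Viable cultures as a percentage of the dispensed wells of a 96-well
#' plate (88 by the standard layout), reported to one decimal as in plate
#' summaries.
#'
#' @param nViable number of wells with viable cultures.
#' @param nDispensed number of dispensed wells (default 88).
#' @return Percentage rounded to one decimal, vectorized.
#' @examples
#' successRate(50)   # 56.8
#' @export
successRate <- function(nViable, nDispensed = 88) {
  if (any(nDispensed <= 0)) stop("nDispensed must be > 0")
  if (any(nViable < 0 | nViable > nDispensed))
    stop("nViable must lie in [0, nDispensed]")
  round(100 * nViable / nDispensed, 1)
}

#' Summarize culture runs into a condition grid
#'
#' Pivots per-plate viable-well records into the complete sample x
#' dilution x enrichment-time grid (one column per medium kept long),
#' marking combinations that were not run as \code{NA}, and totals the
#' cultures obtained.
#'
#' @param records data.frame with columns sample_id, dilution_exponent,
#'   enrichment_h, medium, n_viable and optionally n_dispensed (default
#'   88).
#' @return A list with \code{grid} (complete tidy grid with rate_pct) and
#'   \code{totalCultures} (sum of viable wells).
#' @examples
#' rec <- data.frame(sample_id = "S1", dilution_exponent = 5,
#'                   enrichment_h = c(15, 21), medium = "BSM-MUP",
#'                   n_viable = c(25, 50))
#' summarizeRuns(rec)$totalCultures
#' @export
summarizeRuns <- function(records) {
  need <- c("sample_id", "dilution_exponent", "enrichment_h", "medium",
            "n_viable")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  if (is.null(records$n_dispensed))
    records$n_dispensed <- rep(88, nrow(records))
  key <- do.call(paste, records[c("sample_id", "dilution_exponent",
                                  "enrichment_h", "medium")])
  if (anyDuplicated(key))
    stop("duplicate (sample, dilution, enrichment, medium) keys: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  if (nrow(records) == 0) {
    return(list(grid = records, totalCultures = 0L))
  }
  grid <- expand.grid(
    sample_id = unique(records$sample_id),
    dilution_exponent = unique(records$dilution_exponent),
    enrichment_h = unique(records$enrichment_h),
    medium = unique(records$medium),
    stringsAsFactors = FALSE)
  grid <- merge(grid, records, all.x = TRUE, sort = FALSE)
  grid$rate_pct <- ifelse(is.na(grid$n_viable), NA_real_,
                          successRate(ifelse(is.na(grid$n_viable), 0,
                                             grid$n_viable),
                                      ifelse(is.na(grid$n_dispensed), 88,
                                             grid$n_dispensed)))
  grid <- grid[order(grid$sample_id, grid$dilution_exponent,
                     grid$enrichment_h, grid$medium), ]
  rownames(grid) <- NULL
  list(grid = grid, totalCultures = sum(records$n_viable))
}

#' Mock-community abundance shift with a paired test
#'
#' Per-species change in relative abundance between the pre- and
#' post-dispensing community across replicates: the per-replicate delta is
#' \code{post - pre}, the summary its mean in percentage points, and the
#' p-value a two-sided one-sample t-test of the deltas against zero
#' (an exact sign-flip permutation test is available via
#' \code{test = "permutation"}; neither is claimed to reproduce any
#' published p-value, the original test being unnamed). With
#' zero-variance deltas the t-statistic is undefined: p is 1 when the
#' mean is also zero, \code{NA} (with a warning) otherwise.
#'
#' @param table data.frame with columns species, replicate, condition
#'   (\code{"pre"} or \code{"post"}) and abundance; each (replicate,
#'   condition) profile must sum to 1.
#' @param test \code{"t"} (default) or \code{"permutation"}.
#' @return data.frame with columns species, mean_delta_pp, p_value,
#'   n_replicates, sorted by mean delta.
#' @examples
#' tab <- expand.grid(species = c("a", "b"), replicate = 1:3,
#'                    condition = c("pre", "post"))
#' tab$abundance <- ifelse(tab$species == "a",
#'                         ifelse(tab$condition == "pre", 0.6, 0.4),
#'                         ifelse(tab$condition == "pre", 0.4, 0.6))
#' abundanceShift(tab)
#' @export
abundanceShift <- function(table, test = c("t", "permutation")) {
  test <- match.arg(test)
  need <- c("species", "replicate", "condition", "abundance")
  if (!all(need %in% names(table)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  if (!all(table$condition %in% c("pre", "post")))
    stop("condition must be 'pre' or 'post'")
  sums <- tapply(table$abundance,
                 interaction(table$replicate, table$condition, drop = TRUE),
                 sum)
  if (any(abs(sums - 1) > 1e-6))
    stop("each (replicate, condition) profile must sum to 1")
  pre <- table[table$condition == "pre", ]
  post <- table[table$condition == "post", ]
  if (!setequal(unique(pre$replicate), unique(post$replicate)))
    stop("mismatched replicate sets between pre and post")
  reps <- sort(unique(pre$replicate))
  if (length(reps) < 2)
    stop("need >= 2 replicates with both conditions")
  species <- sort(unique(table$species))
  out <- lapply(species, function(sp) {
    deltas <- vapply(reps, function(r) {
      po <- post$abundance[post$species == sp & post$replicate == r]
      pr <- pre$abundance[pre$species == sp & pre$replicate == r]
      sum(po) - sum(pr)  # absent species counts as abundance 0
    }, numeric(1))
    p <- if (stats::sd(deltas) < 1e-12) {
      if (abs(mean(deltas)) < 1e-12) {
        1
      } else {
        warning("constant non-zero deltas for ", sp,
                ": t-test undefined, p = NA")
        NA_real_
      }
    } else if (test == "t") {
      stats::t.test(deltas, mu = 0)$p.value
    } else {
      signFlipPValue(deltas)
    }
    data.frame(species = sp, mean_delta_pp = 100 * mean(deltas),
               p_value = p, n_replicates = length(reps))
  })
  out <- do.call(rbind, out)
  out[order(out$mean_delta_pp), , drop = FALSE]
}

## exact two-sided sign-flip permutation p-value of mean(deltas) vs 0
signFlipPValue <- function(deltas, maxExact = 15) {
  n <- length(deltas)
  obs <- abs(mean(deltas))
  if (n <= maxExact) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    stat <- abs(signs %*% deltas) / n
    mean(stat >= obs - 1e-12)
  } else {
    set.seed(0)
    stat <- replicate(1e4, abs(mean(sample(c(-1, 1), n, TRUE) * deltas)))
    mean(stat >= obs - 1e-12)
  }
}
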