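# Independent oracles used across test files.

# Brute-force constrained average-linkage: cluster-pair averages are
# recomputed from the raw distance matrix at every step (the package uses
# Lance-Williams updates instead). NA distances forbid a merge.
oracleAvgLink <- function(d, aniThreshold) {
  ids <- rownames(d)
  cutoff <- (100 - aniThreshold) + 1e-9
  clusters <- as.list(ids)
  repeat {
    k <- length(clusters)
    if (k == 1) break
    best <- NULL
    bestD <- Inf
    bestKey <- NULL
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        dv <- d[clusters[[i]], clusters[[j]], drop = FALSE]
        if (anyNA(dv)) next
        avg <- mean(dv)
        key <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
        better <- avg < bestD - 1e-12 ||
          (abs(avg - bestD) <= 1e-12 &&
             (key[1] < bestKey[1] ||
                (key[1] == bestKey[1] && key[2] < bestKey[2])))
        if (is.null(best) || better) {
          best <- c(i, j)
          bestD <- avg
          bestKey <- key
        }
      }
    }
    if (is.null(best) || bestD > cutoff) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best[2]]
  }
  part <- integer(length(ids))
  names(part) <- ids
  for (ci in seq_along(clusters)) part[clusters[[ci]]] <- ci
  part
}

# partitions as label vectors over the same names; equal up to relabeling
samePartition <- function(a, b) {
  if (!setequal(names(a), names(b))) return(FALSE)
  canon <- function(p) {
    p <- p[sort(names(p))]
    blockMin <- tapply(names(p), p, min)
    unname(blockMin[as.character(p)])
  }
  identical(canon(a), canon(b))
}

# refinement: every block of fine lies inside one block of coarse
refines <- function(fine, coarse) {
  fine <- fine[names(coarse)]
  all(tapply(coarse, fine, function(x) length(unique(x))) == 1L)
}

# random small ANI fixture with occasional unlinked pairs
randomAniFixture <- function(seed) {
  set.seed(seed)
  nLin <- sample(1:4, 1)
  sizes <- sample(1:3, nLin, replace = TRUE)
  while (sum(sizes) > 8) sizes <- sizes - (sizes > 1)
  between <- matrix(runif(nLin^2, 95, 99.7), nLin, nLin)
  between <- (between + t(between)) / 2
  n <- sum(sizes)
  af <- matrix(sample(c(80, 85, 90, 60), n * n, replace = TRUE,
                      prob = c(0.3, 0.3, 0.3, 0.1)), n, n)
  af <- pmax(af, t(af))  # symmetric enough; buildDistance averages anyway
  simulateAniMatrix(nLin, sizes, betweenAni = between,
                    alignedFraction = af, seed = seed + 1000)
}
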