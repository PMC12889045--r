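test_that("quality filter drops impure and partial genomes, keeps boundaries", {
  q <- data.frame(genome_id = c("a", "b", "c", "d", "e"),
                  completeness = c(99, 49.9, 50, 98, 100),
                  contamination = c(1, 2, 3, 90, 90.1))
  out <- qcFilter(q)
  expect_setequal(out$dropped, c("b", "e"))    # strict inequalities
  expect_setequal(out$kept, c("a", "c", "d"))  # exactly 90 / exactly 50 kept
  expect_error(qcFilter(q[c(1, 1, 2), ]), "duplicate")
  empty <- qcFilter(q[0, ])
  expect_length(empty$kept, 0)
})

test_that("the packaged 96-genome quality table loses exactly 2 genomes", {
  path <- system.file("extdata", "genome_quality_synthetic.tsv",
                      package = "dispenseQC")
  q <- read.delim(path)
  expect_equal(nrow(q), 96)
  out <- qcFilter(q)
  expect_length(out$dropped, 2)
  expect_length(out$kept, 94)
})

test_that("distances average the two comparison directions", {
  ids <- c("g1", "g2")
  a <- matrix(c(100, 99.6, 99.4, 100), 2, 2, byrow = TRUE,
              dimnames = list(ids, ids))
  af <- matrix(c(100, 80, 80, 100), 2, 2, dimnames = list(ids, ids))
  d <- buildDistance(ANIMatrix(a, af))
  expect_equal(d["g1", "g2"], 0.5)
  expect_equal(d["g2", "g1"], 0.5)
  expect_equal(diag(d), c(g1 = 0, g2 = 0))
})

test_that("low aligned fraction unlinks a pair; missing linked pairs error", {
  ids <- c("g1", "g2", "g3")
  a <- matrix(99.5, 3, 3, dimnames = list(ids, ids))
  diag(a) <- 100
  af <- matrix(85, 3, 3, dimnames = list(ids, ids))
  af["g1", "g3"] <- af["g3", "g1"] <- 60
  d <- buildDistance(ANIMatrix(a, af), minAlignedFraction = 75)
  expect_true(is.na(d["g1", "g3"]))
  expect_false(is.na(d["g1", "g2"]))
  aMiss <- a
  aMiss["g1", "g2"] <- aMiss["g2", "g1"] <- NA
  expect_error(buildDistance(ANIMatrix(aMiss, af)), "missing ANI")
})

test_that("threshold boundaries: 99.5% ANI merges at 99 but not at 99.9", {
  ids <- c("g1", "g2")
  a <- matrix(c(100, 99.5, 99.5, 100), 2, 2, dimnames = list(ids, ids))
  af <- matrix(90, 2, 2, dimnames = list(ids, ids))
  d <- buildDistance(ANIMatrix(a, af))
  expect_equal(max(clusterGenomes(d, 99)), 1L)
  expect_equal(max(clusterGenomes(d, 99.9)), 2L)
  # a pair at exactly the threshold ANI is merged (<= on merge height)
  aEq <- matrix(c(100, 99, 99, 100), 2, 2, dimnames = list(ids, ids))
  expect_equal(max(clusterGenomes(buildDistance(ANIMatrix(aEq, af)), 99)),
               1L)
})

test_that("identical genomes collapse to one cluster; unlinked stay apart", {
  ids <- paste0("g", 1:3)
  a <- matrix(100, 3, 3, dimnames = list(ids, ids))
  af <- matrix(90, 3, 3, dimnames = list(ids, ids))
  expect_equal(max(clusterGenomes(buildDistance(ANIMatrix(a, af)), 99.9)),
               1L)
  af2 <- matrix(40, 2, 2, dimnames = list(ids[1:2], ids[1:2]))
  a2 <- a[1:2, 1:2]
  d2 <- buildDistance(ANIMatrix(a2, af2))
  expect_equal(max(clusterGenomes(d2, 99)), 2L)
})

test_that("partitions match the brute-force average-linkage oracle", {
  for (seed in 1:200) {
    sim <- randomAniFixture(seed)
    d <- buildDistance(sim$ani)
    for (thr in c(99, 99.9)) {
      got <- clusterGenomes(d, thr)
      want <- oracleAvgLink(d, thr)
      expect_true(samePartition(got, want),
                  label = sprintf("seed %d thr %s", seed, thr))
    }
  }
})

test_that("hclust average linkage agrees on fully linked matrices", {
  for (seed in c(3, 17, 99)) {
    sim <- simulateAniMatrix(3, 3, betweenAni = 97, seed = seed)
    d <- buildDistance(sim$ani)
    got <- clusterGenomes(d, 99)
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    want <- stats::cutree(hc, h = 1 + 1e-9)
    expect_true(samePartition(got, want))
  }
})

test_that("clustering is invariant to genome input order", {
  for (seed in c(5, 23)) {
    sim <- randomAniFixture(seed)
    d <- buildDistance(sim$ani)
    base <- clusterGenomes(d, 99.9)
    set.seed(seed)
    perm <- sample(nrow(d))
    dp <- d[perm, perm, drop = FALSE]
    expect_true(samePartition(clusterGenomes(dp, 99.9), base))
  }
})

test_that("raising the ANI threshold never merges clusters back", {
  for (seed in c(7, 31, 64)) {
    sim <- randomAniFixture(seed)
    d <- buildDistance(sim$ani)
    ks <- vapply(c(95, 99, 99.5, 99.9, 99.99),
                 function(t) max(clusterGenomes(d, t)), numeric(1))
    expect_true(!is.unsorted(ks))
  }
})

test_that("strain/lineage assignment recovers constructed nesting", {
  # lineages 1+2 share a strain (ANI 99.3 between them), lineage 3 apart
  between <- matrix(97, 3, 3)
  between[1, 2] <- between[2, 1] <- 99.3
  sim <- simulateAniMatrix(3, 2, betweenAni = between, seed = 12)
  asg <- strainAndLineage(sim$ani)
  expect_equal(nStrains(asg), 2L)
  expect_equal(nLineages(asg), 3L)
  a <- assignments(asg)
  expect_true(all(tapply(a$strain_id, a$lineage_id,
                         function(s) length(unique(s))) == 1L))
  # true lineage labels coincide with recovered lineage blocks
  expect_true(samePartition(
    stats::setNames(as.integer(factor(a$lineage_id)), a$genome_id),
    sim$lineage))
})

test_that("degenerate assignments: single genome and unlinked pair", {
  one <- matrix(100, 1, 1, dimnames = list("g1", "g1"))
  asg1 <- strainAndLineage(ANIMatrix(one, one))
  expect_equal(nStrains(asg1), 1L)
  expect_equal(nLineages(asg1), 1L)
  ids <- c("g1", "g2")
  a <- matrix(c(100, 99.99, 99.99, 100), 2, 2, dimnames = list(ids, ids))
  af <- matrix(c(100, 50, 50, 100), 2, 2, dimnames = list(ids, ids))
  asg2 <- strainAndLineage(ANIMatrix(a, af))  # af 50 < 75 self filter
  expect_equal(nStrains(asg2), 2L)
  expect_equal(nLineages(asg2), 2L)
})

test_that("lineages refine strains across random matrices", {
  for (seed in 101:130) {
    sim <- randomAniFixture(seed)
    asg <- assignments(strainAndLineage(sim$ani))
    fine <- stats::setNames(asg$lineage_id, asg$genome_id)
    coarse <- stats::setNames(asg$strain_id, asg$genome_id)
    expect_true(refines(fine, coarse))
  }
})

test_that("novelty calls honor the threshold boundary and reference filter", {
  refs <- data.frame(
    lineage_id = c("L1", "L1", "L2", "L3", "L3"),
    ref_id = c("r1", "r2", "r1", "r1", "r2"),
    ani_pct = c(98.7, 97.2, 99.0, 99.8, 98.0),
    aligned_fraction_pct = c(80, 90, 70, 40, 45))
  out <- noveltyCall(refs)
  expect_equal(out$status[out$lineage_id == "L1"], "novel")     # 98.7 < 99
  expect_equal(out$status[out$lineage_id == "L2"], "known")     # exactly 99
  expect_equal(out$status[out$lineage_id == "L3"], "no_reference")
  expect_true(is.na(out$best_ref_ani[out$lineage_id == "L3"]))
  expect_equal(out$best_ref_ani[out$lineage_id == "L1"], 98.7)
})
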