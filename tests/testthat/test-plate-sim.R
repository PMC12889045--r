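test_that("parameter validation rejects out-of-range inputs", {
  expect_error(dispensingParams(emptyFraction = 1.2), "probability")
  expect_error(dispensingParams(colorProp = -0.1), "probability")
  expect_error(dispensingParams(bgSd = -1), "sds")
  expect_error(simulateWashSeries(1000, retentionTrue = 1), "strictly inside")
  expect_error(simulateWashSeries(1000, retentionTrue = 0), "strictly inside")
  expect_error(simulateAniMatrix(0, 3), "positive")
  expect_error(simulateAniMatrix(2, 2, betweenAni = 99.95), "strictly below")
})

test_that("noise-free all-green plate puts signal only in the green channel", {
  p <- dispensingParams(emptyFraction = 0, multiFraction = 0, colorProp = 1,
                        bgSd = 0, signalSd = 0)
  sim <- simulatePlate(p, nPlates = 1, seed = 1)
  disp <- wellsWithRole(PlateLayout(), "dispensed")
  r <- sim$readings[sim$readings$well %in% disp, ]
  expect_equal(r$intensity[r$channel == "green"], rep(1100, 88))
  expect_equal(r$intensity[r$channel == "red"], rep(100, 88))
  ctrl <- sim$readings[sim$readings$well %in% c("A12", "D12"), ]
  expect_true(all(ctrl$intensity == 100))
})

test_that("simulators are bit-reproducible for a fixed seed", {
  p <- dispensingParams()
  expect_identical(simulatePlate(p, nPlates = 2, seed = 9),
                   simulatePlate(p, nPlates = 2, seed = 9))
  expect_identical(simulateMockDispense(letters[1:4], rep(0.25, 4), seed = 3),
                   simulateMockDispense(letters[1:4], rep(0.25, 4), seed = 3))
  s1 <- simulateAniMatrix(3, 3, seed = 5)
  s2 <- simulateAniMatrix(3, 3, seed = 5)
  expect_identical(aniValues(s1$ani), aniValues(s2$ani))
})

test_that("truth bookkeeping: colors sum to cells, controls are empty", {
  sim <- simulatePlate(dispensingParams(multiFraction = 0.3,
                                        extraCellMean = 1), seed = 2)
  expect_true(all(sim$truth$n_green + sim$truth$n_red == sim$truth$n_cells))
  ctrl <- sim$truth$well %in% wellsWithRole(PlateLayout(), c("blank", "ntc"))
  expect_true(all(sim$truth$n_cells[ctrl] == 0))
})

test_that("empirical dual fraction matches the collision expectation", {
  m <- 0.2
  p <- 0.5
  n <- 1e5
  sc <- simulateSignalCounts(n, dispensingParams(
    emptyFraction = 0, multiFraction = m, extraCellMean = 0,
    colorProp = p), seed = 11)
  expected <- 2 * p * (1 - p) * m
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(sc@nDual / nNonEmpty(sc) - expected), 3 * se)
})

test_that("dual fraction converges to the general multi-cell expectation", {
  # cells in a multi well: k = 2 + Poisson(mu); dual prob given k is
  # 1 - p^k - (1-p)^k; oracle by direct expectation over k
  m <- 0.3
  p <- 0.6
  mu <- 1
  k <- 2:60
  pk <- dpois(k - 2, mu)
  expected <- m * sum(pk * (1 - p^k - (1 - p)^k))
  sc <- simulateSignalCounts(1e5, dispensingParams(
    emptyFraction = 0, multiFraction = m, extraCellMean = mu,
    colorProp = p), seed = 13)
  se <- sqrt(expected * (1 - expected) / 1e5)
  expect_lt(abs(sc@nDual / nNonEmpty(sc) - expected), 3 * se)
})

test_that("fixture experiment encodes the exact class composition", {
  fx <- fixtureExperiment(seed = 4)
  expect_equal(sum(fx$truth$n_cells[fx$truth$well %in%
                     wellsWithRole(fx$layout, "dispensed")] > 0), 477)
  comp <- fx$metadata$composition
  expect_identical(unname(comp), c(225L, 225L, 27L, 51L))
  expect_equal(nrow(fx$readings), 6 * 96 * 2)
  # dual wells carry one cell of each color
  dual <- fx$truth[fx$truth$n_green > 0 & fx$truth$n_red > 0 &
                     fx$truth$n_cells == 2, ]
  expect_equal(nrow(dual), 27)
})

test_that("unbiased mock dispensing preserves proportions within noise", {
  pre <- c(0.4, 0.3, 0.2, 0.1)
  out <- simulateMockDispense(letters[1:4], pre, nDroplets = 1e5, seed = 21)
  se <- sqrt(pre * (1 - pre) / 1e5)
  expect_true(all(abs(out$post - pre) < 4 * se))
})

test_that("bias weights tilt the multinomial expectation", {
  k <- 9
  pre <- rep(1 / k, k)
  w <- rep(1, k)
  w[3] <- 2
  out <- simulateMockDispense(paste0("sp", 1:k), pre, biasWeights = w,
                              nDroplets = 1e5, seed = 8)
  expected <- w * pre / sum(w * pre)
  se <- sqrt(expected * (1 - expected) / 1e5)
  expect_true(all(abs(out$post - expected) < 3 * se))
})

test_that("absent species stay absent and zero survival errors", {
  out <- simulateMockDispense(c("a", "b", "c"), c(0.5, 0.5, 0),
                              nDroplets = 1e4, seed = 2)
  expect_equal(out$post[3], 0)
  expect_error(
    simulateMockDispense(c("a", "b"), c(0.5, 0.5), nDroplets = 50,
                         viability = c(0, 0), seed = 2),
    "degenerate")
})

test_that("wash series follows exact geometric decay when noise-free", {
  ws <- simulateWashSeries(1000, 0.1, nWashes = 3, noiseSd = 0, seed = 1)
  expect_equal(ws@leftoverRates, c(100, 10, 1))
  expect_equal(contaminationRate(ws@leftoverRates[3], ws@originalRate),
               0.1^3)
})

test_that("simulated ANI matrices have the block structure they claim", {
  sim <- simulateAniMatrix(3, c(2, 3, 2), betweenAni = 97,
                           withinAniLow = 99.9, seed = 6)
  a <- aniValues(sim$ani)
  lin <- sim$lineage
  expect_equal(unname(diag(a)), rep(100, 7))
  same <- outer(lin, lin, "==") & upper.tri(a)
  expect_true(all(a[same] >= 99.9))
  expect_true(all(a[!same & upper.tri(a)] < 99.9))
})
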