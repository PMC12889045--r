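makeNorm <- function(wells, channels, norms, plate = "plate01") {
  data.frame(plate_id = plate, well = rep(wells, length(channels)),
             channel = rep(channels, each = length(wells)),
             intensity = 1, norm = norms)
}

test_that("min-max endpoints map to 0 and 1 per channel", {
  sim <- simulatePlate(dispensingParams(), nPlates = 2, seed = 3)
  norm <- normalizeReadings(sim$readings)
  for (ch in c("green", "red")) {
    v <- norm$norm[norm$channel == ch]
    expect_equal(min(v), 0)
    expect_equal(max(v), 1)
  }
})

test_that("a reading at the NTC mean that is also the channel minimum maps to 0", {
  layout <- PlateLayout()
  wells <- names(roles(layout))
  # all background wells at exactly 50; one dispensed well carries signal,
  # so after NTC division the channel minimum is the NTC-mean value 1
  df <- expand.grid(well = wells, channel = c("green", "red"),
                    stringsAsFactors = FALSE)
  df$plate_id <- "plate01"
  df$intensity <- 50
  df$intensity[df$well == "A1"] <- 500
  norm <- normalizeReadings(df, layout)
  expect_equal(norm$norm[norm$well == "D12" & norm$channel == "green"],
               rep(0, 1))
  expect_equal(unique(norm$norm[norm$well == "A1"]), 1)
})

test_that("normalization demands NTC wells and a non-degenerate scale", {
  layout <- PlateLayout()
  df <- expand.grid(well = setdiff(names(roles(layout)),
                                   wellsWithRole(layout, "ntc")),
                    channel = c("green", "red"), stringsAsFactors = FALSE)
  df$plate_id <- "p1"
  df$intensity <- 10
  expect_error(normalizeReadings(df, layout), "NTC")
  df2 <- expand.grid(well = names(roles(layout)),
                     channel = c("green", "red"), stringsAsFactors = FALSE)
  df2$plate_id <- "p1"
  df2$intensity <- 10  # constant channel
  expect_error(normalizeReadings(df2, layout), "degenerate")
})

test_that("threshold is mean + 2 sd of background wells (n-1 denominator)", {
  nr <- makeNorm(c("D12", "E12"), c("green", "red"), c(0.1, 0.1, 0.1, 0.1))
  thr <- computeThresholds(nr, PlateLayout())
  expect_equal(unname(threshold(thr)), c(0.1, 0.1))

  # hand oracle: mean 0.1, sd = sqrt(2 * 0.1^2 / 1) = 0.1414214
  nr2 <- makeNorm(c("D12", "E12"), c("green", "red"), c(0, 0.2, 0, 0.2))
  thr2 <- computeThresholds(nr2, PlateLayout())
  expect_equal(unname(threshold(thr2)),
               rep(0.1 + 2 * sqrt(0.02), 2), tolerance = 1e-12)

  expect_error(
    computeThresholds(makeNorm("D12", c("green", "red"), c(0.1, 0.1)),
                      PlateLayout()),
    ">= 2 background wells")
})

test_that("classification boundaries: ties negative, both above is dual", {
  layout <- PlateLayout()
  thr <- new("FluorThresholds", bgMean = c(green = 0.1, red = 0.1),
             bgSd = c(green = 0, red = 0),
             threshold = c(green = 0.1, red = 0.1))
  disp <- wellsWithRole(layout, "dispensed")
  norms <- rep(0, 88)
  norms[1] <- 0.1    # exactly at threshold: negative
  norms[2] <- 0.100001
  g <- makeNorm(disp, "green", norms)
  r <- makeNorm(disp, "red", ifelse(seq_along(disp) == 2, 0.2, 0))
  cls <- classifyWells(rbind(g, r), thr, layout)
  expect_equal(cls$class[cls$well == "A1"], "empty")
  expect_equal(cls$class[cls$well == "A2"], "dual")
  expect_true(all(cls$class[!cls$well %in% c("A1", "A2")] == "empty"))
})

test_that("missing channel readings for dispensed wells are reported", {
  sim <- simulatePlate(dispensingParams(), seed = 5)
  norm <- normalizeReadings(sim$readings)
  thr <- computeThresholds(norm)
  broken <- norm[!(norm$well == "B3" & norm$channel == "red"), ]
  expect_error(classifyWells(broken, thr), "B3")
})

test_that("noise-free plates classify with 100% accuracy against truth", {
  p <- dispensingParams(emptyFraction = 0.1, multiFraction = 0.2,
                        colorProp = 0.5, bgSd = 0, signalSd = 0)
  sim <- simulatePlate(p, nPlates = 3, seed = 17)
  norm <- normalizeReadings(sim$readings)
  thr <- computeThresholds(norm)
  cls <- classifyWells(norm, thr)
  truth <- sim$truth[sim$truth$well %in%
                       wellsWithRole(PlateLayout(), "dispensed"), ]
  m <- merge(cls, truth, by = c("plate_id", "well"))
  trueClass <- with(m, ifelse(n_cells == 0, "empty",
                       ifelse(n_green > 0 & n_red > 0, "dual",
                       ifelse(n_green > 0, "green_only", "red_only"))))
  expect_equal(m$class, trueClass)
})

test_that("classification is invariant to positive affine raw rescaling", {
  fx <- fixtureExperiment(seed = 2)
  base <- classifyWells(
    normalizeReadings(fx$readings, fx$layout),
    computeThresholds(normalizeReadings(fx$readings, fx$layout),
                      fx$layout),
    fx$layout)
  scaled <- fx$readings
  gains <- c(green = 3.7, red = 0.42)
  offsets <- c(green = 55, red = 10)
  scaled$intensity <- gains[scaled$channel] * scaled$intensity +
    offsets[scaled$channel]
  normS <- normalizeReadings(scaled, fx$layout)
  clsS <- classifyWells(normS, computeThresholds(normS, fx$layout),
                        fx$layout)
  expect_equal(base$class, clsS$class)
})

test_that("blanks can be pooled into the background set", {
  fx <- fixtureExperiment(seed = 3)
  norm <- normalizeReadings(fx$readings, fx$layout)
  thrPooled <- computeThresholds(norm, fx$layout,
                                 backgroundRoles = c("ntc", "blank"))
  cls <- classifyWells(norm, thrPooled, fx$layout)
  expect_equal(unname(signalCounts(tallyClasses(cls))),
               unname(fx$metadata$composition))
})

test_that("tally matches a brute-force per-label count and sums close", {
  expect_equal(unname(signalCounts(tallyClasses(character(0)))),
               rep(0L, 4))
  set.seed(31)
  for (i in 1:5) {
    labs <- sample(c("empty", "green_only", "red_only", "dual"),
                   sample(1:200, 1), replace = TRUE)
    sc <- tallyClasses(labs)
    expect_equal(unname(signalCounts(sc)),
                 c(sum(labs == "green_only"), sum(labs == "red_only"),
                   sum(labs == "dual"), sum(labs == "empty")))
    ne <- nNonEmpty(sc)
    if (ne > 0) {
      expect_equal((sc@nGreenOnly + sc@nRedOnly + sc@nDual) / ne, 1)
    }
  }
  expect_error(tallyClasses(c("empty", "weird")), "unknown well class")
})

test_that("the benchmark experiment reproduces its constructed tallies", {
  fx <- fixtureExperiment(seed = 1)
  norm <- normalizeReadings(fx$readings, fx$layout)
  thr <- computeThresholds(norm, fx$layout)
  sc <- tallyClasses(classifyWells(norm, thr, fx$layout))
  expect_equal(unname(signalCounts(sc)), c(225L, 225L, 27L, 51L))
  expect_equal(nNonEmpty(sc), 477L)
})
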