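## Independent metric oracles, coded without reference to the package
## implementations.
oraclePearson <- function(x, y) stats::cor(x, y)
oracleRmse <- function(o, p) {
  acc <- 0
  for (i in seq_along(o)) acc <- acc + (o[i] - p[i])^2
  sqrt(acc / length(o))
}

## Small noiseless sample set from a linear mapping of the nine predictors.
linearSamples <- function(n, seed = 1, noise = 0) {
  set.seed(seed)
  X <- data.frame(
    lon = runif(n, 100, 120), lat = runif(n, 25, 40),
    doy = sample(1:365, n, replace = TRUE), aod = runif(n, 0, 2),
    rh = runif(n, 30, 95), temp = runif(n, 260, 300),
    ws = runif(n, 0.5, 8), sp = runif(n, 99000, 103000),
    hpbl = runif(n, 200, 1800)
  )
  X$pm25 <- pmax(30 + 35 * X$aod + 0.08 * X$rh - 0.01 * X$hpbl -
                   1.2 * X$ws + rnorm(n, 0, noise), 0)
  X
}

test_that("pearsonR matches identity, reversal, and the covariance oracle", {
  expect_equal(pearsonR(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(pearsonR(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pearsonR(c(1, 2, 3, 4), c(2, 2, 4, 3)),
               oraclePearson(c(1, 2, 3, 4), c(2, 2, 4, 3)),
               tolerance = 1e-12)
  set.seed(7)
  for (i in 1:50) {
    x <- rnorm(20); y <- rnorm(20)
    expect_equal(pearsonR(x, y), oraclePearson(x, y), tolerance = 1e-12)
    ## invariance under positive affine transforms
    expect_equal(pearsonR(2.5 * x + 3, y), pearsonR(x, y),
                 tolerance = 1e-12)
  }
  expect_error(pearsonR(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearsonR(1, 1), "at least 2")
})

test_that("rmse matches closed forms and the loop oracle", {
  expect_equal(rmse(c(5, 5), c(5, 5)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  set.seed(8)
  for (i in 1:50) {
    o <- rnorm(15, 50, 10); p <- rnorm(15, 50, 10)
    expect_equal(rmse(o, p), oracleRmse(o, p), tolerance = 1e-12)
    expect_gte(rmse(o, p), 0)
  }
  expect_error(rmse(numeric(0), numeric(0)), "empty")
})

test_that("training is deterministic, warns on out-of-range widths, rejects degenerate labels", {
  s <- linearSamples(150)
  m1 <- suppressWarnings(trainRetrieval(s, maxEpochs = 50L, seed = 3L))
  m2 <- suppressWarnings(trainRetrieval(s, maxEpochs = 50L, seed = 3L))
  expect_identical(m1@W1, m2@W1)
  expect_identical(m1@W2, m2@W2)
  expect_warning(trainRetrieval(s, hiddenNodes = 25L, maxEpochs = 5L),
                 "outside the heuristic range")
  expect_no_warning(trainRetrieval(s, hiddenNodes = 18L, maxEpochs = 5L))
  s0 <- s; s0$pm25 <- 77
  expect_error(trainRetrieval(s0), "degenerate label")
})

test_that("the network recovers a noiseless linear mapping (fit R >= 0.99)", {
  s <- linearSamples(2000)
  m <- trainRetrieval(s, maxEpochs = 800L, seed = 1L)
  pred <- predict(m, s)
  expect_gte(pearsonR(s$pm25, pred), 0.99)
})

test_that("prediction clamps at zero and propagates missing predictors", {
  s <- linearSamples(120)
  m <- suppressWarnings(trainRetrieval(s, maxEpochs = 20L, seed = 2L))
  zero <- m
  zero@W1[] <- 0; zero@b1[] <- 0; zero@W2[] <- 0; zero@b2 <- 0
  ## all-zero weights predict the (clamped) label z-score origin shifted
  ## back: max(labelCenter, 0) -- with zero center it is exactly 0
  zero@labelCenter <- 0
  expect_equal(predict(zero, s[1:5, ]), rep(0, 5))
  sNA <- s[1:6, ]
  sNA$aod[3] <- NA
  p <- predict(m, sNA)
  expect_true(is.na(p[3]))
  expect_true(all(!is.na(p[-3])))
  expect_true(all(p >= 0, na.rm = TRUE))
})

test_that("missing AOD pixels yield missing retrieved pixels", {
  cfg <- simulationConfig(nStations = 2L, startDate = "2013-02-01",
                          endDate = "2013-02-28",
                          newYearDates = "2013-02-10",
                          cloudMissingProb = 0.6, seed = 12L)
  sim <- generateStationSeries(cfg)
  grids <- generateGrids(cfg, sim$truth,
                         dates = as.Date("2013-02-05"))
  s <- linearSamples(120)
  m <- suppressWarnings(trainRetrieval(s, maxEpochs = 20L, seed = 2L))
  day <- grids[[1]]
  ret <- retrieveGrid(m, day)
  merged <- mergeDailyAOD(day$terra, day$aqua)
  expect_identical(is.na(gridValues(ret)), is.na(gridValues(merged)))
  expect_identical(gridVariable(ret), "PM2.5")
})

test_that("cross-validation folds partition the samples almost equally", {
  f <- cvFolds(25, 10, seed = 5)
  expect_equal(sort(as.vector(table(f))), c(rep(2L, 5), rep(3L, 5)))
  expect_length(f, 25)
  for (seed in 1:10) {
    f <- cvFolds(103, 10, seed = seed)
    sizes <- table(factor(f, levels = 1:10))
    expect_lte(diff(range(sizes)), 1)
    expect_equal(sum(sizes), 103)
  }
  expect_error(cvFolds(25, 1), "k must be")
  expect_error(cvFolds(5, 10), "at least k")
})

test_that("every sample is validated exactly once and CV tracks the fit", {
  s <- linearSamples(400)
  cv <- crossValidate(s, k = 10, seed = 2, maxEpochs = 300L)
  pred <- attr(cv, "predictions")
  expect_true(all(!is.na(pred)))          # each sample predicted once
  folds <- attr(cv, "folds")
  expect_setequal(unique(folds), 1:10)
  m <- trainRetrieval(s, maxEpochs = 300L, seed = 2)
  fitRval <- pearsonR(s$pm25, predict(m, s))
  ## out-of-fold R cannot beat the in-sample fit by more than slack
  expect_lte(fitR(cv), fitRval + 0.02)
  expect_gte(fitR(cv), 0.97)
})

test_that("the hand-rolled network is competitive with an independent MLP on the same data", {
  skip_if_not_installed("nnet")
  s <- linearSamples(600, seed = 4, noise = 5)
  m <- trainRetrieval(s, maxEpochs = 500L, seed = 1L)
  ours <- rmse(s$pm25, predict(m, s))
  X <- scale(as.matrix(s[, c("lon", "lat", "doy", "aod", "rh", "temp",
                             "ws", "sp", "hpbl")]))
  set.seed(1)
  ref <- nnet::nnet(X, scale(s$pm25), size = 18, linout = TRUE,
                    maxit = 500, trace = FALSE, decay = 0)
  refRmse <- sqrt(mean((predict(ref, X) * sd(s$pm25) + mean(s$pm25) -
                          s$pm25)^2))
  expect_lt(ours, 2 * refRmse + 1)
})

test_that("model JSON serialisation round-trips weights and predictions", {
  s <- linearSamples(150)
  m <- suppressWarnings(trainRetrieval(s, maxEpochs = 30L, seed = 6L))
  f <- tempfile(fileext = ".json")
  writeRetrievalModel(m, f)
  r <- readRetrievalModel(f)
  expect_equal(r@W1, m@W1)
  expect_equal(r@b2, m@b2)
  expect_equal(predict(r, s[1:10, ]), predict(m, s[1:10, ]))
})
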