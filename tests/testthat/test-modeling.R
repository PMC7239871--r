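test_that("splits follow the 80/20 rule with balanced folds", {
  plan <- makeSplit(100, seed = 1)
  expect_length(plan@trainIds, 80L)
  expect_length(plan@testIds, 20L)
  expect_true(all(lengths(plan@folds) == 16L))

  # n = 147: round(0.8 * 147) = 118 training structures
  plan147 <- makeSplit(147, seed = 2)
  expect_length(plan147@trainIds, 118L)
  expect_length(plan147@testIds, 29L)
  expect_lte(diff(range(lengths(plan147@folds))), 1L)

  # partition invariants
  expect_length(intersect(plan@trainIds, plan@testIds), 0L)
  expect_setequal(unlist(plan@folds), plan@trainIds)

  expect_error(makeSplit(9, seed = 1), "too small")
})

test_that("the same seed reproduces the identical plan", {
  a <- makeSplit(57, seed = 42)
  b <- makeSplit(57, seed = 42)
  expect_identical(a@trainIds, b@trainIds)
  expect_identical(a@folds, b@folds)
  c <- makeSplit(57, seed = 43)
  expect_false(identical(a@trainIds, c@trainIds))
})

test_that("kNN prediction is the exp(-d)-weighted neighbour average", {
  # hand-computed 3-point example: neighbours at d = 1 and 2
  tr <- rbind(a = c(1, 0), b = c(2, 0))
  colnames(tr) <- c("d1", "d2")
  m <- structure(list(x = tr, y = c(3, 7), ids = c("a", "b"),
                      subset = c("d1", "d2"), k = 2L, q2 = 1),
                 class = "knnModel")
  q <- matrix(c(0, 0), 1, dimnames = list(NULL, c("d1", "d2")))
  expected <- (exp(-1) * 3 + exp(-2) * 7) / (exp(-1) + exp(-2))
  expect_equal(unname(knnPredict(m, q)), expected, tolerance = 1e-12)

  # symmetric equidistant neighbours average their values
  m$y <- c(0, 2)
  qmid <- matrix(c(1.5, 0), 1, dimnames = list(NULL, c("d1", "d2")))
  expect_equal(unname(knnPredict(m, qmid)), 1, tolerance = 1e-12)

  # k = 1 on a coincident point returns that training value
  m$k <- 1L
  expect_equal(unname(knnPredict(m, matrix(c(1, 0), 1,
    dimnames = list(NULL, c("d1", "d2"))))), 0)
})

test_that("kNN prediction ignores columns outside the selected subset", {
  set.seed(3)
  x <- matrix(runif(60), 12, 5, dimnames = list(NULL, paste0("d", 1:5)))
  y <- x[, 1] * 2
  m <- structure(list(x = x, y = y, ids = NULL, subset = c("d1", "d3"),
                      k = 3L, q2 = 1), class = "knnModel")
  q <- matrix(runif(5), 1, dimnames = list(NULL, paste0("d", 1:5)))
  p1 <- knnPredict(m, q)
  q2 <- q; q2[, c(2, 4, 5)] <- 99
  expect_identical(knnPredict(m, q2), p1)
})

test_that("variable selection recovers planted descriptors", {
  # y depends only on descriptors 3 and 7 (n = 60, sigma = 0.05 * range)
  hits <- 0L
  nSeeds <- 100L
  for (s in seq_len(nSeeds)) {
    set.seed(1000 + s)
    x <- matrix(runif(60 * 20), 60, 20, dimnames = list(NULL, paste0("d", 1:20)))
    y0 <- 3 * x[, 3] - 2 * x[, 7]
    y <- y0 + rnorm(60, 0, 0.05 * diff(range(y0)))
    m <- knnFit(x, y, subsetSizes = c(2, 4), saSteps = 60L, seed = s)
    if (any(c("d3", "d7") %in% m$subset)) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})

test_that("degenerate kNN inputs are handled", {
  x <- matrix(runif(40), 10, 4, dimnames = list(NULL, paste0("d", 1:4)))
  expect_error(knnFit(x, rnorm(10), subsetSizes = 10), "subset size")
  # constant endpoint: constant prediction, zero error
  m <- knnFit(x, rep(2, 10), subsetSizes = 2, seed = 1)
  p <- knnPredict(m, x)
  expect_true(all(p == 2))
})

test_that("evaluate matches hand formulas and documents the R2 convention", {
  expect_equal(unname(evaluateModel(c(0, 1, 2), c(0, 1, 2))),
               c(1, 0))
  # anti-correlated predictions: squared Pearson gives R2 = 1, RMSE > 0
  ev <- evaluateModel(c(2, 1, 0), c(0, 1, 2))
  expect_equal(unname(ev["R2"]), 1)
  expect_gt(ev["RMSE"], 0)
  # the coefficient-of-determination alternative is negative there
  expect_lt(evaluateModel(c(2, 1, 0), c(0, 1, 2), method = "cod")["R2"], 0)

  expect_equal(unname(evaluateModel(c(0, 1, 4), c(0, 1, 2))["RMSE"]),
               sqrt(4 / 3), tolerance = 1e-12)
  expect_warning(ev2 <- evaluateModel(c(1, 2, 3), c(5, 5, 5)), "constant")
  expect_true(is.na(ev2["R2"]))
})

test_that("evaluate agrees with brute-force formulas on random vectors", {
  set.seed(8)
  for (i in 1:25) {
    n <- sample(5:50, 1)
    p <- rnorm(n); o <- rnorm(n)
    ev <- evaluateModel(p, o)
    expect_equal(unname(ev["RMSE"]), sqrt(sum((p - o)^2) / n),
                 tolerance = 1e-12)
    expect_equal(unname(ev["R2"]), cor(p, o)^2, tolerance = 1e-12)
  }
})

test_that("the DNN learns, is deterministic, and flags divergence", {
  set.seed(21)
  n <- 200
  x <- matrix(runif(n * 5), n, 5, dimnames = list(NULL, paste0("d", 1:5)))
  y <- x %*% c(1, -2, 0.5, 1.5, -1) + rnorm(n, 0, 0.05)
  m <- dnnFit(x, y, hidden = c(32, 16, 8), epochs = 30L, seed = 1)
  expect_lt(tail(m$history, 1), m$history[1])
  expect_length(m$history, 30L)
  p <- dnnPredict(m, x)
  expect_true(all(is.finite(p)))
  expect_gt(cor(p, y)^2, 0.5)

  # identical seeds give bitwise-identical training trajectories
  m2 <- dnnFit(x, y, hidden = c(32, 16, 8), epochs = 30L, seed = 1)
  expect_identical(m$history, m2$history)
  expect_identical(m$W, m2$W)

  # constant endpoint collapses to the constant
  mC <- dnnFit(x, rep(1.5, n), hidden = c(8, 4), epochs = 20L, seed = 2)
  expect_lt(max(abs(dnnPredict(mC, x) - 1.5)), 0.2)

  # absurd learning rate diverges with a named error
  expect_error(
    dnnFit(x, y * 1e6, hidden = c(16, 8), epochs = 50L, lr = 1e12, seed = 3),
    "divergence")
})

test_that("cross-validation predicts every training point exactly once", {
  set.seed(17)
  n <- 60
  x <- matrix(runif(n * 8), n, 8,
              dimnames = list(sprintf("s%02d", 1:n), paste0("d", 1:8)))
  y <- setNames(2 * x[, 2] - x[, 5] + rnorm(n, 0, 0.1), rownames(x))
  plan <- makeSplit(rownames(x), seed = 5)
  rep <- crossValidate(x, y, plan, method = "knn", seed = 5,
                       subsetSizes = c(2, 4), saSteps = 40L)
  cv <- rep@cvPredictions
  expect_setequal(cv$id, plan@trainIds)
  expect_equal(anyDuplicated(cv$id), 0L)
  expect_setequal(rep@valPredictions$id, plan@testIds)
  expect_true(all(is.finite(rep@valPredictions$predicted)))
  m <- modelMetrics(rep)
  expect_named(m, c("R2_5CV", "RMSE_5CV", "R2_val", "RMSE_val"))
  expect_true(all(m[c("RMSE_5CV", "RMSE_val")] >= 0))

  # identical seeds reproduce identical numbers
  rep2 <- crossValidate(x, y, plan, method = "knn", seed = 5,
                        subsetSizes = c(2, 4), saSteps = 40L)
  expect_identical(modelMetrics(rep), modelMetrics(rep2))
})

test_that("no test information leaks into fitting or normalization", {
  set.seed(23)
  n <- 50
  x <- matrix(runif(n * 6), n, 6,
              dimnames = list(sprintf("s%02d", 1:n), paste0("d", 1:6)))
  y <- setNames(x[, 1] + rnorm(n, 0, 0.05), rownames(x))
  plan <- makeSplit(rownames(x), seed = 9)

  rep1 <- crossValidate(x, y, plan, method = "knn", seed = 9,
                        subsetSizes = 2, saSteps = 30L)
  # corrupt the test rows wildly: training-side results must not move
  x2 <- x
  x2[plan@testIds, ] <- x2[plan@testIds, ] * 100 + 55
  y2 <- y
  y2[plan@testIds] <- y2[plan@testIds] + 1000
  rep2 <- crossValidate(x2, y2, plan, method = "knn", seed = 9,
                        subsetSizes = 2, saSteps = 30L)
  expect_identical(rep1@cvPredictions, rep2@cvPredictions)
  expect_identical(modelMetrics(rep1)[c("R2_5CV", "RMSE_5CV")],
                   modelMetrics(rep2)[c("R2_5CV", "RMSE_5CV")])
})
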