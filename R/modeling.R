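## Quantitative nanostructure-activity modeling: 80/20 split with 5-fold
## cross-validation, kNN regression with weighted-neighbour prediction and
## simulated-annealing variable selection, a feedforward neural network
## (relu, dropout, rmsprop, MSE), and R2/RMSE reporting.  Normalization
## statistics are always fitted on training data only.

#' Draw an 80/20 split with 5 CV folds
#'
#' `round(0.8 n)` ids go to training; the training ids are dealt into five
#' folds round-robin after a seeded shuffle, so fold sizes differ by at
#' most one.
#'
#' @param ids Character vector of structure ids (n >= 10), or a number n.
#' @param seed Integer seed; the same seed reproduces the plan exactly.
#' @param nFolds Number of CV folds (default 5).
#' @return A [SplitPlan-class].
#' @export
makeSplit <- function(ids, seed = 1L, nFolds = 5L) {
  if (is.numeric(ids) && length(ids) == 1) ids <- as.character(seq_len(ids))
  ids <- as.character(ids)
  n <- length(ids)
  if (n < 10) stop("too small: need at least 10 ids, got ", n)
  oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))
  set.seed(as.integer(seed))
  perm <- sample(ids)
  nTrain <- round(0.8 * n)
  train <- perm[seq_len(nTrain)]
  test <- perm[-seq_len(nTrain)]
  folds <- split(train, rep_len(seq_len(nFolds), nTrain))
  names(folds) <- NULL
  new("SplitPlan", seed = as.integer(seed), trainIds = train,
      testIds = test, folds = folds)
}

## squared-distance matrix contribution of one column
.colD2 <- function(col) {
  d <- outer(col, col, "-")
  d * d
}

## leave-one-out q2 of weighted kNN on a column subset (the variable
## selection objective); returns the best (q2, k) over kRange
.looQ2 <- function(x, y, subset, kRange) {
  D2 <- Reduce(`+`, lapply(subset, function(j) .colD2(x[, j])))
  .looQ2FromD2(D2, y, kRange)
}

## same, from a precomputed squared-distance matrix (incremental SA updates);
## vectorized via cumulative weighted sums over the kmax nearest neighbours
.looQ2FromD2 <- function(D2, y, kRange) {
  D <- sqrt(pmax(D2, 0))
  diag(D) <- Inf
  n <- nrow(D)
  kmax <- min(max(kRange), n - 1L)
  idxRow <- seq_len(n)
  cw <- 0; cwy <- 0
  best <- c(q2 = -Inf, k = kRange[1])
  vy <- sum((y - mean(y))^2)
  for (k in seq_len(kmax)) {
    j <- max.col(-D, ties.method = "first")
    dk <- D[cbind(idxRow, j)]
    D[cbind(idxRow, j)] <- Inf
    w <- pmax(exp(-dk), 1e-300)
    cw <- cw + w
    cwy <- cwy + w * y[j]
    if (k %in% kRange) {
      pred <- cwy / cw
      pc <- pred - mean(pred)
      vp <- sum(pc^2)
      q2 <- if (vp < 1e-24 || vy < 1e-24) 0
            else sum(pc * (y - mean(y)))^2 / (vp * vy)
      if (q2 > best["q2"]) best <- c(q2 = q2, k = k)
    }
  }
  best
}

#' Fit a weighted-neighbour kNN model with variable selection
#'
#' Selects a descriptor subset by simulated annealing (geometric cooling)
#' maximizing the leave-one-out q2 on the training set; prediction uses the
#' weighted average of the k nearest training points in the selected-subset
#' Euclidean metric, with weights `exp(-d)`.  k is searched over `kRange`
#' jointly with the subset.
#'
#' @param x Normalized training matrix (rows = structures, named columns).
#' @param y Numeric endpoint values.
#' @param kRange Candidate neighbour counts (default 1:5).
#' @param subsetSizes Candidate subset sizes (default `c(5, 10, 15, 20, 25,
#'   30)`, capped at `ncol(x)`).
#' @param saSteps Annealing steps per subset size.
#' @param t0,cooling Initial temperature and geometric cooling factor.
#' @param seed Integer seed.
#' @return A `knnModel` list: `x`, `y`, `ids`, `subset`, `k`, `q2`.
#' @export
knnFit <- function(x, y, kRange = 1:5, subsetSizes = c(5, 10, 15, 20, 25, 30),
                   saSteps = 400L, t0 = 0.05, cooling = 0.97, seed = 1L) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("d", seq_len(ncol(x)))
  stopifnot(length(y) == nrow(x))
  subsetSizes <- unique(subsetSizes[subsetSizes <= ncol(x)])
  if (!length(subsetSizes))
    stop("subset size exceeds available descriptors (", ncol(x), ")")
  if (stats::sd(y) < 1e-12) {
    ## constant endpoint: any subset predicts the constant
    return(structure(list(x = x, y = y, ids = rownames(x),
                          subset = colnames(x)[seq_len(min(subsetSizes))],
                          k = kRange[1], q2 = 0),
                     class = "knnModel"))
  }
  oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))
  set.seed(as.integer(seed))
  p <- ncol(x)
  bestAll <- NULL
  for (sz in subsetSizes) {
    cur <- sort(sample(p, sz))
    curD2 <- Reduce(`+`, lapply(cur, function(j) .colD2(x[, j])))
    curBest <- .looQ2FromD2(curD2, y, kRange)
    best <- list(subset = cur, q2 = curBest["q2"], k = curBest["k"])
    temp <- t0
    curQ2 <- curBest["q2"]
    for (step in seq_len(saSteps)) {
      if (sz >= p) break
      out <- sample(sz, 1)
      inn <- sample(setdiff(seq_len(p), cur), 1)
      candD2 <- curD2 - .colD2(x[, cur[out]]) + .colD2(x[, inn])
      res <- .looQ2FromD2(candD2, y, kRange)
      delta <- res["q2"] - curQ2
      if (delta > 0 || stats::runif(1) < exp(delta / temp)) {
        cur[out] <- inn
        curD2 <- candD2
        curQ2 <- res["q2"]
        if (curQ2 > best$q2)
          best <- list(subset = sort(cur), q2 = curQ2, k = res["k"])
      }
      temp <- temp * cooling
    }
    if (is.null(bestAll) || best$q2 > bestAll$q2) bestAll <- best
  }
  structure(list(x = x, y = y, ids = rownames(x),
                 subset = colnames(x)[bestAll$subset],
                 k = as.integer(bestAll$k), q2 = as.numeric(bestAll$q2)),
            class = "knnModel")
}

#' Predict with a fitted kNN model
#'
#' `yhat = sum(w_i y_i) / sum(w_i)` over the k nearest training points in
#' the selected-subset Euclidean metric, `w_i = exp(-d_i)`.  Distance ties
#' are broken by training id order, so predictions are deterministic and
#' invariant to descriptor columns outside the selected subset.
#'
#' @param model A `knnModel` from [knnFit()].
#' @param newx Matrix (or single row) with at least the selected columns,
#'   on the training normalization scale.
#' @return Numeric predictions.
#' @export
knnPredict <- function(model, newx) {
  stopifnot(inherits(model, "knnModel"))
  newx <- rbind(newx)
  if (!all(model$subset %in% colnames(newx))) {
    if (ncol(newx) == ncol(model$x)) colnames(newx) <- colnames(model$x)
    else stop("dimension mismatch: query lacks the selected descriptors")
  }
  tr <- model$x[, model$subset, drop = FALSE]
  qu <- newx[, model$subset, drop = FALSE]
  k <- model$k
  ord0 <- seq_len(nrow(tr))
  apply(qu, 1, function(q) {
    d <- sqrt(colSums((t(tr) - q)^2))
    nb <- order(d, ord0)[seq_len(k)]
    w <- exp(-d[nb])
    if (sum(w) < 1e-300) mean(model$y[nb]) else sum(w * model$y[nb]) / sum(w)
  })
}

#' Fit a feedforward neural-network regressor
#'
#' Fully connected network with rectified-linear hidden layers (default
#' widths 512/128/64), inverted dropout (rate 0.2) after each hidden layer,
#' an rmsprop optimizer at its standard learning rate, and mean-squared-
#' error loss, trained for 300 epochs by default.  The endpoint is
#' standardized internally and predictions are returned on the original
#' scale.  Fully deterministic given the seed.
#'
#' @param x Normalized training matrix.
#' @param y Endpoint values.
#' @param hidden Hidden-layer widths.
#' @param dropout Dropout rate after each hidden layer.
#' @param epochs Training epochs.
#' @param batchSize Minibatch size.
#' @param lr rmsprop learning rate.
#' @param seed Integer seed.
#' @return A `dnnModel` list with weights, scaling, and per-epoch `history`.
#' @export
dnnFit <- function(x, y, hidden = c(512, 128, 64), dropout = 0.2,
                   epochs = 300L, batchSize = 32L, lr = 1e-3, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 10) stop("too small: need n >= 10")
  yMu <- mean(y)
  ySd <- stats::sd(y)
  if (ySd < 1e-12) ySd <- 1
  ys <- (y - yMu) / ySd
  oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))
  set.seed(as.integer(seed))
  sizes <- c(ncol(x), hidden, 1L)
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  cW <- vector("list", L); cb <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1],
                                  sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
    cW[[l]] <- W[[l]] * 0; cb[[l]] <- b[[l]] * 0
  }
  rho <- 0.9; eps <- 1e-8
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    perm <- sample(n)
    batches <- split(perm, ceiling(seq_along(perm) / batchSize))
    epLoss <- 0
    for (bt in batches) {
      A <- list(x[bt, , drop = FALSE])
      masks <- vector("list", L - 1)
      for (l in seq_len(L)) {
        Z <- A[[l]] %*% W[[l]] + matrix(b[[l]], length(bt), sizes[l + 1],
                                        byrow = TRUE)
        if (l < L) {
          Z <- pmax(Z, 0)
          if (dropout > 0) {
            mk <- matrix(stats::runif(length(Z)) >= dropout, nrow(Z), ncol(Z))
            Z <- Z * mk / (1 - dropout)
            masks[[l]] <- mk
          }
        }
        A[[l + 1]] <- Z
      }
      pred <- A[[L + 1]][, 1]
      err <- pred - ys[bt]
      loss <- mean(err^2)
      if (!is.finite(loss) || loss > 1e50)
        stop("divergence: runaway loss at epoch ", ep, " (seed ", seed, ")")
      epLoss <- epLoss + loss * length(bt)
      delta <- matrix(2 * err / length(bt), ncol = 1)
      for (l in L:1) {
        gW <- t(A[[l]]) %*% delta
        gb <- colSums(delta)
        if (l > 1) {
          delta <- delta %*% t(W[[l]])
          act <- A[[l]]
          delta <- delta * (act > 0)
          if (dropout > 0 && !is.null(masks[[l - 1]]))
            delta <- delta * masks[[l - 1]] / (1 - dropout)
        }
        cW[[l]] <- rho * cW[[l]] + (1 - rho) * gW^2
        cb[[l]] <- rho * cb[[l]] + (1 - rho) * gb^2
        W[[l]] <- W[[l]] - lr * gW / (sqrt(cW[[l]]) + eps)
        b[[l]] <- b[[l]] - lr * gb / (sqrt(cb[[l]]) + eps)
      }
    }
    history[ep] <- epLoss / n
  }
  structure(list(W = W, b = b, sizes = sizes, yMu = yMu, ySd = ySd,
                 history = history, seed = as.integer(seed),
                 columns = colnames(x)),
            class = "dnnModel")
}

#' Predict with a fitted neural-network model
#' @param model A `dnnModel` from [dnnFit()].
#' @param newx Matrix on the training normalization scale.
#' @return Numeric predictions on the original endpoint scale.
#' @export
dnnPredict <- function(model, newx) {
  stopifnot(inherits(model, "dnnModel"))
  A <- as.matrix(rbind(newx))
  if (!is.null(model$columns) && !is.null(colnames(A)) &&
      all(model$columns %in% colnames(A)))
    A <- A[, model$columns, drop = FALSE]
  L <- length(model$W)
  for (l in seq_len(L)) {
    A <- A %*% model$W[[l]] + matrix(model$b[[l]], nrow(A),
                                     ncol(model$W[[l]]), byrow = TRUE)
    if (l < L) A <- pmax(A, 0)
  }
  A[, 1] * model$ySd + model$yMu
}

#' R2 and RMSE of predictions against observations
#'
#' `RMSE = sqrt(mean((pred - obs)^2))`; `R2` is the squared Pearson
#' correlation between predicted and observed values (the common QSAR
#' convention).  Set `method = "cod"` for the coefficient-of-determination
#' alternative `1 - SSres/SStot`.  Constant observations leave R2
#' undefined (`NA` with a warning).
#'
#' @param predictions,truth Equal-length numeric vectors (length >= 2).
#' @param method `"pearson"` (default) or `"cod"`.
#' @return Named numeric vector `c(R2, RMSE)`.
#' @export
evaluateModel <- function(predictions, truth, method = c("pearson", "cod")) {
  method <- match.arg(method)
  stopifnot(length(predictions) == length(truth), length(truth) >= 2)
  rmse <- sqrt(mean((predictions - truth)^2))
  if (stats::sd(truth) < 1e-300) {
    warning("constant truth: R2 undefined")
    return(c(R2 = NA_real_, RMSE = rmse))
  }
  r2 <- if (method == "pearson") {
    if (stats::sd(predictions) < 1e-300) 0
    else stats::cor(predictions, truth)^2
  } else {
    1 - sum((truth - predictions)^2) / sum((truth - mean(truth))^2)
  }
  c(R2 = r2, RMSE = rmse)
}

#' Run the full modeling protocol
#'
#' For each of the five folds, a model is trained on the other four and
#' predicts the held-out fold, so every training point receives exactly one
#' out-of-fold prediction; `R2_5CV`/`RMSE_5CV` are computed on the pooled
#' out-of-fold predictions.  A final model refit on the complete training
#' set predicts the external 20% test set (`R2_val`/`RMSE_val`).  Min-max
#' normalization statistics are fitted on the respective training portion
#' only and applied to the held-out data, so no test information leaks into
#' fitting.
#'
#' @param x RAW (filtered, unnormalized) structures x descriptors matrix
#'   with rownames matching the plan ids.
#' @param y Named endpoint vector (names = ids), or vector aligned with
#'   `rownames(x)`.
#' @param plan A [SplitPlan-class] from [makeSplit()].
#' @param method `"knn"` or `"dnn"`.
#' @param ... Passed to [knnFit()] or [dnnFit()].
#' @return A [ModelReport-class].
#' @export
crossValidate <- function(x, y, plan, method = c("knn", "dnn"), ...) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(nrow(x)))
  if (is.null(names(y))) names(y) <- rownames(x)
  stopifnot(all(c(plan@trainIds, plan@testIds) %in% rownames(x)))
  if (any(lengths(plan@folds) < 2)) stop("fold with fewer than 2 points")

  fitPredict <- function(trainIds, predictIds, ...) {
    xtr <- x[trainIds, , drop = FALSE]
    ## fit scaling on the training portion only; drop in-fold constants
    rg <- apply(xtr, 2, function(v) diff(range(v)))
    use <- rg > 0
    st <- list(min = apply(xtr[, use, drop = FALSE], 2, min),
               range = rg[use])
    xtrN <- normalizeDescriptors(xtr[, use, drop = FALSE], stats = st)
    xpeN <- normalizeDescriptors(x[predictIds, use, drop = FALSE],
                                 stats = st)
    if (method == "knn") {
      m <- knnFit(xtrN, y[trainIds], ...)
      list(pred = knnPredict(m, xpeN), model = m)
    } else {
      m <- dnnFit(xtrN, y[trainIds], ...)
      list(pred = dnnPredict(m, xpeN), model = m)
    }
  }

  cvRows <- list()
  for (f in seq_along(plan@folds)) {
    hold <- plan@folds[[f]]
    trn <- setdiff(plan@trainIds, hold)
    fp <- fitPredict(trn, hold, ...)
    cvRows[[f]] <- data.frame(id = hold, fold = f, observed = y[hold],
                              predicted = fp$pred, row.names = NULL)
  }
  cvDf <- do.call(rbind, cvRows)
  cvMet <- evaluateModel(cvDf$predicted, cvDf$observed)

  ext <- fitPredict(plan@trainIds, plan@testIds, ...)
  valDf <- data.frame(id = plan@testIds, observed = y[plan@testIds],
                      predicted = ext$pred, row.names = NULL)
  valMet <- evaluateModel(valDf$predicted, valDf$observed)

  perFold <- vapply(split(cvDf, cvDf$fold), function(d)
    evaluateModel(d$predicted, d$observed)["RMSE"], numeric(1))

  details <- list(method = method, seed = plan@seed, perFoldRMSE = perFold)
  if (method == "knn") {
    details$subset <- ext$model$subset
    details$k <- ext$model$k
  } else {
    details$history <- ext$model$history
  }
  new("ModelReport",
      metrics = c(R2_5CV = unname(cvMet["R2"]),
                  RMSE_5CV = unname(cvMet["RMSE"]),
                  R2_val = unname(valMet["R2"]),
                  RMSE_val = unname(valMet["RMSE"])),
      cvPredictions = cvDf, valPredictions = valDf, details = details)
}
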