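## Three-layer back-propagation network for AOD -> PM2.5 retrieval, with
## Pearson R / RMSE validation metrics and 10-fold sample-based
## cross-validation. The network (9 inputs -> 18 hidden tanh units -> 1
## linear output), its gradients, and the training loop are implemented
## here directly.

#' Pearson product-moment correlation
#'
#' Standard covariance/SD form, used as the model-fit metric R between
#' observed and retrieved PM2.5.
#'
#' @param observed,predicted numeric vectors of equal length (>= 2).
#' @return correlation in \[-1, 1\].
#' @examples
#' pearsonR(c(1, 2, 3), c(1, 2, 3))   # 1
#' @export
pearsonR <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length")
  if (length(observed) < 2L) stop("need at least 2 samples")
  if (anyNA(observed) || anyNA(predicted)) stop("missing values not allowed")
  dx <- observed - mean(observed)
  dy <- predicted - mean(predicted)
  sxx <- sum(dx^2); syy <- sum(dy^2)
  if (sxx == 0 || syy == 0)
    stop("undefined correlation: an input has zero variance")
  sum(dx * dy) / sqrt(sxx * syy)
}

#' Root-mean-square error
#'
#' @param observed,predicted numeric vectors of equal length (>= 1).
#' @return RMSE in the units of the inputs (ug/m3 for PM2.5).
#' @examples
#' rmse(c(0, 0), c(3, 4))   # sqrt(12.5)
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length")
  if (length(observed) == 0L) stop("empty input")
  if (anyNA(observed) || anyNA(predicted)) stop("missing values not allowed")
  sqrt(mean((observed - predicted)^2))
}

.forwardPass <- function(X, W1, b1, W2, b2) {
  H <- tanh(sweep(X %*% W1, 2, b1, "+"))
  list(H = H, yhat = drop(H %*% W2) + b2)
}

## Gradient of loss = mean((yhat - y)^2) / 2 w.r.t. all parameters.
.gradients <- function(X, y, W1, b1, W2, b2) {
  fp <- .forwardPass(X, W1, b1, W2, b2)
  e <- (fp$yhat - y) / length(y)
  dH <- (e %*% t(W2)) * (1 - fp$H^2)
  list(
    loss = sum((fp$yhat - y)^2) / (2 * length(y)),
    gW1 = crossprod(X, dH),
    gb1 = colSums(dH),
    gW2 = crossprod(fp$H, matrix(e)),
    gb2 = sum(e)
  )
}

#' Train the retrieval network
#'
#' Fits the three-layer back-propagation network on z-scored predictors
#' and label by full-batch gradient back-propagation. The default
#' optimiser is iRPROP- (per-weight adaptive step sizes, robust without a
#' learning-rate choice); `method = "gd"` selects plain gradient descent
#' with momentum. Training is deterministic given `seed`.
#'
#' The hidden-layer width defaults to 18 units; a heuristic places the
#' useful range between 2 + mu and 2n + 1 (= 19 for nine inputs and one
#' output), and sizes outside \[2, 19\] trigger a warning but proceed.
#'
#' @param samples data.frame with the nine predictors `lon`, `lat`, `doy`,
#'   `aod`, `rh`, `temp`, `ws`, `sp`, `hpbl` (no missing values) and the
#'   label `pm25`.
#' @param hiddenNodes hidden-layer width (default 18).
#' @param seed integer seed for weight initialisation.
#' @param maxEpochs maximum full-batch epochs.
#' @param tol relative loss-change threshold for early stopping.
#' @param method `"rprop"` (default) or `"gd"`.
#' @param learningRate,momentum parameters for `method = "gd"`.
#' @return a [RetrievalModel-class].
#' @export
trainRetrieval <- function(samples, hiddenNodes = 18L, seed = 1L,
                           maxEpochs = 2000L, tol = 1e-10,
                           method = c("rprop", "gd"),
                           learningRate = 0.05, momentum = 0.9) {
  method <- match.arg(method)
  miss <- setdiff(c(.FEATURES, "pm25"), colnames(samples))
  if (length(miss))
    stop("samples is missing columns: ", paste(miss, collapse = ", "))
  X <- as.matrix(samples[, .FEATURES])
  y <- samples$pm25
  if (anyNA(X) || anyNA(y)) stop("samples must have no missing predictors")
  n <- nrow(X)
  if (n < 100L)
    warning("training on fewer than 100 samples (n = ", n, ")")
  if (sd(y) == 0) stop("degenerate label vector: pm25 is constant")
  hiddenNodes <- as.integer(hiddenNodes)
  if (hiddenNodes < 2L || hiddenNodes > 19L)
    warning("hiddenNodes = ", hiddenNodes,
            " is outside the heuristic range [2, 19]; proceeding")

  center <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scl, "/")
  yc <- mean(y); ys <- sd(y)
  yn <- (y - yc) / ys

  nIn <- length(.FEATURES)
  theta <- withSeed(seed, runif(nIn * hiddenNodes + hiddenNodes +
                                  hiddenNodes + 1L, -0.5, 0.5))
  unpack <- function(th) {
    i <- 0L
    W1 <- matrix(th[i + seq_len(nIn * hiddenNodes)], nIn, hiddenNodes)
    i <- i + nIn * hiddenNodes
    b1 <- th[i + seq_len(hiddenNodes)]; i <- i + hiddenNodes
    W2 <- matrix(th[i + seq_len(hiddenNodes)], hiddenNodes, 1L)
    i <- i + hiddenNodes
    list(W1 = W1, b1 = b1, W2 = W2, b2 = th[i + 1L])
  }
  gradVec <- function(th) {
    p <- unpack(th)
    g <- .gradients(Xs, yn, p$W1, p$b1, p$W2, p$b2)
    list(loss = g$loss,
         g = c(as.vector(g$gW1), g$gb1, as.vector(g$gW2), g$gb2))
  }

  nPar <- length(theta)
  prevLoss <- Inf
  epochs <- 0L
  if (method == "rprop") {
    delta <- rep(0.0125, nPar)
    gPrev <- numeric(nPar)
    for (ep in seq_len(maxEpochs)) {
      gr <- gradVec(theta)
      g <- gr$g
      sgnChange <- g * gPrev
      delta[sgnChange > 0] <- pmin(delta[sgnChange > 0] * 1.2, 50)
      delta[sgnChange < 0] <- pmax(delta[sgnChange < 0] * 0.5, 1e-9)
      g[sgnChange < 0] <- 0          # iRPROP-: skip after sign flip
      theta <- theta - sign(g) * delta
      gPrev <- g
      epochs <- ep
      if (is.finite(prevLoss) && prevLoss > 0 &&
          abs(prevLoss - gr$loss) / prevLoss < tol) break
      prevLoss <- gr$loss
    }
  } else {
    vel <- numeric(nPar)
    for (ep in seq_len(maxEpochs)) {
      gr <- gradVec(theta)
      vel <- momentum * vel - learningRate * gr$g
      theta <- theta + vel
      epochs <- ep
      if (is.finite(prevLoss) && prevLoss > 0 &&
          abs(prevLoss - gr$loss) / prevLoss < tol) break
      prevLoss <- gr$loss
    }
  }
  finalLoss <- gradVec(theta)$loss
  p <- unpack(theta)
  new("RetrievalModel",
    featureNames = .FEATURES, center = center, scale = scl,
    labelCenter = yc, labelScale = ys,
    W1 = p$W1, b1 = p$b1, W2 = p$W2, b2 = p$b2,
    activation = "tanh",
    trainingLog = list(epochs = epochs, finalLoss = finalLoss,
                       seed = as.integer(seed), method = method))
}

#' Predict PM2.5 from a trained retrieval model
#'
#' Rows (or pixels) with any missing predictor yield a missing prediction;
#' retrieved concentrations are clamped at zero.
#'
#' @param object a [RetrievalModel-class].
#' @param newdata data.frame containing the nine predictor columns.
#' @param ... unused.
#' @return numeric vector of PM2.5 (ug/m3).
#' @aliases predict
#' @export
setMethod("predict", "RetrievalModel", function(object, newdata, ...) {
  miss <- setdiff(object@featureNames, colnames(newdata))
  if (length(miss))
    stop("newdata is missing predictors: ", paste(miss, collapse = ", "))
  X <- as.matrix(newdata[, object@featureNames, drop = FALSE])
  ok <- stats::complete.cases(X)
  out <- rep(NA_real_, nrow(X))
  if (any(ok)) {
    Xs <- sweep(sweep(X[ok, , drop = FALSE], 2, object@center), 2,
                object@scale, "/")
    fp <- .forwardPass(Xs, object@W1, object@b1, object@W2, object@b2)
    out[ok] <- pmax(fp$yhat * object@labelScale + object@labelCenter, 0)
  }
  out
})

#' Retrieve a daily PM2.5 grid
#'
#' Merges the day's Terra/Aqua AOD overpasses, assembles the nine
#' predictors per pixel, and applies the trained network. Pixels with any
#' missing predictor (e.g. cloud-masked AOD) are missing in the output.
#'
#' @param model a [RetrievalModel-class].
#' @param gridDay one element of the list returned by [generateGrids()]
#'   (components `date`, `terra`, `aqua`, `rh`, `temp`, `ws`, `sp`,
#'   `hpbl`), or the same structure with a pre-merged `aod` component.
#' @return a [GridField-class] with variable `"PM2.5"`.
#' @export
retrieveGrid <- function(model, gridDay) {
  aod <- if (!is.null(gridDay$aod)) gridDay$aod
         else mergeDailyAOD(gridDay$terra, gridDay$aqua)
  lon <- gridLon(aod); lat <- gridLat(aod)
  df <- data.frame(
    lon = rep(lon, each = length(lat)),
    lat = rep(lat, times = length(lon)),
    doy = dayOfYear(gridDay$date),
    aod = as.vector(gridValues(aod)),
    rh = as.vector(gridValues(gridDay$rh)),
    temp = as.vector(gridValues(gridDay$temp)),
    ws = as.vector(gridValues(gridDay$ws)),
    sp = as.vector(gridValues(gridDay$sp)),
    hpbl = as.vector(gridValues(gridDay$hpbl))
  )
  pred <- predict(model, df)
  GridField("PM2.5", gridDay$date, lon, lat,
            matrix(pred, nrow = length(lat), ncol = length(lon)))
}

#' Random k-fold assignment for sample-based cross-validation
#'
#' Samples are divided almost equally: fold sizes differ by at most one.
#'
#' @param n number of samples.
#' @param k number of folds (>= 2).
#' @param seed RNG seed.
#' @return integer vector of fold labels in `1:k`, length `n`.
#' @export
cvFolds <- function(n, k = 10L, seed = 1L) {
  if (k < 2L) stop("k must be >= 2")
  if (n < k) stop("need at least k samples")
  withSeed(seed, sample(rep_len(seq_len(k), n)))
}

#' k-fold sample-based cross-validation of the retrieval network
#'
#' All samples are divided almost equally into `k` random folds; each
#' round trains on k - 1 folds and predicts the held-out fold, so every
#' sample is predicted exactly once out-of-fold. R and RMSE are computed
#' on the pooled out-of-fold predictions.
#'
#' @inheritParams trainRetrieval
#' @param k number of folds (default 10).
#' @param ... further arguments passed to [trainRetrieval()].
#' @return a [FitMetrics-class]; the fold assignment and pooled
#'   out-of-fold predictions are attached as attributes `"folds"` and
#'   `"predictions"`.
#' @export
crossValidate <- function(samples, k = 10L, seed = 1L, ...) {
  n <- nrow(samples)
  folds <- cvFolds(n, k, seed)
  pred <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    hold <- folds == f
    model <- trainRetrieval(samples[!hold, , drop = FALSE],
                            seed = subSeed(seed, f), ...)
    pred[hold] <- predict(model, samples[hold, , drop = FALSE])
  }
  metrics <- FitMetrics(pearsonR(samples$pm25, pred),
                        rmse(samples$pm25, pred), n)
  attr(metrics, "folds") <- folds
  attr(metrics, "predictions") <- pred
  metrics
}

#' Serialise a retrieval model to JSON
#'
#' Weight matrices, biases, and normalisation constants are written
#' explicitly so the model is portable and inspectable.
#'
#' @param model a [RetrievalModel-class].
#' @param path output `.json` file.
#' @return `path`, invisibly.
#' @export
writeRetrievalModel <- function(model, path) {
  obj <- list(
    featureNames = model@featureNames,
    center = model@center, scale = model@scale,
    labelCenter = model@labelCenter, labelScale = model@labelScale,
    W1 = model@W1, b1 = model@b1, W2 = model@W2, b2 = model@b2,
    activation = model@activation, trainingLog = model@trainingLog
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @describeIn writeRetrievalModel read a model back from JSON.
#' @export
readRetrievalModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("RetrievalModel",
    featureNames = obj$featureNames,
    center = stats::setNames(obj$center, obj$featureNames),
    scale = stats::setNames(obj$scale, obj$featureNames),
    labelCenter = obj$labelCenter, labelScale = obj$labelScale,
    W1 = as.matrix(obj$W1), b1 = obj$b1,
    W2 = as.matrix(obj$W2), b2 = obj$b2,
    activation = obj$activation, trainingLog = obj$trainingLog)
}
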