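#' Fit a quantitative reaction-property regression (QRPR) model
#'
#' The regressors used underneath the applicability-domain machinery: a
#' 500-tree random forest (`"rfr"`) whose per-tree spread provides an ensemble
#' prediction variance, or a Gaussian-process regressor with RBF kernel
#' (`"gpr"`) whose posterior predictive variance provides a confidence score.
#' The property is standardized internally for the GPR fit and predictions are
#' rescaled back before they are returned.
#'
#' @param x standardized descriptor matrix (training block).
#' @param y numeric property vector.
#' @param method `"rfr"` or `"gpr"`.
#' @param max_features fraction of columns sampled at each tree split
#'   (random-forest only); default 1/3.
#' @param ntree number of trees (random-forest only); default 500.
#' @param alpha GPR noise level (regularization of the kernel matrix).
#' @param gamma RBF kernel parameter, `exp(-gamma * |u - v|^2)`; default
#'   `1/ncol(x)`.
#' @return object of class `qrpr_model` with a [predict.qrpr_model()] method
#'   returning both the predicted mean and the prediction variance.
#' @export
qrpr_fit <- function(x, y, method = c("rfr", "gpr"),
                     max_features = 1 / 3, ntree = 500L,
                     alpha = 0.01, gamma = NULL) {
  method <- match.arg(method)
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y))
  obj <- list(method = method, p = ncol(x))
  if (method == "rfr") {
    mtry <- max(1L, min(ncol(x), round(max_features * ncol(x))))
    obj$fit <- randomForest::randomForest(x, y, ntree = ntree, mtry = mtry)
    obj$max_features <- max_features
    obj$ntree <- ntree
  } else {
    if (is.null(gamma)) gamma <- 1 / ncol(x)
    yc <- mean(y)
    ys <- sqrt(mean((y - yc)^2))
    if (ys == 0) ys <- 1
    obj$fit <- kernlab::gausspr(x, (y - yc) / ys,
                                kernel = "rbfdot", kpar = list(sigma = gamma),
                                var = alpha, variance.model = TRUE,
                                scaled = FALSE)
    obj$alpha <- alpha; obj$gamma <- gamma
    obj$y_center <- yc; obj$y_scale <- ys
  }
  class(obj) <- "qrpr_model"
  obj
}

#' Predict from a QRPR model
#'
#' @param object a [qrpr_fit()] model.
#' @param newdata descriptor matrix in the training standardization.
#' @param ... unused.
#' @return list with `mean` (predicted property, original scale) and `var`
#'   (prediction variance: population variance of the per-tree predictions for
#'   the random forest; posterior predictive variance in standardized-property
#'   units for the GPR).
#' @export
predict.qrpr_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (object$method == "rfr") {
    pa <- predict(object$fit, newdata, predict.all = TRUE)
    mu <- as.numeric(pa$aggregate)
    v <- apply(pa$individual, 1L, function(z) mean((z - mean(z))^2))
    list(mean = mu, var = as.numeric(v))
  } else {
    mu <- as.numeric(kernlab::predict(object$fit, newdata))
    sdev <- as.numeric(kernlab::predict(object$fit, newdata, type = "sdeviation"))
    list(mean = mu * object$y_scale + object$y_center, var = sdev^2)
  }
}

#' @export
print.qrpr_model <- function(x, ...) {
  cat(sprintf("<qrpr_model> %s on %d descriptors\n",
              if (x$method == "rfr")
                sprintf("random forest (%d trees, max_features=%.2f)", x$ntree, x$max_features)
              else
                sprintf("Gaussian process (alpha=%.3g, gamma=%.3g)", x$alpha, x$gamma),
              x$p))
  invisible(x)
}
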