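#' Fit an applicability-domain definition model
#'
#' Single entry point for every AD definition method. All methods share one
#' contract: the fitted object decides, for every test reaction, whether it is
#' an X-inlier (within AD, `TRUE`) or an X-outlier (`FALSE`); score-based
#' methods additionally expose a continuous reliability score, and the
#' decision is then a pure function of the score and the stored threshold.
#'
#' Methods and their inputs:
#' \describe{
#'   \item{`"leverage"`}{`x`. Score is the leverage `h = x^T (X^T X)^- x`
#'     (pseudo-inverse, so rank-deficient fragment matrices are handled);
#'     inlier iff `h <= threshold`. Default threshold `h* = 3 (M + 1) / N`
#'     where `M` counts the non-constant columns of `x`.}
#'   \item{`"z1nn"`}{`x`. Score is the Euclidean distance to the nearest
#'     training row; inlier iff `d <= Dc` with `Dc = Z * sigma + mean` of the
#'     training nearest-neighbour distances (self-matches excluded). Default
#'     `Z = 0.5`; a tuned `threshold` overrides `Dc`.}
#'   \item{`"1svm"`}{`x`. One-class SVM with RBF kernel (`nu`, `gamma`);
#'     score is the decision value, inlier iff `score >= 0`.}
#'   \item{`"2cc"`}{`x`, `flags` (training Y-outlier labels from
#'     [twoclass_label()]). A 500-tree random-forest classifier learns to
#'     separate Y-inliers from Y-outliers; score is the predicted Y-inlier
#'     probability, inlier iff `score > threshold` (`p*`, default 0.5). If the
#'     training labels are single-class the method is inapplicable: the fitted
#'     object carries `degenerate = TRUE`, decides all-inlier, and a warning is
#'     issued.}
#'   \item{`"bb"`}{`x`. Bounding box: inlier iff every descriptor lies within
#'     the training `[min, max]` (bounds inclusive).}
#'   \item{`"fc"`}{Fragment control; no state beyond the descriptor
#'     vocabulary. `predict` takes the per-reaction unseen-fragment sets from
#'     [predict.reaction_descriptors()]; inlier iff the set is empty.}
#'   \item{`"rtc"`}{`reactions` (SMILES vector, or list of signature sets) and
#'     `radius` (default 1 — the RTC1 convention). Stores the union of
#'     training reaction-centre signatures; a test reaction is an inlier iff
#'     its signature set is nonempty and contained in the training set.}
#'   \item{`"rfr_var"`}{`x`, `y`. Score is the population variance of the
#'     per-tree predictions of a 500-tree random-forest regressor; inlier iff
#'     `var <= threshold` (`sigma*`, default: the largest training-row
#'     variance).}
#'   \item{`"gpr"`}{`x`, `y`. Score is the Gaussian-process posterior
#'     predictive variance; inlier iff `var <= threshold` (default as above).}
#'   \item{`"oz"`, `"pz"`}{Zero models: optimistic (all inliers) and
#'     pessimistic (all outliers) baselines.}
#' }
#'
#' @param method one of `"leverage"`, `"z1nn"`, `"1svm"`, `"2cc"`, `"bb"`,
#'   `"fc"`, `"rtc"`, `"rfr_var"`, `"gpr"`, `"oz"`, `"pz"`.
#' @param x standardized training descriptor matrix (methods operating in
#'   descriptor space).
#' @param y training property values (`"rfr_var"`, `"gpr"`).
#' @param flags logical training Y-outlier flags (`"2cc"`).
#' @param reactions training reactions (`"rtc"`): reaction SMILES, parsed
#'   reactions, CGRs, or precomputed signature sets.
#' @param threshold decision threshold override (`h*`, `Dc`, `p*`, `sigma*`).
#' @param Z Z-1NN significance factor (default 0.5).
#' @param nu,gamma one-class SVM hyperparameters (`gamma` also for `"gpr"`).
#' @param max_features fraction of columns tried per split for the
#'   random-forest based methods (default 1/3).
#' @param ntree forest size for `"2cc"` and `"rfr_var"` (default 500).
#' @param alpha GPR noise level.
#' @param radius RTC neighbourhood radius (default 1).
#' @return an object of class `c("ad_<method>", "ad_model")`.
#' @examples
#' x <- matrix(rnorm(40), 20, 2)
#' ad <- ad_fit("leverage", x)
#' predict(ad, x[1:3, , drop = FALSE])
#' @export
ad_fit <- function(method, x = NULL, y = NULL, flags = NULL, reactions = NULL,
                   threshold = NULL, Z = 0.5, nu = 0.05, gamma = NULL,
                   max_features = 1 / 3, ntree = 500L, alpha = 0.01,
                   radius = 1L) {
  method <- match.arg(method, c("leverage", "z1nn", "1svm", "2cc", "bb", "fc",
                                "rtc", "rfr_var", "gpr", "oz", "pz"))
  obj <- list(method = method)
  if (method %in% c("leverage", "z1nn", "1svm", "2cc", "bb", "rfr_var", "gpr")) {
    x <- as.matrix(x)
    stopifnot(nrow(x) >= 1L)
  }
  switch(method,
    leverage = {
      stopifnot(nrow(x) >= 2L)
      xtx <- crossprod(x)
      obj$pinv <- pseudo_inverse(xtx)
      m_eff <- sum(apply(x, 2L, function(col) max(col) > min(col)))
      obj$threshold <- threshold %||% (3 * (m_eff + 1) / nrow(x))
      obj$inlier_if <- "le"
    },
    z1nn = {
      stopifnot(nrow(x) >= 2L)
      obj$train <- x
      d <- nn_dist(x, x, exclude_self = TRUE)
      obj$train_nn <- d
      obj$nn_mean <- mean(d)
      obj$nn_sd <- stats::sd(d)
      obj$Z <- Z
      obj$threshold <- threshold %||% (Z * obj$nn_sd + obj$nn_mean)
      obj$inlier_if <- "le"
    },
    `1svm` = {
      stopifnot(nu > 0, nu <= 1)
      if (is.null(gamma)) gamma <- 1 / ncol(x)
      obj$fit <- e1071::svm(x, type = "one-classification", kernel = "radial",
                            nu = nu, gamma = gamma, scale = FALSE)
      obj$nu <- nu; obj$gamma <- gamma
      obj$threshold <- 0
      obj$inlier_if <- "ge"
    },
    `2cc` = {
      stopifnot(is.logical(flags), length(flags) == nrow(x))
      if (length(unique(flags)) < 2L || min(table(flags)) < 2L) {
        warning("2CC inapplicable: training set lacks two Y-classes; ",
                "falling back to an all-inlier decision", call. = FALSE)
        obj$degenerate <- TRUE
      } else {
        mtry <- max(1L, min(ncol(x), round(max_features * ncol(x))))
        lab <- factor(ifelse(flags, "youtlier", "yinlier"),
                      levels = c("yinlier", "youtlier"))
        obj$fit <- randomForest::randomForest(x, lab, ntree = ntree, mtry = mtry)
        obj$degenerate <- FALSE
      }
      obj$max_features <- max_features
      obj$threshold <- threshold %||% 0.5
      obj$inlier_if <- "gt"
    },
    bb = {
      obj$lo <- apply(x, 2L, min)
      obj$hi <- apply(x, 2L, max)
    },
    fc = {
      # all state lives in the descriptor vocabulary; nothing to fit
    },
    rtc = {
      stopifnot(!is.null(reactions), radius >= 0)
      sets <- rtc_signature_sets(reactions, radius)
      obj$radius <- as.integer(radius)
      obj$signatures <- sort(unique(unlist(sets)))
    },
    rfr_var = {
      stopifnot(length(y) == nrow(x))
      obj$fit <- qrpr_fit(x, y, "rfr", max_features = max_features, ntree = ntree)
      tr <- predict(obj$fit, x)$var
      obj$threshold <- threshold %||% max(tr)
      obj$inlier_if <- "le"
    },
    gpr = {
      stopifnot(length(y) == nrow(x))
      obj$fit <- qrpr_fit(x, y, "gpr", alpha = alpha, gamma = gamma)
      tr <- predict(obj$fit, x)$var
      obj$threshold <- threshold %||% max(tr)
      obj$inlier_if <- "le"
    },
    oz = NULL,
    pz = NULL
  )
  class(obj) <- c(paste0("ad_", sub("^1", "one", method)), "ad_model")
  obj
}

#' Predict AD membership
#'
#' @param object a fitted [ad_fit()] model.
#' @param newdata method-dependent test input: a descriptor matrix for the
#'   descriptor-space methods; a list of unseen-fragment sets (from
#'   [predict.reaction_descriptors()]) for fragment control; reactions or
#'   signature sets for reaction type control; a row count for the zero
#'   models.
#' @param type `"decision"` (logical, `TRUE` = X-inlier) or `"score"`
#'   (continuous reliability score, score-based methods only).
#' @param ... unused.
#' @return logical or numeric vector, one element per test reaction.
#' @export
predict.ad_model <- function(object, newdata, type = c("decision", "score"), ...) {
  type <- match.arg(type)
  score <- ad_score(object, newdata)
  if (type == "score") {
    if (is.null(score))
      stop("method ", sQuote(object$method), " has no continuous score", call. = FALSE)
    return(score)
  }
  if (!is.null(score))
    return(switch(object$inlier_if,
                  le = score <= object$threshold,
                  ge = score >= object$threshold,
                  gt = score > object$threshold))
  ad_decide_direct(object, newdata)
}

ad_score <- function(object, newdata) {
  switch(object$method,
    leverage = {
      x <- as.matrix(newdata)
      rowSums((x %*% object$pinv) * x)
    },
    z1nn = nn_dist(as.matrix(newdata), object$train, exclude_self = FALSE),
    `1svm` = {
      p <- predict(object$fit, as.matrix(newdata), decision.values = TRUE)
      as.numeric(attr(p, "decision.values"))
    },
    `2cc` = {
      if (isTRUE(object$degenerate)) rep(1, NROW(newdata))
      else predict(object$fit, as.matrix(newdata), type = "prob")[, "yinlier"]
    },
    rfr_var = predict(object$fit, as.matrix(newdata))$var,
    gpr = predict(object$fit, as.matrix(newdata))$var,
    NULL
  )
}

ad_decide_direct <- function(object, newdata) {
  switch(object$method,
    bb = {
      x <- as.matrix(newdata)
      ok <- rep(TRUE, nrow(x))
      for (j in seq_len(ncol(x)))
        ok <- ok & x[, j] >= object$lo[j] & x[, j] <= object$hi[j]
      ok
    },
    fc = fragment_control_decide(newdata),
    rtc = {
      sets <- rtc_signature_sets(newdata, object$radius)
      vapply(sets, function(s)
        length(s) > 0L && all(s %in% object$signatures), logical(1))
    },
    oz = rep(TRUE, newdata_count(newdata)),
    pz = rep(FALSE, newdata_count(newdata)),
    stop("no decision rule for method ", sQuote(object$method), call. = FALSE)
  )
}

newdata_count <- function(newdata) {
  if (is.numeric(newdata) && length(newdata) == 1L) as.integer(newdata)
  else NROW(newdata)
}

#' @export
print.ad_model <- function(x, ...) {
  thr <- if (!is.null(x$threshold))
    sprintf(" (inlier iff score %s %.4g)",
            switch(x$inlier_if, le = "<=", ge = ">=", gt = ">"), x$threshold)
  else ""
  cat(sprintf("<ad_model> %s%s\n", x$method, thr))
  invisible(x)
}

#' Fragment-control decision
#'
#' A reaction is within the AD iff its CGR contains no fragment absent from
#' the training vocabulary.
#'
#' @param unseen list of character vectors of unseen fragments per reaction,
#'   as returned by [predict.reaction_descriptors()].
#' @return logical vector, `TRUE` = X-inlier.
#' @export
fragment_control_decide <- function(unseen) {
  vapply(unseen, function(s) length(s) == 0L, logical(1))
}

#' Label training Y-outliers from cross-validated errors
#'
#' A reaction is a Y-outlier iff its cross-validated absolute prediction error
#' exceeds `3 * rmse` (strict inequality; the boundary case is a Y-inlier).
#'
#' @param cv_errors vector of cross-validated prediction errors (signed or
#'   absolute).
#' @param rmse root-mean-square error of the same predictions (> 0).
#' @return logical vector, `TRUE` = Y-outlier.
#' @export
twoclass_label <- function(cv_errors, rmse) {
  stopifnot(rmse > 0)
  abs(cv_errors) > 3 * rmse
}

#' Zero-model and perfect-model decisions
#'
#' `zero_model_decisions` returns the optimistic (`"oz"`, all X-inliers) or
#' pessimistic (`"pz"`, all X-outliers) baseline. `perfect_decisions` returns
#' the "Perfect AD model": X-inlier iff the absolute prediction error is at
#' most `3 * rmse`, i.e. exactly the Y-inliers.
#'
#' @param n number of reactions.
#' @param type `"oz"` or `"pz"`.
#' @param cv_errors,rmse as in [twoclass_label()].
#' @return logical decision vector.
#' @export
zero_model_decisions <- function(n, type = c("oz", "pz")) {
  type <- match.arg(type)
  rep(type == "oz", n)
}

#' @rdname zero_model_decisions
#' @export
perfect_decisions <- function(cv_errors, rmse) {
  !twoclass_label(cv_errors, rmse)
}

#' Combine AD decisions into a composite AD
#'
#' A reaction is inside a composite AD iff it is inside every component AD
#' (logical AND). Composite methods are conventionally written with an
#' asterisk, e.g. `RFR_VAR*` for the combination with RTC1.
#'
#' @param ... logical decision vectors of equal length (or one list of them).
#' @return logical vector.
#' @export
composite_decide <- function(...) {
  ds <- list(...)
  if (length(ds) == 1L && is.list(ds[[1]])) ds <- ds[[1]]
  stopifnot(length(ds) >= 1L)
  Reduce(`&`, ds)
}

pseudo_inverse <- function(m, tol = 1e-10) {
  s <- svd(m)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# Euclidean nearest-neighbour distance of each row of a to rows of b.
# Ties are irrelevant (only the minimum is used); with exclude_self the
# diagonal of the self-distance matrix is removed.
nn_dist <- function(a, b, exclude_self = FALSE) {
  aa <- rowSums(a^2); bb <- rowSums(b^2)
  d2 <- outer(aa, bb, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  if (exclude_self) diag(d2) <- Inf
  sqrt(apply(d2, 1L, min))
}

rtc_signature_sets <- function(reactions, radius) {
  # precomputed signature sets: a list of character vectors whose strings are
  # signatures, not SMILES (signatures always contain '||', SMILES never do)
  if (is.list(reactions) && all(vapply(reactions, is.character, logical(1)))) {
    u <- unlist(reactions)
    if (!length(u) || all(grepl("||", u, fixed = TRUE)))
      return(reactions)
  }
  if (is.character(reactions))
    return(lapply(reactions, cached_signature_set, radius = radius))
  lapply(reactions, signature_set, radius = radius)
}
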