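#' AD performance metrics
#'
#' The four metrics used to score an applicability-domain definition against
#' the predictions of its QRPR model, plus the inlier/outlier confusion
#' quadrants.
#'
#' * `ad_coverage`: fraction of reactions decided X-inliers.
#' * `ad_oir`: `RMSE_out - RMSE_in` (Out and In RMSE). Positive values mean
#'   the AD isolates poorly predicted reactions; 0 by convention when either
#'   side is empty.
#' * `ad_delta_r2`: `R2_in - R2_all` with `R2 = 1 - SS_res / SS_tot`.
#'   An empty inlier set uses `R2_in = 0` (so the pessimistic zero model
#'   yields `-R2_all`); an inlier set with fewer than two reactions or a
#'   constant observed property leaves the metric undefined (`NA`, excluded
#'   from ranking).
#' * `ad_od`: Outlier Detection, the balanced accuracy
#'   `(TO/(TO+FI) + TI/(TI+FO)) / 2` of recognising Y-outliers as X-outliers;
#'   0.5 by convention when either Y-class is absent.
#' * `ad_auc`: area under the ROC curve obtained by sweeping the absolute
#'   prediction error as the threshold, with X-inliers as the positive class:
#'   the probability that a random X-inlier has a smaller absolute error than
#'   a random X-outlier, ties counted 1/2. `NA` when only one decision class
#'   is present. A diagnostic metric only; unsuitable as a tuning objective.
#'
#' @param decisions logical vector, `TRUE` = X-inlier.
#' @param errors prediction errors (signed or absolute), one per reaction.
#' @param y_true,y_pred observed and predicted property values.
#' @param y_outlier_flags logical vector, `TRUE` = Y-outlier.
#' @param abs_errors absolute prediction errors.
#' @param quadrants a `quadrant_counts()` result (or any list with `TO`, `TI`,
#'   `FO`, `FI`).
#' @return a scalar metric value; `quadrant_counts` returns a list of the four
#'   counts.
#' @name ad-metrics
NULL

#' @rdname ad-metrics
#' @export
ad_coverage <- function(decisions) {
  stopifnot(length(decisions) >= 1L)
  mean(decisions)
}

#' @rdname ad-metrics
#' @export
ad_oir <- function(errors, decisions) {
  stopifnot(length(errors) == length(decisions))
  n_in <- sum(decisions); n_out <- sum(!decisions)
  if (n_in == 0L || n_out == 0L) return(0)
  rmse <- function(e) sqrt(mean(e^2))
  rmse(errors[!decisions]) - rmse(errors[decisions])
}

#' @rdname ad-metrics
#' @export
ad_delta_r2 <- function(y_true, y_pred, decisions) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) == length(decisions))
  r2 <- function(y, yh) 1 - sum((y - yh)^2) / sum((y - mean(y))^2)
  r2_all <- r2(y_true, y_pred)
  n_in <- sum(decisions)
  if (n_in == 0L) return(0 - r2_all)
  y_in <- y_true[decisions]
  if (n_in < 2L || max(y_in) == min(y_in)) return(NA_real_)
  r2(y_in, y_pred[decisions]) - r2_all
}

#' @rdname ad-metrics
#' @export
quadrant_counts <- function(y_outlier_flags, decisions) {
  stopifnot(length(y_outlier_flags) == length(decisions))
  list(TO = sum(y_outlier_flags & !decisions),
       TI = sum(!y_outlier_flags & decisions),
       FO = sum(!y_outlier_flags & !decisions),
       FI = sum(y_outlier_flags & decisions))
}

#' @rdname ad-metrics
#' @export
ad_od <- function(quadrants) {
  with(quadrants, {
    if (TO + FI == 0L || TI + FO == 0L) return(0.5)
    (TO / (TO + FI) + TI / (TI + FO)) / 2
  })
}

#' @rdname ad-metrics
#' @export
ad_auc <- function(abs_errors, decisions) {
  stopifnot(length(abs_errors) == length(decisions))
  n_in <- sum(decisions); n_out <- sum(!decisions)
  if (n_in == 0L || n_out == 0L) return(NA_real_)
  # normalized rank-sum: P(err_out > err_in) + P(err_out = err_in)/2
  r <- rank(abs(abs_errors))
  (sum(r[!decisions]) - n_out * (n_out + 1) / 2) / (n_in * n_out)
}

#' Full metrics report for one AD definition
#'
#' Computes coverage, OIR, delta-R2, OD, AUC, the confusion quadrants and the
#' in/out/overall RMSE and R2 of the underlying predictions.
#'
#' @param y_true,y_pred observed and predicted property values.
#' @param decisions logical AD decisions (`TRUE` = X-inlier).
#' @param y_outlier_flags logical Y-outlier flags; if `NULL`, derived from the
#'   prediction errors by the 3xRMSE rule ([twoclass_label()]).
#' @return object of class `ad_metrics`: a named list of scalar metrics plus
#'   `quadrants`.
#' @export
ad_metrics <- function(y_true, y_pred, decisions, y_outlier_flags = NULL) {
  err <- y_true - y_pred
  if (is.null(y_outlier_flags))
    y_outlier_flags <- twoclass_label(err, sqrt(mean(err^2)))
  q <- quadrant_counts(y_outlier_flags, decisions)
  rmse <- function(e) if (length(e)) sqrt(mean(e^2)) else NA_real_
  r2 <- function(y, yh) {
    if (length(y) < 2L || max(y) == min(y)) return(NA_real_)
    1 - sum((y - yh)^2) / sum((y - mean(y))^2)
  }
  structure(list(
    coverage = ad_coverage(decisions),
    oir = ad_oir(err, decisions),
    delta_r2_ad = ad_delta_r2(y_true, y_pred, decisions),
    od = ad_od(q),
    auc_ad = ad_auc(abs(err), decisions),
    rmse_in = rmse(err[decisions]),
    rmse_out = rmse(err[!decisions]),
    rmse_all = rmse(err),
    r2_in = r2(y_true[decisions], y_pred[decisions]),
    r2_all = r2(y_true, y_pred),
    quadrants = q
  ), class = "ad_metrics")
}

#' @export
print.ad_metrics <- function(x, digits = 3, ...) {
  cat(sprintf("coverage %.2f | OIR %s | dR2_AD %s | OD %.2f | AUC_AD %s\n",
              x$coverage, fmt_na(x$oir, digits), fmt_na(x$delta_r2_ad, digits),
              x$od, fmt_na(x$auc_ad, digits)))
  cat(sprintf("quadrants: TO=%d TI=%d FO=%d FI=%d\n",
              x$quadrants$TO, x$quadrants$TI, x$quadrants$FO, x$quadrants$FI))
  invisible(x)
}

fmt_na <- function(v, digits = 3) {
  if (is.na(v)) "NA" else formatC(v, digits = digits, format = "f")
}

#' Flatten a metrics report
#'
#' @param x an [ad_metrics()] object.
#' @return one-row data frame with the scalar metrics and quadrant counts,
#'   suitable for stacking into a benchmark table or JSON export.
#' @export
as.data.frame.ad_metrics <- function(x, ...) {
  data.frame(coverage = x$coverage, oir = x$oir, delta_r2_ad = x$delta_r2_ad,
             od = x$od, auc_ad = x$auc_ad,
             rmse_in = x$rmse_in, rmse_out = x$rmse_out, rmse_all = x$rmse_all,
             r2_in = x$r2_in, r2_all = x$r2_all,
             TO = x$quadrants$TO, TI = x$quadrants$TI,
             FO = x$quadrants$FO, FI = x$quadrants$FI)
}
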