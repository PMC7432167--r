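#' Benchmark configuration
#'
#' Collects the tunable knobs of the nested cross-validation benchmark:
#' fold counts, forest size, hyperparameter grids, the number of
#' threshold-grid quantiles, and the reaction-type-control radius. The
#' defaults are the full study settings; smaller values give proportionally
#' faster runs.
#'
#' @param outer,inner outer and inner fold counts (default 5 and 5).
#' @param ntree forest size for the random-forest regressor/classifier
#'   (default 500).
#' @param max_features_grid grid of column fractions tried per split.
#' @param nu_grid,gamma_grid one-class SVM grids (`gamma_grid` is shared with
#'   the GPR kernel).
#' @param alpha_grid GPR noise-level grid.
#' @param n_quantiles number of training-score quantiles used as the decision
#'   threshold grid for `h*`, `Dc`, `sigma*` and `p*` (default 20).
#' @param radius reaction-type-control neighbourhood radius (default 1, RTC1).
#' @param min_atoms,max_atoms fragment size bounds.
#' @return a list of class `ad_config`.
#' @export
ad_config <- function(outer = 5L, inner = 5L, ntree = 500L,
                      max_features_grid = c(0.1, 0.3, 0.5, 0.7, 1.0),
                      nu_grid = c(0.01, 0.05, 0.1, 0.2, 0.35, 0.5),
                      gamma_grid = 10^seq(-4, 0, length.out = 7),
                      alpha_grid = 10^seq(-3, 1, length.out = 5),
                      n_quantiles = 20L, radius = 1L,
                      min_atoms = 2L, max_atoms = 4L) {
  structure(list(outer = as.integer(outer), inner = as.integer(inner),
                 ntree = as.integer(ntree),
                 max_features_grid = max_features_grid,
                 nu_grid = nu_grid, gamma_grid = gamma_grid,
                 alpha_grid = alpha_grid,
                 n_quantiles = as.integer(n_quantiles),
                 radius = as.integer(radius),
                 min_atoms = as.integer(min_atoms),
                 max_atoms = as.integer(max_atoms)),
            class = "ad_config")
}

#' @export
print.ad_config <- function(x, ...) {
  cat("<ad_config>\n")
  for (nm in names(x))
    cat(sprintf("  %-18s %s\n", nm, paste(signif(unlist(x[[nm]]), 4), collapse = " ")))
  invisible(x)
}

#' Nested cross-validation plan
#'
#' Seeded uniform (unstratified) assignment of reactions to outer folds, and
#' of each outer-training set to inner folds. The plan is a pure function of
#' `(n, outer, inner, seed)`.
#'
#' @param n number of reactions.
#' @param outer,inner fold counts.
#' @param seed integer seed.
#' @return object of class `cv_plan`: `outer_id` (fold of each reaction) and
#'   `inner_id` (list over outer folds; inner fold of each outer-training row,
#'   `NA` at the outer-test rows).
#' @export
cv_plan <- function(n, outer = 5L, inner = 5L, seed = 1L) {
  stopifnot(n >= outer, outer >= 2L, inner >= 2L)
  set.seed(as.integer(seed))
  outer_id <- sample(rep_len(seq_len(outer), n))
  inner_id <- vector("list", outer)
  for (k in seq_len(outer)) {
    tr <- which(outer_id != k)
    set.seed(as.integer(seed) + 1009L * k)
    v <- rep(NA_integer_, n)
    v[tr] <- sample(rep_len(seq_len(inner), length(tr)))
    inner_id[[k]] <- v
  }
  structure(list(n = n, outer = outer, inner = inner, seed = as.integer(seed),
                 outer_id = outer_id, inner_id = inner_id), class = "cv_plan")
}

#' Tune QRPR hyperparameters by inner-fold RMSE
#'
#' Grid search minimizing the mean inner-fold RMSE of prediction (without AD
#' application). For the random forest the grid is over `max_features`; for
#' the Gaussian process over `(alpha, gamma)` pairs. Ties keep the first grid
#' point. The chosen model is refit on the full training block.
#'
#' @param x,y training descriptor block and property.
#' @param inner_id inner fold id per training row.
#' @param method `"rfr"` or `"gpr"`.
#' @param config an [ad_config()].
#' @param seed integer seed for the randomized fits.
#' @return list with `fit` (refit [qrpr_fit()] model), `params`, `cv_pred` and
#'   `cv_var` (inner cross-validation predictions/variances per training row
#'   under the chosen hyperparameters), and `rmse` (its pooled RMSE).
#' @export
tune_qrpr <- function(x, y, inner_id, method = c("rfr", "gpr"),
                      config = ad_config(), seed = 1L) {
  method <- match.arg(method)
  grid <- if (method == "rfr") {
    data.frame(max_features = config$max_features_grid)
  } else {
    expand.grid(alpha = config$alpha_grid, gamma = config$gamma_grid,
                KEEP.OUT.ATTRS = FALSE)
  }
  folds <- sort(unique(inner_id))
  best <- NULL
  for (g in seq_len(nrow(grid))) {
    pred <- var <- rep(NA_real_, length(y))
    for (j in folds) {
      trj <- which(inner_id != j); tej <- which(inner_id == j)
      fit <- with_seed(seed + 101L * g + j, fit_qrpr_row(
        x[trj, , drop = FALSE], y[trj], method, grid[g, , drop = FALSE], config))
      p <- predict(fit, x[tej, , drop = FALSE])
      pred[tej] <- p$mean; var[tej] <- p$var
    }
    rmse <- sqrt(mean((y - pred)^2))
    if (is.null(best) || rmse < best$rmse - 1e-12)
      best <- list(g = g, rmse = rmse, cv_pred = pred, cv_var = var)
  }
  params <- grid[best$g, , drop = FALSE]
  fit <- with_seed(seed + 999983L, fit_qrpr_row(x, y, method, params, config))
  list(fit = fit, params = params, cv_pred = best$cv_pred, cv_var = best$cv_var,
       rmse = best$rmse)
}

fit_qrpr_row <- function(x, y, method, row, config) {
  if (method == "rfr")
    qrpr_fit(x, y, "rfr", max_features = row$max_features, ntree = config$ntree)
  else
    qrpr_fit(x, y, "gpr", alpha = row$alpha, gamma = row$gamma)
}

# --- threshold selection -----------------------------------------------------

# Pick the best threshold quantile for pooled inner scores. The candidate
# thresholds are the `probs` quantiles of the pooled training-score
# distribution; the chosen quantile LEVEL is returned so the caller can map it
# onto the refit model's own training-score distribution (inner and refit
# score scales differ slightly because the refit model sees more data).
# Objective is maximized; ties resolved toward larger coverage, then first
# grid point.
pick_threshold <- function(scores, errors, probs, inlier_if, objective, flags) {
  grid <- stats::quantile(scores, probs = probs, names = FALSE, type = 7)
  best <- NULL
  for (i in seq_along(grid)) {
    dec <- switch(inlier_if,
                  le = scores <= grid[i],
                  ge = scores >= grid[i],
                  gt = scores > grid[i])
    val <- objective_value(objective, errors, dec, flags)
    cov <- mean(dec)
    if (is.null(best) || val > best$val + 1e-12 ||
        (val > best$val - 1e-12 && cov > best$cov + 1e-12)) {
      best <- list(i = i, val = val, cov = cov)
    }
  }
  probs[best$i]
}

objective_value <- function(objective, errors, decisions, flags) {
  switch(objective,
         OIR = ad_oir(errors, decisions),
         OD = ad_od(quadrant_counts(flags, decisions)),
         stop("unknown tuning objective ", sQuote(objective), call. = FALSE))
}

quantile_probs <- function(n_quantiles) seq_len(n_quantiles) / n_quantiles

score_grid <- function(scores, n_quantiles) {
  unique(stats::quantile(scores, probs = quantile_probs(n_quantiles),
                         names = FALSE, type = 7))
}

#' Tune an AD definition on inner folds
#'
#' Maximizes `OIR` or `OD`, computed on the pooled inner-fold predictions of
#' the accompanying QRPR model, over the method's hyperparameter grid.
#' Threshold grids are the `n_quantiles` quantiles of the pooled training
#' score distribution; ties are broken toward larger coverage, then first
#' grid point. Methods without hyperparameters are fitted unchanged.
#'
#' @param method AD method name as in [ad_fit()].
#' @param x,y training block and property.
#' @param inner_id inner fold assignment per training row.
#' @param cv_pred inner cross-validation property predictions (from
#'   [tune_qrpr()]).
#' @param cv_var inner cross-validation prediction variances (variance-based
#'   methods reuse them as tuning scores).
#' @param objective `"OIR"` or `"OD"`.
#' @param config an [ad_config()].
#' @param seed integer seed.
#' @return fitted [ad_fit()] model on the full `(x, y)` with tuned
#'   hyperparameters (attribute `tuned` lists the chosen values).
#' @export
tune_ad <- function(method, x, y, inner_id, cv_pred, cv_var = NULL,
                    objective = c("OIR", "OD"), config = ad_config(),
                    seed = 1L) {
  objective <- match.arg(objective)
  errors <- y - cv_pred
  flags <- twoclass_label(errors, sqrt(mean(errors^2)))
  folds <- sort(unique(inner_id))

  inner_scores <- function(fit_score) {
    # fit on inner-train, score inner-test; returns the pooled score vector
    out <- rep(NA_real_, length(y))
    for (j in folds) {
      trj <- which(inner_id != j); tej <- which(inner_id == j)
      out[tej] <- fit_score(trj, tej, j)
    }
    out
  }

  probs <- quantile_probs(config$n_quantiles)

  if (method == "leverage") {
    sc <- inner_scores(function(trj, tej, j) {
      ad <- ad_fit("leverage", x[trj, , drop = FALSE])
      predict(ad, x[tej, , drop = FALSE], type = "score")
    })
    p <- pick_threshold(sc, errors, probs, "le", objective, flags)
    fit <- ad_fit("leverage", x)
    fit$threshold <- stats::quantile(predict(fit, x, type = "score"),
                                     probs = p, names = FALSE)
    attr(fit, "tuned") <- list(quantile = p)
  } else if (method == "z1nn") {
    sc <- inner_scores(function(trj, tej, j) {
      ad <- ad_fit("z1nn", x[trj, , drop = FALSE])
      predict(ad, x[tej, , drop = FALSE], type = "score")
    })
    p <- pick_threshold(sc, errors, probs, "le", objective, flags)
    fit <- ad_fit("z1nn", x)
    fit$threshold <- stats::quantile(fit$train_nn, probs = p, names = FALSE)
    attr(fit, "tuned") <- list(quantile = p)
  } else if (method == "1svm") {
    grid <- expand.grid(nu = config$nu_grid, gamma = config$gamma_grid,
                        KEEP.OUT.ATTRS = FALSE)
    best <- NULL
    for (g in seq_len(nrow(grid))) {
      dec <- rep(NA, length(y))
      for (j in folds) {
        trj <- which(inner_id != j); tej <- which(inner_id == j)
        ad <- with_seed(seed + 31L * g + j,
                        ad_fit("1svm", x[trj, , drop = FALSE],
                               nu = grid$nu[g], gamma = grid$gamma[g]))
        dec[tej] <- predict(ad, x[tej, , drop = FALSE])
      }
      val <- objective_value(objective, errors, dec, flags)
      cov <- mean(dec)
      if (is.null(best) || val > best$val + 1e-12 ||
          (val > best$val - 1e-12 && cov > best$cov + 1e-12))
        best <- list(g = g, val = val, cov = cov)
    }
    fit <- with_seed(seed + 77L,
                     ad_fit("1svm", x, nu = grid$nu[best$g],
                            gamma = grid$gamma[best$g]))
    attr(fit, "tuned") <- grid[best$g, ]
  } else if (method == "2cc") {
    if (length(unique(flags)) < 2L || min(table(flags)) < 2L) {
      fit <- suppressWarnings(ad_fit("2cc", x, flags = flags))
      warning("2CC inapplicable on this training set (single Y-class); ",
              "recorded as all-inlier", call. = FALSE)
      return(fit)
    }
    best <- NULL
    for (mf in config$max_features_grid) {
      sc <- inner_scores(function(trj, tej, j) {
        fj <- flags[trj]
        if (length(unique(fj)) < 2L || min(table(fj)) < 2L)
          return(rep(1, length(tej)))  # degenerate inner fold: all-inlier scores
        ad <- with_seed(seed + 13L * j + round(1e4 * mf),
                        ad_fit("2cc", x[trj, , drop = FALSE], flags = fj,
                               max_features = mf, ntree = config$ntree))
        predict(ad, x[tej, , drop = FALSE], type = "score")
      })
      for (p in score_grid(sc, config$n_quantiles)) {
        dec <- sc > p
        val <- objective_value(objective, errors, dec, flags)
        cov <- mean(dec)
        if (is.null(best) || val > best$val + 1e-12 ||
            (val > best$val - 1e-12 && cov > best$cov + 1e-12))
          best <- list(mf = mf, p = p, val = val, cov = cov)
      }
    }
    fit <- with_seed(seed + 42L,
                     ad_fit("2cc", x, flags = flags, max_features = best$mf,
                            threshold = best$p, ntree = config$ntree))
    attr(fit, "tuned") <- list(max_features = best$mf, p_star = best$p)
  } else if (method %in% c("rfr_var", "gpr")) {
    stopifnot(!is.null(cv_var))
    p <- pick_threshold(cv_var, errors, probs, "le", objective, flags)
    fit <- if (method == "rfr_var")
      with_seed(seed + 55L, ad_fit("rfr_var", x, y, ntree = config$ntree))
    else ad_fit("gpr", x, y)
    # sigma* is the chosen quantile level mapped onto the refit model's own
    # training-variance distribution
    fit$threshold <- stats::quantile(predict(fit$fit, x)$var, probs = p,
                                     names = FALSE)
    attr(fit, "tuned") <- list(quantile = p, sigma_star = fit$threshold)
  } else {
    stop("method ", sQuote(method), " has no tunable hyperparameters; ",
         "use ad_fit() directly", call. = FALSE)
  }
  fit
}

# --- the benchmark -----------------------------------------------------------

#' Run the nested cross-validation AD benchmark
#'
#' For each outer fold: fits descriptors on the outer-training set, tunes the
#' QRPR regressors by inner-fold RMSE, tunes each AD definition's
#' hyperparameters on the inner folds by the requested objective(s), refits
#' everything on the outer-training set, and predicts property and AD
#' membership on the outer-test set. Predictions and decisions from all outer
#' folds are merged before the metrics are computed. Composite models
#' (`name*`) AND each decision with the RTC1 decision; the zero models and the
#' Perfect AD model are included as baselines. GPR-based rows are evaluated
#' against the Gaussian-process predictions, all other rows against the
#' random-forest predictions.
#'
#' @param data dataset data frame (see [reaction_descriptors()] for the
#'   required columns).
#' @param methods character vector of method names: any of `"BB"`, `"FC"`,
#'   `"RTC1"`, `"Leverage"`, `"Z-1NN"`, `"Lev_cv"`, `"Z-1NN_cv"`, `"1-SVM"`,
#'   `"2CC"`, `"RFR_VAR"`, `"GPR-AD"`, `"OZ"`, `"PZ"`, `"Perfect"`.
#' @param objectives tuning objectives for the tunable methods (default both
#'   `"OIR"` and `"OD"`; each produces a separate model row `name/objective`).
#' @param config an [ad_config()].
#' @param seed integer seed; the entire benchmark is a pure function of
#'   `(data, methods, objectives, config, seed)`.
#' @param composites include the `name*` composites with RTC1 (default TRUE).
#' @return object of class `ad_benchmark`: `metrics` (one row per model),
#'   `predictions` (per-reaction merged outer-fold predictions and decisions),
#'   `plan`, `config`, `seed`.
#' @export
run_benchmark <- function(data,
                          methods = c("BB", "FC", "RTC1", "Leverage", "Z-1NN",
                                      "Lev_cv", "Z-1NN_cv", "1-SVM", "2CC",
                                      "RFR_VAR", "GPR-AD", "OZ", "PZ", "Perfect"),
                          objectives = c("OIR", "OD"),
                          config = ad_config(), seed = 1L,
                          composites = TRUE) {
  stopifnot(nrow(data) >= 2L * config$outer)
  plan <- cv_plan(nrow(data), config$outer, config$inner, seed)
  n <- nrow(data)
  need_gpr <- "GPR-AD" %in% methods
  need_rtc <- composites || "RTC1" %in% methods

  pred_rfr <- var_rfr <- rep(NA_real_, n)
  pred_gpr <- var_gpr <- rep(NA_real_, n)
  decisions <- list()
  add_dec <- function(name, te, dec) {
    if (is.null(decisions[[name]])) decisions[[name]] <<- rep(NA, n)
    decisions[[name]][te] <<- dec
  }
  tunable <- c("Lev_cv" = "leverage", "Z-1NN_cv" = "z1nn", "1-SVM" = "1svm",
               "2CC" = "2cc", "RFR_VAR" = "rfr_var", "GPR-AD" = "gpr")

  for (k in seq_len(config$outer)) {
    tr <- which(plan$outer_id != k)
    te <- which(plan$outer_id == k)
    fold_seed <- plan$seed + 10000L * k
    desc <- reaction_descriptors(data[tr, ], config$min_atoms, config$max_atoms)
    x <- desc$x; y <- desc$y
    tp <- predict(desc, data[te, ])
    inner_id <- plan$inner_id[[k]][tr]

    rfr <- tune_qrpr(x, y, inner_id, "rfr", config, seed = fold_seed)
    p <- predict(rfr$fit, tp$x)
    pred_rfr[te] <- p$mean; var_rfr[te] <- p$var
    if (need_gpr) {
      gpr <- tune_qrpr(x, y, inner_id, "gpr", config, seed = fold_seed + 1L)
      pg <- predict(gpr$fit, tp$x)
      pred_gpr[te] <- pg$mean; var_gpr[te] <- pg$var
    }
    if (need_rtc) {
      rtc <- ad_fit("rtc", reactions = data$reaction[tr], radius = config$radius)
      add_dec("RTC1", te, predict(rtc, data$reaction[te]))
    }
    if ("BB" %in% methods)
      add_dec("BB", te, predict(ad_fit("bb", x), tp$x))
    if ("FC" %in% methods)
      add_dec("FC", te, fragment_control_decide(tp$unseen))
    if ("Leverage" %in% methods)
      add_dec("Leverage", te, predict(ad_fit("leverage", x), tp$x))
    if ("Z-1NN" %in% methods)
      add_dec("Z-1NN", te, predict(ad_fit("z1nn", x), tp$x))
    if ("OZ" %in% methods) add_dec("OZ", te, rep(TRUE, length(te)))
    if ("PZ" %in% methods) add_dec("PZ", te, rep(FALSE, length(te)))

    for (mname in intersect(names(tunable), methods)) {
      internal <- tunable[[mname]]
      cvp <- if (internal == "gpr") gpr$cv_pred else rfr$cv_pred
      cvv <- if (internal == "gpr") gpr$cv_var else rfr$cv_var
      for (obj in objectives) {
        fit <- withCallingHandlers(
          tune_ad(internal, x, y, inner_id, cvp, cvv, objective = obj,
                  config = config, seed = fold_seed + 17L * match(obj, objectives)),
          warning = function(w) invokeRestart("muffleWarning"))
        dec <- if (internal %in% c("1svm", "2cc", "leverage", "z1nn",
                                   "rfr_var", "gpr"))
          suppressWarnings(predict(fit, tp$x))
        else predict(fit, tp$x)
        add_dec(paste0(mname, "/", obj), te, dec)
      }
    }
  }

  err_rfr <- data$property - pred_rfr
  flags_rfr <- twoclass_label(err_rfr, sqrt(mean(err_rfr^2)))
  if (need_gpr) {
    err_gpr <- data$property - pred_gpr
    flags_gpr <- twoclass_label(err_gpr, sqrt(mean(err_gpr^2)))
  }
  if ("Perfect" %in% methods) decisions[["Perfect"]] <- !flags_rfr

  base_names <- names(decisions)
  if (composites) {
    rtc_dec <- decisions[["RTC1"]]
    for (nm in setdiff(base_names, c("RTC1", "OZ", "PZ", "Perfect"))) {
      star <- sub("^([^/]+)(/?.*)$", "\\1*\\2", nm)
      decisions[[star]] <- decisions[[nm]] & rtc_dec
    }
    if (!("RTC1" %in% methods)) decisions[["RTC1"]] <- NULL
  }

  rows <- lapply(names(decisions), function(nm) {
    is_gpr <- grepl("^GPR-AD", nm)
    yp <- if (is_gpr) pred_gpr else pred_rfr
    fl <- if (is_gpr) flags_gpr else flags_rfr
    cbind(data.frame(model = nm, stringsAsFactors = FALSE),
          as.data.frame(ad_metrics(data$property, yp, decisions[[nm]],
                                   y_outlier_flags = fl)))
  })
  metrics <- do.call(rbind, rows)
  metrics <- metrics[order(metrics$model), ]
  rownames(metrics) <- NULL

  preds <- data.frame(id = data$id %||% seq_len(n),
                      fold = plan$outer_id,
                      y_true = data$property,
                      y_pred_rfr = pred_rfr, var_rfr = var_rfr,
                      stringsAsFactors = FALSE)
  if (need_gpr) { preds$y_pred_gpr <- pred_gpr; preds$var_gpr <- var_gpr }
  for (nm in names(decisions)) preds[[nm]] <- decisions[[nm]]

  structure(list(metrics = metrics, predictions = preds, plan = plan,
                 config = config, seed = as.integer(seed)),
            class = "ad_benchmark")
}

#' @export
print.ad_benchmark <- function(x, digits = 2, ...) {
  cat(sprintf("<ad_benchmark> %d reactions, %dx%d nested CV, seed %d\n",
              nrow(x$predictions), x$config$outer, x$config$inner, x$seed))
  tab <- x$metrics[, c("model", "coverage", "oir", "delta_r2_ad", "od", "auc_ad")]
  tab[-1] <- lapply(tab[-1], round, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Serialize a benchmark report to JSON
#'
#' Deterministic JSON rendering of the metrics and per-reaction decisions;
#' two runs with identical inputs and seed produce byte-identical strings.
#'
#' @param report an [run_benchmark()] result.
#' @param path optional file to write to.
#' @return the JSON string, invisibly when `path` is given.
#' @export
benchmark_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(list(seed = report$seed,
                              metrics = report$metrics,
                              predictions = report$predictions),
                         dataframe = "columns", digits = NA, na = "null",
                         auto_unbox = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Cross-validated QRPR predictions without AD
#'
#' Simple k-fold cross-validation of the random-forest QRPR model with
#' per-fold descriptor refits: every reaction is predicted by a model that
#' never saw it. Used for Y-outlier labelling and for the zero/perfect
#' baseline identities.
#'
#' @param data dataset data frame.
#' @param folds fold count (default 5).
#' @param seed integer seed.
#' @param ntree,max_features forest settings.
#' @param config an [ad_config()] for the descriptor settings.
#' @return list with `pred`, `var` (per reaction), `rmse` and `flags`
#'   (3xRMSE Y-outlier labels).
#' @export
qrpr_cv_predict <- function(data, folds = 5L, seed = 1L, ntree = 500L,
                            max_features = 1 / 3, config = ad_config()) {
  n <- nrow(data)
  set.seed(as.integer(seed))
  fid <- sample(rep_len(seq_len(folds), n))
  pred <- var <- rep(NA_real_, n)
  for (j in seq_len(folds)) {
    tr <- which(fid != j); te <- which(fid == j)
    desc <- reaction_descriptors(data[tr, ], config$min_atoms, config$max_atoms)
    fit <- with_seed(seed + 31L * j,
                     qrpr_fit(desc$x, desc$y, "rfr",
                              max_features = max_features, ntree = ntree))
    p <- predict(fit, predict(desc, data[te, ])$x)
    pred[te] <- p$mean; var[te] <- p$var
  }
  err <- data$property - pred
  rmse <- sqrt(mean(err^2))
  list(pred = pred, var = var, rmse = rmse,
       flags = twoclass_label(err, rmse))
}

#' Fraction of a foreign dataset flagged as X-outliers
#'
#' Fits a structure-based AD (reaction type control or fragment control) on a
#' training dataset and reports the fraction of a foreign dataset decided
#' outside the AD — the non-native reaction-type detection rate.
#'
#' @param train_data,foreign_data dataset data frames.
#' @param method `"rtc"` or `"fc"`.
#' @param radius RTC neighbourhood radius (default 1).
#' @param config an [ad_config()] (fragment bounds for FC).
#' @return fraction in `[0, 1]` of foreign reactions decided X-outliers.
#' @export
detect_nonnative <- function(train_data, foreign_data, method = c("rtc", "fc"),
                             radius = 1L, config = ad_config()) {
  method <- match.arg(method)
  if (method == "rtc") {
    ad <- ad_fit("rtc", reactions = train_data$reaction, radius = radius)
    mean(!predict(ad, foreign_data$reaction))
  } else {
    desc <- reaction_descriptors(train_data, config$min_atoms, config$max_atoms)
    tp <- predict(desc, foreign_data)
    mean(!fragment_control_decide(tp$unseen))
  }
}

#' Penalty ranking of AD definition models across datasets
#'
#' For every dataset and every characteristic — coverage, performance
#' improvement (`delta_r2_ad`) and Y-outlier detection (`od`) — a model gets
#' penalty 0 when its value is in the top 50% (strictly above the median over
#' models; `NA` values are penalized), else 1. When non-native detection
#' rates are supplied, a further penalty of 1 is added per dataset whenever at
#' least one non-native reaction was accepted as an X-inlier (rate < 1).
#' Models are ranked by ascending penalty sum; ties are broken alphabetically.
#'
#' @param reports named list (one element per dataset) of benchmark metric
#'   tables (`$metrics` of [run_benchmark()], or any data frame with columns
#'   `model`, `coverage`, `delta_r2_ad`, `od`).
#' @param nonnative optional named list parallel to `reports`: named numeric
#'   vectors (model -> fraction of non-native reactions flagged X-outliers).
#' @return data frame `model`, `penalty`, `rank`, ordered by rank.
#' @export
rank_methods <- function(reports, nonnative = NULL) {
  stopifnot(length(reports) >= 1L)
  tabs <- lapply(reports, function(r) if (inherits(r, "ad_benchmark")) r$metrics else r)
  models <- sort(unique(unlist(lapply(tabs, `[[`, "model"))))
  stopifnot(length(models) >= 2L)
  penalty <- setNames(numeric(length(models)), models)
  for (ds in seq_along(tabs)) {
    t <- tabs[[ds]]
    for (ch in c("coverage", "delta_r2_ad", "od")) {
      v <- setNames(t[[ch]], t$model)[models]
      med <- stats::median(v, na.rm = TRUE)
      penalty <- penalty + ifelse(!is.na(v) & v > med, 0, 1)
    }
    if (!is.null(nonnative)) {
      nn <- nonnative[[ds]][models]
      penalty <- penalty + ifelse(!is.na(nn) & nn >= 1, 0, 1)
    }
  }
  out <- data.frame(model = models, penalty = as.numeric(penalty),
                    stringsAsFactors = FALSE)
  out <- out[order(out$penalty, out$model), ]
  out$rank <- rank(out$penalty, ties.method = "min")
  rownames(out) <- NULL
  out
}

#' Validate AD definitions on an external test set
#'
#' Trains the full pipeline (descriptors, QRPR tuning, AD tuning) on the
#' training dataset using an internal cross-validation split, applies it to an
#' external test set, and reports, per AD model, the coverage and the
#' prediction quality (R2, RMSE) computed on the decided X-inliers only,
#' together with the no-AD baseline.
#'
#' @param train_data,test_data dataset data frames.
#' @param methods,objectives,config,seed as in [run_benchmark()].
#' @param composites AND the decisions with RTC1 (default TRUE), mirroring the
#'   composite AD convention.
#' @return data frame with one row per model: `model`, `coverage`, `r2_in`,
#'   `rmse_in`, `n_in`; the last row is the `Without AD` baseline. The
#'   per-reaction decisions are attached as the `decisions` attribute (a
#'   logical matrix, one column per model).
#' @export
external_validate <- function(train_data, test_data,
                              methods = c("RTC1", "BB", "2CC", "RFR_VAR",
                                          "GPR-AD", "OZ", "PZ"),
                              objectives = "OIR",
                              config = ad_config(), seed = 1L,
                              composites = TRUE) {
  n <- nrow(train_data)
  set.seed(as.integer(seed))
  inner_id <- sample(rep_len(seq_len(config$inner), n))
  desc <- reaction_descriptors(train_data, config$min_atoms, config$max_atoms)
  x <- desc$x; y <- desc$y
  tp <- predict(desc, test_data)
  rfr <- tune_qrpr(x, y, inner_id, "rfr", config, seed = seed)
  yp <- predict(rfr$fit, tp$x)$mean
  need_gpr <- "GPR-AD" %in% methods
  if (need_gpr) {
    gpr <- tune_qrpr(x, y, inner_id, "gpr", config, seed = seed + 1L)
    yp_gpr <- predict(gpr$fit, tp$x)$mean
  }
  rtc_dec <- NULL
  if (composites || "RTC1" %in% methods) {
    rtc <- ad_fit("rtc", reactions = train_data$reaction, radius = config$radius)
    rtc_dec <- predict(rtc, test_data$reaction)
  }
  decisions <- list()
  if ("RTC1" %in% methods) decisions[["RTC1"]] <- rtc_dec
  if ("BB" %in% methods) decisions[["BB"]] <- predict(ad_fit("bb", x), tp$x)
  if ("FC" %in% methods) decisions[["FC"]] <- fragment_control_decide(tp$unseen)
  if ("Leverage" %in% methods)
    decisions[["Leverage"]] <- predict(ad_fit("leverage", x), tp$x)
  if ("Z-1NN" %in% methods)
    decisions[["Z-1NN"]] <- predict(ad_fit("z1nn", x), tp$x)
  if ("OZ" %in% methods) decisions[["OZ"]] <- rep(TRUE, nrow(test_data))
  if ("PZ" %in% methods) decisions[["PZ"]] <- rep(FALSE, nrow(test_data))
  tunable <- c("Lev_cv" = "leverage", "Z-1NN_cv" = "z1nn", "1-SVM" = "1svm",
               "2CC" = "2cc", "RFR_VAR" = "rfr_var", "GPR-AD" = "gpr")
  for (mname in intersect(names(tunable), methods)) {
    internal <- tunable[[mname]]
    cvp <- if (internal == "gpr") gpr$cv_pred else rfr$cv_pred
    cvv <- if (internal == "gpr") gpr$cv_var else rfr$cv_var
    for (obj in objectives) {
      fit <- withCallingHandlers(
        tune_ad(internal, x, y, inner_id, cvp, cvv, objective = obj,
                config = config, seed = seed + 17L * match(obj, objectives)),
        warning = function(w) invokeRestart("muffleWarning"))
      nm <- if (length(objectives) > 1L) paste0(mname, "/", obj) else mname
      decisions[[nm]] <- suppressWarnings(predict(fit, tp$x))
    }
  }
  if (composites) {
    for (nm in setdiff(names(decisions), c("RTC1", "OZ", "PZ")))
      decisions[[sub("^([^/]+)(/?.*)$", "\\1*\\2", nm)]] <-
        decisions[[nm]] & rtc_dec
  }
  r2 <- function(yt, yh) {
    if (length(yt) < 2L || max(yt) == min(yt)) return(NA_real_)
    1 - sum((yt - yh)^2) / sum((yt - mean(yt))^2)
  }
  row_for <- function(nm, dec) {
    pred <- if (grepl("^GPR-AD", nm)) yp_gpr else yp
    n_in <- sum(dec)
    data.frame(model = nm, coverage = mean(dec),
               r2_in = if (n_in) r2(test_data$property[dec], pred[dec]) else NA_real_,
               rmse_in = if (n_in)
                 sqrt(mean((test_data$property[dec] - pred[dec])^2)) else NA_real_,
               n_in = n_in, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(names(decisions),
                               function(nm) row_for(nm, decisions[[nm]])))
  out <- rbind(out, data.frame(model = "Without AD", coverage = 1,
                               r2_in = r2(test_data$property, yp),
                               rmse_in = sqrt(mean((test_data$property - yp)^2)),
                               n_in = nrow(test_data), stringsAsFactors = FALSE))
  rownames(out) <- NULL
  attr(out, "decisions") <- do.call(cbind, decisions)
  out
}
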