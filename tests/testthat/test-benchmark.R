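# a small configuration keeping the full workflow fast
small_config <- function() {
  ad_config(outer = 3, inner = 3, ntree = 100,
            max_features_grid = c(0.3, 1.0),
            nu_grid = c(0.05, 0.2), gamma_grid = 10^c(-3, -1),
            alpha_grid = c(0.01, 0.1), n_quantiles = 10)
}

test_that("cv_plan partitions reproducibly from the seed", {
  p1 <- cv_plan(53, outer = 4, inner = 3, seed = 9)
  p2 <- cv_plan(53, outer = 4, inner = 3, seed = 9)
  expect_identical(p1, p2)
  expect_setequal(unique(p1$outer_id), 1:4)
  expect_equal(length(p1$outer_id), 53)
  for (k in 1:4) {
    inner <- p1$inner_id[[k]]
    expect_true(all(is.na(inner[p1$outer_id == k])))
    expect_setequal(unique(stats::na.omit(inner)), 1:3)
  }
  expect_false(identical(p1$outer_id, cv_plan(53, 4, 3, seed = 10)$outer_id))
})

test_that("QRPR tuning picks a single-point grid and is deterministic", {
  d <- suite_sample("substitution", 45, seed = 14)
  fit <- reaction_descriptors(d)
  set.seed(14)
  inner_id <- sample(rep_len(1:3, 45))
  cfg <- small_config(); cfg$max_features_grid <- 0.5
  t1 <- tune_qrpr(fit$x, fit$y, inner_id, "rfr", cfg, seed = 1)
  expect_equal(t1$params$max_features, 0.5)
  t2 <- tune_qrpr(fit$x, fit$y, inner_id, "rfr", cfg, seed = 1)
  expect_identical(t1$cv_pred, t2$cv_pred)
  expect_identical(predict(t1$fit, fit$x)$mean, predict(t2$fit, fit$x)$mean)
})

test_that("AD tuning responds to planted outliers and leaves fixed methods unchanged", {
  d <- suite_sample("substitution", 90, seed = 15)
  fit <- reaction_descriptors(d)
  set.seed(15)
  inner_id <- sample(rep_len(1:3, 90))
  cfg <- small_config()
  rfr <- tune_qrpr(fit$x, fit$y, inner_id, "rfr", cfg, seed = 2)
  tuned <- tune_ad("rfr_var", fit$x, fit$y, inner_id, rfr$cv_pred, rfr$cv_var,
                   objective = "OIR", config = cfg, seed = 2)
  expect_s3_class(tuned, "ad_model")
  expect_true(is.finite(tuned$threshold))
  expect_error(tune_ad("bb", fit$x, fit$y, inner_id, rfr$cv_pred,
                       config = cfg), "no tunable")
})

test_that("the benchmark reproduces the zero and perfect model identities", {
  d <- suite_sample("substitution", 60, seed = 16)
  bm <- run_benchmark(d, methods = c("OZ", "PZ", "Perfect", "RTC1"),
                      objectives = "OIR", config = small_config(), seed = 5)
  m <- bm$metrics
  row <- function(nm) m[m$model == nm, ]
  expect_equal(row("OZ")$coverage, 1.00)
  expect_equal(row("PZ")$coverage, 0.00)
  expect_equal(row("OZ")$oir, 0)
  expect_equal(row("OZ")$delta_r2_ad, 0)
  expect_equal(row("OZ")$od, 0.5)
  expect_equal(row("PZ")$od, 0.5)
  expect_equal(row("Perfect")$od, 1.0)
  # PZ convention: R2_in treated as 0, so delta-R2 is minus the overall R2
  expect_equal(row("PZ")$delta_r2_ad, -row("PZ")$r2_all)
})

test_that("the benchmark is byte-identical across reruns with one seed", {
  d <- suite_sample("elimination", 60, seed = 17)
  cfg <- small_config()
  methods <- c("BB", "RTC1", "RFR_VAR", "Leverage", "OZ", "PZ", "Perfect")
  b1 <- run_benchmark(d, methods = methods, objectives = "OIR",
                      config = cfg, seed = 11)
  b2 <- run_benchmark(d, methods = methods, objectives = "OIR",
                      config = cfg, seed = 11)
  expect_identical(benchmark_json(b1), benchmark_json(b2))
  b3 <- run_benchmark(d, methods = methods, objectives = "OIR",
                      config = cfg, seed = 12)
  expect_false(identical(benchmark_json(b1), benchmark_json(b3)))
})

test_that("composite decisions satisfy the AND identities on merged folds", {
  d <- suite_sample("substitution", 60, seed = 18)
  bm <- run_benchmark(d, methods = c("BB", "RTC1", "RFR_VAR", "OZ"),
                      objectives = "OIR", config = small_config(), seed = 6)
  pr <- bm$predictions
  expect_equal(pr[["BB*"]], pr[["BB"]] & pr[["RTC1"]])
  expect_equal(pr[["RFR_VAR*/OIR"]], pr[["RFR_VAR/OIR"]] & pr[["RTC1"]])
  m <- bm$metrics
  cov <- setNames(m$coverage, m$model)
  expect_lte(cov[["BB*"]], min(cov[["BB"]], cov[["RTC1"]]))
  expect_lte(cov[["RFR_VAR*/OIR"]], min(cov[["RFR_VAR/OIR"]], cov[["RTC1"]]))
  # an always-inlier component leaves the composite equal to RTC1
  expect_equal(pr[["OZ"]] & pr[["RTC1"]], pr[["RTC1"]])
})

test_that("non-native detection is complete across suites and zero on self", {
  a <- suite_sample("substitution", 40, seed = 19)
  b <- suite_sample("elimination", 40, seed = 19)
  expect_equal(detect_nonnative(a, b, "rtc"), 1.0)
  expect_equal(detect_nonnative(b, a, "rtc"), 1.0)
  expect_equal(detect_nonnative(a, a, "rtc"), 0.0)
  expect_equal(detect_nonnative(a, b, "fc"), 1.0)
})

test_that("penalty ranking puts the perfect model first and respects the rules", {
  t1 <- data.frame(model = c("Perfect", "A", "B", "C"),
                   coverage = c(0.98, 0.95, 0.60, 0.40),
                   delta_r2_ad = c(0.06, 0.01, 0.05, NA),
                   od = c(1.0, 0.55, 0.80, 0.70))
  r <- rank_methods(list(ds1 = t1))
  expect_equal(r$model[r$rank == 1], "Perfect")
  expect_equal(r$penalty[r$model == "C"], 3)  # NA and below-median values penalized
  # identical methods share a penalty; non-native acceptance adds one
  t2 <- rbind(t1, data.frame(model = "A2", coverage = 0.95,
                             delta_r2_ad = 0.01, od = 0.55))
  nn <- list(ds1 = c(Perfect = 1, A = 1, A2 = 1, B = 0.9, C = 1))
  r2 <- rank_methods(list(ds1 = t2), nonnative = nn)
  expect_equal(r2$penalty[r2$model == "A"], r2$penalty[r2$model == "A2"])
  base <- rank_methods(list(ds1 = t2))
  expect_equal(r2$penalty[r2$model == "B"] - base$penalty[base$model == "B"], 1)
})

test_that("external validation reports the OZ/PZ extremes correctly", {
  d <- suite_sample("substitution", 60, seed = 20)
  te <- suite_sample("substitution", 30, seed = 21, truth = attr(d, "truth"))
  ev <- external_validate(d, te, methods = c("OZ", "PZ", "BB"),
                          config = small_config(), seed = 4, composites = FALSE)
  oz <- ev[ev$model == "OZ", ]; noad <- ev[ev$model == "Without AD", ]
  expect_equal(oz$coverage, 1)
  expect_equal(oz$r2_in, noad$r2_in)
  expect_equal(oz$rmse_in, noad$rmse_in)
  pz <- ev[ev$model == "PZ", ]
  expect_equal(pz$coverage, 0)
  expect_true(is.na(pz$r2_in))
  dec <- attr(ev, "decisions")
  expect_equal(dim(dec), c(30L, 3L))
})
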