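test_that("leverage reproduces the hat-matrix by hand and by trace identity", {
  # X = [[1], [-1]]: XtX = 2, h = x^2/2 = 0.5 for both rows
  x <- matrix(c(1, -1), 2, 1)
  ad <- ad_fit("leverage", x)
  expect_equal(predict(ad, x, type = "score"), c(0.5, 0.5))
  # default threshold from the printed formula: M = 3, N = 40 -> 0.3
  x2 <- matrix(rnorm(120), 40, 3)
  expect_equal(ad_fit("leverage", x2)$threshold, 3 * (3 + 1) / 40)
  # point at the centroid of centered descriptors has h = 0 and is an inlier
  xc <- scale(x2, scale = FALSE)
  adc <- ad_fit("leverage", xc)
  expect_equal(unname(predict(adc, matrix(0, 1, 3), type = "score")), 0)
  expect_true(predict(adc, matrix(0, 1, 3)))
  # trace of the hat matrix equals rank(X), incl. rank-deficient X
  set.seed(1)
  for (rep in 1:20) {
    n <- sample(10:50, 1); p <- sample(2:20, 1)
    x3 <- matrix(rnorm(n * p), n, p)
    if (rep %% 3 == 0) x3 <- cbind(x3, x3[, 1] + x3[, 2])  # force deficiency
    ad3 <- ad_fit("leverage", x3)
    expect_equal(sum(predict(ad3, x3, type = "score")),
                 qr(x3)$rank, tolerance = 1e-8)
  }
})

test_that("Z-1NN distance threshold follows Dc = Z*sigma + mean", {
  x <- matrix(c(0, 1, 2), 3, 1)
  ad <- ad_fit("z1nn", x, Z = 0.5)
  expect_equal(ad$nn_mean, 1)
  expect_equal(ad$nn_sd, 0)
  expect_equal(ad$threshold, 1)
  expect_true(predict(ad, matrix(1.5, 1, 1)))     # d = 0.5 <= 1
  expect_false(predict(ad, matrix(4.5, 1, 1)))    # d = 2.5 > 1
  # large Z eventually admits any finite point
  adZ <- ad_fit("z1nn", matrix(rnorm(20), 10, 2), Z = 1e6)
  expect_true(all(predict(adZ, matrix(5, 3, 2))))
})

test_that("one-class SVM respects the nu bound and flags far points", {
  set.seed(5)
  x <- matrix(rnorm(400), 200, 2)
  for (nu in c(0.05, 0.2)) {
    ad <- ad_fit("1svm", x, nu = nu, gamma = 0.5)
    expect_lte(mean(!predict(ad, x)), nu + 0.1)
  }
  ad <- ad_fit("1svm", x, nu = 0.1, gamma = 0.5)
  expect_false(predict(ad, matrix(10, 1, 2)))   # >= 10 training sds away
  # a point duplicating a dense-cluster member is an inlier
  expect_true(predict(ad, matrix(0, 1, 2)))
  # decisions agree with the library's own predict
  expect_equal(unname(predict(ad, x)), unname(as.logical(predict(ad$fit, x))))
})

test_that("Y-outlier labelling uses a strict 3xRMSE rule", {
  expect_equal(twoclass_label(c(0.1, 3.5), 1), c(FALSE, TRUE))
  expect_equal(twoclass_label(c(-3.5, 2.9), 1), c(TRUE, FALSE))
  expect_false(twoclass_label(3, 1))  # boundary is a Y-inlier
  expect_error(twoclass_label(1, 0))
})

test_that("two-class classifier separates planted labels and degrades gracefully", {
  set.seed(7)
  x <- rbind(matrix(rnorm(100, 0), 50, 2), matrix(rnorm(20, 6), 10, 2))
  flags <- c(rep(FALSE, 50), rep(TRUE, 10))
  ad <- ad_fit("2cc", x, flags = flags, max_features = 1, ntree = 200)
  expect_equal(unname(predict(ad, x)), !flags)   # separable at p* = 0.5
  # threshold extremes: the decision is strict (score > p*), so p* below the
  # probability floor admits everything and p* = 1 excludes everything
  ad0 <- ad_fit("2cc", x, flags = flags, threshold = -1e-9, ntree = 100)
  expect_true(all(predict(ad0, x)))
  ad1 <- ad_fit("2cc", x, flags = flags, threshold = 1, ntree = 100)
  expect_false(any(predict(ad1, x)))
  # single-class training: structured fallback, all-inlier with a warning
  expect_warning(adw <- ad_fit("2cc", x, flags = rep(FALSE, 60)), "2CC inapplicable")
  expect_true(adw$degenerate)
  expect_true(all(predict(adw, x)))
})

test_that("bounding box uses closed intervals per descriptor", {
  x <- matrix(runif(60), 20, 3)
  ad <- ad_fit("bb", x)
  expect_true(all(predict(ad, x)))
  probe <- x[1, , drop = FALSE]
  probe[1, 2] <- max(x[, 2]) + 1e-9
  expect_false(predict(ad, probe))
  probe[1, 2] <- max(x[, 2])           # equality at a bound is inside
  expect_true(predict(ad, probe))
})

test_that("fragment control accepts covered reactions and rejects novel fragments", {
  train <- suite_sample("substitution", 25, seed = 8)
  fit <- reaction_descriptors(train)
  expect_true(all(fragment_control_decide(predict(fit, train)$unseen)))
  novel <- train[1, ]
  novel$reaction <- "[CH3:4][CH2:1][I:2].[OH-:3]>>[CH3:4][CH2:1][OH:3].[I-:2]"
  expect_false(fragment_control_decide(predict(fit, novel)$unseen))
})

test_that("fragment control passes zwitterion tautomers over an elimination set while RTC rejects them", {
  elim <- suite_sample("elimination", 100, seed = 12)
  zwit <- suite_sample("zwitterion", 60, seed = 13)
  fit <- reaction_descriptors(elim)
  fc_dec <- fragment_control_decide(predict(fit, zwit)$unseen)
  expect_gte(sum(fc_dec), 1L)          # the documented FC failure mode
  rtc <- ad_fit("rtc", reactions = elim$reaction, radius = 1)
  expect_false(any(predict(rtc, zwit$reaction)))
})

test_that("reaction type control accepts native types and rejects novel centers", {
  train <- suite_sample("substitution", 40, seed = 4)
  rtc <- ad_fit("rtc", reactions = train$reaction, radius = 1)
  expect_true(all(predict(rtc, train$reaction)))
  foreign <- suite_sample("cycloaddition", 15, seed = 4)
  expect_false(any(predict(rtc, foreign$reaction)))
  # native center, novel first-shell substituent: outlier at R = 1
  lgs <- suite_sample("leaving_group_shift", 10, seed = 4)
  expect_false(any(predict(rtc, lgs$reaction)))
  rtc0 <- ad_fit("rtc", reactions = train$reaction, radius = 0)
  expect_true(all(predict(rtc0, lgs$reaction)))
  # a change-free reaction has an empty signature set and is never an inlier
  expect_false(predict(rtc, "[CH4:1]>>[CH4:1]"))
})

test_that("ensemble-variance ADs decide by the sigma* threshold", {
  d <- suite_sample("substitution", 50, seed = 21)
  fit <- reaction_descriptors(d)
  set.seed(1)
  ad <- ad_fit("rfr_var", fit$x, fit$y, ntree = 100, threshold = Inf)
  expect_true(all(predict(ad, fit$x)))   # sigma* = Inf is the optimistic zero model
  sc <- predict(ad, fit$x, type = "score")
  expect_true(all(sc >= 0))
  thr <- stats::median(sc)
  ad2 <- ad_fit("rfr_var", fit$x, fit$y, ntree = 100, threshold = thr)
  set.seed(1)
  ad2$fit <- ad$fit
  expect_equal(unname(predict(ad2, fit$x)), unname(sc <= thr))
})

test_that("GPR posterior variance matches the closed form and grows off-sample", {
  d <- suite_sample("substitution", 40, seed = 22)
  fit <- reaction_descriptors(d)
  m <- qrpr_fit(fit$x, fit$y, "gpr", alpha = 0.05, gamma = 0.01)
  far <- fit$x[1:2, , drop = FALSE] + 10
  p <- predict(m, rbind(fit$x[1:5, ], far))
  o <- gpr_oracle(fit$x, fit$y, rbind(fit$x[1:5, ], far),
                  alpha = 0.05, gamma = 0.01)
  expect_equal(p$mean, o$mean, tolerance = 1e-6)
  expect_equal(p$var, o$var, tolerance = 1e-6)
  # stationary kernel: variance at training points below variance far away
  expect_true(all(p$var[1:5] < min(p$var[6:7])))
  ad <- ad_fit("gpr", fit$x, fit$y, alpha = 0.05, gamma = 0.01)
  expect_true(all(predict(ad, fit$x)))   # default sigma* covers training rows
  expect_false(any(predict(ad, far)))
})

test_that("zero and perfect baselines obey their identities", {
  expect_equal(zero_model_decisions(4, "oz"), rep(TRUE, 4))
  expect_equal(zero_model_decisions(4, "pz"), rep(FALSE, 4))
  err <- c(rep(0.1, 19), 5)   # one gross error among twenty small ones
  rmse <- sqrt(mean(err^2))
  pd <- perfect_decisions(err, rmse)
  expect_equal(pd, abs(err) <= 3 * rmse)
  flags <- twoclass_label(err, rmse)
  expect_equal(ad_od(quadrant_counts(flags, pd)), 1.0)
  expect_true(all(perfect_decisions(rep(0, 5), 1)))
})

test_that("composite decisions are a logical AND with the expected identities", {
  a <- c(TRUE, TRUE, FALSE)
  b <- c(TRUE, FALSE, FALSE)
  expect_equal(composite_decide(a, b), c(TRUE, FALSE, FALSE))
  expect_equal(composite_decide(a), a)
  oz <- rep(TRUE, 3); pz <- rep(FALSE, 3)
  expect_equal(composite_decide(oz, b), b)    # Composite(OZ, m) = m
  expect_equal(composite_decide(pz, b), pz)   # Composite(PZ, m) = PZ
  expect_equal(composite_decide(list(a, b, oz)), a & b)
})

test_that("coverage is monotone in the threshold for score-based methods", {
  d <- suite_sample("elimination", 60, seed = 30)
  fit <- reaction_descriptors(d)
  te <- suite_sample("elimination", 30, seed = 31, truth = attr(d, "truth"))
  xt <- predict(fit, te)$x
  cov_curve <- function(scores, thrs, inlier_if) {
    vapply(thrs, function(t) mean(switch(inlier_if,
                                         le = scores <= t, gt = scores > t)),
           numeric(1))
  }
  for (m in c("leverage", "z1nn")) {
    ad <- ad_fit(m, fit$x)
    sc <- predict(ad, xt, type = "score")
    cc <- cov_curve(sc, sort(unique(sc)), "le")
    expect_true(all(diff(cc) >= 0))
  }
  set.seed(2)
  ad <- ad_fit("rfr_var", fit$x, fit$y, ntree = 100)
  sc <- predict(ad, xt, type = "score")
  expect_true(all(diff(cov_curve(sc, sort(unique(sc)), "le")) >= 0))
  flags <- twoclass_label(fit$y - mean(fit$y), sd(fit$y))
  if (sum(flags) >= 2) {
    ad2 <- ad_fit("2cc", fit$x, flags = flags, ntree = 100)
    sc2 <- predict(ad2, xt, type = "score")
    expect_true(all(diff(cov_curve(sc2, sort(unique(sc2)), "gt")) <= 0))
  }
})

test_that("BB, FC and RTC classify every training reaction as an inlier", {
  d <- suite_sample("cycloaddition", 30, seed = 33)
  fit <- reaction_descriptors(d)
  expect_true(all(predict(ad_fit("bb", fit$x), fit$x)))
  expect_true(all(fragment_control_decide(predict(fit, d)$unseen)))
  rtc <- ad_fit("rtc", reactions = d$reaction, radius = 1)
  expect_true(all(predict(rtc, d$reaction)))
})
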