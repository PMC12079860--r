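test_that("the ASAP formula evaluates exactly", {
  # all non-intercept terms vanish: age 0, female, AFP 1, PIVKA 1
  expect_identical(asap_score(0, 0, 1, 1), -6.836)
  # male adds exactly 0.989 (up to floating-point rounding of the sum)
  expect_equal(asap_score(0, 1, 1, 1) - asap_score(0, 0, 1, 1), 0.989,
               tolerance = 1e-12)
  # hand evaluation: -6.836 + 0.042*65 + 0.989 + 1.841*1 + 0.949*2
  expect_equal(asap_score(65, 1, 10, 100), 0.622, tolerance = 1e-12)
  # strictly increasing in age, AFP, PIVKA
  expect_gt(asap_score(66, 1, 10, 100), asap_score(65, 1, 10, 100))
  expect_gt(asap_score(65, 1, 11, 100), asap_score(65, 1, 10, 100))
  expect_gt(asap_score(65, 1, 10, 101), asap_score(65, 1, 10, 100))
  # zero biomarkers are floored before the log
  expect_true(is.finite(asap_score(65, 1, 0, 0)))
  expect_error(asap_score(65, 2, 10, 100), "sex")
})

test_that("detection-limit clipping clamps to the assay range", {
  co <- tibble::tibble(afp = c(3000, 0.1, 12), pivka = c(1, 80000, 500))
  cl <- clip_to_detection_limits(co)
  expect_equal(cl$afp, c(2000, 0.5, 12))
  expect_equal(cl$pivka, c(5, 75000, 500))
})

test_that("logistic fits recover signal and backward elimination drops noise", {
  set.seed(31)
  n <- 120
  latent <- rnorm(n)
  dat <- tibble::tibble(
    group = ifelse(stats::plogis(1.5 * latent) > runif(n), "HCC", "ctrl"),
    signal = latent,
    noise = rnorm(n)
  )
  fit <- fit_combined(dat, "group", c("signal", "noise"), case = "HCC")
  td <- tidy(fit)
  expect_gt(td$estimate[td$term == "signal"], 0)
  g <- glance(fit)
  expect_gt(g$auc, 0.75)
  expect_equal(g$aic, stats::AIC(fit$fit), tolerance = 1e-9)
  expect_equal(sort(fit$features), c("noise", "signal"))  # enter keeps all

  # pure-noise feature is eliminated in ~95% of cohorts at the 0.05 rule
  kept_noise <- replicate(60, {
    lat <- rnorm(n)
    d <- tibble::tibble(
      group = ifelse(stats::plogis(1.5 * lat) > runif(n), "HCC", "ctrl"),
      signal = lat, noise = rnorm(n)
    )
    bw <- fit_combined(d, "group", c("signal", "noise"), case = "HCC",
                       method = "backward")
    "noise" %in% bw$features
  })
  expect_lt(mean(kept_noise), 0.15)

  # enter and backward agree when every feature is informative
  strong <- tibble::tibble(
    group = rep(c("HCC", "ctrl"), each = 60),
    f1 = c(rnorm(60, 2), rnorm(60)),
    f2 = c(rnorm(60, 2), rnorm(60))
  )
  en <- fit_combined(strong, "group", c("f1", "f2"), case = "HCC")
  bw <- fit_combined(strong, "group", c("f1", "f2"), case = "HCC",
                     method = "backward")
  expect_setequal(en$features, bw$features)

  # perfect separation is flagged, not an error
  sep <- tibble::tibble(group = rep(c("HCC", "ctrl"), each = 15),
                        f = c(rnorm(15, 10), rnorm(15, -10)))
  fs <- suppressWarnings(fit_combined(sep, "group", "f", case = "HCC"))
  expect_true(fs$separation)
})

test_that("fixed-specificity evaluation matches brute-force enumeration", {
  scores <- c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2)
  labels <- rep(c("HCC", "cirr"), each = 3)
  ev <- evaluate_classifier(scores, labels, "HCC", "cirr",
                            fixed_specificity = 2 / 3)
  # brute force: try every candidate threshold, keep the smallest whose
  # specificity reaches the target, then read off sensitivity
  cand <- sort(unique(scores))
  spec <- vapply(cand, function(t) mean(scores[4:6] <= t), numeric(1))
  sens <- vapply(cand, function(t) mean(scores[1:3] > t), numeric(1))
  i <- min(which(spec >= 2 / 3))
  expect_equal(ev$threshold, cand[i])
  expect_equal(ev$sensitivity, sens[i])
  expect_gte(ev$specificity, 2 / 3)
  # rank AUC against pROC as an independent implementation
  proc_auc <- as.numeric(pROC::auc(pROC::roc(labels, scores,
                                             levels = c("cirr", "HCC"),
                                             direction = "<", quiet = TRUE)))
  expect_equal(ev$auc, proc_auc, tolerance = 1e-12)

  # perfectly separated scores
  ps <- evaluate_classifier(c(5, 6, 7, 1, 2, 3), labels, "HCC", "cirr",
                            fixed_specificity = 0.9)
  expect_equal(ps$auc, 1)
  expect_equal(ps$sensitivity, 1)

  # training evaluation always achieves at least the requested specificity
  set.seed(17)
  for (i in 1:25) {
    sc <- rnorm(40)
    lb <- sample(rep(c("a", "b"), 20))
    s <- runif(1, 0.5, 0.95)
    e <- evaluate_classifier(sc, lb, "a", "b", fixed_specificity = s)
    expect_gte(e$specificity, s)
  }

  # a carried-over threshold is used unchanged on validation data
  ev2 <- evaluate_classifier(scores + 10, labels, "HCC", "cirr",
                             fixed_specificity = 2 / 3, threshold = ev$threshold)
  expect_equal(ev2$threshold, ev$threshold)
  expect_equal(ev2$sensitivity, 1)  # everything sits above the old threshold
  expect_equal(ev2$specificity, 0)  # specificity drifts on shifted data

  expect_error(evaluate_classifier(1:5, rep("a", 5), "a", "b"), "class")
})

test_that("the paired AUC comparison is rank-invariant and calibrated", {
  set.seed(23)
  labels <- rep(c("a", "b"), each = 30)
  sc <- c(rnorm(30, 1), rnorm(30))
  self <- compare_auc(sc, sc, labels, "a", "b")
  expect_equal(self$p_value, 1)
  expect_equal(self$delta, 0)
  mono <- compare_auc(sc, exp(sc), labels, "a", "b")
  expect_equal(mono$p_value, 1)
  expect_equal(mono$delta, 0)

  # type-I error near 0.05 under equal true AUC
  rejections <- replicate(200, {
    lb <- rep(c("a", "b"), each = 30)
    s1 <- c(rnorm(30, 0.8), rnorm(30))
    s2 <- c(rnorm(30, 0.8), rnorm(30))
    compare_auc(s1, s2, lb, "a", "b")$p_value < 0.05
  })
  expect_lt(mean(rejections), 0.12)
  expect_gt(mean(rejections), 0.005)
})
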