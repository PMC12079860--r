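dmr_score_tbl <- function(scores_case, scores_ctrl, dmr_id = "d1") {
  tibble::tibble(
    dmr_id = dmr_id,
    sample = c(paste0("case_", seq_along(scores_case)),
               paste0("ctrl_", seq_along(scores_ctrl))),
    score = c(scores_case, scores_ctrl),
    group = rep(c("case", "ctrl"), c(length(scores_case), length(scores_ctrl)))
  )
}

test_that("Youden threshold lands in the separating gap of the worked case", {
  # cases {10, 8}, controls {3, 5}: every enumerated cut with J = 1 lies in
  # (5, 8]; tie-break toward the larger threshold
  th <- fit_dmr_thresholds(dmr_score_tbl(c(10, 8), c(3, 5)), "case", "ctrl")
  expect_gt(th$threshold, 5)
  expect_lte(th$threshold, 8)
  expect_equal(th$auc, 1)
  # J at the fitted threshold is 1 (computed independently)
  expect_equal(mean(c(10, 8) > th$threshold) + mean(c(3, 5) <= th$threshold) - 1, 1)

  # perfectly separated larger sample
  th2 <- fit_dmr_thresholds(dmr_score_tbl(11:20, 1:10), "case", "ctrl")
  expect_equal(th2$auc, 1)
  expect_gt(th2$threshold, 10)
  expect_lte(th2$threshold, 11)
})

test_that("labels independent of scores give AUC near 0.5 on average", {
  set.seed(99)
  aucs <- replicate(200, {
    sc <- rnorm(20)
    fit_dmr_thresholds(dmr_score_tbl(sc[1:10], sc[11:20]), "case", "ctrl")$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.04)  # SE ~ 0.0075
})

test_that("constant scores drop the DMR with a warning", {
  tbl <- dplyr::bind_rows(dmr_score_tbl(c(1, 1), c(1, 1), "flat"),
                          dmr_score_tbl(c(9, 8), c(1, 2), "ok"))
  expect_warning(th <- fit_dmr_thresholds(tbl, "case", "ctrl"), "flat")
  expect_equal(th$dmr_id, "ok")
})

test_that("cumulative scores count orientation-adjusted threshold crossings", {
  thr <- tibble::tibble(dmr_id = c("a", "b", "c"),
                        threshold = c(5, 5, 5),
                        orientation = c("above", "above", "below"))
  sc <- tibble::tibble(
    dmr_id = rep(c("a", "b", "c"), times = 3),
    sample = rep(c("s1", "s2", "s3"), each = 3),
    score = c(10, 10, 1,   1, 1, 10,   5, 5, 5)
  )
  ms <- score_samples(sc, thr)
  expect_equal(ms$score[ms$sample == "s1"], 3L)  # above, above, below: all hit
  expect_equal(ms$score[ms$sample == "s2"], 0L)
  expect_equal(ms$score[ms$sample == "s3"], 0L)  # exactly at threshold: negative
  expect_true(all(ms$score >= 0 & ms$score <= unique(ms$n_dmrs)))

  # monotone: raising one hyper-DMR score never lowers the sample's score
  sc_up <- dplyr::mutate(sc, score = ifelse(sample == "s2" & dmr_id == "a",
                                            100, score))
  ms_up <- score_samples(sc_up, thr)
  expect_gte(ms_up$score[ms_up$sample == "s2"], ms$score[ms$sample == "s2"])

  # missing DMR scores contribute zero, with a message
  expect_message(ms_miss <- score_samples(sc[-1, ], thr), "missing")
  expect_equal(ms_miss$score[ms_miss$sample == "s1"], 2L)
})

test_that("score comparison flags planted signatures and matches hand BH", {
  set.seed(5)
  # five signatures: one strongly planted, four null
  tbl <- purrr::map_dfr(1:5, function(i) {
    case <- if (i == 1) rep(8L, 10) else rpois(10, 2)
    ctrl <- if (i == 1) rep(0L, 10) else rpois(10, 2)
    tibble::tibble(signature = paste0("sig", i),
                   sample = c(paste0("c", 1:10), paste0("k", 1:10)),
                   group = rep(c("case", "ctrl"), each = 10),
                   score = c(case, ctrl))
  })
  cmp <- compare_scores(tbl, "case", "ctrl")
  expect_true(cmp$significant[cmp$signature == "sig1"])
  expect_true(cmp$capped[cmp$signature == "sig1"])  # control mean 0 -> capped
  expect_equal(cmp$fold_change[cmp$signature == "sig1"], 1e6)

  # BH step against an independent hand computation on the same p-values
  p <- cmp$p_value
  n <- length(p)
  o <- order(p)
  hand <- numeric(n)
  hand[o] <- rev(cummin(rev(p[o] * n / seq_len(n))))
  hand <- pmin(hand, 1)
  expect_equal(cmp$q_value, hand, tolerance = 1e-12)

  # identical groups: nothing flagged
  null_tbl <- dplyr::mutate(tbl, score = rep(rpois(10, 3), 10))
  cmp0 <- compare_scores(null_tbl, "case", "ctrl")
  expect_false(any(cmp0$significant))

  # all-zero scores in both groups: undefined fold, flagged
  zero <- dmr_score_tbl(rep(0, 5), rep(0, 5)) |>
    dplyr::mutate(signature = "z") |> dplyr::select(-dmr_id)
  cz <- compare_scores(zero, "case", "ctrl")
  expect_true(is.na(cz$fold_change))
  expect_true(cz$capped)
})

test_that("tissue-trained thresholds applied to held-out data do not refit", {
  # fit on training, apply to a shifted cohort: thresholds stay identical
  th <- fit_dmr_thresholds(dmr_score_tbl(c(10, 9, 8), c(1, 2, 3)), "case", "ctrl")
  held_out <- tibble::tibble(dmr_id = "d1",
                             sample = c("h1", "h2"),
                             score = c(100, -100))
  ms <- score_samples(held_out, th)
  expect_equal(ms$score[ms$sample == "h1"], 1L)
  expect_equal(ms$score[ms$sample == "h2"], 0L)
})
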