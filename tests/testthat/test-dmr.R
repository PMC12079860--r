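test_that("the per-site statistic matches an independent 2x2 chi-square oracle", {
  # textbook-style table [[30, 9970], [10, 9990]]
  res <- per_site_test(counts_for_table(30L, 9970L, 10L, 9990L),
                       case = "case", control = "ctrl")
  oracle <- stats::chisq.test(matrix(c(30, 9970, 10, 9990), 2, byrow = TRUE),
                              correct = FALSE)
  s1 <- res[res$pos == 100, ]
  expect_equal(s1$statistic, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(s1$p_value, oracle$p.value, tolerance = 1e-12)
  expect_equal(s1$direction, "hyper")  # 30/10000 > 10/10000

  # 1000 random tables, relative error below 1e-9
  set.seed(404)
  worst <- 0
  for (i in 1:1000) {
    tab <- matrix(rpois(4, lambda = sample(c(5, 50, 500, 5000), 4, TRUE)) + 1L, 2)
    mine <- per_site_test(counts_for_table(tab[1, 1], tab[1, 2],
                                           tab[2, 1], tab[2, 2]),
                          case = "case", control = "ctrl")
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    rel <- abs(mine$statistic[mine$pos == 100] - unname(ref$statistic)) /
      max(unname(ref$statistic), 1e-300)
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-9)
})

test_that("per-site test handles nulls, zeros and label swaps correctly", {
  # identical pooled proportions -> statistic 0, p = 1
  eq <- per_site_test(counts_for_table(50L, 950L, 100L, 1900L),
                      case = "case", control = "ctrl")
  expect_equal(eq$statistic, c(0, 0), tolerance = 1e-12)
  expect_equal(eq$p_value, c(1, 1), tolerance = 1e-12)
  expect_true(all(is.na(eq$direction)))

  # zero coverage at a site
  z <- per_site_test(counts_for_table(0L, 100L, 0L, 100L),
                     case = "case", control = "ctrl")
  expect_equal(z$p_value[z$pos == 100], 1)
  expect_true(is.na(z$direction[z$pos == 100]))

  # swapping labels flips direction, preserves p
  fwd <- per_site_test(counts_for_table(30L, 70L, 10L, 90L),
                       case = "case", control = "ctrl")
  rev <- per_site_test(counts_for_table(30L, 70L, 10L, 90L),
                       case = "ctrl", control = "case")
  expect_equal(fwd$p_value, rev$p_value, tolerance = 1e-12)
  expect_equal(fwd$direction[fwd$pos == 100], "hyper")
  expect_equal(rev$direction[rev$pos == 100], "hypo")
})

test_that("binning traces the run rule: gaps and direction changes split DMRs", {
  base_p <- 1e-12  # far below any Bonferroni cut used here
  pos <- c(100, 300, 500, 700, 900,   5000, 5200, 5400)
  tests <- make_site_tests(pos, base_p, "hyper")
  dmrs <- call_dmrs(tests, max_gap = 1000, min_sites = 3, min_size = 0,
                    min_fold = 1)
  expect_equal(nrow(dmrs), 2)
  expect_equal(dmrs$n_sites, c(5L, 3L))
  expect_equal(dmrs$start, c(100L, 5000L))
  expect_equal(dmrs$end, c(901L, 5401L))

  # a significant hypo site inside a hyper run splits it
  tests2 <- make_site_tests(c(100, 300, 500, 700, 900),
                            base_p, c("hyper", "hyper", "hypo", "hyper", "hyper"))
  dmrs2 <- call_dmrs(tests2, max_gap = 1000, min_sites = 2, min_size = 0,
                     min_fold = 1)
  expect_equal(nrow(dmrs2), 2)
  expect_true(all(dmrs2$direction == "hyper"))
  expect_equal(dmrs2$n_sites, c(2L, 2L))

  # non-significant sites do not join a run
  tests3 <- make_site_tests(c(100, 300, 500), c(base_p, 0.5, base_p), "hyper")
  dmrs3 <- call_dmrs(tests3, max_gap = 1000, min_sites = 2, min_size = 0,
                     min_fold = 1)
  expect_equal(nrow(dmrs3), 1)
  expect_equal(dmrs3$n_sites, 2L)

  # empty input
  expect_equal(nrow(call_dmrs(tests[0, ])), 0)
  # no significant sites
  expect_equal(nrow(call_dmrs(make_site_tests(pos, 0.5, "hyper"))), 0)
})

test_that("threshold filters are monotone and the Bonferroni cut is p < alpha/n", {
  base <- make_site_tests(seq(100, 2000, by = 100), 1e-12, "hyper",
                          case_count = 2000, control_count = 500)
  # fold = (2000/1e6)/(500/1e6) = 4 per bin
  d0 <- call_dmrs(base, min_sites = 1, min_size = 0, min_fold = 1)
  expect_equal(d0$fold_change, 4)

  grid <- expand.grid(min_sites = c(1, 5, 50), min_size = c(0, 500, 1e5),
                      min_fold = c(1, 2, 8))
  n_prev <- Inf
  for (i in order(grid$min_sites + grid$min_size / 1e5 + grid$min_fold)) {
    n_i <- nrow(call_dmrs(base, min_sites = grid$min_sites[i],
                          min_size = grid$min_size[i],
                          min_fold = grid$min_fold[i]))
    expect_lte(n_i, nrow(d0))
  }
  expect_equal(nrow(call_dmrs(base, min_fold = 5)), 0)  # fold 4 < 5
  expect_equal(nrow(call_dmrs(base, min_sites = 21)), 0)

  # significance boundary: p must be strictly below alpha / n_tests
  n <- 20
  at_cut <- make_site_tests(seq(100, 2000, by = 100), 0.05 / n, "hyper")
  expect_equal(nrow(call_dmrs(at_cut, min_sites = 1, min_size = 0, min_fold = 1)), 0)
  below <- make_site_tests(seq(100, 2000, by = 100), 0.05 / n * 0.999, "hyper")
  expect_gt(nrow(call_dmrs(below, min_sites = 1, min_size = 0, min_fold = 1)), 0)

  # hypo DMRs must pass 1/min_fold
  hypo <- make_site_tests(seq(100, 500, by = 100), 1e-12, "hypo",
                          case_count = 100, control_count = 500)
  dh <- call_dmrs(hypo, min_sites = 1, min_size = 0, min_fold = 2)
  expect_equal(nrow(dh), 1)
  expect_equal(dh$fold_change, 0.2)
  expect_equal(dh$direction, "hypo")
})

test_that("DMR annotation reports every overlapped class, else intergenic", {
  reg <- suppressMessages(define_regions(toy_annotation()))
  dmrs <- tibble::tibble(
    chrom = "chr1",
    start = c(4600L, 4100L, 12000L),
    end = c(4800L, 4300L, 12100L),
    n_sites = 4L, fold_change = 3, direction = "hyper", min_p_adj = 1e-8
  )
  ann <- annotate_dmrs(dmrs, reg)
  expect_setequal(ann$classes[[1]], c("TSS", "cpg_island"))  # inside both
  expect_equal(ann$classes[[2]], "TSS")                      # before the island
  expect_equal(ann$classes[[3]], "intergenic")
  tall <- dmr_class_counts(ann)
  expect_equal(tall$n[tall$class == "TSS"], 2L)
  expect_equal(tall$n[tall$class == "cpg_island"], 1L)
  expect_equal(tall$n[tall$class == "intergenic"], 1L)
})

test_that("sex-chromosome removal filters exactly the listed chromosomes", {
  x <- tibble::tibble(chrom = c("chr1", "chrX", "chrY", "chr2"), pos = 1:4)
  out <- remove_sex_chromosomes(x)
  expect_equal(out$chrom, c("chr1", "chr2"))
  expect_identical(remove_sex_chromosomes(x[x$chrom == "chr1", ])$chrom, "chr1")
  expect_equal(nrow(remove_sex_chromosomes(x[0, ])), 0)
})
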