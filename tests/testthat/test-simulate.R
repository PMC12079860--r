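test_that("generated annotation counts follow the requested densities", {
  gn <- generate_genome(n_chroms = 1, chrom_length = 1e5,
                        gene_density = 50, island_density = 10, seed = 1)
  # Poisson means: 5 genes, 1 island on 100 kb
  expect_true(abs(nrow(gn$genes) - 5) <= 3 * sqrt(5))
  expect_true(abs(nrow(gn$cpg_islands) - 1) <= 3 * sqrt(1) + 1)
  expect_gt(nrow(gn$sites), 0)
  # structural invariants
  expect_true(all(gn$sites$pos >= 0 & gn$sites$pos < 1e5))
  expect_true(!is.unsorted(gn$sites$pos))
  expect_true(all(ifelse(gn$genes$strand == "+",
                         gn$genes$tss < gn$genes$tes,
                         gn$genes$tss > gn$genes$tes)))
  isl <- gn$cpg_islands
  if (nrow(isl) > 1) {
    expect_true(all(isl$start[-1] >= isl$end[-nrow(isl)]))
  }
})

test_that("degenerate genome requests error out", {
  expect_error(generate_genome(chrom_length = 1e4, gene_density = 0, seed = 1),
               class = "medseqr_no_gene_error")
  expect_error(generate_genome(chrom_length = 5e3, seed = 1))
})

test_that("the generator is deterministic for a fixed seed", {
  a <- generate_genome(chrom_length = 5e4, seed = 7)
  b <- generate_genome(chrom_length = 5e4, seed = 7)
  expect_identical(a, b)
  d <- simulation_design(n_per_group = 3, seed = 11)
  gn <- a
  expect_identical(simulate_site_counts(gn, d), simulate_site_counts(gn, d))
  dct <- tibble::tibble(group = "g", marker = "m", delta_ct = 3)
  expect_identical(simulate_qmsp(dct, n_per_group = 4, seed = 5),
                   simulate_qmsp(dct, n_per_group = 4, seed = 5))
  expect_identical(simulate_cohort(c(HCC = 4, cirrhosis = 4), seed = 9),
                   simulate_cohort(c(HCC = 4, cirrhosis = 4), seed = 9))
})

test_that("null designs give matched group means and planted DMRs the planted fold", {
  gn <- generate_genome(chrom_length = 2e5, seed = 2)
  null_d <- simulation_design(n_per_group = 10, mean_depth = 50, seed = 3)
  cnt <- simulate_site_counts(gn, null_d)
  grp_rpm <- cnt |>
    dplyr::left_join(library_sizes(cnt), by = c("sample", "group")) |>
    dplyr::group_by(chrom, pos, group) |>
    dplyr::summarise(rpm = mean(1e6 * count / library_size), .groups = "drop") |>
    tidyr::pivot_wider(names_from = group, values_from = rpm)
  # mean relative difference across sites ~ 0 under the null
  rel <- (grp_rpm$tumor - grp_rpm$control) / (grp_rpm$tumor + grp_rpm$control + 1)
  expect_lt(abs(mean(rel)), 0.01)

  pd <- plant_dmrs(gn, n = 1, width = 1000, fold_change = 4, seed = 4)
  d <- simulation_design(n_per_group = 10, planted_dmrs = pd,
                         mean_depth = 50, seed = 5)
  cnt2 <- simulate_site_counts(gn, d)
  inside <- cnt2 |>
    dplyr::filter(pos >= pd$start, pos < pd$end) |>
    dplyr::group_by(group) |>
    dplyr::summarise(m = mean(count), .groups = "drop")
  ratio <- inside$m[inside$group == "tumor"] / inside$m[inside$group == "control"]
  expect_true(abs(ratio - 4) / 4 < 0.2)

  # fold 1 "planting" is a no-op
  pd1 <- dplyr::mutate(pd, fold_change = 1)
  d1 <- simulation_design(n_per_group = 10, planted_dmrs = pd1,
                          mean_depth = 50, seed = 5)
  cnt3 <- simulate_site_counts(gn, d1)
  inside3 <- cnt3 |>
    dplyr::filter(pos >= pd$start, pos < pd$end) |>
    dplyr::group_by(group) |>
    dplyr::summarise(m = mean(count), .groups = "drop")
  ratio3 <- inside3$m[inside3$group == "tumor"] / inside3$m[inside3$group == "control"]
  expect_true(abs(ratio3 - 1) < 0.2)
})

test_that("an unplantable DMR warns and is skipped", {
  gn <- generate_genome(chrom_length = 5e4, seed = 2)
  # interval past the last site but within bounds is free of sites
  gap_start <- max(gn$sites$pos) + 1L
  pd <- tibble::tibble(chrom = "chr1", start = gap_start, end = gap_start + 10L,
                       direction = "hyper", fold_change = 4)
  d <- simulation_design(n_per_group = 2, planted_dmrs = pd, seed = 3)
  expect_warning(simulate_site_counts(gn, d), "no LpnPI site")
})

test_that("cfDNA mixture means are the convex combination of the profiles", {
  gn <- generate_genome(chrom_length = 1e5, seed = 6)
  pd <- plant_dmrs(gn, n = 1, width = 1000, fold_change = 4, seed = 7)
  d <- simulation_design(n_per_group = 5, planted_dmrs = pd, seed = 8)
  tp <- site_mean_profile(gn, d, "tumor")
  bp <- site_mean_profile(gn, d, "control")

  # closed-form: fold 4 at fraction 0.02 dilutes to 1.06
  in_dmr <- tp$pos >= pd$start & tp$pos < pd$end
  expect_equal(tp$mean[in_dmr] / bp$mean[in_dmr], rep(4, sum(in_dmr)))
  mix <- 0.02 * tp$mean + 0.98 * bp$mean
  expect_equal(mix[in_dmr] / bp$mean[in_dmr], rep(1.06, sum(in_dmr)))

  # boundary fractions reproduce the pure profiles in expectation
  for (f in c(0, 1)) {
    cf <- simulate_cfdna_counts(tp, bp, tumor_fraction = f, n_per_group = 40,
                                dispersion = 0.1, seed = 9)
    target <- if (f == 1) tp$mean else bp$mean
    obs <- cf |>
      dplyr::filter(group == "tumor") |>
      dplyr::group_by(chrom, pos) |>
      dplyr::summarise(m = mean(count), .groups = "drop")
    expect_lt(abs(mean(obs$m - target)), 0.2)
    expect_gt(stats::cor(obs$m, target), 0.9)
  }

  # intermediate fraction: observed means track the mixture genome-wide
  cf <- simulate_cfdna_counts(tp, bp, tumor_fraction = 0.3, n_per_group = 60,
                              dispersion = 0.1, seed = 10)
  obs <- cf |>
    dplyr::filter(group == "tumor") |>
    dplyr::group_by(chrom, pos) |>
    dplyr::summarise(m = mean(count), .groups = "drop")
  mix30 <- 0.3 * tp$mean + 0.7 * bp$mean
  expect_lt(max(abs(obs$m[in_dmr] - mix30[in_dmr])) /
              mean(mix30[in_dmr]), 0.25)

  expect_error(simulate_cfdna_counts(tp[-1, ], bp, 0.5),
               class = "medseqr_index_mismatch")
})

test_that("qMSP simulation reproduces the delta-Ct arithmetic", {
  dct <- tibble::tibble(group = c("a", "b"), marker = "m", delta_ct = c(3, 5))
  noiseless <- simulate_qmsp(dct, sd = 0, n_per_group = 10, seed = 1)
  lv <- qmsp_levels(noiseless)
  expect_equal(unique(lv$level[lv$group == "a"]), 2^-3)
  expect_equal(unique(lv$level[lv$group == "b"]), 2^-5)

  noisy <- qmsp_levels(simulate_qmsp(dct, sd = 0.5, n_per_group = 100, seed = 2))
  med <- tapply(noisy$level, noisy$group, median)
  expect_true(abs(med[["a"]] / med[["b"]] - 4) < 1)
})

test_that("cohort simulation orders group medians and respects bounds", {
  co <- simulate_cohort(c(HCC = 200, cirrhosis = 200), seed = 3)
  med <- co |>
    dplyr::group_by(group) |>
    dplyr::summarise(afp = median(afp), pivka = median(pivka))
  expect_gt(med$afp[med$group == "HCC"], med$afp[med$group == "cirrhosis"])
  expect_gt(med$pivka[med$group == "HCC"], med$pivka[med$group == "cirrhosis"])
  expect_true(all(co$afp >= 0.5 & co$afp <= 2000))
  expect_true(all(co$pivka >= 5 & co$pivka <= 75000))

  all_male <- simulate_cohort(c(HCC = 20), male_fraction = 1, seed = 4)
  expect_true(all(all_male$sex == 1))
  empty <- simulate_cohort(c(HCC = 0), seed = 5)
  expect_equal(nrow(empty), 0)
})
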