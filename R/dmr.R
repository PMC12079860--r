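#' Per-site two-group chi-square test
#'
#' Pools raw counts within each group at every LpnPI site and tests the
#' 2x2 table \[site reads vs all-other reads\] x \[case vs control\] with the
#' chi-square statistic (no continuity correction). Using library-size
#' totals as the complement row is the coverage normalization a 2x2 test
#' admits: the chi-square needs counts, while RPM values determine direction
#' and fold change. Sites with zero pooled reads in both groups get p = 1
#' and no direction.
#'
#' @param counts Long count tibble (chrom, pos, sample, group, count)
#'   containing both groups.
#' @param case,control Group labels (defaults: first and second label found).
#' @return Tibble of class `medseq_site_tests`, sorted by coordinate:
#'   chrom, pos, case_count, control_count (pooled), case_rpm, control_rpm,
#'   statistic, p_value, direction ("hyper"/"hypo" relative to the case
#'   group, NA when means are equal).
#' @examples
#' gn <- generate_genome(chrom_length = 2e4, seed = 1)
#' cnt <- simulate_site_counts(gn, simulation_design(n_per_group = 4, seed = 2))
#' head(per_site_test(cnt, "tumor", "control"))
#' @export
per_site_test <- function(counts, case = NULL, control = NULL) {
  assert_columns(counts, c("chrom", "pos", "sample", "group", "count"), "counts")
  groups <- unique(counts$group)
  case <- case %||% groups[1]
  control <- control %||% setdiff(groups, case)[1]
  if (!all(c(case, control) %in% groups)) {
    stop_medseqr("case/control labels not found in `counts$group`.")
  }

  dat <- counts[counts$group %in% c(case, control), ]
  pooled <- dat |>
    distinct(.data$chrom, .data$pos) |>
    arrange(.data$chrom, .data$pos)
  ridx <- vctrs::vec_match(dat[c("chrom", "pos")], pooled[c("chrom", "pos")])
  pool_one <- function(sel) {
    out <- numeric(nrow(pooled))
    agg <- rowsum(as.numeric(dat$count[sel]), ridx[sel])
    out[as.integer(rownames(agg))] <- agg[, 1]
    out
  }
  pooled$case_count <- pool_one(dat$group == case)
  pooled$control_count <- pool_one(dat$group == control)

  n_case <- sum(pooled$case_count)
  n_control <- sum(pooled$control_count)
  if (n_case == 0 || n_control == 0) {
    stop_medseqr("a group has zero total reads; cannot test.")
  }

  a <- as.numeric(pooled$case_count)
  c_ <- as.numeric(pooled$control_count)
  b <- n_case - a
  d <- n_control - c_
  n <- n_case + n_control
  denom <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  stat <- ifelse(denom > 0, n * (a * d - b * c_)^2 / denom, 0)
  stat[(a + c_) == 0] <- 0
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  p[(a + c_) == 0] <- 1

  case_rpm <- 1e6 * a / n_case
  control_rpm <- 1e6 * c_ / n_control
  direction <- dplyr::case_when(
    case_rpm > control_rpm ~ "hyper",
    case_rpm < control_rpm ~ "hypo",
    TRUE ~ NA_character_
  )

  out <- pooled |>
    mutate(
      case_rpm = case_rpm, control_rpm = control_rpm,
      statistic = stat, p_value = p, direction = direction
    )
  attr(out, "group_totals") <- c(case = n_case, control = n_control)
  attr(out, "labels") <- c(case = case, control = control)
  class(out) <- c("medseq_site_tests", class(out))
  out
}

#' Call DMRs by binning runs of Bonferroni-significant sites
#'
#' A site is significant iff its chi-square p-value is below
#' `alpha / n_tests` (Bonferroni over the testable sites). Neighboring
#' significant sites with the same direction are binned into one candidate
#' DMR as long as consecutive sites are at most `max_gap` bp apart; a
#' direction change or a larger gap starts a new bin. Candidate DMRs are
#' then filtered on site count, genomic size and fold change of summed RPM
#' (hyper DMRs must reach `min_fold`, hypo DMRs `1/min_fold`).
#'
#' @param tests A [per_site_test()] result (sorted by position).
#' @param alpha Family-wise significance level before correction.
#' @param n_tests Bonferroni denominator; defaults to the number of testable
#'   sites (pooled coverage > 0) in `tests`, after any upstream filtering
#'   such as [remove_sex_chromosomes()].
#' @param max_gap Maximum distance in bp between consecutive binned sites.
#' @param min_sites,min_size,min_fold DMR retention thresholds: minimum
#'   number of binned sites, minimum span in bp, minimum fold change (applied
#'   as `max(fold, 1/fold) >= min_fold`).
#' @return Tibble of class `medseq_dmrs`: chrom, start, end (half-open;
#'   end = last site + 1), n_sites, fold_change (case/control ratio of summed
#'   RPM, capped at 1e6 when the control sum is zero), direction, min_p_adj
#'   (smallest Bonferroni-adjusted p in the bin).
#' @export
call_dmrs <- function(tests, alpha = 0.05, n_tests = NULL,
                      max_gap = 1000, min_sites = 4, min_size = 100,
                      min_fold = 2) {
  assert_columns(tests, c("chrom", "pos", "case_count", "control_count",
                          "p_value", "direction"), "tests")
  assert_scalar_number(alpha, "alpha", lower = 0, upper = 1)
  assert_scalar_number(max_gap, "max_gap", lower = 0)
  assert_scalar_number(min_sites, "min_sites", lower = 1)
  assert_scalar_number(min_size, "min_size", lower = 0)
  assert_scalar_number(min_fold, "min_fold", lower = 1)

  empty <- tibble(
    chrom = character(), start = integer(), end = integer(),
    n_sites = integer(), fold_change = numeric(), direction = character(),
    min_p_adj = numeric()
  )
  class(empty) <- c("medseq_dmrs", class(empty))
  if (nrow(tests) == 0L) return(empty)

  testable <- tests$case_count + tests$control_count > 0
  n_tests <- n_tests %||% sum(testable)
  if (n_tests < 1) return(empty)
  totals <- attr(tests, "group_totals") %||%
    c(case = sum(tests$case_count), control = sum(tests$control_count))

  sig <- tests |>
    filter(.data$p_value < alpha / n_tests, !is.na(.data$direction)) |>
    arrange(.data$chrom, .data$pos)
  if (nrow(sig) == 0L) return(empty)

  sig <- sig |>
    group_by(.data$chrom) |>
    mutate(
      new_bin = dplyr::coalesce(
        .data$pos - lag(.data$pos) > max_gap |
          .data$direction != lag(.data$direction),
        TRUE
      )
    ) |>
    ungroup() |>
    mutate(bin = cumsum(.data$new_bin))

  dmrs <- sig |>
    group_by(.data$bin) |>
    summarise(
      chrom = .data$chrom[1],
      start = as.integer(min(.data$pos)),
      end = as.integer(max(.data$pos) + 1L),
      n_sites = dplyr::n(),
      case_sum = sum(.data$case_count),
      control_sum = sum(.data$control_count),
      direction = .data$direction[1],
      min_p_adj = pmin(1, min(.data$p_value) * n_tests),
      .groups = "drop"
    ) |>
    mutate(
      fold_change = (.data$case_sum / totals[["case"]]) /
        (.data$control_sum / totals[["control"]]),
      fold_change = ifelse(is.finite(.data$fold_change),
                           .data$fold_change, 1e6)
    ) |>
    filter(
      .data$n_sites >= min_sites,
      .data$end - .data$start >= min_size,
      pmax(.data$fold_change, 1 / .data$fold_change) >= min_fold
    ) |>
    arrange(.data$chrom, .data$start) |>
    select("chrom", "start", "end", "n_sites", "fold_change",
           "direction", "min_p_adj")

  class(dmrs) <- c("medseq_dmrs", class(dmrs))
  dmrs
}

#' Annotate DMRs with overlapping region classes
#'
#' Labels each DMR with every region class it overlaps by at least 1 bp
#' (half-open interval intersection); DMRs overlapping nothing are labelled
#' "intergenic". A DMR overlapping a TSS window and a CpG island carries both
#' classes, so per-class tallies count it once per class.
#'
#' @param dmrs A [call_dmrs()] result.
#' @param regions A [define_regions()] result.
#' @return `dmrs` with a `classes` list-column and an `annotation` string
#'   column (","-joined classes).
#' @export
annotate_dmrs <- function(dmrs, regions) {
  assert_columns(dmrs, c("chrom", "start", "end"), "dmrs")
  assert_columns(regions, c("chrom", "start", "end", "class"), "regions")
  cls <- purrr::map(seq_len(nrow(dmrs)), function(i) {
    hit <- regions$chrom == dmrs$chrom[i] &
      regions$start < dmrs$end[i] & dmrs$start[i] < regions$end
    found <- sort(unique(regions$class[hit]))
    if (length(found) == 0L) "intergenic" else found
  })
  dmrs$classes <- cls
  dmrs$annotation <- vapply(cls, paste, character(1), collapse = ",")
  dmrs
}

#' Per-class DMR tallies
#'
#' @param annotated An [annotate_dmrs()] result.
#' @return Tibble (class, n): each DMR counted once per class it overlaps.
#' @export
dmr_class_counts <- function(annotated) {
  assert_columns(annotated, "classes", "annotated")
  tibble(class = unlist(annotated$classes)) |>
    count(.data$class, name = "n")
}

#' Drop entries on sex chromosomes
#'
#' Removes all rows mapped to the listed sex chromosomes, avoiding
#' sex-related methylation effects in DMR sets or site tables.
#'
#' @param x Any tibble with a `chrom` column (sites, tests, or DMRs).
#' @param sex_chroms Chromosome names to remove.
#' @return `x` without rows on `sex_chroms`; classes and attributes kept.
#' @export
remove_sex_chromosomes <- function(x, sex_chroms = c("chrX", "chrY", "X", "Y")) {
  assert_columns(x, "chrom", "x")
  keep <- !x$chrom %in% sex_chroms
  out <- x[keep, ]
  for (at in c("group_totals", "labels")) {
    if (!is.null(attr(x, at))) attr(out, at) <- attr(x, at)
  }
  out
}
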