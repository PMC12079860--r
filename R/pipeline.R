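#' Convert a DMR set to a region table
#'
#' Gives each DMR a stable identifier so it can be scored with
#' [score_regions()] and tracked as a marker.
#'
#' @param dmrs A [call_dmrs()] result.
#' @return Tibble (region_id, chrom, start, end, direction).
#' @export
dmrs_as_regions <- function(dmrs) {
  assert_columns(dmrs, c("chrom", "start", "end", "direction"), "dmrs")
  tibble(
    region_id = sprintf("dmr_%03d_%s_%d", seq_len(nrow(dmrs)),
                        dmrs$chrom, dmrs$start),
    chrom = dmrs$chrom, start = dmrs$start, end = dmrs$end,
    direction = dmrs$direction
  )
}

#' Tissue discovery phase: DMR calling and marker selection
#'
#' Runs the discovery arm end to end on a tissue count table: per-site
#' chi-square testing (sex chromosomes removed), Bonferroni-corrected DMR
#' calling, annotation against TSS/gene-body/CpG-island regions, per-DMR
#' ROC-threshold fitting on the training labels, and selection of the top-k
#' DMRs by training AUC as the marker panel.
#'
#' @param genome A [generate_genome()]-style annotation.
#' @param counts Long tissue count tibble with both groups.
#' @param case,control Group labels (case = tumor group).
#' @param top_k Number of markers to select (default 5); if fewer DMRs are
#'   available, all are returned with a warning.
#' @param alpha,max_gap,min_sites,min_size,min_fold Passed to [call_dmrs()].
#' @param sex_chroms Passed to [remove_sex_chromosomes()].
#' @return List of class `discovery_result`: `tests`, `dmrs` (annotated),
#'   `dmr_regions`, `dmr_scores`, `thresholds`, `top_markers` (dmr ids,
#'   ranked by training AUC).
#' @export
run_discovery <- function(genome, counts, case, control, top_k = 5,
                          alpha = 0.05, max_gap = 1000, min_sites = 4,
                          min_size = 100, min_fold = 2,
                          sex_chroms = c("chrX", "chrY", "X", "Y")) {
  tests <- per_site_test(counts, case, control)
  tests <- remove_sex_chromosomes(tests, sex_chroms)
  dmrs <- call_dmrs(tests, alpha = alpha, max_gap = max_gap,
                    min_sites = min_sites, min_size = min_size,
                    min_fold = min_fold)
  regions <- define_regions(genome)
  dmrs <- annotate_dmrs(dmrs, regions)
  inform(sprintf("discovery: %d testable sites -> %d DMRs.",
                 sum(tests$case_count + tests$control_count > 0), nrow(dmrs)))
  if (nrow(dmrs) == 0L) {
    out <- list(tests = tests, dmrs = dmrs, dmr_regions = NULL,
                dmr_scores = NULL, thresholds = NULL, top_markers = character())
    class(out) <- "discovery_result"
    return(out)
  }

  dmr_regions <- dmrs_as_regions(dmrs)
  dmr_scores <- score_regions(counts, dmr_regions)
  thresholds <- fit_dmr_thresholds(
    dmr_scores, case = case, control = control,
    directions = tibble(dmr_id = dmr_regions$region_id,
                        direction = dmr_regions$direction)
  )
  ranked <- arrange(thresholds, dplyr::desc(.data$auc))
  if (top_k > nrow(ranked)) {
    warn(sprintf("only %d DMR(s) available; returning all.", nrow(ranked)))
    top_k <- nrow(ranked)
  }
  out <- list(
    tests = tests, dmrs = dmrs, dmr_regions = dmr_regions,
    dmr_scores = dmr_scores, thresholds = thresholds,
    top_markers = ranked$dmr_id[seq_len(top_k)]
  )
  class(out) <- "discovery_result"
  out
}

#' @export
print.discovery_result <- function(x, ...) {
  cat(sprintf("<discovery_result> %d DMRs; %d marker(s) selected\n",
              nrow(x$dmrs), length(x$top_markers)))
  if (length(x$top_markers)) {
    cat("  top markers:", paste(x$top_markers, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Blood evaluation phase: combined classifiers on train/validation cohorts
#'
#' Fits four logistic models on the training cohort -- markers only
#' (`dmm_only`), ASAP score only (`asap_only`), ASAP plus all markers
#' (`asap_dmm`, enter method) and ASAP plus markers refined by backward
#' elimination (`asap_backward`) -- then applies the frozen models and their
#' training operating thresholds to the validation cohort. Validation labels
#' are used only in the final evaluation step.
#'
#' @param train,validation Cohort tibbles with columns sample, group, age,
#'   sex, afp, pivka and one column per marker.
#' @param markers Character vector of marker column names.
#' @param case,control Group labels.
#' @param fixed_specificity Operating specificity on the training controls.
#' @return List of class `blood_evaluation`: `models` (named `combined_fit`
#'   list) and `results`, a tibble (model, cohort, auc, sensitivity,
#'   specificity, threshold, aic).
#' @export
run_blood_evaluation <- function(train, validation, markers, case, control,
                                 fixed_specificity = 0.813) {
  assert_columns(train, c("sample", "group", "age", "sex", "afp", "pivka", markers),
                 "train")
  if (nrow(validation) == 0L) stop_medseqr("validation cohort is empty.")
  miss <- setdiff(markers, names(validation))
  if (length(miss) > 0L) {
    stop_medseqr(sprintf("marker(s) missing in validation: %s.",
                         paste(miss, collapse = ", ")))
  }
  assert_columns(validation, c("sample", "group", "age", "sex", "afp", "pivka"),
                 "validation")
  train <- add_asap_score(train)
  validation <- add_asap_score(validation)

  specs <- list(
    dmm_only = list(features = markers, method = "enter"),
    asap_only = list(features = "asap", method = "enter"),
    asap_dmm = list(features = c("asap", markers), method = "enter"),
    asap_backward = list(features = c("asap", markers), method = "backward")
  )
  models <- purrr::map(specs, function(s) {
    fit_combined(train, "group", s$features, case = case, method = s$method)
  })

  results <- purrr::imap_dfr(models, function(m, name) {
    tr_scores <- predict(m, train)
    ev_tr <- evaluate_classifier(tr_scores, train$group, case, control,
                                 fixed_specificity = fixed_specificity)
    va_scores <- predict(m, validation)
    ev_va <- evaluate_classifier(va_scores, validation$group, case, control,
                                 fixed_specificity = fixed_specificity,
                                 threshold = ev_tr$threshold)
    aic <- glance(m)$aic
    bind_rows(
      mutate(glance(ev_tr), model = name, cohort = "train", aic = aic),
      mutate(glance(ev_va), model = name, cohort = "validation", aic = aic)
    )
  }) |>
    select("model", "cohort", "auc", "sensitivity", "specificity",
           "threshold", "aic")

  structure(list(models = models, results = results,
                 fixed_specificity = fixed_specificity),
            class = "blood_evaluation")
}

#' @export
print.blood_evaluation <- function(x, ...) {
  cat(sprintf("<blood_evaluation> %d models at fixed specificity %.1f%%\n",
              length(x$models), 100 * x$fixed_specificity))
  print(x$results, n = Inf)
  invisible(x)
}

#' End-to-end demonstration: tissue discovery to blood evaluation
#'
#' Reproduces the study design on synthetic cohorts in one call: generates a
#' toy genome with planted hypermethylated DMRs, simulates a two-group
#' tissue cohort, runs DMR discovery and marker selection, then simulates
#' cfDNA cohorts across a ladder of tumor fractions, scores them with the
#' frozen tissue thresholds (the dilution curve), and evaluates combined
#' ASAP + marker classifiers on a train/validation pair of low-fraction
#' cfDNA cohorts.
#'
#' @param seed Integer seed driving every stochastic step.
#' @param n_planted Number of planted DMRs.
#' @param fold_change Planted tissue fold change.
#' @param tissue_n,cfdna_n Samples per group in the tissue and cfDNA cohorts.
#' @param tumor_fractions Dilution ladder.
#' @param eval_fraction Tumor fraction of the cohorts used for classifier
#'   evaluation.
#' @param mean_depth,dispersion Count-model parameters.
#' @return List of class `medseq_demo`: `genome`, `planted`, `discovery`,
#'   `dilution` (tibble tumor_fraction, auc), `evaluation`
#'   (a `blood_evaluation`), `seed`.
#' @export
run_demo <- function(seed = 1, n_planted = 8, fold_change = 4,
                     tissue_n = 20, cfdna_n = 250,
                     tumor_fractions = c(1, 0.25, 0.05, 0),
                     eval_fraction = 0.01,
                     mean_depth = 50, dispersion = 0.1) {
  genome <- generate_genome(n_chroms = 1, chrom_length = 1e6,
                            gene_density = 50, island_density = 10,
                            seed = seed)
  planted <- plant_dmrs(genome, n = n_planted, width = 1000,
                        fold_change = fold_change, seed = seed + 1)
  design <- simulation_design(
    n_per_group = tissue_n, group_labels = c("tumor", "control"),
    planted_dmrs = planted, mean_depth = mean_depth,
    dispersion = dispersion, seed = seed + 2
  )
  tissue <- simulate_site_counts(genome, design)
  discovery <- run_discovery(genome, tissue, "tumor", "control", top_k = 5)

  tumor_prof <- site_mean_profile(genome, design, "tumor")
  bg_prof <- site_mean_profile(genome, design, "control")
  marker_thresholds <- discovery$thresholds

  dilution <- purrr::imap_dfr(tumor_fractions, function(f, i) {
    cf <- simulate_cfdna_counts(tumor_prof, bg_prof, tumor_fraction = f,
                                n_per_group = cfdna_n, dispersion = dispersion,
                                seed = seed + 100 + i)
    sc <- score_regions(cf, discovery$dmr_regions)
    ms <- score_samples(sc, marker_thresholds)
    tibble(tumor_fraction = f,
           auc = rank_auc(ms$score, ms$group, "tumor"))
  })

  evaluation <- demo_blood_evaluation(genome, discovery, tumor_prof, bg_prof,
                                      eval_fraction, cfdna_n, dispersion, seed)

  structure(list(genome = genome, planted = planted, discovery = discovery,
                 dilution = dilution, evaluation = evaluation, seed = seed),
            class = "medseq_demo")
}

# Builds train/validation cfDNA cohorts at one tumor fraction, attaches
# simulated clinical covariates, and runs the combined-model evaluation on
# the selected markers' RPM scores.
demo_blood_evaluation <- function(genome, discovery, tumor_prof, bg_prof,
                                  fraction, n_per_group, dispersion, seed) {
  markers <- discovery$top_markers
  marker_regions <- discovery$dmr_regions |>
    filter(.data$region_id %in% markers)

  make_cohort <- function(sd_offset) {
    cf <- simulate_cfdna_counts(tumor_prof, bg_prof, tumor_fraction = fraction,
                                n_per_group = n_per_group,
                                dispersion = dispersion, seed = seed + sd_offset)
    sc <- score_regions(cf, marker_regions) |>
      select("region_id", "sample", "group", "score") |>
      tidyr::pivot_wider(names_from = "region_id", values_from = "score")
    clin <- simulate_cohort(
      n_per_group = c(HCC = n_per_group, cirrhosis = n_per_group),
      seed = seed + sd_offset + 1
    )
    # align clinical covariates to the cfDNA samples by group order
    sc$clin_group <- ifelse(sc$group == "tumor", "HCC", "cirrhosis")
    sc |>
      group_by(.data$clin_group) |>
      mutate(clin_row = row_number()) |>
      ungroup() |>
      left_join(
        clin |> group_by(.data$group) |> mutate(clin_row = row_number()) |>
          ungroup() |> rename(clin_group = "group", clin_sample = "sample"),
        by = c("clin_group", "clin_row")
      ) |>
      select(-"clin_group", -"clin_row", -"clin_sample")
  }

  train <- make_cohort(200)
  validation <- make_cohort(300)
  run_blood_evaluation(train, validation, markers,
                       case = "tumor", control = "control")
}

#' Plant candidate DMRs at random in a genome
#'
#' Picks non-overlapping intervals of the given width, each guaranteed to
#' contain at least `min_sites` LpnPI sites, for use as a design's
#' `planted_dmrs`.
#'
#' @param genome A [generate_genome()] result.
#' @param n Number of regions.
#' @param width Region width in bp.
#' @param fold_change Fold change to plant.
#' @param direction "hyper" or "hypo".
#' @param min_sites Minimum LpnPI sites per region.
#' @param seed Integer RNG seed.
#' @return Tibble (chrom, start, end, direction, fold_change).
#' @export
plant_dmrs <- function(genome, n = 8, width = 1000, fold_change = 4,
                       direction = "hyper", min_sites = 8, seed = 1) {
  sites <- genome$sites
  with_seed(seed, {
    placed <- tibble(chrom = character(), start = integer(), end = integer())
    tries <- 0L
    while (nrow(placed) < n && tries < 5000L) {
      tries <- tries + 1L
      ch <- sample(genome$chromosomes$chrom, 1)
      len <- genome$chromosomes$length[genome$chromosomes$chrom == ch]
      s <- sample.int(len - width, 1)
      e <- s + width
      pos <- sites$pos[sites$chrom == ch]
      if (sum(pos >= s & pos < e) < min_sites) next
      if (any(placed$chrom == ch & placed$start < e + 2000 & s < placed$end + 2000)) next
      placed <- bind_rows(placed, tibble(chrom = ch, start = as.integer(s),
                                         end = as.integer(e)))
    }
    if (nrow(placed) < n) {
      stop_medseqr("could not place the requested number of DMRs; lower `min_sites` or `n`.")
    }
    mutate(placed, direction = direction, fold_change = fold_change)
  })
}
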