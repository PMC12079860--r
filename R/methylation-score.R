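# Per-DMR ROC thresholds and the cumulative DNA methylation score.
#
# Thresholds are learned on a labelled training set and applied unchanged to
# any other cohort: fit_dmr_thresholds() and score_samples() are separate on
# purpose, so no information can leak from an evaluation cohort into the
# thresholds.

# Candidate cut points: midpoints between consecutive sorted unique values,
# plus one below the minimum and one above the maximum, so "everyone
# positive" and "no one positive" are both reachable with a strict ">" rule.
threshold_candidates <- function(values) {
  u <- sort(unique(values))
  if (length(u) < 2L) return(NULL)
  step <- min(diff(u)) / 2
  c(u[1] - step, (u[-1] + u[-length(u)]) / 2, u[length(u)] + step)
}

#' Fit per-DMR ROC-optimal thresholds
#'
#' For every DMR, picks the score threshold maximizing Youden's J
#' (sensitivity + specificity - 1) on the training labels; ties are broken
#' toward the larger threshold. For hyper DMRs a sample is positive when its
#' score is strictly above the threshold; for hypo DMRs, strictly below.
#' The training AUC (rank/Mann-Whitney formulation, orientation-adjusted) is
#' recorded. DMRs with constant scores across the training samples have no
#' usable threshold and are dropped with a warning.
#'
#' @param dmr_scores Long tibble (dmr_id, sample, score, group), e.g.
#'   [score_regions()] output on a DMR set with `region_id` renamed/used as
#'   `dmr_id` (a `region_id` column is accepted and treated as `dmr_id`).
#' @param case,control Training group labels.
#' @param directions Optional tibble (dmr_id, direction); defaults to
#'   "hyper" for every DMR.
#' @param criterion "youden" (default) or "closest01" (closest to the (0,1)
#'   corner of ROC space).
#' @return Tibble of class `dmr_thresholds`: dmr_id, threshold, orientation
#'   ("above"/"below"), auc, n_case, n_control.
#' @export
fit_dmr_thresholds <- function(dmr_scores, case, control, directions = NULL,
                               criterion = c("youden", "closest01")) {
  criterion <- match.arg(criterion)
  if ("region_id" %in% names(dmr_scores) && !"dmr_id" %in% names(dmr_scores)) {
    dmr_scores <- rename(dmr_scores, dmr_id = "region_id")
  }
  assert_columns(dmr_scores, c("dmr_id", "sample", "score", "group"), "dmr_scores")
  dat <- filter(dmr_scores, .data$group %in% c(case, control))
  if (min(table(distinct(dat, .data$sample, .data$group)$group)) < 2) {
    stop_medseqr("need >= 2 samples per label to fit thresholds.")
  }
  if (is.null(directions)) {
    directions <- tibble(dmr_id = unique(dat$dmr_id), direction = "hyper")
  }
  assert_columns(directions, c("dmr_id", "direction"), "directions")

  fits <- dat |>
    left_join(directions, by = "dmr_id") |>
    group_by(.data$dmr_id, .data$direction) |>
    summarise(
      fit = list({
        sc <- .data$score
        lb <- .data$group
        cand <- threshold_candidates(sc)
        if (is.null(cand)) {
          tibble(threshold = NA_real_, auc = NA_real_)
        } else {
          hyper <- .data$direction[1] == "hyper"
          sens <- vapply(cand, function(t) {
            if (hyper) mean(sc[lb == case] > t) else mean(sc[lb == case] < t)
          }, numeric(1))
          spec <- vapply(cand, function(t) {
            if (hyper) mean(sc[lb == control] <= t) else mean(sc[lb == control] >= t)
          }, numeric(1))
          obj <- if (criterion == "youden") {
            sens + spec - 1
          } else {
            -sqrt((1 - sens)^2 + (1 - spec)^2)
          }
          best <- which(obj >= max(obj) - 1e-12)
          thr <- max(cand[best])  # tie toward the larger threshold
          auc <- rank_auc(if (hyper) sc else -sc, lb, case)
          tibble(threshold = thr, auc = auc)
        }
      }),
      n_case = sum(.data$group == case),
      n_control = sum(.data$group == control),
      .groups = "drop"
    ) |>
    tidyr::unnest("fit")

  dropped <- fits |> filter(is.na(.data$threshold))
  if (nrow(dropped) > 0L) {
    warn(sprintf("constant training scores for %d DMR(s): %s -- dropped.",
                 nrow(dropped), paste(dropped$dmr_id, collapse = ", ")))
    fits <- fits |> filter(!is.na(.data$threshold))
  }

  out <- fits |>
    mutate(orientation = ifelse(.data$direction == "hyper", "above", "below")) |>
    select("dmr_id", "threshold", "orientation", "auc", "n_case", "n_control")
  class(out) <- c("dmr_thresholds", class(out))
  out
}

#' Cumulative DNA methylation scores
#'
#' Applies fitted per-DMR thresholds to a score table: each DMR contributes
#' 1 when the sample's orientation-adjusted comparison is satisfied (score
#' strictly above the threshold for "above", strictly below for "below"),
#' and the per-sample sum over the signature is the DNA methylation score.
#' A sample missing a score for some DMR contributes 0 there (reported via a
#' message).
#'
#' @param dmr_scores Long tibble (dmr_id or region_id, sample, score; group
#'   carried through).
#' @param thresholds A [fit_dmr_thresholds()] result.
#' @return Tibble (sample, group if present, score, n_dmrs) with
#'   `0 <= score <= n_dmrs`.
#' @export
score_samples <- function(dmr_scores, thresholds) {
  if ("region_id" %in% names(dmr_scores) && !"dmr_id" %in% names(dmr_scores)) {
    dmr_scores <- rename(dmr_scores, dmr_id = "region_id")
  }
  assert_columns(dmr_scores, c("dmr_id", "sample", "score"), "dmr_scores")
  assert_columns(thresholds, c("dmr_id", "threshold", "orientation"), "thresholds")

  samples <- distinct(dmr_scores, .data$sample)
  grid <- tidyr::expand_grid(sample = samples$sample,
                             dmr_id = thresholds$dmr_id)
  joined <- grid |>
    left_join(select(dmr_scores, "dmr_id", "sample", "score"),
              by = c("dmr_id", "sample")) |>
    left_join(select(thresholds, "dmr_id", "threshold", "orientation"),
              by = "dmr_id")
  n_missing <- sum(is.na(joined$score))
  if (n_missing > 0L) {
    inform(sprintf("%d sample x DMR score(s) missing; counted as 0.", n_missing))
  }
  joined <- joined |>
    mutate(positive = dplyr::case_when(
      is.na(.data$score) ~ 0L,
      .data$orientation == "above" & .data$score > .data$threshold ~ 1L,
      .data$orientation == "below" & .data$score < .data$threshold ~ 1L,
      TRUE ~ 0L
    ))
  out <- joined |>
    group_by(.data$sample) |>
    summarise(score = sum(.data$positive),
              n_dmrs = nrow(thresholds), .groups = "drop")
  if ("group" %in% names(dmr_scores)) {
    out <- left_join(out, distinct(dmr_scores, .data$sample, .data$group),
                     by = "sample")
  }
  out
}

#' Compare methylation scores between groups
#'
#' Per signature, tests case vs control score vectors with a two-sided
#' Mann-Whitney test and reports the fold change of group means, with
#' Benjamini-Hochberg correction across signatures and a significance flag
#' at q < 0.01. A rank test is used rather than a count-model fit: the
#' inputs are small integer score vectors without the dispersion structure a
#' negative-binomial count model needs. Infinite fold changes (zero control
#' mean) are capped at 1e6 and flagged; all-zero scores in both groups give
#' an undefined (NA) fold change, flagged.
#'
#' @param scores Tibble (sample, group, score; optional `signature` column
#'   for several signatures, default a single one).
#' @param case,control Group labels.
#' @param q_cutoff FDR significance cutoff (default 0.01).
#' @return Tibble (signature, n_case, n_control, fold_change, capped,
#'   p_value, q_value, significant).
#' @export
compare_scores <- function(scores, case, control, q_cutoff = 0.01) {
  assert_columns(scores, c("sample", "group", "score"), "scores")
  if (!"signature" %in% names(scores)) scores$signature <- "signature"
  dat <- filter(scores, .data$group %in% c(case, control))
  out <- dat |>
    group_by(.data$signature) |>
    summarise(
      n_case = sum(.data$group == case),
      n_control = sum(.data$group == control),
      mean_case = mean(.data$score[.data$group == case]),
      mean_control = mean(.data$score[.data$group == control]),
      p_value = {
        x <- .data$score[.data$group == case]
        y <- .data$score[.data$group == control]
        if (length(unique(c(x, y))) == 1L) 1 else {
          suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value)
        }
      },
      .groups = "drop"
    ) |>
    mutate(
      fold_change = dplyr::case_when(
        .data$mean_case == 0 & .data$mean_control == 0 ~ NA_real_,
        .data$mean_control == 0 ~ 1e6,
        TRUE ~ .data$mean_case / .data$mean_control
      ),
      capped = !is.na(.data$fold_change) & .data$fold_change == 1e6 |
        is.na(.data$fold_change),
      q_value = p.adjust(.data$p_value, method = "BH"),
      significant = .data$q_value < q_cutoff
    ) |>
    select("signature", "n_case", "n_control", "fold_change", "capped",
           "p_value", "q_value", "significant")
  out
}
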