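#' Relative methylation level from qMSP Ct values
#'
#' Computes the comparative-Ct quantity `2^-(ct_target - ct_reference)`
#' against the ACTB reference. An undetermined target Ct (NA: no
#' amplification) maps to level 0, the qMSP semantics of absent methylation.
#' The level is scale-free: adding a constant to both Ct values leaves it
#' unchanged.
#'
#' @param ct_target,ct_reference Numeric vectors of quantification cycles.
#' @return Numeric vector of relative methylation levels.
#' @examples
#' relative_methylation(26, 25)   # one-cycle halving -> 0.5
#' @export
relative_methylation <- function(ct_target, ct_reference) {
  if (any(is.na(ct_reference))) {
    stop_medseqr("reference Ct must be present and finite.")
  }
  ifelse(is.na(ct_target), 0, 2^(-(ct_target - ct_reference)))
}

#' Add relative methylation levels to a qMSP table
#'
#' @param data Long qMSP tibble (sample, marker, ct_target, ct_reference,
#'   other columns carried through).
#' @return `data` with `level` (relative methylation) and `undetermined`
#'   (logical flag for NA target Ct) columns.
#' @export
qmsp_levels <- function(data) {
  assert_columns(data, c("sample", "marker", "ct_target", "ct_reference"), "data")
  data |>
    mutate(
      undetermined = is.na(.data$ct_target),
      level = relative_methylation(.data$ct_target, .data$ct_reference)
    )
}

#' Empirical percentile threshold
#'
#' The q-th empirical percentile with linear interpolation between order
#' statistics (type-7 quantile: `h = (n-1) q/100 + 1`,
#' `x_(floor h) + (h - floor h)(x_(floor h + 1) - x_(floor h))`).
#'
#' @param values Numeric vector of control values (at least `min_n`).
#' @param q Percentile in \[0,100\] (default 95).
#' @param min_n Minimum number of control values required.
#' @return The threshold (scalar).
#' @export
percentile_threshold <- function(values, q = 95, min_n = 5) {
  assert_scalar_number(q, "q", lower = 0, upper = 100)
  if (length(values) < min_n || anyNA(values)) {
    stop_medseqr(sprintf("need >= %d non-missing control values.", min_n))
  }
  unname(quantile(values, probs = q / 100, type = 7))
}

#' Per-marker positivity thresholds from a control group
#'
#' Computes the q-th percentile of the control group's relative methylation
#' levels for each marker; the thresholds derive from controls only.
#'
#' @param levels A [qmsp_levels()] result with a `group` column.
#' @param control_group Label of the control group.
#' @param q Percentile (default 95).
#' @param min_n Minimum controls per marker; fewer raises an error naming
#'   the marker.
#' @return Tibble (marker, threshold, n_control).
#' @export
qmsp_thresholds <- function(levels, control_group, q = 95, min_n = 5) {
  assert_columns(levels, c("marker", "group", "level"), "levels")
  ctrl <- filter(levels, .data$group == control_group)
  if (nrow(ctrl) == 0L) stop_medseqr("no samples in the control group.")
  short <- ctrl |> count(.data$marker) |> filter(.data$n < min_n)
  if (nrow(short) > 0L) {
    stop_medseqr(sprintf("fewer than %d controls for marker(s): %s.",
                         min_n, paste(short$marker, collapse = ", ")))
  }
  ctrl |>
    group_by(.data$marker) |>
    summarise(threshold = percentile_threshold(.data$level, q = q, min_n = min_n),
              n_control = dplyr::n(), .groups = "drop")
}

#' Call per-sample marker positivity against control thresholds
#'
#' A sample is positive for a marker iff its level strictly exceeds the
#' marker's control-derived threshold (a value exactly equal to the
#' threshold is negative).
#'
#' @param levels A [qmsp_levels()] result.
#' @param thresholds A [qmsp_thresholds()] result.
#' @return `levels` with `threshold` and binary `positive` columns.
#' @export
call_positivity <- function(levels, thresholds) {
  assert_columns(levels, c("sample", "marker", "level"), "levels")
  assert_columns(thresholds, c("marker", "threshold"), "thresholds")
  miss <- setdiff(unique(levels$marker), thresholds$marker)
  if (length(miss) > 0L) {
    stop_medseqr(sprintf("no threshold for marker(s): %s.", paste(miss, collapse = ", ")))
  }
  levels |>
    left_join(select(thresholds, "marker", "threshold"), by = "marker") |>
    mutate(positive = as.integer(.data$level > .data$threshold))
}

#' Per-marker detection fractions by group
#'
#' @param positivity A [call_positivity()] result with a `group` column.
#' @return Tibble (marker, group, n, positives, fraction, pct) where pct is
#'   the detection percentage `100 * positives / n`.
#' @export
detection_fractions <- function(positivity) {
  assert_columns(positivity, c("marker", "group", "positive"), "positivity")
  positivity |>
    group_by(.data$marker, .data$group) |>
    summarise(
      n = dplyr::n(),
      positives = sum(.data$positive),
      .groups = "drop"
    ) |>
    mutate(fraction = .data$positives / .data$n, pct = 100 * .data$fraction)
}

#' Mann-Whitney comparison of marker levels between two groups
#'
#' Two-sided Mann-Whitney U test per marker. The exact null distribution is
#' used when both groups have fewer than 50 samples and the data are
#' tie-free (the `stats::wilcox.test` switch point); otherwise the normal
#' approximation with tie correction applies. All-tied data give p = 1.
#'
#' @param levels A [qmsp_levels()] result (or any tibble with marker, group,
#'   level).
#' @param case,control Group labels.
#' @return Tibble (marker, n_case, n_control, statistic, p_value).
#' @export
compare_marker_groups <- function(levels, case, control) {
  assert_columns(levels, c("marker", "group", "level"), "levels")
  dat <- filter(levels, .data$group %in% c(case, control))
  dat |>
    group_by(.data$marker) |>
    summarise(
      n_case = sum(.data$group == case),
      n_control = sum(.data$group == control),
      test = list({
        x <- .data$level[.data$group == case]
        y <- .data$level[.data$group == control]
        if (min(length(x), length(y)) < 3L) {
          stop_medseqr("need >= 3 samples per group for the Mann-Whitney test.")
        }
        if (length(unique(c(x, y))) == 1L) {
          tibble(statistic = length(x) * length(y) / 2, p_value = 1)
        } else {
          wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
          tibble(statistic = unname(wt$statistic), p_value = wt$p.value)
        }
      }),
      .groups = "drop"
    ) |>
    tidyr::unnest("test")
}
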