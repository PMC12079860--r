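#' Simulate a qMSP Ct table
#'
#' Draws target and reference (ACTB) quantification cycles for each sample and
#' marker. The reference Ct is Gaussian around a fixed mean; the target Ct is
#' the reference plus the group's mean delta-Ct plus Gaussian noise, so the
#' relative methylation level `2^-(ct_target - ct_reference)` is lognormal
#' with group-dependent location, emulating qMSP panel data.
#'
#' @param delta_ct Tibble with columns group, marker, delta_ct (group mean
#'   Ct difference target - reference; larger = less methylation).
#' @param sd Gaussian noise SD on the target Ct, in cycles (>= 0).
#' @param n_per_group Samples per group.
#' @param ct_ref_mean,ct_ref_sd Mean and SD of the reference Ct.
#' @param seed Integer RNG seed.
#' @return Tibble (sample, group, marker, ct_target, ct_reference).
#' @examples
#' dct <- tibble::tibble(group = c("HCC", "cirrhosis"), marker = "FGF19",
#'                       delta_ct = c(4, 8))
#' head(simulate_qmsp(dct, sd = 0.5, n_per_group = 5, seed = 1))
#' @export
simulate_qmsp <- function(delta_ct, sd = 0.5, n_per_group = 20,
                          ct_ref_mean = 25, ct_ref_sd = 0.5, seed = 1) {
  assert_columns(delta_ct, c("group", "marker", "delta_ct"), "delta_ct")
  assert_scalar_number(sd, "sd", lower = 0)
  assert_scalar_number(n_per_group, "n_per_group", lower = 1)
  groups <- unique(delta_ct$group)
  with_seed(seed, {
    samples <- tibble(
      group = rep(groups, each = n_per_group),
      sample = sprintf("%s_%03d", rep(groups, each = n_per_group),
                       rep(seq_len(n_per_group), times = length(groups))),
      ct_reference = rnorm(length(groups) * n_per_group, ct_ref_mean, ct_ref_sd)
    )
    out <- samples |>
      left_join(delta_ct, by = "group", relationship = "many-to-many") |>
      mutate(ct_target = .data$ct_reference + .data$delta_ct +
               rnorm(dplyr::n(), 0, sd)) |>
      select("sample", "group", "marker", "ct_target", "ct_reference")
    out
  })
}

#' Default clinical distribution parameters for cohort simulation
#'
#' Lognormal location/scale parameters for serum AFP (ng/mL) and PIVKA-II
#' (mAU/mL) per group, chosen so the simulated group medians fall near
#' typical published cirrhotic-HCC and cirrhosis cohort medians (HCC AFP
#' median ~15 ng/mL vs cirrhosis ~4.5; HCC PIVKA median ~400 mAU/mL vs
#' cirrhosis ~70).
#'
#' @return Tibble (group, afp_meanlog, afp_sdlog, pivka_meanlog, pivka_sdlog).
#' @export
default_cohort_params <- function() {
  tibble(
    group = c("HCC", "cirrhosis"),
    afp_meanlog = c(log(15), log(4.5)),
    afp_sdlog = c(1.5, 0.5),
    pivka_meanlog = c(log(400), log(70)),
    pivka_sdlog = c(1.5, 0.8)
  )
}

#' Simulate a clinical cohort with group-dependent biomarkers
#'
#' Generates per-sample age, sex, AFP and PIVKA-II values with lognormal
#' biomarker distributions per group. Biomarker values are clipped to the
#' assay detection limits (AFP 0.5-2000 ng/mL, PIVKA-II 5-75000 mAU/mL)
#' exactly as a clinical laboratory would report them.
#'
#' @param n_per_group Named integer vector of samples per group (names must
#'   match `params$group`); 0 gives an empty table.
#' @param params Distribution parameters as in [default_cohort_params()].
#' @param age_range Two-element range of ages in years (uniform integer).
#' @param male_fraction Probability of male sex in \[0,1\].
#' @param seed Integer RNG seed.
#' @return Tibble (sample, group, age, sex, afp, pivka); sex coded 1 = male,
#'   0 = female.
#' @export
simulate_cohort <- function(n_per_group,
                            params = default_cohort_params(),
                            age_range = c(45, 85),
                            male_fraction = 0.75,
                            seed = 1) {
  assert_columns(params, c("group", "afp_meanlog", "afp_sdlog",
                           "pivka_meanlog", "pivka_sdlog"), "params")
  assert_scalar_number(male_fraction, "male_fraction", lower = 0, upper = 1)
  if (is.null(names(n_per_group)) || !all(names(n_per_group) %in% params$group)) {
    stop_medseqr("`n_per_group` must be named by groups present in `params`.")
  }
  with_seed(seed, {
    out <- purrr::map_dfr(names(n_per_group), function(g) {
      n <- n_per_group[[g]]
      if (n == 0L) {
        return(tibble(sample = character(), group = character(), age = integer(),
                      sex = integer(), afp = numeric(), pivka = numeric()))
      }
      p <- params[params$group == g, ]
      tibble(
        sample = sprintf("%s_%03d", g, seq_len(n)),
        group = g,
        age = as.integer(round(runif(n, age_range[1], age_range[2]))),
        sex = rbinom(n, 1, male_fraction),
        afp = rlnorm(n, p$afp_meanlog, p$afp_sdlog),
        pivka = rlnorm(n, p$pivka_meanlog, p$pivka_sdlog)
      )
    })
    if (nrow(out) > 0L) out <- clip_to_detection_limits(out)
    out
  })
}
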