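#' Describe a two-group MeD-seq simulation
#'
#' Collects the parameters of a simulated two-group comparison: group sizes,
#' planted differentially methylated regions, sequencing depth and
#' overdispersion, and the cfDNA tumor fraction. The first group label is the
#' case group; planted DMRs perturb its site means.
#'
#' Counts are drawn from a negative binomial (Poisson in the limit
#' `dispersion = 0`), matching the overdispersion of sequencing count data.
#' The default `tumor_fraction` of 0.02 reflects the 1-3% hepatocyte
#' contribution to circulating cfDNA in the liver setting this package
#' models. The default depth is a placeholder at toy scale, not an estimate
#' of real MeD-seq library depth.
#'
#' @param n_per_group Samples per group.
#' @param group_labels Two group labels; the first is the case group.
#' @param planted_dmrs `NULL` or a tibble with columns chrom, start, end
#'   (0-based half-open), direction ("hyper"/"hypo") and fold_change (> 0).
#' @param mean_depth Expected reads per site per sample (> 0).
#' @param dispersion Negative-binomial dispersion; 0 gives Poisson counts.
#' @param tumor_fraction Fraction in \[0,1\] of cfDNA derived from tumor.
#' @param background_shift sdlog of a per-site lognormal perturbation applied
#'   to the case group only (models a global methylation shift such as the
#'   cirrhosis-vs-healthy contrast); 0 disables it.
#' @param seed Integer RNG seed.
#'
#' @return A `simulation_design` list.
#' @export
simulation_design <- function(n_per_group = 10,
                              group_labels = c("tumor", "control"),
                              planted_dmrs = NULL,
                              mean_depth = 50,
                              dispersion = 0.1,
                              tumor_fraction = 0.02,
                              background_shift = 0,
                              seed = 1) {
  assert_scalar_number(n_per_group, "n_per_group", lower = 0)
  assert_scalar_number(mean_depth, "mean_depth")
  if (mean_depth <= 0) stop_medseqr("`mean_depth` must be > 0.")
  assert_scalar_number(dispersion, "dispersion", lower = 0)
  assert_scalar_number(tumor_fraction, "tumor_fraction", lower = 0, upper = 1)
  assert_scalar_number(background_shift, "background_shift", lower = 0)
  if (length(group_labels) != 2L || anyDuplicated(group_labels)) {
    stop_medseqr("`group_labels` must be two distinct labels.")
  }
  if (!is.null(planted_dmrs)) {
    assert_columns(planted_dmrs, c("chrom", "start", "end", "direction", "fold_change"),
                   "planted_dmrs")
    if (any(planted_dmrs$fold_change <= 0)) {
      stop_medseqr("planted fold_change values must be > 0.")
    }
    if (!all(planted_dmrs$direction %in% c("hyper", "hypo"))) {
      stop_medseqr("planted direction must be 'hyper' or 'hypo'.")
    }
  }
  structure(
    list(
      n_per_group = as.integer(n_per_group),
      group_labels = group_labels,
      planted_dmrs = planted_dmrs,
      mean_depth = mean_depth,
      dispersion = dispersion,
      tumor_fraction = tumor_fraction,
      background_shift = background_shift,
      seed = as.integer(seed)
    ),
    class = "simulation_design"
  )
}

# Per-site expected depth shared by both groups: a gamma(shape, shape) weight
# (mean 1, CV ~ 1/sqrt(shape)) times mean_depth. Deterministic given the
# design seed, so group means can be reconstructed via site_mean_profile().
site_weights <- function(n_sites, seed) {
  with_seed(seed + 1000003L, rgamma(n_sites, shape = 5, rate = 5))
}

# Expected count per site for one group under a design (before NB sampling).
design_site_means <- function(genome, design, group) {
  sites <- genome$sites
  mu <- design$mean_depth * site_weights(nrow(sites), design$seed)
  is_case <- group == design$group_labels[1]
  if (is_case && !is.null(design$planted_dmrs)) {
    pd <- design$planted_dmrs
    bad <- !pd$chrom %in% sites$chrom
    if (any(bad)) stop_medseqr("planted DMR on a chromosome absent from the genome.")
    for (i in seq_len(nrow(pd))) {
      hit <- sites$chrom == pd$chrom[i] & sites$pos >= pd$start[i] & sites$pos < pd$end[i]
      if (!any(hit)) {
        warn(sprintf("planted DMR %s:%d-%d contains no LpnPI site; not plantable.",
                     pd$chrom[i], pd$start[i], pd$end[i]))
        next
      }
      mu[hit] <- if (pd$direction[i] == "hyper") {
        mu[hit] * pd$fold_change[i]
      } else {
        mu[hit] / pd$fold_change[i]
      }
    }
  }
  if (is_case && design$background_shift > 0) {
    shift <- with_seed(design$seed + 2000003L,
                       rlnorm(nrow(sites), meanlog = 0, sdlog = design$background_shift))
    mu <- mu * shift
  }
  mu
}

#' Expected per-site count profile of one group
#'
#' Returns the deterministic mean structure (before negative-binomial
#' sampling) that [simulate_site_counts()] uses for a group: the tissue
#' profiles consumed by [simulate_cfdna_counts()].
#'
#' @param genome A [generate_genome()] result.
#' @param design A [simulation_design()].
#' @param group One of the design's group labels.
#' @return Tibble with columns chrom, pos, mean.
#' @export
site_mean_profile <- function(genome, design, group) {
  stopifnot(inherits(genome, "medseq_genome"), inherits(design, "simulation_design"))
  if (!group %in% design$group_labels) {
    stop_medseqr(sprintf("group '%s' is not in the design's labels.", group))
  }
  tibble(
    chrom = genome$sites$chrom,
    pos = genome$sites$pos,
    mean = design_site_means(genome, design, group)
  )
}

nb_draw <- function(n, mu, dispersion) {
  if (dispersion <= 0) rpois(n, mu) else rnbinom(n, size = 1 / dispersion, mu = mu)
}

#' Simulate per-sample LpnPI site counts for two groups
#'
#' Draws negative-binomial read counts at every LpnPI site for each sample of
#' both design groups. Inside planted hypermethylated DMRs the case-group
#' mean is multiplied by the planted fold change (divided, for hypo). Site
#' depth heterogeneity is shared between groups, so sites outside planted
#' DMRs are null by construction.
#'
#' @param genome A [generate_genome()] result.
#' @param design A [simulation_design()].
#' @return A long tibble (class `medseq_counts`) with columns chrom, pos,
#'   sample, group, count; one row per site x sample.
#' @examples
#' gn <- generate_genome(chrom_length = 5e4, seed = 1)
#' cnt <- simulate_site_counts(gn, simulation_design(n_per_group = 3, seed = 2))
#' library_sizes(cnt)
#' @export
simulate_site_counts <- function(genome, design) {
  stopifnot(inherits(genome, "medseq_genome"), inherits(design, "simulation_design"))
  sites <- genome$sites
  n_sites <- nrow(sites)
  mus <- lapply(design$group_labels, function(g) design_site_means(genome, design, g))
  with_seed(design$seed, {
    out <- purrr::map2_dfr(design$group_labels, mus, function(g, mu) {
      if (design$n_per_group == 0L) {
        return(tibble(chrom = character(), pos = integer(), sample = character(),
                      group = character(), count = integer()))
      }
      samples <- sprintf("%s_%02d", g, seq_len(design$n_per_group))
      tibble(
        chrom = rep(sites$chrom, times = design$n_per_group),
        pos = rep(sites$pos, times = design$n_per_group),
        sample = rep(samples, each = n_sites),
        group = g,
        count = as.integer(nb_draw(n_sites * design$n_per_group, rep(mu, design$n_per_group),
                                   design$dispersion))
      )
    })
    class(out) <- c("medseq_counts", class(out))
    out
  })
}

#' Simulate cell-free DNA counts as a tumor/background mixture
#'
#' Models plasma cfDNA as a convex mixture of a tumor tissue profile and a
#' background (non-tumor) profile: the expected count at each site is
#' `tumor_fraction * tumor + (1 - tumor_fraction) * background`, then
#' negative-binomial sampled. Control samples are drawn from the background
#' profile alone. At low tumor fractions the planted tissue signal is diluted
#' toward the background, which is the mechanism behind the loss of
#' methylation-marker signal in blood.
#'
#' @param tumor_profile,background_profile Tibbles (chrom, pos, mean) on the
#'   same site index, e.g. from [site_mean_profile()].
#' @param tumor_fraction Mixing fraction in \[0,1\].
#' @param n_per_group Samples per group.
#' @param dispersion Negative-binomial dispersion.
#' @param group_labels Case and control labels for the output.
#' @param seed Integer RNG seed.
#' @return A long `medseq_counts` tibble as in [simulate_site_counts()].
#' @export
simulate_cfdna_counts <- function(tumor_profile, background_profile,
                                  tumor_fraction,
                                  n_per_group = 10,
                                  dispersion = 0.1,
                                  group_labels = c("tumor", "control"),
                                  seed = 1) {
  assert_columns(tumor_profile, c("chrom", "pos", "mean"), "tumor_profile")
  assert_columns(background_profile, c("chrom", "pos", "mean"), "background_profile")
  assert_scalar_number(tumor_fraction, "tumor_fraction", lower = 0, upper = 1)
  if (nrow(tumor_profile) != nrow(background_profile) ||
      !all(tumor_profile$chrom == background_profile$chrom) ||
      !all(tumor_profile$pos == background_profile$pos)) {
    stop_medseqr("tumor and background profiles must share the same site index.",
                 class = "medseqr_index_mismatch")
  }
  mu_case <- tumor_fraction * tumor_profile$mean +
    (1 - tumor_fraction) * background_profile$mean
  mu_ctrl <- background_profile$mean
  n_sites <- nrow(tumor_profile)
  with_seed(seed, {
    out <- purrr::map2_dfr(group_labels, list(mu_case, mu_ctrl), function(g, mu) {
      samples <- sprintf("%s_%02d", g, seq_len(n_per_group))
      tibble(
        chrom = rep(tumor_profile$chrom, times = n_per_group),
        pos = rep(tumor_profile$pos, times = n_per_group),
        sample = rep(samples, each = n_sites),
        group = g,
        count = as.integer(nb_draw(n_sites * n_per_group, rep(mu, n_per_group), dispersion))
      )
    })
    class(out) <- c("medseq_counts", class(out))
    out
  })
}

#' Per-sample library sizes of a count table
#'
#' @param counts A long count tibble (chrom, pos, sample, count; group optional).
#' @return Tibble (sample, group if present, library_size).
#' @export
library_sizes <- function(counts) {
  assert_columns(counts, c("sample", "count"), "counts")
  grp <- intersect("group", names(counts))
  counts |>
    group_by(dplyr::across(dplyr::all_of(c("sample", grp)))) |>
    summarise(library_size = sum(.data$count), .groups = "drop")
}

#' Emit LpnPI digestion fragments from a site-count table
#'
#' Converts per-site counts into individual 32-bp fragment records, the read
#' model of an LpnPI digest: the enzyme cuts around a methylated
#' CpG-containing recognition site, so every fragment carries its origin site
#' at a fixed offset from the 5' end. Each count unit becomes one fragment
#' whose origin site sits `site_offset` bp from the fragment's 5' end --
#' inside the positional filter window of [filter_reads()], so a round trip
#' through filtering and assignment recovers the original matrix exactly.
#'
#' @param counts A long count tibble (chrom, pos, sample, count).
#' @param read_length Fragment length in bp (default 32).
#' @param site_offset Distance of the origin site from the 5' end (default 13).
#' @return Tibble of reads: sample, chrom, start (0-based), length.
#' @export
simulate_reads <- function(counts, read_length = 32, site_offset = 13) {
  assert_columns(counts, c("chrom", "pos", "sample", "count"), "counts")
  assert_scalar_number(read_length, "read_length", lower = 1)
  assert_scalar_number(site_offset, "site_offset", lower = 0, upper = read_length - 1)
  nz <- counts[counts$count > 0, ]
  tibble(
    sample = rep(nz$sample, times = nz$count),
    chrom = rep(nz$chrom, times = nz$count),
    start = rep(as.integer(nz$pos - site_offset), times = nz$count),
    length = as.integer(read_length)
  )
}
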