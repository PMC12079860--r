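#' Build TSS, gene-body and CpG-island regions from an annotation
#'
#' Constructs the three region classes used for read-count scoring, with
#' 0-based half-open coordinates (BED convention):
#' * TSS: 1 kb before to 1 kb after the transcription start site
#'   (`[tss - flank, tss + flank)`), on either strand;
#' * gene body: from 1 kb after the TSS to the transcription end site,
#'   strand-aware (`[tss + flank, tes)` on plus, `[tes, tss - flank)` on
#'   minus);
#' * CpG islands, passed through unchanged.
#'
#' Regions extending past chromosome ends are clipped; genes too short to
#' leave a non-empty body beyond the flank have the body omitted with a
#' message.
#'
#' @param genome A [generate_genome()] result, or any list with tibbles
#'   `chromosomes` (chrom, length), `genes` (gene_id, chrom, strand, tss,
#'   tes) and `cpg_islands` (island_id, chrom, start, end).
#' @param tss_flank Flank size in bp (default 1000).
#' @return Tibble (region_id, chrom, start, end, class) with class one of
#'   "TSS", "gene_body", "cpg_island".
#' @examples
#' gn <- generate_genome(chrom_length = 5e4, seed = 1)
#' dplyr::count(define_regions(gn), class)
#' @export
define_regions <- function(genome, tss_flank = 1000) {
  assert_scalar_number(tss_flank, "tss_flank", lower = 1)
  genes <- genome$genes
  chrlen <- setNames(genome$chromosomes$length, genome$chromosomes$chrom)

  tss_regions <- genes |>
    mutate(
      region_id = paste0(.data$gene_id, "_tss"),
      start = pmax(0L, as.integer(.data$tss - tss_flank)),
      end = as.integer(unname(pmin(chrlen[.data$chrom], .data$tss + tss_flank))),
      class = "TSS"
    ) |>
    select("region_id", "chrom", "start", "end", "class")

  body_regions <- genes |>
    mutate(
      region_id = paste0(.data$gene_id, "_body"),
      start = ifelse(.data$strand == "+", .data$tss + tss_flank, .data$tes),
      end = ifelse(.data$strand == "+", .data$tes, .data$tss - tss_flank),
      start = pmax(0L, as.integer(.data$start)),
      end = as.integer(unname(pmin(chrlen[.data$chrom], .data$end))),
      class = "gene_body"
    ) |>
    select("region_id", "chrom", "start", "end", "class")
  empty <- body_regions$end <= body_regions$start
  if (any(empty)) {
    inform(sprintf("%d gene(s) shorter than the TSS flank: gene body omitted.",
                   sum(empty)))
    body_regions <- body_regions[!empty, ]
  }

  island_regions <- genome$cpg_islands |>
    mutate(region_id = .data$island_id, class = "cpg_island") |>
    select("region_id", "chrom", "start", "end", "class")

  out <- bind_rows(tss_regions, body_regions, island_regions) |>
    arrange(.data$chrom, .data$start, .data$region_id)
  if (any(out$end <= out$start)) {
    out <- out[out$end > out$start, ]
  }
  out
}

#' RPM-normalized region read-count scores
#'
#' Sums per-site counts over each region (sites with `start <= pos < end`,
#' half-open) and normalizes to reads per million mapped: `score = 1e6 *
#' region_count / library_size`. Overlapping regions each receive the full
#' counts of their shared sites (region-wise, not partition-wise, scoring).
#' Regions containing no LpnPI site score 0 and are flagged via `n_sites`.
#'
#' @param counts Long count tibble (chrom, pos, sample, count; group carried
#'   through if present).
#' @param regions Region tibble (region_id, chrom, start, end, ...), e.g.
#'   from [define_regions()] or a DMR set.
#' @param library_size Optional named vector of per-sample library sizes;
#'   defaults to the per-sample total of `counts`.
#' @return Long tibble (region_id, class if present, n_sites, sample, group
#'   if present, score).
#' @export
score_regions <- function(counts, regions, library_size = NULL) {
  assert_columns(counts, c("chrom", "pos", "sample", "count"), "counts")
  assert_columns(regions, c("region_id", "chrom", "start", "end"), "regions")
  if (any(regions$end <= regions$start)) {
    stop_medseqr("regions must satisfy start < end.")
  }

  sites <- counts |> distinct(.data$chrom, .data$pos) |> arrange(.data$chrom, .data$pos)
  sites$row <- seq_len(nrow(sites))
  samples <- unique(counts$sample)

  # site x sample count matrix for fast per-region column sums
  m <- matrix(0, nrow = nrow(sites), ncol = length(samples),
              dimnames = list(NULL, samples))
  ridx <- vctrs::vec_match(counts[c("chrom", "pos")], sites[c("chrom", "pos")])
  cidx <- match(counts$sample, samples)
  li <- (cidx - 1L) * nrow(sites) + ridx
  if (anyDuplicated(li)) {
    agg <- rowsum(as.numeric(counts$count), li)
    m[as.integer(rownames(agg))] <- agg[, 1]
  } else {
    m[li] <- counts$count
  }

  if (is.null(library_size)) {
    library_size <- colSums(m)
  } else {
    if (!all(samples %in% names(library_size))) {
      stop_medseqr("`library_size` must be named and cover every sample.")
    }
    library_size <- library_size[samples]
  }
  if (any(library_size <= 0)) {
    stop_medseqr("library sizes must be positive for RPM normalization.")
  }

  per_region <- purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    ch <- regions$chrom[i]
    pos <- sites$pos[sites$chrom == ch]
    rows <- sites$row[sites$chrom == ch]
    lo <- findInterval(regions$start[i] - 1L, pos) + 1L
    hi <- findInterval(regions$end[i] - 1L, pos)  # pos <= end - 1, i.e. pos < end
    if (lo > hi || length(pos) == 0L) {
      sums <- rep(0, length(samples))
      ns <- 0L
    } else {
      block <- m[rows[lo:hi], , drop = FALSE]
      sums <- colSums(block)
      ns <- hi - lo + 1L
    }
    tibble(
      region_id = regions$region_id[i],
      n_sites = ns,
      sample = samples,
      score = as.numeric(1e6 * sums / library_size)
    )
  })

  if ("class" %in% names(regions)) {
    per_region <- left_join(per_region,
                            select(regions, "region_id", "class"),
                            by = "region_id")
  }
  if ("group" %in% names(counts)) {
    per_region <- left_join(per_region,
                            distinct(counts, .data$sample, .data$group),
                            by = "sample")
  }
  per_region
}
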