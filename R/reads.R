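# Positional read filter and site assignment.
#
# Real MeD-seq processing trims adaptors, maps reads with bowtie2 and keeps
# those carrying an LpnPI recognition site 13-17 bp from either fragment end.
# This package operates post-alignment: reads arrive as mapped intervals
# (chrom, start, length) and the filter checks site positions directly
# against the LpnPI site index. A loader for externally produced per-site
# count tables is provided in read_site_counts().

# 5'-most site position within [lo, hi] for each query, NA if none.
# pos must be sorted ascending.
first_site_in <- function(pos, lo, hi) {
  i <- findInterval(lo - 1L, pos) + 1L
  hit <- i <= length(pos) & ifelse(i <= length(pos), pos[pmin(i, length(pos))] <= hi, FALSE)
  ifelse(hit & lo <= hi, pos[pmin(i, length(pos))], NA_integer_)
}

#' Filter reads by LpnPI-site position
#'
#' Keeps a read iff at least one LpnPI site lies at a distance within
#' `[min_offset, max_offset]` bp (inclusive on both ends) of either the 5' or
#' the 3' end of the read. Distances are measured from the terminal base:
#' the 5' offset of a site at `pos` is `pos - start`; the 3' offset is
#' `(start + length - 1) - pos`.
#'
#' Each kept read is annotated with the 5'-most qualifying site
#' (`site_pos`), the site it will be attributed to by [assign_reads()], so a
#' read qualifying at both ends is counted once. Filtering is idempotent.
#'
#' @param reads Tibble of mapped reads: chrom, start (0-based), length;
#'   an optional sample column is carried through.
#' @param sites LpnPI site index: tibble (chrom, pos).
#' @param min_offset,max_offset Inclusive offset window in bp (defaults 13
#'   and 17).
#' @return The kept reads with a `site_pos` column; per-sample filter
#'   statistics are attached as attribute `"filter_stats"` and retrievable
#'   with [filter_stats()].
#' @examples
#' sites <- tibble::tibble(chrom = "chr1", pos = 100L)
#' reads <- tibble::tibble(chrom = "chr1", start = c(85L, 50L), length = 32L)
#' filter_stats(filter_reads(reads, sites))
#' @export
filter_reads <- function(reads, sites, min_offset = 13, max_offset = 17) {
  assert_columns(reads, c("chrom", "start", "length"), "reads")
  assert_columns(sites, c("chrom", "pos"), "sites")
  assert_scalar_number(min_offset, "min_offset", lower = 0)
  assert_scalar_number(max_offset, "max_offset", lower = 0)
  if (min_offset > max_offset) {
    stop_medseqr("`min_offset` must be <= `max_offset`.")
  }
  if (!"sample" %in% names(reads)) reads$sample <- "sample_1"
  if (nrow(reads) == 0L) {
    out <- mutate(reads, site_pos = integer())
    attr(out, "filter_stats") <- tibble(
      sample = character(), total_reads = integer(), kept_reads = integer(),
      discarded_reads = integer(), cpg_read_fraction = numeric()
    )
    return(out)
  }

  site_pos <- numeric(nrow(reads))
  site_pos[] <- NA_integer_
  for (ch in unique(reads$chrom)) {
    ri <- which(reads$chrom == ch)
    pos <- sort(sites$pos[sites$chrom == ch])
    if (length(pos) == 0L) next
    start <- reads$start[ri]
    end3 <- start + reads$length[ri] - 1L
    # qualifying positions form two windows per read
    hit5 <- first_site_in(pos, start + min_offset, start + max_offset)
    hit3 <- first_site_in(pos, end3 - max_offset, end3 - min_offset)
    site_pos[ri] <- pmin(hit5, hit3, na.rm = TRUE)
  }
  reads$site_pos <- as.integer(site_pos)
  kept <- reads[!is.na(reads$site_pos), ]

  totals <- count(reads, .data$sample, name = "total_reads")
  kepts <- count(kept, .data$sample, name = "kept_reads")
  stats <- totals |>
    left_join(kepts, by = "sample") |>
    mutate(
      kept_reads = dplyr::coalesce(.data$kept_reads, 0L),
      discarded_reads = .data$total_reads - .data$kept_reads,
      cpg_read_fraction = .data$kept_reads / .data$total_reads
    )
  attr(kept, "filter_stats") <- stats
  kept
}

#' Retrieve the statistics attached by [filter_reads()]
#'
#' @param kept The tibble returned by [filter_reads()].
#' @return Tibble (sample, total_reads, kept_reads, discarded_reads,
#'   cpg_read_fraction).
#' @export
filter_stats <- function(kept) {
  s <- attr(kept, "filter_stats")
  if (is.null(s)) stop_medseqr("no filter statistics attached; run filter_reads() first.")
  s
}

#' Assign filtered reads to LpnPI sites
#'
#' Tallies each kept read at the site that satisfied the positional filter
#' (the 5'-most qualifying site). Every site of the index appears in the
#' output, with zero counts where no read was assigned. Reads whose
#' qualifying site is absent from the supplied index are counted in an
#' unassigned bucket and reported via a message.
#'
#' @param kept Output of [filter_reads()] (must carry `site_pos`).
#' @param sites LpnPI site index tibble (chrom, pos).
#' @return Long count tibble (chrom, pos, sample, count) covering the full
#'   index, with attributes `library_size` (named per sample: number of kept
#'   reads) and `unassigned` (named per sample).
#' @export
assign_reads <- function(kept, sites) {
  assert_columns(kept, c("chrom", "site_pos", "sample"), "kept")
  assert_columns(sites, c("chrom", "pos"), "sites")
  sites <- arrange(sites, .data$chrom, .data$pos)
  samples <- unique(kept$sample)
  if (length(samples) == 0L) samples <- "sample_1"

  key_sites <- paste(sites$chrom, sites$pos)
  key_reads <- paste(kept$chrom, kept$site_pos)
  known <- key_reads %in% key_sites

  unassigned <- vapply(samples, function(s) sum(!known & kept$sample == s), integer(1))
  if (any(unassigned > 0L)) {
    inform(sprintf("%d read(s) matched a site absent from the index; left unassigned.",
                   sum(unassigned)))
  }

  grid <- tidyr::expand_grid(
    sites |> select("chrom", "pos"),
    sample = samples
  )
  tallied <- kept[known, ] |>
    count(.data$chrom, pos = .data$site_pos, .data$sample, name = "count")
  out <- grid |>
    left_join(tallied, by = c("chrom", "pos", "sample")) |>
    mutate(count = dplyr::coalesce(.data$count, 0L)) |>
    arrange(.data$sample, .data$chrom, .data$pos)

  attr(out, "library_size") <- vapply(samples, function(s) sum(kept$sample == s), integer(1))
  attr(out, "unassigned") <- unassigned
  class(out) <- c("medseq_counts", class(out))
  out
}

#' Sample-level quality control
#'
#' Applies the MeD-seq sample QC rule: a sample passes iff its total read
#' count is strictly greater than `min_total_reads` AND the fraction of reads
#' containing a CpG/LpnPI site is strictly greater than `min_cpg_fraction`.
#' Defaults are the production-scale thresholds (20 million reads, 20%); at
#' toy scale pass e.g. `min_total_reads = 2000`.
#'
#' @param data Tibble with columns sample, total_reads, cpg_read_fraction
#'   (e.g. from [filter_stats()]).
#' @param min_total_reads Minimum total reads (exclusive bound).
#' @param min_cpg_fraction Minimum CpG-read fraction (exclusive bound).
#' @return `data` with logical `pass` and character `reasons` columns
#'   (failed criteria, ";"-separated, empty when passing).
#' @export
qc_sample <- function(data, min_total_reads = 2e7, min_cpg_fraction = 0.20) {
  assert_columns(data, c("sample", "total_reads", "cpg_read_fraction"), "data")
  data |>
    mutate(
      pass = .data$total_reads > min_total_reads &
        .data$cpg_read_fraction > min_cpg_fraction,
      reasons = purrr::map2_chr(
        .data$total_reads, .data$cpg_read_fraction,
        function(tr, cf) {
          r <- c(
            if (tr <= min_total_reads) sprintf("total_reads %s <= %s", format(tr), format(min_total_reads)),
            if (cf <= min_cpg_fraction) sprintf("cpg_read_fraction %.3f <= %.3f", cf, min_cpg_fraction)
          )
          paste(r, collapse = "; ")
        }
      )
    )
}
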