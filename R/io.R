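# Plain-text interchange: BED for intervals, TSV for count and score
# matrices, JSON for QC reports. Comment lines starting with '#' carry
# provenance (seed, parameters) and are skipped on read.

#' Write genomic intervals as BED
#'
#' Writes 0-based half-open intervals with the region class or DMR direction
#' in the name column; DMR sets additionally carry -log10(p), direction,
#' site count and fold change in BED6+ columns.
#'
#' @param x A region tibble (region_id/class) or [call_dmrs()] result.
#' @param path Output file.
#' @param header Optional provenance string written as a leading `#` comment.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, header = NULL) {
  assert_columns(x, c("chrom", "start", "end"), "x")
  is_dmr <- all(c("n_sites", "fold_change", "direction", "min_p_adj") %in% names(x))
  df <- if (is_dmr) {
    data.frame(
      chrom = x$chrom, start = x$start, end = x$end,
      name = sprintf("dmr_%03d", seq_len(nrow(x))),
      score = round(-log10(pmax(x$min_p_adj, 1e-300)), 3),
      strand = ".",
      direction = x$direction, n_sites = x$n_sites,
      fold_change = signif(x$fold_change, 6),
      classes = if ("annotation" %in% names(x)) x$annotation else ".",
      check.names = FALSE
    )
  } else {
    data.frame(
      chrom = x$chrom, start = x$start, end = x$end,
      name = if ("region_id" %in% names(x)) x$region_id else ".",
      score = 0, strand = ".",
      class = if ("class" %in% names(x)) x$class else ".",
      check.names = FALSE
    )
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' @param path BED file (3+ columns, `#` comments skipped).
#' @return Tibble (chrom, start, end, region_id, class when present).
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  out <- tibble(chrom = df[[1]], start = as.integer(df[[2]]),
                end = as.integer(df[[3]]))
  if (ncol(df) >= 4) out$region_id <- df[[4]]
  if (ncol(df) >= 7) out$class <- df[[7]]
  out
}

#' Write a site-count table as TSV
#'
#' Rows are sites (`chrom:pos`), columns samples; a `#` header carries
#' provenance.
#'
#' @param counts Long count tibble (chrom, pos, sample, count).
#' @param path Output file.
#' @param header Optional provenance string.
#' @return `path`, invisibly.
#' @export
write_site_counts <- function(counts, path, header = NULL) {
  assert_columns(counts, c("chrom", "pos", "sample", "count"), "counts")
  wide <- counts |>
    mutate(site = paste0(.data$chrom, ":", .data$pos)) |>
    select("site", "sample", "count") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "count",
                       values_fill = 0L)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(as.data.frame(wide), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a site-count TSV (e.g. from an external pipeline)
#'
#' Inverse of [write_site_counts()]: accepts any TSV whose first column is
#' `chrom:pos` site keys and remaining columns are per-sample counts.
#'
#' @param path TSV file.
#' @param groups Optional named vector mapping sample -> group, added as a
#'   `group` column.
#' @return Long count tibble (chrom, pos, sample, count).
#' @export
read_site_counts <- function(path, groups = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  key <- strsplit(df[[1]], ":", fixed = TRUE)
  long <- as_tibble(df[-1]) |>
    mutate(chrom = vapply(key, `[`, character(1), 1),
           pos = as.integer(vapply(key, `[`, character(1), 2))) |>
    tidyr::pivot_longer(cols = -c("chrom", "pos"),
                        names_to = "sample", values_to = "count") |>
    mutate(count = as.integer(.data$count)) |>
    arrange(.data$sample, .data$chrom, .data$pos)
  if (!is.null(groups)) long$group <- unname(groups[long$sample])
  class(long) <- c("medseq_counts", class(long))
  long
}

#' Write a QC report as JSON
#'
#' @param qc A [qc_sample()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_qc_json <- function(qc, path) {
  assert_columns(qc, c("sample", "pass"), "qc")
  jsonlite::write_json(qc, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a long-format qMSP table
#'
#' @param path CSV or TSV with columns sample, marker, ct_target,
#'   ct_reference and optionally group (delimiter inferred from the
#'   extension; `.csv` = comma).
#' @return Tibble ready for [qmsp_levels()].
#' @export
read_qmsp <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  out <- readr::read_delim(path, delim = delim, comment = "#",
                           show_col_types = FALSE)
  assert_columns(out, c("sample", "marker", "ct_target", "ct_reference"),
                 "qMSP table")
  out
}
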