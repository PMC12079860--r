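# Shared fixture builders. Everything is generated in code; no files.

# A minimal genome-like annotation list accepted by define_regions() etc.
toy_annotation <- function() {
  list(
    chromosomes = tibble::tibble(chrom = "chr1", length = 20000L),
    genes = tibble::tibble(
      gene_id = c("gplus", "gminus"),
      chrom = "chr1",
      strand = c("+", "-"),
      tss = c(5000L, 19000L),
      tes = c(9000L, 15000L)
    ),
    cpg_islands = tibble::tibble(
      island_id = "cgi1", chrom = "chr1", start = 4500L, end = 5200L
    )
  )
}

# Hand-built per-site test table with the attributes call_dmrs() expects.
make_site_tests <- function(pos, p_value, direction,
                            case_count = 1000, control_count = 500,
                            chrom = "chr1",
                            totals = c(case = 1e6, control = 1e6)) {
  out <- tibble::tibble(
    chrom = chrom, pos = as.integer(pos),
    case_count = rep_len(case_count, length(pos)),
    control_count = rep_len(control_count, length(pos)),
    case_rpm = 1e6 * rep_len(case_count, length(pos)) / totals[["case"]],
    control_rpm = 1e6 * rep_len(control_count, length(pos)) / totals[["control"]],
    statistic = NA_real_,
    p_value = rep_len(p_value, length(pos)),
    direction = rep_len(direction, length(pos))
  )
  attr(out, "group_totals") <- totals
  class(out) <- c("medseq_site_tests", class(out))
  out
}

# Long count tibble encoding one 2x2 table per site pair:
# site 1 holds (a, c), site 2 the complements (b, d).
counts_for_table <- function(a, b, c_, d) {
  tibble::tibble(
    chrom = "chr1",
    pos = rep(c(100L, 200L), times = 2),
    sample = rep(c("case_1", "ctrl_1"), each = 2),
    group = rep(c("case", "ctrl"), each = 2),
    count = c(a, b, c_, d)
  )
}
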