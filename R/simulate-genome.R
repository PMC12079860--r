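#' Generate a toy annotated genome with LpnPI sites
#'
#' Builds a small stand-in for a reference genome plus UCSC-style annotation:
#' chromosome lengths, gene models (TSS/TES with strand), CpG islands, and the
#' ordered positions of CpG-containing LpnPI recognition sites that form the
#' coordinate system for all downstream counting. Sites are placed as point
#' positions (one per simulated CpG); the callers consume positions only, so
#' the recognition motif itself is not modelled.
#'
#' Genes and islands are drawn as Poisson counts around `density * length`,
#' so realised numbers vary around the expectation. LpnPI sites are placed
#' uniformly at `site_density` per kb genome-wide, with a `island_site_boost`-fold
#' enrichment inside CpG islands (islands are CpG dense by definition).
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp (>= 10 kb).
#' @param gene_density Expected genes per Mb (> 0).
#' @param island_density Expected CpG islands per Mb (> 0).
#' @param site_density Expected LpnPI sites per kb outside islands.
#' @param island_site_boost Fold enrichment of site density inside islands.
#' @param seed Integer RNG seed (mandatory; the generator never touches the
#'   caller's RNG state).
#'
#' @return An object of class `medseq_genome`: a list of tibbles
#'   `chromosomes` (chrom, length), `genes` (gene_id, chrom, strand, tss, tes),
#'   `cpg_islands` (island_id, chrom, start, end; 0-based half-open) and
#'   `sites` (chrom, pos), sorted by coordinate.
#'
#' @examples
#' gn <- generate_genome(n_chroms = 1, chrom_length = 1e5, seed = 1)
#' nrow(gn$sites)
#' @export
generate_genome <- function(n_chroms = 1,
                            chrom_length = 1e6,
                            gene_density = 50,
                            island_density = 10,
                            site_density = 10,
                            island_site_boost = 5,
                            seed) {
  assert_scalar_number(n_chroms, "n_chroms", lower = 1)
  assert_scalar_number(chrom_length, "chrom_length", lower = 1e4)
  assert_scalar_number(site_density, "site_density")
  assert_scalar_number(island_site_boost, "island_site_boost", lower = 1)
  if (!is.numeric(gene_density) || gene_density <= 0) {
    stop_medseqr("`gene_density` must be > 0: no gene is placeable otherwise.",
      class = "medseqr_no_gene_error")
  }
  if (!is.numeric(island_density) || island_density <= 0) {
    stop_medseqr("`island_density` must be > 0.")
  }
  # genes need room for a body beyond the default 1 kb TSS flank
  min_span <- 3000
  if (chrom_length < min_span + 2000) {
    stop_medseqr("Chromosome too short to host any gene.",
      class = "medseqr_no_gene_error")
  }

  with_seed(seed, {
    chroms <- tibble(
      chrom = sprintf("chr%d", seq_len(n_chroms)),
      length = as.integer(chrom_length)
    )

    genes <- purrr::map_dfr(chroms$chrom, function(ch) {
      n_genes <- rpois(1, gene_density * chrom_length / 1e6)
      if (n_genes == 0L) {
        return(tibble(
          gene_id = character(), chrom = character(), strand = character(),
          tss = integer(), tes = integer()
        ))
      }
      span <- round(runif(n_genes, min_span, min(20000, chrom_length / 2)))
      strand <- sample(c("+", "-"), n_genes, replace = TRUE)
      anchor <- round(runif(n_genes, 1000, chrom_length - max(span) - 1000))
      tss <- ifelse(strand == "+", anchor, anchor + span)
      tes <- ifelse(strand == "+", anchor + span, anchor)
      tibble(
        gene_id = sprintf("%s_g%03d", ch, seq_len(n_genes)),
        chrom = ch, strand = strand,
        tss = as.integer(tss), tes = as.integer(tes)
      )
    })

    islands <- purrr::map_dfr(chroms$chrom, function(ch) {
      n_isl <- rpois(1, island_density * chrom_length / 1e6)
      if (n_isl == 0L) {
        return(tibble(island_id = character(), chrom = character(),
                      start = integer(), end = integer()))
      }
      len <- round(runif(n_isl, 200, 1500))
      start <- sort(round(runif(n_isl, 0, chrom_length - max(len))))
      end <- start + len
      # enforce non-overlap per chromosome by dropping later overlappers
      keep <- rep(TRUE, n_isl)
      if (n_isl > 1L) {
        hi <- end[1]
        for (i in 2:n_isl) {
          if (start[i] < hi) keep[i] <- FALSE else hi <- end[i]
        }
      }
      tibble(
        island_id = sprintf("%s_cgi%03d", ch, seq_len(sum(keep))),
        chrom = ch,
        start = as.integer(start[keep]), end = as.integer(end[keep])
      )
    })

    sites <- purrr::map_dfr(chroms$chrom, function(ch) {
      n_bg <- rpois(1, site_density * chrom_length / 1000)
      pos <- round(runif(n_bg, 0, chrom_length - 1))
      isl <- islands[islands$chrom == ch, ]
      if (nrow(isl) > 0L) {
        extra_rate <- site_density * (island_site_boost - 1) / 1000
        extra <- purrr::map2(isl$start, isl$end, function(s, e) {
          n_e <- rpois(1, extra_rate * (e - s))
          round(runif(n_e, s, e - 1))
        })
        pos <- c(pos, unlist(extra))
      }
      tibble(chrom = ch, pos = sort(unique(as.integer(pos))))
    })

    structure(
      list(chromosomes = chroms, genes = genes,
           cpg_islands = islands, sites = sites),
      class = "medseq_genome"
    )
  })
}

#' @export
print.medseq_genome <- function(x, ...) {
  cat("<medseq_genome>\n")
  cat(sprintf("  chromosomes: %d (total %s bp)\n",
              nrow(x$chromosomes), format(sum(x$chromosomes$length), big.mark = ",")))
  cat(sprintf("  genes: %d | CpG islands: %d | LpnPI sites: %d\n",
              nrow(x$genes), nrow(x$cpg_islands), nrow(x$sites)))
  invisible(x)
}
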