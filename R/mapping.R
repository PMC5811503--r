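#' Assign SNP P-values to genes by chromosomal proximity
#'
#' Each gene receives the best (minimum) P-value among the SNPs falling
#' within `window` bases of either end of its span. With the gene span
#' `[start, end)` in 0-based half-open coordinates and SNP positions
#' 1-based, a SNP at position `p` is in the window iff
#' `start - window < p <= end + window`. A SNP may fall in the windows of
#' several overlapping genes and is then assigned to all of them. Genes
#' with no SNP in their window get `NA` (they remain in the analysis with
#' neutral GWAS evidence and can still be nominated by the network).
#'
#' @param snps Data frame of SNP records (`chrom`, `pos`, `pvalue`), as
#'   returned by [read_summary_stats()].
#' @param genes Data frame of gene models (`gene_id`, `chrom`, `start`,
#'   `end`), as returned by [read_gene_models()].
#' @param window Non-negative distance in bases (default 10000, i.e. 10 kb).
#' @return A data frame with one row per input gene (order preserved):
#'   `gene_id`, `assigned_pvalue` (`NA` when no SNP in window),
#'   `best_snp_chrom`, `best_snp_pos` (position of the winning SNP; ties on
#'   P broken by smallest position) and `n_snps_in_window`.
#' @export
assign_snps_to_genes <- function(snps, genes, window = 10000) {
  assert_number(window, "window", lower = 0)
  assert_columns(snps, c("chrom", "pos", "pvalue"), "SNP table")
  assert_columns(genes, c("gene_id", "chrom", "start", "end"), "gene table")

  orphan_snp <- setdiff(unique(snps$chrom), unique(genes$chrom))
  orphan_gene <- setdiff(unique(genes$chrom), unique(snps$chrom))
  if (length(orphan_snp) || length(orphan_gene))
    warning("chromosome naming mismatch between SNPs and genes; orphans: ",
            paste(c(orphan_snp, orphan_gene), collapse = ", "), call. = FALSE)

  out <- data.frame(gene_id = genes$gene_id,
                    assigned_pvalue = NA_real_,
                    best_snp_chrom = NA_character_,
                    best_snp_pos = NA_integer_,
                    n_snps_in_window = 0L,
                    stringsAsFactors = FALSE)
  if (nrow(snps) == 0 || nrow(genes) == 0) return(out)

  # windowed gene span in 1-based closed coordinates: [start - window + 1,
  # end + window]; equivalent to the (start - window, end + window] rule on
  # 1-based SNP positions.
  lv <- union(unique(genes$chrom), unique(snps$chrom))
  gene_gr <- GenomicRanges::GRanges(
    factor(genes$chrom, levels = lv),
    IRanges::IRanges(start = pmax(genes$start - window + 1, 1),
                     end = genes$end + window))
  snp_gr <- GenomicRanges::GRanges(factor(snps$chrom, levels = lv),
                                   IRanges::IRanges(snps$pos, snps$pos))
  hits <- GenomicRanges::findOverlaps(gene_gr, snp_gr)
  if (length(hits) == 0) return(out)

  dt <- data.table::data.table(
    g = S4Vectors::queryHits(hits),
    pvalue = snps$pvalue[S4Vectors::subjectHits(hits)],
    pos = snps$pos[S4Vectors::subjectHits(hits)],
    chrom = snps$chrom[S4Vectors::subjectHits(hits)])
  data.table::setorder(dt, g, pvalue, pos)
  best <- dt[, list(pvalue = pvalue[1], pos = pos[1], chrom = chrom[1],
                    n = .N), by = "g"]
  out$assigned_pvalue[best$g] <- best$pvalue
  out$best_snp_chrom[best$g] <- best$chrom
  out$best_snp_pos[best$g] <- as.integer(best$pos)
  out$n_snps_in_window[best$g] <- best$n
  out
}
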