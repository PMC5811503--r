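#' Phenotype-involvement probability from assigned P-values
#'
#' Converts the per-gene assigned P-value into the probability p_j that the
#' gene is involved in the phenotype — the quantity whose excess over 1/2,
#' `2 p_j - 1`, weights the gene's contribution to neighbours in the soft
#' guilt-by-association sum.
#'
#' Two calibrations are available. `"complement"` (default) uses
#' `p = 1 - P`: a gene with overwhelming association (P near 0) donates
#' full weight, one with P = 1/2 donates nothing, and no reference set is
#' needed. `"calibrated"` passes the gene's calibrated GWAS log odds (see
#' [calibrate_gene_log_odds()]) plus the log prior odds of reference
#' membership through the logistic function. Genes without an assigned
#' P-value are neutral (`p = 0.5`) under both modes.
#'
#' @param assignments Data frame from [assign_snps_to_genes()] (needs
#'   `gene_id`, `assigned_pvalue`).
#' @param mode `"complement"` or `"calibrated"`.
#' @param reference Character vector of reference phenotype-associated gene
#'   IDs; required for `mode = "calibrated"`.
#' @param bin_size Rank-bin size for the calibrated mode.
#' @return Named numeric vector of probabilities in \[0, 1\].
#' @export
prob_from_pvalue <- function(assignments, mode = c("complement", "calibrated"),
                             reference = NULL, bin_size = 100) {
  mode <- match.arg(mode)
  assert_columns(assignments, c("gene_id", "assigned_pvalue"), "assignments")
  p <- assignments$assigned_pvalue
  if (mode == "complement") {
    prob <- ifelse(is.na(p), 0.5, 1 - p)
  } else {
    if (is.null(reference))
      stop("mode='calibrated' requires a reference gene set", call. = FALSE)
    lo <- calibrate_gene_log_odds(assignments, reference, bin_size = bin_size)
    npos <- sum(assignments$gene_id %in% reference)
    nneg <- nrow(assignments) - npos
    prior <- log(npos / nneg)
    prob <- plogis(unname(lo[assignments$gene_id]) + prior)
    prob[is.na(p)] <- 0.5
  }
  setNames(prob, assignments$gene_id)
}

#' Calibrated per-gene GWAS log odds
#'
#' Estimates, for each gene, the log odds that it belongs to the reference
#' phenotype-associated set given its GWAS rank — the GWAS evidence term of
#' the naive-Bayes combination. Genes with an assigned P-value are sorted
#' by ascending P and cut into consecutive rank bins of `bin_size` (the
#' last bin may be smaller). Each bin's log-likelihood ratio is
#' `LLR_b = ln[ ((TP_b + 0.5) / (P_tot + 1)) / ((FP_b + 0.5) / (N_tot + 1)) ]`
#' with Jeffreys-style 0.5 pseudocounts, where `TP_b` / `FP_b` count
#' reference / non-reference genes in bin `b` and `P_tot` / `N_tot` are the
#' totals over scored genes. The bin sequence is then made non-increasing
#' in P by weighted isotonic regression (pool-adjacent-violators, weights =
#' bin sizes), so the calibrated evidence never rewards a worse P-value.
#' Genes without an assigned P-value receive 0 (neutral odds).
#'
#' @inheritParams prob_from_pvalue
#' @param reference Character vector of reference gene IDs; must overlap
#'   the scored genes.
#' @param bin_size Number of genes per rank bin (default 100).
#' @return Named numeric vector of log odds (natural log), one per gene in
#'   `assignments`.
#' @export
calibrate_gene_log_odds <- function(assignments, reference, bin_size = 100) {
  assert_columns(assignments, c("gene_id", "assigned_pvalue"), "assignments")
  assert_number(bin_size, "bin_size", lower = 1)
  scored <- assignments[!is.na(assignments$assigned_pvalue), ]
  if (nrow(scored) < 2)
    stop("need at least 2 genes with assigned P-values to calibrate",
         call. = FALSE)
  is_pos <- scored$gene_id %in% reference
  if (!any(is_pos))
    stop("no reference gene has an assigned P-value: check that the ",
         "reference list and the annotation use the same gene identifiers ",
         "(case, transcript suffixes)", call. = FALSE)
  o <- order(scored$assigned_pvalue, scored$gene_id)
  is_pos <- is_pos[o]
  n <- nrow(scored)
  bin <- ceiling(seq_len(n) / bin_size)
  if (max(bin) < 2)
    warning("fewer than 2 rank bins (", n, " scored genes, bin_size ",
            bin_size, "); calibration is a single constant", call. = FALSE)
  tp <- tapply(is_pos, bin, sum)
  size <- tapply(is_pos, bin, length)
  fp <- size - tp
  p_tot <- sum(tp); n_tot <- sum(fp)
  llr <- log(((tp + 0.5) / (p_tot + 1)) / ((fp + 0.5) / (n_tot + 1)))
  llr_iso <- pav_nonincreasing(as.numeric(llr), as.numeric(size))
  gene_lo <- llr_iso[bin]
  out <- setNames(rep(0, nrow(assignments)), assignments$gene_id)
  out[scored$gene_id[o]] <- gene_lo
  out
}

# Weighted isotonic regression onto non-increasing sequences
# (pool-adjacent-violators). Returns the fitted values.
pav_nonincreasing <- function(y, w = rep(1, length(y))) {
  stopifnot(length(y) == length(w), all(w > 0))
  n <- length(y)
  if (n <= 1) return(y)
  # blocks as parallel stacks of (value, weight, count)
  val <- numeric(n); wt <- numeric(n); cnt <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    top <- top + 1L
    val[top] <- y[i]; wt[top] <- w[i]; cnt[top] <- 1L
    while (top > 1L && val[top] > val[top - 1L]) {
      # later block exceeds earlier one: pool (weighted mean)
      wsum <- wt[top] + wt[top - 1L]
      val[top - 1L] <- (val[top] * wt[top] + val[top - 1L] * wt[top - 1L]) / wsum
      wt[top - 1L] <- wsum
      cnt[top - 1L] <- cnt[top - 1L] + cnt[top]
      top <- top - 1L
    }
  }
  rep(val[seq_len(top)], cnt[seq_len(top)])
}

#' Full per-gene GWAS evidence table
#'
#' Convenience wrapper producing the table the boosting and evaluation
#' layers consume: one row per gene with the assigned P-value, the
#' phenotype-involvement probability and the calibrated GWAS log odds.
#' Genes named in `extra_genes` (e.g. network-only or reference-only genes
#' absent from the annotation) are appended with neutral evidence
#' (`assigned_pvalue = NA`, `prob = 0.5`, `log_odds_gwas = 0`).
#'
#' @inheritParams prob_from_pvalue
#' @param extra_genes Additional gene IDs to carry with neutral scores.
#' @return Data frame with columns `gene_id`, `assigned_pvalue`, `prob`,
#'   `log_odds_gwas`.
#' @export
score_genes <- function(assignments, reference = NULL,
                        prob_mode = c("complement", "calibrated"),
                        bin_size = 100, extra_genes = NULL) {
  prob_mode <- match.arg(prob_mode)
  assert_columns(assignments, c("gene_id", "assigned_pvalue"), "assignments")
  extra <- setdiff(unique(extra_genes), assignments$gene_id)
  if (length(extra)) {
    message(length(extra), " gene(s) outside the annotation carried with ",
            "neutral GWAS evidence")
    assignments <- rbind(
      assignments[, c("gene_id", "assigned_pvalue")],
      data.frame(gene_id = extra, assigned_pvalue = NA_real_,
                 stringsAsFactors = FALSE))
  }
  prob <- prob_from_pvalue(assignments, mode = prob_mode,
                           reference = reference, bin_size = bin_size)
  lo <- if (is.null(reference)) {
    warning("no reference set supplied: GWAS log odds set to 0 for all ",
            "genes (ranking will reflect network evidence only)",
            call. = FALSE)
    setNames(rep(0, nrow(assignments)), assignments$gene_id)
  } else {
    calibrate_gene_log_odds(assignments, reference, bin_size = bin_size)
  }
  data.frame(gene_id = assignments$gene_id,
             assigned_pvalue = assignments$assigned_pvalue,
             prob = unname(prob[assignments$gene_id]),
             log_odds_gwas = unname(lo[assignments$gene_id]),
             stringsAsFactors = FALSE)
}
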