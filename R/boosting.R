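#' Select the genes allowed to donate guilt-by-association score
#'
#' Network boosting can inflate hub genes connected to many weakly
#' associated neighbours; restricting the donors to genes whose assigned
#' P-value passes a log10(P) threshold suppresses this artifact. The
#' boundary is inclusive (a gene with log10(P) exactly at the threshold
#' contributes), and genes without an assigned P-value never contribute.
#' Non-contributors still *receive* boosts.
#'
#' @param scores Data frame with `gene_id` and `assigned_pvalue` (e.g. from
#'   [score_genes()]).
#' @param log10p_threshold Threshold on log10(P), e.g. -3.6.
#' @return Character vector of contributor gene IDs.
#' @export
select_contributors <- function(scores, log10p_threshold) {
  assert_number(log10p_threshold, "log10p_threshold")
  assert_columns(scores, c("gene_id", "assigned_pvalue"), "scores")
  p <- scores$assigned_pvalue
  ok <- !is.na(p) & log10(p) <= log10p_threshold + 1e-9
  scores$gene_id[ok]
}

#' Soft guilt-by-association score
#'
#' For each gene i, sums the evidence donated by its network neighbours:
#' `S_i = sum_j (2 p_j - 1) * l_ij` over neighbours j that are in the
#' contributor set and have `2 p_j - 1 > 0`, where `l_ij` is the edge
#' weight. A neutral neighbour (p = 1/2) donates nothing; the sum is
#' therefore always non-negative. Genes absent from the network score 0.
#'
#' @param net A [cofunc_network()].
#' @param probs Named numeric vector of phenotype-involvement probabilities
#'   p_j (see [prob_from_pvalue()]); network nodes missing from `probs`
#'   default to the neutral 0.5.
#' @param contributors Character vector of gene IDs allowed to donate (see
#'   [select_contributors()]).
#' @return Named numeric vector of GBA scores over the union of network
#'   nodes and `names(probs)`.
#' @export
soft_gba <- function(net, probs, contributors) {
  stopifnot(inherits(net, "cofunc_network"))
  if (is.null(names(probs)) && length(probs) > 0)
    stop("`probs` must be a named vector (names = gene IDs)", call. = FALSE)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1))
    stop("`probs` must lie in [0, 1] with no NAs", call. = FALSE)
  universe <- union(net$nodes, names(probs))
  p <- rep(0.5, length(universe))
  p[match(names(probs), universe)] <- unname(probs)
  w <- pmax(2 * p - 1, 0)
  w[!(universe %in% contributors)] <- 0
  s <- as.numeric(network_adjacency(net, universe) %*% w)
  setNames(s, universe)
}

#' Combine network and GWAS evidence (naive Bayes)
#'
#' Under the assumption that the network and the GWAS are conditionally
#' independent given phenotype association, the posterior log odds of
#' association is the sum of the GBA score and the GWAS log odds:
#' `final_score = S_i + log O(i | GWAS)`. The gene universe is the union
#' of both inputs, with neutral defaults (0) for genes present in only one.
#'
#' @param gba Named numeric vector of GBA scores (see [soft_gba()]).
#' @param gwas_log_odds Named numeric vector of per-gene GWAS log odds.
#' @return Data frame sorted by `final_score` descending (ties broken by
#'   `gene_id` ascending) with columns `gene_id`, `gba_score`,
#'   `log_odds_gwas`, `final_score`, `rank`.
#' @export
combine_scores <- function(gba, gwas_log_odds) {
  universe <- union(names(gba), names(gwas_log_odds))
  s <- setNames(rep(0, length(universe)), universe)
  s[names(gba)] <- unname(gba)
  lo <- setNames(rep(0, length(universe)), universe)
  lo[names(gwas_log_odds)] <- unname(gwas_log_odds)
  final <- s + lo
  o <- order(-final, universe)
  data.frame(gene_id = universe[o], gba_score = unname(s[o]),
             log_odds_gwas = unname(lo[o]), final_score = unname(final[o]),
             rank = seq_along(o), stringsAsFactors = FALSE)
}

#' Boost a GWAS gene ranking with the network at one threshold
#'
#' Runs contributor selection, the soft GBA sum and the naive-Bayes
#' combination at a single contributor threshold.
#'
#' @param net A [cofunc_network()].
#' @param scores Per-gene evidence table from [score_genes()] (columns
#'   `gene_id`, `assigned_pvalue`, `prob`, `log_odds_gwas`).
#' @param log10p_threshold Contributor threshold on log10(P).
#' @return Data frame as [combine_scores()], plus `assigned_pvalue` and
#'   `was_contributor`.
#' @export
boost <- function(net, scores, log10p_threshold) {
  assert_columns(scores, c("gene_id", "assigned_pvalue", "prob",
                           "log_odds_gwas"), "scores")
  contributors <- select_contributors(scores, log10p_threshold)
  gba <- soft_gba(net, setNames(scores$prob, scores$gene_id), contributors)
  res <- combine_scores(gba, setNames(scores$log_odds_gwas, scores$gene_id))
  res$assigned_pvalue <- scores$assigned_pvalue[match(res$gene_id,
                                                      scores$gene_id)]
  res$was_contributor <- res$gene_id %in% contributors
  res
}
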