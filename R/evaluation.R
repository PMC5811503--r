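#' Partial AUC before a false-positive-rate cutoff
#'
#' Early-retrieval metric: the area under the ROC curve restricted to
#' FPR in \[0, `fpr_max`\], normalized by `fpr_max` so that a perfect
#' ranking scores 1 and the chance line scores `fpr_max / 2 / fpr_max`
#' (0.025 at the default 5% cutoff). Tied scores are handled as a single
#' block drawn as a diagonal ROC segment — equivalent to averaging over
#' all orderings of the tied genes, and deterministic.
#'
#' @param ranking Either a named numeric vector of scores (higher = better)
#'   or a data frame with `gene_id` and a `final_score` (or `score`)
#'   column, e.g. the output of [boost()]. The evaluation universe is all
#'   ranked genes.
#' @param positives Character vector of reference (positive) gene IDs;
#'   genes not in the ranking are ignored, but at least one must be
#'   present.
#' @param fpr_max Upper FPR bound of the integration, in (0, 1\];
#'   default 0.05.
#' @return A single number in \[0, 1\].
#' @export
partial_auc <- function(ranking, positives, fpr_max = 0.05) {
  assert_number(fpr_max, "fpr_max", lower = 1e-12, upper = 1)
  if (is.data.frame(ranking)) {
    assert_columns(ranking, "gene_id", "ranking")
    col <- intersect(c("final_score", "score"), names(ranking))[1]
    if (is.na(col))
      stop("ranking data frame needs a 'final_score' or 'score' column",
           call. = FALSE)
    score <- setNames(ranking[[col]], ranking$gene_id)
  } else {
    score <- ranking
    if (is.null(names(score)))
      stop("`ranking` must be a named score vector or a data frame",
           call. = FALSE)
  }
  is_pos <- names(score) %in% positives
  if (!any(is_pos))
    stop("none of the ", length(unique(positives)), " positive IDs occurs ",
         "in the ranking (", length(score), " genes): check gene-identifier ",
         "matching (e.g. '", head(positives, 1), "' vs '",
         head(names(score), 1), "')", call. = FALSE)
  pauc_vec(unname(score), is_pos, fpr_max)
}

# Core pAUC on a plain score vector + positive mask. ROC vertices are the
# block boundaries of the score-sorted sequence; the curve is integrated by
# trapezoid over FPR in [0, fpr_max], interpolating linearly into a block
# that straddles the cutoff.
pauc_vec <- function(score, is_pos, fpr_max = 0.05) {
  stopifnot(length(score) == length(is_pos))
  n_pos <- sum(is_pos)
  n_neg <- length(score) - n_pos
  if (n_pos == 0) stop("no positives in the evaluation universe", call. = FALSE)
  if (n_neg == 0) stop("no negatives in the evaluation universe", call. = FALSE)
  o <- order(score, decreasing = TRUE)
  s <- score[o]
  y <- is_pos[o]
  n <- length(s)
  block_end <- which(c(s[-1] != s[-n], TRUE))
  tpr <- c(0, cumsum(y)[block_end] / n_pos)
  fpr <- c(0, cumsum(!y)[block_end] / n_neg)
  k <- length(fpr)
  x0 <- fpr[-k]; x1 <- fpr[-1]
  y0 <- tpr[-k]; y1 <- tpr[-1]
  x1c <- pmin(x1, fpr_max)
  live <- x0 < fpr_max & x1 > x0          # vertical segments add no area
  yc <- y0 + (y1 - y0) * (x1c - x0) / pmax(x1 - x0, .Machine$double.xmin)
  sum(((x1c - x0) * (y0 + yc) / 2)[live]) / fpr_max
}

#' Contributor-threshold grid
#'
#' Arithmetic progression of log10(P) thresholds from `lo` in steps of
#' `step`, excluding values above `hi`. The defaults (-6, -2, 0.3)
#' reproduce the standard 14-point scan grid -6.0, -5.7, ..., -2.1.
#'
#' @param lo,hi Grid bounds on log10(P), `lo < hi`.
#' @param step Positive grid interval.
#' @return Numeric vector of thresholds.
#' @export
build_grid <- function(lo = -6, hi = -2, step = 0.3) {
  assert_number(lo, "lo"); assert_number(hi, "hi")
  assert_number(step, "step", lower = .Machine$double.eps)
  if (lo >= hi) stop("`lo` must be below `hi`", call. = FALSE)
  k <- 0:floor((hi - lo) / step + 1e-9)
  grid <- round(lo + k * step, 9)
  grid <- grid[grid <= hi + 1e-9]
  if (!length(grid)) stop("empty threshold grid", call. = FALSE)
  grid
}

#' Scan contributor thresholds and test boosting against a randomized null
#'
#' For every grid threshold, boosts the ranking on the real network and on
#' `n_random` randomized networks, scoring each by [partial_auc()] against
#' the reference set. The same randomized networks (seeds derived
#' deterministically from `seed` and the replicate index) are reused across
#' all grid points, so differences across thresholds reflect the threshold
#' and not permutation noise. A threshold is called significant when the
#' real network's pAUC exceeds the null mean by more than two null standard
#' deviations. The optimal threshold is the grid point maximizing the real
#' pAUC (earliest on ties); the final ranking is materialized there.
#'
#' @param net A [cofunc_network()].
#' @param scores Per-gene evidence table from [score_genes()].
#' @param reference Character vector of reference phenotype-associated gene
#'   IDs (the positives).
#' @param grid Thresholds from [build_grid()].
#' @param n_random Number of randomized networks for the null (default
#'   100); 0 disables the null band (significance reported as `NA`).
#' @param seed Master seed; required when `n_random > 0`.
#' @param fpr_max FPR cutoff of the partial AUC (default 0.05).
#' @param null_model `"permute"` (node-label permutation, default) or
#'   `"rewire"` (degree-preserving edge swaps); see [randomize_network()].
#' @return A `gwab_scan` object: list with `grid`, `auc_real`,
#'   `auc_random_mean`, `auc_random_sd`, `significant`, `auc_gwas_only`,
#'   `optimal_threshold`, `final_ranking` (a [boost()] table with an
#'   `is_reference` column), and the scan settings.
#' @export
run_scan <- function(net, scores, reference, grid = build_grid(),
                     n_random = 100, seed = NULL, fpr_max = 0.05,
                     null_model = c("permute", "rewire")) {
  stopifnot(inherits(net, "cofunc_network"))
  null_model <- match.arg(null_model)
  assert_number(n_random, "n_random", lower = 0)
  assert_columns(scores, c("gene_id", "assigned_pvalue", "prob",
                           "log_odds_gwas"), "scores")
  if (n_random > 0 && is.null(seed))
    stop("`seed` is required when n_random > 0 (the null must be ",
         "reproducible)", call. = FALSE)
  if (!length(grid)) stop("empty threshold grid", call. = FALSE)
  reference <- unique(reference)

  # evaluation universe: annotation/GWAS genes + network nodes + reference
  universe <- union(scores$gene_id, union(net$nodes, reference))
  extra <- setdiff(universe, scores$gene_id)
  if (length(extra))
    scores <- rbind(scores,
                    data.frame(gene_id = extra, assigned_pvalue = NA_real_,
                               prob = 0.5, log_odds_gwas = 0,
                               stringsAsFactors = FALSE))
  prob <- scores$prob
  lo_vec <- scores$log_odds_gwas
  pos_mask <- scores$gene_id %in% reference
  if (!any(pos_mask))
    stop("no reference gene in the evaluation universe: check ID matching",
         call. = FALSE)

  A_real <- network_adjacency(net, scores$gene_id)
  A_rand <- lapply(seq_len(n_random), function(r)
    network_adjacency(randomize_network(net, derive_seed(seed, r),
                                        method = null_model),
                      scores$gene_id))

  auc_gwas_only <- pauc_vec(lo_vec, pos_mask, fpr_max)

  n_grid <- length(grid)
  auc_real <- numeric(n_grid)
  auc_rand_mean <- rep(NA_real_, n_grid)
  auc_rand_sd <- rep(NA_real_, n_grid)
  base_w <- pmax(2 * prob - 1, 0)
  logp <- suppressWarnings(log10(scores$assigned_pvalue))
  for (g in seq_len(n_grid)) {
    w <- base_w
    w[is.na(logp) | logp > grid[g] + 1e-9] <- 0
    auc_real[g] <- pauc_vec(as.numeric(A_real %*% w) + lo_vec, pos_mask,
                            fpr_max)
    if (n_random > 0) {
      aucs <- vapply(A_rand, function(A)
        pauc_vec(as.numeric(A %*% w) + lo_vec, pos_mask, fpr_max), 0)
      auc_rand_mean[g] <- mean(aucs)
      auc_rand_sd[g] <- if (n_random > 1) sd(aucs) else NA_real_
    }
  }
  significant <- auc_real > auc_rand_mean + 2 * auc_rand_sd
  optimal <- grid[which.max(auc_real)]
  final <- boost(net, scores, optimal)
  final$is_reference <- final$gene_id %in% reference

  structure(list(
    grid = grid, auc_real = auc_real, auc_random_mean = auc_rand_mean,
    auc_random_sd = auc_rand_sd, significant = significant,
    auc_gwas_only = auc_gwas_only, optimal_threshold = optimal,
    final_ranking = final, n_random = as.integer(n_random),
    fpr_max = fpr_max, null_model = null_model, seed = seed
  ), class = "gwab_scan")
}

#' @export
print.gwab_scan <- function(x, ...) {
  cat(sprintf("threshold scan: %d grid points in [%.3g, %.3g], %d randomized networks (%s null)\n",
              length(x$grid), min(x$grid), max(x$grid), x$n_random,
              x$null_model))
  cat(sprintf("pAUC(<%.3g%% FPR): GWAS-only %.4f; best boosted %.4f at log10(P) <= %.2f\n",
              100 * x$fpr_max, x$auc_gwas_only, max(x$auc_real),
              x$optimal_threshold))
  i <- which.max(x$auc_real)
  if (x$n_random > 1)
    cat(sprintf("null at optimum: %.4f +/- %.4f (2-SD band); significant at %d/%d thresholds\n",
                x$auc_random_mean[i], x$auc_random_sd[i],
                sum(x$significant, na.rm = TRUE), length(x$grid)))
  invisible(x)
}

#' Plot-ready scan curves
#'
#' Long-form data for drawing the scan figure: the boosted pAUC curve, the
#' flat GWAS-only baseline and the randomized-network 2-SD band, per grid
#' threshold.
#'
#' @param scan A `gwab_scan` object.
#' @return Data frame with `log10p_threshold`, `auc_real`, `auc_gwas_only`,
#'   `auc_random_mean`, `auc_random_sd`, `band_lo`, `band_hi`,
#'   `significant`, `optimal`.
#' @export
scan_curves <- function(scan) {
  stopifnot(inherits(scan, "gwab_scan"))
  data.frame(
    log10p_threshold = scan$grid,
    auc_real = scan$auc_real,
    auc_gwas_only = scan$auc_gwas_only,
    auc_random_mean = scan$auc_random_mean,
    auc_random_sd = scan$auc_random_sd,
    band_lo = scan$auc_random_mean - 2 * scan$auc_random_sd,
    band_hi = scan$auc_random_mean + 2 * scan$auc_random_sd,
    significant = scan$significant,
    optimal = scan$grid == scan$optimal_threshold,
    stringsAsFactors = FALSE
  )
}
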