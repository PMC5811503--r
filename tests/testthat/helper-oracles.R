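# Independent brute-force oracles used to validate the package's
# vectorized / sparse implementations, plus small fixture builders.
# Oracles deliberately use naive all-pairs / all-thresholds loops.

# soft GBA by dense all-pairs accumulation over an edge data frame
brute_gba <- function(edges, probs, contributors) {
  genes <- sort(union(names(probs), unique(c(edges$gene_a, edges$gene_b))))
  n <- length(genes)
  W <- matrix(0, n, n, dimnames = list(genes, genes))
  for (k in seq_len(nrow(edges))) {
    i <- edges$gene_a[k]; j <- edges$gene_b[k]
    W[i, j] <- W[j, i] <- edges$weight[k]
  }
  p <- setNames(rep(0.5, n), genes)
  p[names(probs)] <- probs
  elig <- (genes %in% contributors) & (2 * p - 1 > 0)
  s <- setNames(numeric(n), genes)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) {
      if (W[i, j] != 0 && elig[j]) acc <- acc + (2 * p[j] - 1) * W[i, j]
    }
    s[i] <- acc
  }
  s
}

# partial AUC by explicit enumeration of ROC vertices at every distinct
# score threshold, trapezoid-integrated up to fpr_max
brute_pauc <- function(score, is_pos, fpr_max = 0.05) {
  P <- sum(is_pos); N <- sum(!is_pos)
  th <- sort(unique(score), decreasing = TRUE)
  tpr <- c(0, vapply(th, function(t) sum(is_pos & score >= t), 0) / P)
  fpr <- c(0, vapply(th, function(t) sum(!is_pos & score >= t), 0) / N)
  area <- 0
  for (k in 2:length(fpr)) {
    x0 <- fpr[k - 1]; x1 <- fpr[k]; y0 <- tpr[k - 1]; y1 <- tpr[k]
    if (x1 <= fpr_max) {
      area <- area + (x1 - x0) * (y0 + y1) / 2
    } else if (x0 < fpr_max) {
      yc <- y0 + (y1 - y0) * (fpr_max - x0) / (x1 - x0)
      area <- area + (fpr_max - x0) * (y0 + yc) / 2
      break
    } else break
  }
  area / fpr_max
}

# SNP-to-gene assignment by scanning every (SNP, gene) pair
brute_assign <- function(snps, genes, window) {
  out <- data.frame(gene_id = genes$gene_id, assigned_pvalue = NA_real_,
                    n_snps_in_window = 0L, stringsAsFactors = FALSE)
  for (g in seq_len(nrow(genes))) {
    inw <- snps$chrom == genes$chrom[g] &
      snps$pos > genes$start[g] - window &
      snps$pos <= genes$end[g] + window
    out$n_snps_in_window[g] <- sum(inw)
    if (any(inw)) out$assigned_pvalue[g] <- min(snps$pvalue[inw])
  }
  out
}

# weighted non-increasing isotonic fit by the minimax characterization:
# fit_i = max over blocks ending at/after i ... computed by negating and
# using the classic min-max formula for non-decreasing regression
brute_isotonic_nonincreasing <- function(y, w) {
  z <- -y
  n <- length(z)
  wmean <- function(s, t) sum(z[s:t] * w[s:t]) / sum(w[s:t])
  fit <- numeric(n)
  for (i in seq_len(n)) {
    # non-decreasing fit_i = max_{s <= i} min_{t >= i} mean(z[s..t])
    best <- -Inf
    for (s in 1:i) {
      m <- Inf
      for (t in i:n) m <- min(m, wmean(s, t))
      best <- max(best, m)
    }
    fit[i] <- best
  }
  -fit
}

# a small deterministic random weighted network as an edge data frame
random_edges <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  genes <- sprintf("N%03d", seq_len(n_nodes))
  pairs <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
  take <- pairs[sample.int(nrow(pairs), min(n_edges, nrow(pairs))), ,
                drop = FALSE]
  data.frame(gene_a = genes[take[, 1]], gene_b = genes[take[, 2]],
             weight = round(runif(nrow(take), 0.1, 3), 3),
             stringsAsFactors = FALSE)
}

# generate a bundle, read it back through the io layer and scan it —
# the canonical end-to-end path shared by several tests
scan_bundle <- function(seed, n_random = 100, ...) {
  d <- tempfile("bundle")
  on.exit(unlink(d, recursive = TRUE))
  b <- simulate_bundle(d, seed = seed, ...)
  snps <- read_summary_stats(b$paths$snps)
  genes <- read_gene_models(b$paths$genes)
  net <- suppressMessages(load_network(b$paths$network))
  ref <- read_gene_list(b$paths$reference)
  assignments <- assign_snps_to_genes(snps, genes)
  scores <- suppressMessages(
    score_genes(assignments, reference = ref,
                extra_genes = union(net$nodes, ref)))
  run_scan(net, scores, ref, n_random = n_random, seed = seed)
}
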