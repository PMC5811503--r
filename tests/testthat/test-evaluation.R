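test_that("partial AUC handles perfect, worst and all-tied rankings", {
  genes <- sprintf("G%03d", 1:100)
  pos <- genes[1:10]
  perfect <- setNames(seq(100, 1), genes)
  expect_equal(partial_auc(perfect, pos), 1.0)
  worst <- setNames(seq_len(100), genes)   # positives at the bottom
  expect_equal(partial_auc(worst, pos), 0.0)
  tied <- setNames(rep(1, 100), genes)
  expect_equal(partial_auc(tied, pos), 0.025)  # fpr_max / 2 normalized
  expect_equal(partial_auc(tied, pos, fpr_max = 1), 0.5)
})

test_that("worked 10-gene example matches explicit ROC enumeration", {
  genes <- letters[1:10]
  score <- setNames(10:1, genes)
  pos <- genes[c(1, 4, 9)]
  is_pos <- genes %in% pos
  expect_equal(partial_auc(score, pos, fpr_max = 0.5),
               brute_pauc(unname(score), is_pos, fpr_max = 0.5))
  expect_equal(partial_auc(score, pos, fpr_max = 1),
               brute_pauc(unname(score), is_pos, fpr_max = 1))
})

test_that("partial AUC equals brute-force ROC enumeration with ties", {
  set.seed(2024)
  for (rep in 1:60) {
    n <- sample(5:200, 1)
    # injected ties: scores drawn from a small support
    score <- sample(seq_len(sample(c(3, 10, n), 1)), n, replace = TRUE) +
      round(runif(n), 2)
    npos <- sample.int(n - 1, 1)
    is_pos <- seq_len(n) %in% sample.int(n, npos)
    genes <- sprintf("g%03d", seq_len(n))
    fpr_max <- sample(c(0.05, 0.2, 1), 1)
    got <- partial_auc(setNames(score, genes), genes[is_pos], fpr_max)
    expect_equal(got, brute_pauc(score, is_pos, fpr_max), tolerance = 1e-12)
    expect_gte(got, 0); expect_lte(got, 1)
  }
})

test_that("partial AUC is invariant under monotone score transforms", {
  set.seed(8)
  genes <- sprintf("g%02d", 1:50)
  score <- setNames(rnorm(50), genes)
  pos <- sample(genes, 8)
  base <- partial_auc(score, pos)
  expect_equal(partial_auc(exp(score), pos), base)
  expect_equal(partial_auc(rank(score), pos), base)
  expect_equal(partial_auc(score * 100 - 3, pos), base)
})

test_that("full-range AUC agrees with the rank-sum statistic", {
  set.seed(9)
  genes <- sprintf("g%03d", 1:120)
  score <- setNames(rnorm(120), genes)
  pos <- sample(genes, 30)
  is_pos <- genes %in% pos
  u <- wilcox.test(score[is_pos], score[!is_pos], exact = FALSE)$statistic
  expect_equal(partial_auc(score, pos, fpr_max = 1),
               unname(u) / (30 * 90))
})

test_that("threshold grids form the documented arithmetic progression", {
  g <- build_grid()
  expect_length(g, 14)
  expect_equal(g[1], -6.0)
  expect_equal(g[14], -2.1)
  expect_equal(g, seq(-6, -2.1, by = 0.3))
  expect_equal(build_grid(-3, -2.7, 0.3), c(-3, -2.7))
  expect_equal(build_grid(-5, -4, 2), -5)        # step overshoots hi
  expect_error(build_grid(-2, -6, 0.3), "lo")
  expect_error(build_grid(-3, -2, -1), "step")
})

test_that("scan on positionally independent scores shows no boost signal", {
  # neutral probabilities: no gene can donate, so real and null coincide
  set.seed(21)
  edges <- random_edges(60, 200, seed = 22)
  net <- cofunc_network(edges, warn = FALSE)
  genes <- sprintf("N%03d", 1:60)
  sc <- data.frame(gene_id = genes, assigned_pvalue = runif(60),
                   prob = 0.5, log_odds_gwas = rnorm(60),
                   stringsAsFactors = FALSE)
  ref <- sample(genes, 10)
  scan <- run_scan(net, sc, ref, grid = build_grid(-4, -2, 1),
                   n_random = 10, seed = 3)
  expect_equal(scan$auc_real, scan$auc_random_mean)
  expect_true(all(scan$auc_random_sd == 0))
  expect_false(any(scan$significant))
  expect_equal(scan$auc_real, rep(scan$auc_gwas_only, length(scan$grid)))
})

test_that("scan without a null band still selects the optimum", {
  set.seed(33)
  edges <- random_edges(40, 120, seed = 34)
  net <- cofunc_network(edges, warn = FALSE)
  genes <- sprintf("N%03d", 1:40)
  sc <- data.frame(gene_id = genes, assigned_pvalue = 10^-runif(40, 0, 5),
                   prob = runif(40), log_odds_gwas = rnorm(40),
                   stringsAsFactors = FALSE)
  ref <- sample(genes, 8)
  scan <- run_scan(net, sc, ref, n_random = 0)
  expect_true(all(is.na(scan$significant)))
  expect_true(all(is.na(scan$auc_random_mean)))
  expect_true(scan$optimal_threshold %in% scan$grid)
  expect_equal(max(scan$auc_real),
               scan$auc_real[match(scan$optimal_threshold, scan$grid)])
  # earliest grid point wins ties
  expect_equal(scan$optimal_threshold,
               scan$grid[which.max(scan$auc_real)])
  # seed is mandatory once a null is requested
  expect_error(run_scan(net, sc, ref, n_random = 5), "seed")
})

test_that("scans are bit-reproducible for a fixed master seed", {
  set.seed(44)
  edges <- random_edges(50, 150, seed = 45)
  net <- cofunc_network(edges, warn = FALSE)
  genes <- sprintf("N%03d", 1:50)
  sc <- data.frame(gene_id = genes, assigned_pvalue = 10^-runif(50, 0, 5),
                   prob = runif(50), log_odds_gwas = rnorm(50),
                   stringsAsFactors = FALSE)
  ref <- sample(genes, 10)
  s1 <- run_scan(net, sc, ref, n_random = 15, seed = 7)
  s2 <- run_scan(net, sc, ref, n_random = 15, seed = 7)
  expect_identical(s1, s2)
  s3 <- run_scan(net, sc, ref, n_random = 15, seed = 8)
  expect_false(identical(s1$auc_random_mean, s3$auc_random_mean))
})

test_that("scan curves expose the null band and optimum for plotting", {
  set.seed(55)
  edges <- random_edges(30, 80, seed = 56)
  net <- cofunc_network(edges, warn = FALSE)
  genes <- sprintf("N%03d", 1:30)
  sc <- data.frame(gene_id = genes, assigned_pvalue = 10^-runif(30, 0, 4),
                   prob = runif(30), log_odds_gwas = rnorm(30),
                   stringsAsFactors = FALSE)
  scan <- run_scan(net, sc, sample(genes, 6), n_random = 8, seed = 2)
  cur <- scan_curves(scan)
  expect_equal(nrow(cur), length(scan$grid))
  expect_equal(cur$band_hi, cur$auc_random_mean + 2 * cur$auc_random_sd)
  expect_equal(sum(cur$optimal), 1)
  expect_equal(cur$log10p_threshold[cur$optimal], scan$optimal_threshold)
})
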