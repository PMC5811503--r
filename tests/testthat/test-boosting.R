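test_that("contributor selection is inclusive at the threshold", {
  sc <- data.frame(gene_id = c("A", "B", "C", "D"),
                   assigned_pvalue = c(1e-4, 1e-3, 1e-2, NA),
                   stringsAsFactors = FALSE)
  expect_setequal(select_contributors(sc, -3), c("A", "B"))
  expect_setequal(select_contributors(sc, -2), c("A", "B", "C"))
  expect_length(select_contributors(sc, -6), 0)
  # missing P never contributes
  expect_false("D" %in% select_contributors(sc, 0))
})

test_that("soft GBA reproduces hand-computed examples", {
  # all-neutral probabilities give zero everywhere
  net <- cofunc_network(data.frame(gene_a = "A", gene_b = "B", weight = 1.5))
  p <- c(A = 0.5, B = 0.5)
  expect_equal(unname(soft_gba(net, p, c("A", "B"))), c(0, 0))

  # single edge, full-confidence contributor: S_A = (2*1 - 1) * 1.5
  p2 <- c(A = 0.5, B = 1.0)
  s <- soft_gba(net, p2, "B")
  expect_equal(s[["A"]], 1.5)
  expect_equal(s[["B"]], 0)  # A is not a contributor

  # star: hub with 10 leaves, leaves contribute 0.6 * 2.0 each
  leaves <- sprintf("L%02d", 1:10)
  star <- cofunc_network(data.frame(gene_a = "HUB", gene_b = leaves,
                                    weight = 2.0))
  probs <- c(setNames(rep(0.8, 10), leaves), HUB = 0.8)
  s1 <- soft_gba(star, probs, leaves)
  expect_equal(s1[["HUB"]], 10 * 0.6 * 2.0)
  expect_equal(unname(s1[leaves]), rep(0, 10))  # hub not a contributor
  s2 <- soft_gba(star, probs, c(leaves, "HUB"))
  expect_equal(unname(s2[leaves]), rep(0.6 * 2.0, 10))
  expect_equal(s1[["HUB"]], brute_gba(star$edges, probs, leaves)[["HUB"]])
})

test_that("sparse GBA equals the dense all-pairs brute force", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(10:60, 1)
    edges <- random_edges(n, sample(10:150, 1), seed = seed + 1000)
    net <- cofunc_network(edges, warn = FALSE)
    probs <- setNames(runif(n), sprintf("N%03d", 1:n))
    contributors <- sample(names(probs), sample.int(n, 1))
    got <- soft_gba(net, probs, contributors)
    want <- brute_gba(net$edges, probs, contributors)
    expect_equal(got[sort(names(got))], want[sort(names(want))],
                 tolerance = 1e-14)
  }
})

test_that("GBA is monotone in neighbour probability and edge addition", {
  edges <- random_edges(20, 50, seed = 4)
  net <- cofunc_network(edges, warn = FALSE)
  probs <- setNames(runif(20, 0.5, 1), sprintf("N%03d", 1:20))
  contributors <- names(probs)[1:10]
  s0 <- soft_gba(net, probs, contributors)
  # raising a contributor's p never decreases any other gene's score
  probs2 <- probs
  probs2["N001"] <- min(1, probs["N001"] + 0.3)
  s1 <- soft_gba(net, probs2, contributors)
  other <- setdiff(names(s0), "N001")
  expect_true(all(s1[other] >= s0[other] - 1e-14))
  # adding an edge to an eligible contributor never decreases the endpoint
  new_edge <- data.frame(gene_a = "N001", gene_b = "N020", weight = 9)
  if (!any(net$edges$gene_a == "N001" & net$edges$gene_b == "N020")) {
    net2 <- cofunc_network(rbind(net$edges, new_edge), warn = FALSE)
    s2 <- soft_gba(net2, probs, contributors)
    expect_gte(s2[["N020"]], s0[["N020"]])
  }
})

test_that("contributor sets grow as the threshold relaxes", {
  set.seed(12)
  sc <- data.frame(gene_id = sprintf("G%03d", 1:200),
                   assigned_pvalue = 10^-runif(200, 0, 7),
                   stringsAsFactors = FALSE)
  grid <- build_grid()
  sets <- lapply(grid, function(t) select_contributors(sc, t))
  for (k in 2:length(sets))
    expect_true(all(sets[[k - 1]] %in% sets[[k]]))
})

test_that("naive-Bayes combination is an exact sum with deterministic order", {
  res <- combine_scores(c(A = 2, B = 0, D = 4), c(A = 1, B = 3, C = 3))
  expect_equal(res$final_score, res$gba_score + res$log_odds_gwas)
  expect_equal(res$gene_id, c("D", "A", "B", "C"))  # three-way tie by gene_id
  expect_equal(res$final_score, c(4, 3, 3, 3))
  expect_equal(res$rank, 1:4)
  # network-only gene: final score is the GBA score plus neutral 0
  expect_equal(res[res$gene_id == "D", "final_score"], 4)
})

test_that("an empty contributor set reduces boost to the GWAS-only ranking", {
  set.seed(5)
  edges <- random_edges(40, 100, seed = 6)
  net <- cofunc_network(edges, warn = FALSE)
  sc <- data.frame(gene_id = sprintf("N%03d", 1:40),
                   assigned_pvalue = runif(40, 0.1, 1),
                   prob = runif(40),
                   log_odds_gwas = rnorm(40), stringsAsFactors = FALSE)
  res <- boost(net, sc, -6)  # best P is 0.1: nobody passes
  expect_true(all(res$gba_score == 0))
  expect_false(any(res$was_contributor))
  gwas_order <- sc$gene_id[order(-sc$log_odds_gwas, sc$gene_id)]
  expect_equal(res$gene_id, gwas_order)
  expect_equal(res$final_score, sort(sc$log_odds_gwas, decreasing = TRUE))
})
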