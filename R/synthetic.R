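# Create `target` intra-module edges by targeted double-edge swaps:
# (m1, x) + (m2, y) -> (m1, m2) + (x, y), with m1, m2 module genes that are
# not yet adjacent and x, y outside the module. Each weight stays on the
# row of its donor edge, so every gene's degree is preserved exactly and
# incident-weight changes are zero-mean. Returns the modified edge list
# and the number of intra-module edges actually created (the module's own
# degrees bound what is achievable).
plant_module_edges <- function(edges, module_ids, target) {
  a <- edges$gene_a; b <- edges$gene_b
  key <- function(x, y) paste(pmin(x, y), pmax(x, y), sep = "\r")
  have <- new.env(hash = TRUE, parent = emptyenv())
  for (k in key(a, b)) assign(k, TRUE, envir = have)
  in_mod <- function(x) x %in% module_ids
  created <- 0L
  attempts <- 0L
  max_attempts <- 200L * target
  while (created < target && attempts < max_attempts) {
    attempts <- attempts + 1L
    m <- module_ids[sample.int(length(module_ids), 2L)]
    if (exists(key(m[1], m[2]), envir = have)) next
    # an edge from each module gene to a non-module partner
    i_cand <- which((a == m[1] & !in_mod(b)) | (b == m[1] & !in_mod(a)))
    j_cand <- which((a == m[2] & !in_mod(b)) | (b == m[2] & !in_mod(a)))
    if (!length(i_cand) || !length(j_cand)) next
    i <- i_cand[sample.int(length(i_cand), 1L)]
    j <- j_cand[sample.int(length(j_cand), 1L)]
    x <- if (a[i] == m[1]) b[i] else a[i]
    y <- if (a[j] == m[2]) b[j] else a[j]
    if (x == y || exists(key(x, y), envir = have)) next
    rm(list = c(key(a[i], b[i]), key(a[j], b[j])), envir = have)
    a[i] <- m[1]; b[i] <- m[2]
    a[j] <- x; b[j] <- y
    assign(key(m[1], m[2]), TRUE, envir = have)
    assign(key(x, y), TRUE, envir = have)
    created <- created + 1L
  }
  if (created < target)
    message(sprintf("planted %d of %d requested intra-module edges (module degrees exhausted)",
                    created, target))
  list(edges = data.frame(gene_a = a, gene_b = b, weight = edges$weight,
                          stringsAsFactors = FALSE),
       n_created = created)
}

#' Simulate a complete input bundle with a planted phenotype module
#'
#' Generates the four inputs of the pipeline — a weighted gene network, a
#' BED gene annotation, a GWAS summary-statistics table and a reference
#' gene list — with controlled signal structure, and writes them to `dir`.
#'
#' Genes are placed without overlap on one synthetic chromosome. Every SNP
#' carries a null P-value drawn from Uniform(0, 1]. A planted module of
#' `module_size` genes plays the phenotype pathway: a fraction
#' `signal_frac` of its members (the "signal" genes, modelling genetic
#' heterogeneity — only some pathway genes harbour detectable variants)
#' each receive one additional SNP whose -log10 P-value is
#' `2 + Exponential(mean = signal_neglog10p)` (i.e. an exponential of that
#' mean truncated below at 2, so signal P-values never exceed 1e-2). The
#' module is wired densely by *degree-preserving* targeted edge swaps:
#' pairs of existing edges (m1, x), (m2, y) with m1, m2 in the module are
#' replaced by (m1, m2) and (x, y), each weight travelling with its donor
#' edge, until `module_intra_edges` intra-module edges exist. Every gene
#' keeps its exact degree and (in expectation) its incident weight, so the
#' planted module is invisible to any per-gene network statistic — only
#' the wiring *between* module members carries the pathway structure that
#' guilt-by-association can exploit to relay signal from the signal genes
#' to the quiet module members. (Simply adding extra module edges would
#' turn the reference genes into artificial hubs, which the
#' label-permutation null of [run_scan()] detects even without any
#' association signal.) The reference list is the *full* module —
#' including the quiet members that GWAS alone misses and boosting should
#' rescue.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed; bundles are bit-reproducible per seed.
#' @param n_genes,n_snps,genome_length Problem size (defaults 2000 genes,
#'   20000 SNPs on a 30-Mb chromosome, giving realistic SNP density for a
#'   plant GWAS at desk scale).
#' @param network_model `"barabasi_albert"` (scale-free, default — hubby
#'   like real co-functional networks) or `"erdos_renyi"`.
#' @param attach_m Edges per new node for the Barabasi-Albert model
#'   (default 4, mean degree about 8).
#' @param edge_prob Edge probability for the Erdos-Renyi model.
#' @param weight_meanlog,weight_sdlog Log-normal parameters of the edge
#'   weights (log-likelihood-score-like, mostly 1-5).
#' @param module_size Number of planted phenotype genes.
#' @param module_intra_edges Intra-module edges created by degree-preserving
#'   swaps (capped by the module genes' own degrees; a shortfall is
#'   reported in the returned truth).
#' @param signal_frac Fraction of module genes carrying association signal.
#' @param signal_neglog10p Mean of the -log10 P excess for signal SNPs.
#' @param window_placement If `TRUE` (default) the signal SNP lies inside
#'   its gene's span; if `FALSE` it is placed up to 5 kb downstream (still
#'   inside the default 10-kb assignment window).
#' @param chrom Name of the synthetic chromosome.
#' @return Invisibly, a list with `paths` (named: `network`, `genes`,
#'   `snps`, `reference`, `truth`) and `truth` (module members, signal
#'   genes, config). The ground truth is also written as JSON.
#' @export
simulate_bundle <- function(dir, seed,
                            n_genes = 2000, n_snps = 20000,
                            genome_length = 3e7,
                            network_model = c("barabasi_albert",
                                              "erdos_renyi"),
                            attach_m = 4, edge_prob = 0.004,
                            weight_meanlog = 0.5, weight_sdlog = 0.6,
                            module_size = 40, module_intra_edges = 100,
                            signal_frac = 0.4, signal_neglog10p = 5,
                            window_placement = TRUE, chrom = "chrS1") {
  network_model <- match.arg(network_model)
  assert_number(seed, "seed")
  assert_number(signal_frac, "signal_frac", lower = 0, upper = 1)
  if (module_size > n_genes)
    stop("module_size must not exceed n_genes", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  sim <- with_seed(seed, {
    # gene placement: random lengths, random non-overlapping layout
    len <- sample(1000:4000, n_genes, replace = TRUE)
    slack <- genome_length - sum(len)
    if (slack < n_genes)
      stop(sprintf("genes do not fit: need > %d bases, genome_length is %s",
                   sum(len) + n_genes, format(genome_length, scientific = FALSE)),
           call. = FALSE)
    cuts <- sort(sample.int(slack, n_genes))
    start0 <- cuts + c(0, cumsum(len[-n_genes]))
    genes <- data.frame(gene_id = sprintf("G%05d", seq_len(n_genes)),
                        chrom = chrom, start = start0, end = start0 + len,
                        stringsAsFactors = FALSE)

    # null SNPs: uniform positions, P ~ Uniform(0, 1]
    snps <- data.frame(chrom = chrom,
                       pos = sample.int(genome_length, n_snps, replace = TRUE),
                       pvalue = 1 - runif(n_snps), stringsAsFactors = FALSE)

    module_idx <- sample.int(n_genes, module_size)
    n_signal <- round(signal_frac * module_size)
    signal_idx <- module_idx[seq_len(n_signal)]
    if (n_signal > 0) {
      offset <- if (window_placement)
        vapply(len[signal_idx], function(l) sample.int(l, 1), 0L)
      else
        len[signal_idx] + sample.int(5000, n_signal, replace = TRUE)
      sig <- data.frame(chrom = chrom,
                        pos = genes$start[signal_idx] + offset,
                        pvalue = 10^-(2 + rexp(n_signal,
                                               rate = 1 / signal_neglog10p)),
                        stringsAsFactors = FALSE)
      snps <- rbind(snps, sig)
    }
    snps <- snps[order(snps$pos), , drop = FALSE]

    # base network topology + log-normal weights
    g <- if (network_model == "barabasi_albert")
      igraph::sample_pa(n_genes, m = attach_m, directed = FALSE)
    else
      igraph::sample_gnp(n_genes, edge_prob)
    el <- igraph::as_edgelist(g, names = FALSE)
    ew <- rlnorm(nrow(el), weight_meanlog, weight_sdlog)
    edges <- data.frame(gene_a = genes$gene_id[el[, 1]],
                        gene_b = genes$gene_id[el[, 2]],
                        weight = ew, stringsAsFactors = FALSE)

    # dense module wiring by degree-preserving targeted swaps
    module_ids <- genes$gene_id[module_idx]
    n_intra <- 0L
    if (module_intra_edges > 0 && module_size >= 2) {
      sw <- plant_module_edges(edges, module_ids, module_intra_edges)
      edges <- sw$edges
      n_intra <- sw$n_created
    }
    list(genes = genes, snps = snps, edges = edges,
         module = sort(module_ids),
         signal_genes = sort(genes$gene_id[signal_idx]),
         n_intra_created = n_intra)
  })

  net <- cofunc_network(sim$edges, warn = FALSE)
  paths <- list(network = file.path(dir, "network.tsv"),
                genes = file.path(dir, "genes.bed"),
                snps = file.path(dir, "snps.tsv"),
                reference = file.path(dir, "reference.txt"),
                truth = file.path(dir, "ground_truth.json"))
  write_network(net, paths$network)
  data.table::fwrite(sim$genes[, c("chrom", "start", "end", "gene_id")],
                     paths$genes, sep = "\t", col.names = FALSE,
                     quote = FALSE)
  data.table::fwrite(sim$snps, paths$snps, sep = "\t", quote = FALSE)
  writeLines(sim$module, paths$reference)
  truth <- list(seed = seed, module = sim$module,
                signal_genes = sim$signal_genes,
                n_intra_created = sim$n_intra_created,
                config = list(n_genes = n_genes, n_snps = n_snps,
                              genome_length = genome_length,
                              network_model = network_model,
                              attach_m = attach_m, edge_prob = edge_prob,
                              weight_meanlog = weight_meanlog,
                              weight_sdlog = weight_sdlog,
                              module_size = module_size,
                              module_intra_edges = module_intra_edges,
                              signal_frac = signal_frac,
                              signal_neglog10p = signal_neglog10p,
                              window_placement = window_placement,
                              chrom = chrom))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(paths = paths, truth = truth))
}
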