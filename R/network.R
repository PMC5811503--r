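#' Construct a co-functional network from an edge list
#'
#' The network is an undirected weighted graph over gene IDs; edge weights
#' are positive functional-coupling scores (log-likelihood scores in
#' AraNet-style networks). Edges are stored once per unordered pair in
#' canonical orientation (`gene_a < gene_b`); self-loops are dropped and
#' duplicate pairs resolved by keeping the maximum weight.
#'
#' @param edges Data frame with columns `gene_a`, `gene_b`, `weight`.
#' @param warn Emit warnings for dropped self-loops / duplicates?
#' @return An object of class `cofunc_network`: a list with `edges` (the
#'   canonical edge data frame) and `nodes` (sorted unique gene IDs).
#' @export
cofunc_network <- function(edges, warn = TRUE) {
  assert_columns(edges, c("gene_a", "gene_b", "weight"), "network edge list")
  a <- trimws(as.character(edges$gene_a))
  b <- trimws(as.character(edges$gene_b))
  w <- as.numeric(edges$weight)
  if (any(is.na(w)) || any(w <= 0))
    stop("all network edge weights must be strictly positive", call. = FALSE)
  loop <- a == b
  if (any(loop)) {
    if (warn) warning(sum(loop), " self-loop(s) dropped from network",
                      call. = FALSE)
    a <- a[!loop]; b <- b[!loop]; w <- w[!loop]
  }
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key)) {
    if (warn) warning(sum(duplicated(key)),
                      " duplicate edge(s) collapsed (max weight kept)",
                      call. = FALSE)
    dt <- data.table::data.table(a = a, b = b, w = w, key_ = key)
    dt <- dt[, list(a = a[1], b = b[1], w = max(w)), by = "key_"]
    a <- dt$a; b <- dt$b; w <- dt$w
  }
  o <- order(a, b)
  structure(list(
    edges = data.frame(gene_a = a[o], gene_b = b[o], weight = w[o],
                       stringsAsFactors = FALSE),
    nodes = sort(unique(c(a, b)))
  ), class = "cofunc_network")
}

#' @export
print.cofunc_network <- function(x, ...) {
  cat(sprintf("cofunc_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) {
    q <- quantile(x$edges$weight, c(0, .25, .5, .75, 1))
    cat(sprintf("edge weights: min %.3g / median %.3g / max %.3g (total %.4g)\n",
                q[1], q[3], q[5], sum(x$edges$weight)))
  }
  invisible(x)
}

#' Load a co-functional gene network from a 3-column edge list
#'
#' Expects whitespace- or tab-separated lines `geneA geneB weight`. Lines
#' with non-numeric or non-positive weights are skipped with a warning; if
#' more than 10% of lines are unusable the load aborts.
#'
#' @param path Path to the edge-list file.
#' @return A [cofunc_network()] object.
#' @export
load_network <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, header = FALSE, data.table = FALSE,
                          colClasses = "character", fill = TRUE)
  if (ncol(dt) < 3)
    stop("network edge list must have 3 columns (geneA geneB weight)",
         call. = FALSE)
  w <- suppressWarnings(as.numeric(dt[[3]]))
  bad <- is.na(w) | w <= 0 | !nzchar(trimws(dt[[1]])) | !nzchar(trimws(dt[[2]]))
  if (any(bad)) {
    if (sum(bad) > 0.1 * nrow(dt))
      stop(sprintf("%d of %d network lines unusable (>10%%); wrong file or dialect?",
                   sum(bad), nrow(dt)), call. = FALSE)
    warning(sprintf("skipped %d network line(s) with missing IDs or non-positive/non-numeric weights",
                    sum(bad)), call. = FALSE)
  }
  net <- cofunc_network(data.frame(gene_a = dt[[1]][!bad], gene_b = dt[[2]][!bad],
                                   weight = w[!bad], stringsAsFactors = FALSE))
  message(sprintf("network loaded: %d nodes, %d edges, total weight %.4g",
                  length(net$nodes), nrow(net$edges), sum(net$edges$weight)))
  net
}

#' Write a network back to a 3-column edge list
#'
#' @param net A `cofunc_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "cofunc_network"))
  data.table::fwrite(net$edges, path, sep = "\t", col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Randomize a network for the null model
#'
#' The default null (`"permute"`) permutes gene labels over network
#' positions: topology and weights are untouched, so the degree sequence,
#' weight distribution and every other graph invariant are preserved
#' exactly — only the association between gene identity and network
#' position is destroyed, which is precisely the null hypothesis of the
#' boosting-significance test. `"rewire"` instead performs degree-preserving
#' double-edge swaps (10 x |E| attempts), keeping each weight attached to
#' its (rewired) edge; it additionally destroys edge-level structure and is
#' offered for sensitivity analysis.
#'
#' @param net A `cofunc_network`.
#' @param seed Integer seed; required so the null is reproducible — there is
#'   no implicit global-RNG fallback.
#' @param method `"permute"` (default) or `"rewire"`.
#' @return A new `cofunc_network` with the same node set.
#' @export
randomize_network <- function(net, seed, method = c("permute", "rewire")) {
  stopifnot(inherits(net, "cofunc_network"))
  method <- match.arg(method)
  if (missing(seed) || is.null(seed))
    stop("randomize_network() requires an explicit seed", call. = FALSE)
  with_seed(seed, {
    if (method == "permute") {
      # a bijective relabelling cannot create self-loops or duplicates, so
      # the full constructor checks are skipped; only the canonical
      # orientation is restored
      relabel <- setNames(sample(net$nodes), net$nodes)
      a <- unname(relabel[net$edges$gene_a])
      b <- unname(relabel[net$edges$gene_b])
      structure(list(
        edges = data.frame(gene_a = pmin(a, b), gene_b = pmax(a, b),
                           weight = net$edges$weight,
                           stringsAsFactors = FALSE),
        nodes = net$nodes
      ), class = "cofunc_network")
    } else {
      rewire_edges(net)
    }
  })
}

# Double-edge-swap rewiring: pick two edges (a,b),(c,d), replace with
# (a,d),(c,b); reject swaps creating self-loops or multi-edges. Weights
# travel with the row they started on.
rewire_edges <- function(net) {
  e <- net$edges
  m <- nrow(e)
  if (m < 2) return(net)
  a <- e$gene_a; b <- e$gene_b
  have <- new.env(hash = TRUE, parent = emptyenv())
  ekey <- function(x, y) if (x < y) paste(x, y, sep = "\r") else paste(y, x, sep = "\r")
  for (i in seq_len(m)) assign(ekey(a[i], b[i]), TRUE, envir = have)
  n_try <- 10L * m
  pick <- matrix(sample.int(m, 2L * n_try, replace = TRUE), ncol = 2)
  flip <- runif(n_try) < 0.5
  for (t in seq_len(n_try)) {
    i <- pick[t, 1]; j <- pick[t, 2]
    if (i == j) next
    ai <- a[i]; bi <- b[i]; aj <- a[j]; bj <- b[j]
    # two swap orientations; choose one at random
    if (flip[t]) { n1a <- ai; n1b <- bj; n2a <- aj; n2b <- bi }
    else         { n1a <- ai; n1b <- aj; n2a <- bi; n2b <- bj }
    if (n1a == n1b || n2a == n2b) next
    k1 <- ekey(n1a, n1b); k2 <- ekey(n2a, n2b)
    if (k1 == k2 || exists(k1, envir = have) || exists(k2, envir = have)) next
    rm(list = c(ekey(ai, bi), ekey(aj, bj)), envir = have)
    assign(k1, TRUE, envir = have); assign(k2, TRUE, envir = have)
    a[i] <- n1a; b[i] <- n1b; a[j] <- n2a; b[j] <- n2b
  }
  cofunc_network(data.frame(gene_a = a, gene_b = b, weight = e$weight,
                            stringsAsFactors = FALSE), warn = FALSE)
}

# Sparse symmetric adjacency of `net` over an explicit gene universe.
# Genes outside the network get all-zero rows/columns.
network_adjacency <- function(net, universe) {
  n <- length(universe)
  i <- match(net$edges$gene_a, universe)
  j <- match(net$edges$gene_b, universe)
  keep <- !is.na(i) & !is.na(j)
  Matrix::sparseMatrix(i = c(i[keep], j[keep]), j = c(j[keep], i[keep]),
                       x = rep(net$edges$weight[keep], 2), dims = c(n, n))
}
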