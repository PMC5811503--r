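#' Read GWAS summary statistics
#'
#' Reads a delimited table of per-SNP association results into a data frame
#' of SNP records. Columns are resolved by name or by 1-based index.
#' Records failing validation (position < 1, P-value outside (0, 1]) are
#' skipped with a warning; a P-value of exactly 0 breaks the downstream
#' log-odds computation and is rejected unless `pvalue_floor` supplies an
#' explicit replacement.
#'
#' @param path Path to a TSV/CSV file (separator auto-detected).
#' @param chrom_col,pos_col,pvalue_col Column name (character) or index
#'   (numeric) for chromosome, position and P-value. Defaults `"chrom"`,
#'   `"pos"`, `"pvalue"`.
#' @param pvalue_floor Optional positive floor substituted for P-values of
#'   exactly 0. When `NULL` (default) zero P-values are skipped.
#' @return A data frame with columns `chrom` (character), `pos` (integer,
#'   1-based) and `pvalue` (double in (0, 1]), in file order.
#' @export
read_summary_stats <- function(path, chrom_col = "chrom", pos_col = "pos",
                               pvalue_col = "pvalue", pvalue_floor = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) {
    warning("summary-statistics file is empty: ", path, call. = FALSE)
    return(data.frame(chrom = character(), pos = integer(),
                      pvalue = double(), stringsAsFactors = FALSE))
  }
  dt <- data.table::fread(path, header = "auto", data.table = FALSE,
                          colClasses = list(character = 1))
  if (nrow(dt) == 0) {
    warning("summary-statistics file has no data rows: ", path, call. = FALSE)
    return(data.frame(chrom = character(), pos = integer(),
                      pvalue = double(), stringsAsFactors = FALSE))
  }
  pick <- function(col, what) {
    if (is.numeric(col)) {
      if (col < 1 || col > ncol(dt))
        stop(sprintf("column index %d for %s out of range (file has %d columns)",
                     as.integer(col), what, ncol(dt)), call. = FALSE)
      return(dt[[as.integer(col)]])
    }
    if (!col %in% names(dt))
      stop(sprintf("required column '%s' (%s) not found; available: %s",
                   col, what, paste(names(dt), collapse = ", ")), call. = FALSE)
    dt[[col]]
  }
  chrom <- as.character(pick(chrom_col, "chromosome"))
  pos <- suppressWarnings(as.numeric(pick(pos_col, "position")))
  pval <- suppressWarnings(as.numeric(pick(pvalue_col, "P-value")))

  if (!is.null(pvalue_floor)) {
    assert_number(pvalue_floor, "pvalue_floor", lower = .Machine$double.xmin,
                  upper = 1)
    n_floored <- sum(!is.na(pval) & pval == 0)
    if (n_floored > 0) {
      pval[!is.na(pval) & pval == 0] <- pvalue_floor
      message(n_floored, " zero P-value(s) replaced by floor ", pvalue_floor)
    }
  }
  bad_pos <- is.na(pos) | pos < 1 | pos != floor(pos)
  bad_p <- is.na(pval) | pval <= 0 | pval > 1
  bad <- bad_pos | bad_p
  if (any(bad)) {
    warning(sprintf("skipped %d malformed summary-statistics line(s) (first at data row %d): %d bad position(s), %d P-value(s) outside (0, 1]",
                    sum(bad), which(bad)[1], sum(bad_pos), sum(bad_p & !bad_pos)),
            call. = FALSE)
  }
  data.frame(chrom = chrom[!bad], pos = as.integer(pos[!bad]),
             pvalue = pval[!bad], stringsAsFactors = FALSE)
}

#' Read gene models from BED or GFF3
#'
#' Parses gene spans into the package's internal 0-based half-open
#' coordinate convention. BED intervals are kept as written (BED is already
#' 0-based half-open); GFF3 `gene` features are converted from 1-based
#' inclusive (`start - 1`, `end`). Gene identifiers come from BED column 4
#' or the GFF3 `ID` attribute.
#'
#' @param path Path to a BED4+ or GFF3 file.
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @return A data frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open) and `strand` (`"+"`, `"-"` or `"."`).
#' @export
read_gene_models <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- switch(ext, bed = "bed", gff = "gff3", gff3 = "gff3",
                     stop("cannot infer gene-model format from extension '",
                          ext, "'; pass format=", call. = FALSE))
  }
  gr <- rtracklayer::import(path, format = format)
  if (format == "gff3") {
    gr <- gr[!is.na(S4Vectors::mcols(gr)$type) &
               as.character(S4Vectors::mcols(gr)$type) == "gene"]
    if (length(gr) == 0) {
      warning("no 'gene'-type features in GFF3 file: ", path, call. = FALSE)
      return(data.frame(gene_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        strand = character(), stringsAsFactors = FALSE))
    }
    ids <- as.character(S4Vectors::mcols(gr)$ID)
    if (anyNA(ids) || any(!nzchar(ids)))
      stop("GFF3 gene feature(s) without an ID attribute", call. = FALSE)
  } else {
    ids <- S4Vectors::mcols(gr)$name
    if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
      stop("BED file must have a name column (BED4+) naming each gene",
           call. = FALSE)
    ids <- as.character(ids)
  }
  ids <- trimws(ids)
  if (anyDuplicated(ids))
    stop("duplicate gene_id(s) in annotation: ",
         paste(head(unique(ids[duplicated(ids)]), 5), collapse = ", "),
         call. = FALSE)
  # rtracklayer yields 1-based closed ranges for both formats; the internal
  # convention is 0-based half-open, so start-1 recovers the BED start and
  # performs the GFF3 conversion in one step.
  out <- data.frame(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = sub("\\*", ".", as.character(BiocGenerics::strand(gr))),
    stringsAsFactors = FALSE
  )
  if (any(out$start < 0) || any(out$start >= out$end))
    stop("invalid gene coordinates (negative or empty span)", call. = FALSE)
  out
}

#' Read a gene list (one ID per line)
#'
#' Lines starting with `#` and blank lines are ignored; IDs are
#' whitespace-trimmed and matched case-sensitively. Duplicates are removed
#' with a warning. Transcript suffixes (e.g. `".1"`) are stripped only on
#' request: implicit ID munging hides matching problems.
#'
#' @param path Path to the list file.
#' @param strip_suffix Strip a trailing `.<digits>` from each ID?
#' @return Character vector of unique gene IDs.
#' @export
read_gene_list <- function(path, strip_suffix = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (strip_suffix) x <- sub("\\.[0-9]+$", "", x)
  if (anyDuplicated(x)) {
    warning(sum(duplicated(x)), " duplicate ID(s) removed from gene list ",
            path, call. = FALSE)
    x <- unique(x)
  }
  if (length(x) == 0) stop("gene list is empty: ", path, call. = FALSE)
  x
}

#' Write / read the ranked gene table
#'
#' The ranked table holds one row per gene in final-score order with columns
#' `gene_id`, `assigned_pvalue`, `gwas_log_odds`, `gba_score`, `final_score`,
#' `rank`, `is_reference`. Numeric fields are emitted with 6 significant
#' digits and round-trip exactly at that precision.
#'
#' @param results A boost-result data frame (see [boost()]), optionally with
#'   an `is_reference` column.
#' @param path Output TSV path.
#' @return `write_ranked_table` returns `path` invisibly; `read_ranked_table`
#'   returns the table as a data frame.
#' @export
write_ranked_table <- function(results, path) {
  assert_columns(results, c("gene_id", "assigned_pvalue", "log_odds_gwas",
                            "gba_score", "final_score", "rank"),
                 "ranked-table input")
  out <- data.frame(
    gene_id = results$gene_id,
    assigned_pvalue = signif(results$assigned_pvalue, 6),
    gwas_log_odds = signif(results$log_odds_gwas, 6),
    gba_score = signif(results$gba_score, 6),
    final_score = signif(results$final_score, 6),
    rank = as.integer(results$rank),
    is_reference = if ("is_reference" %in% names(results))
      results$is_reference else NA,
    stringsAsFactors = FALSE
  )
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_ranked_table
#' @export
read_ranked_table <- function(path) {
  data.table::fread(path, sep = "\t", data.table = FALSE,
                    colClasses = list(character = "gene_id"))
}

#' Write the threshold-scan summary table
#'
#' One row per grid threshold with the partial-AUC of the real network, the
#' randomized-network null mean and SD, and the 2-SD significance call —
#' the quantities needed to draw the scan curve.
#'
#' @param scan A `gwab_scan` object from [run_scan()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_scan_summary <- function(scan, path) {
  stopifnot(inherits(scan, "gwab_scan"))
  out <- data.frame(
    log10p_threshold = scan$grid,
    auc_real = signif(scan$auc_real, 6),
    auc_random_mean = signif(scan$auc_random_mean, 6),
    auc_random_sd = signif(scan$auc_random_sd, 6),
    significant = scan$significant,
    stringsAsFactors = FALSE
  )
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
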