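#' @importFrom data.table data.table as.data.table setorder setnames := .N .SD
#' @importFrom methods is
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", "chrom", "pos", "sample_id", "condition", "meth", "unmeth", "cov",
  "one_sided", "delta_pp", "p", "q", "is_dm", "keep", "grp", "gap",
  "n_sites", "start", "end", "strand", "label", "kmer", "kk", "set",
  "window_id", "present", "n_dm", "n_bg", "total", "direction", "tad_id",
  "gene_id", "reason", "site_id", "mean_cov", "stratum", "transcript_id",
  "klass", "reject_reason", "high_confidence", "meth_pct", "feature",
  "cpg_id", "value", "pct", "gene", "id", "log2fc", "padj", "de"
))

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Reverse complement of DNA strings
#'
#' @param x Character vector of sequences over A/C/G/T/N (any case).
#' @return Character vector of upper-case reverse complements.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x))))
}

stop_if_not_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi) {
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, lo, hi),
         call. = FALSE)
  }
  invisible(x)
}

#' Write a data.frame as a plain TSV
#'
#' Deterministic tab-separated output (no quoting, "NA" for missing),
#' used for all tabular pipeline outputs.
#' @param x data.frame/data.table. @param path Output file.
#' @keywords internal
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA",
                     scipen = 50)
  invisible(path)
}

read_tsv <- function(path, ...) {
  data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA", ...)
}

#' Write intervals as BED6
#'
#' 0-based half-open intervals with name/score/strand columns.
#' @param x data.frame with columns chrom, start, end, name, score, strand.
#' @param path Output file.
#' @keywords internal
write_bed6 <- function(x, path) {
  stopifnot(all(c("chrom", "start", "end", "name", "score", "strand") %in%
                  names(x)))
  bed <- data.table::as.data.table(x)[
    , list(chrom, start = as.integer(start), end = as.integer(end),
           name, score, strand)]
  data.table::fwrite(bed, path, sep = "\t", quote = FALSE, col.names = FALSE,
                     scipen = 50)
  invisible(path)
}

#' Read a BED file (3-6 columns) into a data.table
#'
#' Coordinates stay 0-based half-open, matching the internal convention.
#' @param path BED file.
#' @keywords internal
read_bed <- function(path) {
  x <- data.table::fread(path, sep = "\t", header = FALSE)
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  setnames(x, cols[seq_len(min(ncol(x), 6))])
  if (!"name" %in% names(x)) x$name <- "."
  if (!"score" %in% names(x)) x$score <- 0
  if (!"strand" %in% names(x)) x$strand <- "*"
  x[]
}

bed_to_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = ifelse(x$strand %in% c("+", "-"), x$strand, "*"),
    name = x$name, score = x$score)
}

granges_to_bed_dt <- function(gr) {
  data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) gr$name else ".",
    score = if (!is.null(gr$score)) gr$score else 0,
    strand = {
      s <- as.character(GenomicRanges::strand(gr))
      ifelse(s == "*", ".", s)
    })
}
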