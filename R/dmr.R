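#' Chain DM CpGs into differentially methylated regions
#'
#' Per chromosome, DM sites are sorted by position and chained by single
#' linkage: consecutive sites at most `max_gap` bp apart (inclusive at the
#' boundary) belong to the same chain; chains with at least `min_sites`
#' members are emitted as DMRs. The region span covers the member dyads
#' only (`end` = last member position + 2); direction is `hyper`/`hypo`
#' when all member deltas share a sign, else `mixed`.
#'
#' @param dm_sites `data.table` of DM sites with columns `chrom`, `pos`,
#'   `delta_pp` (any order).
#' @param max_gap Maximum gap between consecutive member CpGs, default 500.
#' @param min_sites Minimum member count, default 2.
#' @return `data.table` of regions: `chrom, start, end, n_sites,
#'   mean_delta_pp, direction, member_pos` (list column).
#' @export
cluster_dmrs <- function(dm_sites, max_gap = 500, min_sites = 2) {
  stop_if_not_scalar_number(max_gap, "max_gap", 0)
  stop_if_not_scalar_number(min_sites, "min_sites", 1)
  empty <- data.table(chrom = character(0), start = integer(0),
                      end = integer(0), n_sites = integer(0),
                      mean_delta_pp = numeric(0), direction = character(0),
                      member_pos = I(list()))
  x <- data.table::as.data.table(dm_sites)
  if (nrow(x) == 0) return(empty)
  if (!"delta_pp" %in% names(x)) x[, delta_pp := NA_real_]
  x <- x[order(chrom, pos)]
  x[, gap := c(Inf, diff(pos)), by = chrom]
  x[, grp := cumsum(gap > max_gap), by = chrom]
  out <- x[, list(start = min(pos), end = max(pos) + 2L, n_sites = .N,
                  mean_delta_pp = mean(delta_pp),
                  direction = if (all(is.na(delta_pp))) NA_character_
                  else if (all(delta_pp > 0)) "hyper"
                  else if (all(delta_pp < 0)) "hypo" else "mixed",
                  member_pos = list(pos)),
           by = list(chrom, grp)]
  out <- out[n_sites >= min_sites]
  out[, grp := NULL]
  if (nrow(out) == 0) return(empty)
  out[order(chrom, start)]
}

#' Per-TAD differential methylation fractions
#'
#' For each topologically associated domain, reports the number of tested
#' CpGs, the number of DM CpGs, the percentage DM (NA when the TAD
#' contains no tested site), and the ids of genes whose TSS falls in the
#' TAD.
#'
#' @param all_sites Tested sites: `data.table` with `chrom`, `pos`.
#' @param dm_sites DM subset, same columns.
#' @param tads Interval `data.table` (`chrom`, `start`, `end` 0-based
#'   half-open, `name`); TADs must be non-overlapping per chromosome.
#' @param genes Gene table with `gene_id`, `chrom`, `tss`.
#' @return `data.table`: `tad_id, chrom, start, end, n_tested, n_dm,
#'   pct_dm, genes` (comma-separated).
#' @export
tad_dm_fraction <- function(all_sites, dm_sites, tads, genes = NULL) {
  tads <- data.table::as.data.table(tads)
  tg <- GenomicRanges::GRanges(tads$chrom,
                               IRanges::IRanges(tads$start + 1L, tads$end))
  if (any(GenomicRanges::countOverlaps(tg, tg) > 1)) {
    stop("TAD intervals overlap; they must be disjoint per chromosome")
  }
  count_in <- function(sites) {
    if (is.null(sites) || nrow(sites) == 0) return(integer(length(tg)))
    sg <- GenomicRanges::GRanges(sites$chrom,
                                 IRanges::IRanges(sites$pos + 1L, width = 1))
    GenomicRanges::countOverlaps(tg, sg)
  }
  n_tested <- count_in(data.table::as.data.table(all_sites))
  n_dm <- count_in(data.table::as.data.table(dm_sites))
  gene_str <- rep("", length(tg))
  if (!is.null(genes) && nrow(genes) > 0) {
    gg <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$tss + 1L, width = 1))
    hits <- GenomicRanges::findOverlaps(tg, gg)
    if (length(hits)) {
      byq <- split(genes$gene_id[S4Vectors::subjectHits(hits)],
                   S4Vectors::queryHits(hits))
      gene_str[as.integer(names(byq))] <-
        vapply(byq, function(g) paste(sort(g), collapse = ","), character(1))
    }
  }
  data.table(
    tad_id = if (!is.null(tads$name)) tads$name else
      sprintf("tad%03d", seq_along(tg)),
    chrom = tads$chrom, start = tads$start, end = tads$end,
    n_tested = n_tested, n_dm = n_dm,
    pct_dm = ifelse(n_tested == 0, NA_real_, 100 * n_dm / n_tested),
    genes = gene_str)
}
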