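#' Classify candidate transcripts as antisense or intergenic lncRNAs
#'
#' Rules, applied in order: reject if spliced length <= `min_len`
#' (">200 nt" is strict); reject if the coding-potential flag is set
#' (coding-potential prediction is consumed as an input, not computed);
#' reject (`sense_overlap`) if the transcript overlaps a coding gene on
#' the same strand; `antisense` if it overlaps a coding gene on the
#' opposite strand; `intergenic` if it overlaps no coding gene on either
#' strand. A call is `high_confidence` iff the transcript's 5' end lies
#' within `cage_max_dist` bp of a same-strand CAGE cluster (a defined
#' 5' end).
#'
#' @param cand_exons Candidate exon table: `transcript_id, chrom, start,
#'   end, strand` (0-based half-open). Every transcript id in `cand_meta`
#'   must have at least one exon row.
#' @param cand_meta Table with `transcript_id` and logical
#'   `coding_potential`.
#' @param genes Coding gene table: `gene_id, chrom, start, end, strand`.
#' @param cage CAGE cluster intervals: `chrom, start, end, strand`.
#' @param min_len Minimum spliced length (exclusive), default 200 nt.
#' @param cage_max_dist Maximum distance of the 5' end to a CAGE cluster,
#'   default 50 bp.
#' @return `data.table`: `transcript_id, klass
#'   (antisense/intergenic/rejected), reject_reason, high_confidence,
#'   spliced_length`.
#' @export
classify_lncrnas <- function(cand_exons, cand_meta, genes, cage,
                             min_len = 200, cage_max_dist = 50) {
  ex <- data.table::as.data.table(cand_exons)
  meta <- data.table::as.data.table(cand_meta)
  genes <- data.table::as.data.table(genes)
  missing_ex <- setdiff(meta$transcript_id, ex$transcript_id)
  if (length(missing_ex)) {
    stop("transcripts without exons: ", paste(missing_ex, collapse = ", "))
  }
  tx <- ex[, list(chrom = chrom[1], start = min(start), end = max(end),
                  strand = strand[1], spliced_length = sum(end - start)),
           by = transcript_id]
  tx <- tx[meta, on = "transcript_id"]

  gg <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start + 1L, genes$end),
                               strand = genes$strand)
  tg <- GenomicRanges::GRanges(tx$chrom,
                               IRanges::IRanges(tx$start + 1L, tx$end),
                               strand = tx$strand)
  same <- IRanges::overlapsAny(tg, gg, ignore.strand = FALSE)
  tg_flip <- tg
  GenomicRanges::strand(tg_flip) <- ifelse(
    as.character(GenomicRanges::strand(tg)) == "+", "-", "+")
  anti <- IRanges::overlapsAny(tg_flip, gg, ignore.strand = FALSE)

  klass <- rep("intergenic", nrow(tx))
  reason <- rep(NA_character_, nrow(tx))
  klass[anti] <- "antisense"
  klass[same] <- "rejected"; reason[same] <- "sense_overlap"
  cp <- tx$coding_potential
  klass[cp] <- "rejected"; reason[cp] <- "coding_potential"
  short <- tx$spliced_length <= min_len
  klass[short] <- "rejected"; reason[short] <- "too_short"

  # CAGE support at the 5' end, same strand
  hc <- rep(FALSE, nrow(tx))
  cage <- data.table::as.data.table(cage)
  if (nrow(cage)) {
    p5 <- ifelse(tx$strand == "+", tx$start, tx$end - 1L)
    pg <- GenomicRanges::GRanges(tx$chrom,
                                 IRanges::IRanges(p5 + 1L, width = 1),
                                 strand = tx$strand)
    cg <- GenomicRanges::GRanges(cage$chrom,
                                 IRanges::IRanges(cage$start + 1L, cage$end),
                                 strand = cage$strand)
    hit <- GenomicRanges::distanceToNearest(pg, cg, ignore.strand = FALSE)
    d <- rep(Inf, nrow(tx))
    d[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
    hc <- d <= cage_max_dist
  }
  hc[klass == "rejected"] <- FALSE

  data.table(transcript_id = tx$transcript_id, klass = klass,
             reject_reason = reason, high_confidence = hc,
             spliced_length = tx$spliced_length)[order(transcript_id)]
}

#' Pair lncRNAs with their nearest differentially expressed genes
#'
#' For each non-rejected lncRNA, finds the nearest coding-gene TSS within
#' `max_dist` of the lncRNA 5' end (ties to the lower gene id) and joins
#' both parties' DE statistics; the pair is `concordant` when both are DE
#' with the same log2FC sign.
#'
#' @param calls Output of [classify_lncrnas()].
#' @param cand_exons Candidate exon table (for coordinates).
#' @param genes Coding gene table with `gene_id, chrom, tss`.
#' @param de_table DE table with `id, log2fc, padj` and optionally `de`
#'   (defaults to `padj < 0.05`), covering lncRNA and gene ids.
#' @param max_dist Maximum pairing distance in bp, default 100 kb.
#' @return `data.table`: `transcript_id, klass, lnc_log2fc, lnc_padj,
#'   nearest_gene, gene_log2fc, gene_padj, distance, concordant`;
#'   `nearest_gene` is NA when no gene lies within `max_dist`.
#' @export
pair_with_neighbor_genes <- function(calls, cand_exons, genes, de_table,
                                     max_dist = 1e5) {
  calls <- data.table::as.data.table(calls)[klass != "rejected"]
  ex <- data.table::as.data.table(cand_exons)
  detab <- data.table::as.data.table(de_table)
  if (!"de" %in% names(detab)) detab[, de := padj < 0.05]
  tx <- ex[, list(chrom = chrom[1], start = min(start), end = max(end),
                  strand = strand[1]), by = transcript_id]
  tx <- tx[calls[, list(transcript_id, klass)], on = "transcript_id"]
  p5 <- ifelse(tx$strand == "+", tx$start, tx$end - 1L)
  near <- nearest_gene_tss(tx$chrom, p5, genes)
  dist <- abs(p5 - near$tss)
  ok <- !is.na(dist) & dist <= max_dist
  de_l <- detab[match(tx$transcript_id, detab$id)]
  de_g <- detab[match(near$nearest_gene, detab$id)]
  out <- data.table(
    transcript_id = tx$transcript_id, klass = tx$klass,
    lnc_log2fc = de_l$log2fc, lnc_padj = de_l$padj,
    nearest_gene = ifelse(ok, near$nearest_gene, NA_character_),
    gene_log2fc = ifelse(ok, de_g$log2fc, NA_real_),
    gene_padj = ifelse(ok, de_g$padj, NA_real_),
    distance = ifelse(ok, dist, NA_real_))
  out[, concordant := !is.na(nearest_gene) &
        isTRUE_vec(de_l$de) & isTRUE_vec(de_g$de) &
        sign(lnc_log2fc) == sign(gene_log2fc)]
  out[order(transcript_id)]
}

isTRUE_vec <- function(x) !is.na(x) & x

utils::globalVariables(c("concordant", "lnc_log2fc", "gene_log2fc"))
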