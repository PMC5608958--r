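FEATURE_LEVELS <- c("promoter", "exon", "intron", "enhancer", "cpg_island",
                    "intergenic")

# nearest gene TSS for query positions; equidistant ties and shared-TSS
# ties both resolve to the lexicographically lower gene id
nearest_gene_tss <- function(chrom, pos, genes) {
  genes <- data.table::as.data.table(genes)
  if (!"strand" %in% names(genes)) genes$strand <- "+"
  out <- data.table(nearest_gene = rep(NA_character_, length(pos)),
                    tss = rep(NA_integer_, length(pos)),
                    gene_strand = rep(NA_character_, length(pos)))
  for (ch in unique(chrom)) {
    g <- genes[genes$chrom == ch]
    qi <- which(chrom == ch)
    if (nrow(g) == 0) next
    # one gene per TSS position (lower id wins outright)
    g <- g[order(tss, gene_id)][!duplicated(tss)]
    tvec <- g$tss
    p <- pos[qi]
    il <- findInterval(p, tvec)
    ir <- pmin(il + 1L, length(tvec))
    ilc <- pmax(il, 1L)
    dl <- ifelse(il >= 1L, p - tvec[ilc], Inf)
    dr <- ifelse(il < length(tvec), tvec[ir] - p, Inf)
    pick_left <- dl < dr |
      (dl == dr & g$gene_id[ilc] <= g$gene_id[ir])
    sel <- ifelse(pick_left, ilc, ir)
    out$nearest_gene[qi] <- g$gene_id[sel]
    out$tss[qi] <- g$tss[sel]
    out$gene_strand[qi] <- g$strand[sel]
  }
  out
}

#' Assign genomic-feature context to CpG sites
#'
#' Each site receives exactly one `primary_label` by the precedence
#' promoter > exon > intron > enhancer > cpg_island > intergenic, where
#' the promoter window spans `promoter_window` bp around the TSS in the
#' gene's orientation (default -1500 upstream to +500 downstream,
#' inclusive). Enhancer overlap is additionally reported as an orthogonal
#' flag, since enhancers are frequently intronic. Signed TSS distance
#' (negative = upstream of the nearest gene, relative to its strand) and
#' the nearest gene id are attached; equidistant TSS ties break to the
#' lexicographically lower gene id. Sites on chromosomes absent from the
#' annotation are labelled intergenic and counted in the
#' `n_unknown_chrom` attribute.
#'
#' @param sites `data.table` with `chrom`, `pos` (0-based C of the dyad).
#' @param bundle `AnnotationBundle` (or any list with `genes`, `exons`,
#'   `enhancers`, `cpg_islands` tables in 0-based half-open coordinates).
#' @param promoter_window Length-2 numeric `c(upstream, downstream)` with
#'   upstream negative, default `c(-1500, 500)`.
#' @return `data.table`: `chrom, pos, site_id, primary_label,
#'   enhancer_overlap, nearest_gene, tss_distance, orientation`.
#' @export
assign_features <- function(sites, bundle, promoter_window = c(-1500, 500)) {
  stopifnot(length(promoter_window) == 2, promoter_window[1] <= 0,
            promoter_window[2] >= 0)
  x <- data.table::as.data.table(sites)[, list(chrom, pos)]
  genes <- data.table::as.data.table(bundle$genes)
  if (nrow(genes) == 0) stop("annotation bundle contains no genes")
  known <- unique(c(genes$chrom, bundle$enhancers$chrom,
                    bundle$cpg_islands$chrom))
  n_unknown <- sum(!x$chrom %in% known)

  sg <- GenomicRanges::GRanges(x$chrom,
                               IRanges::IRanges(x$pos + 1L, width = 1))
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end),
    strand = genes$strand)
  prom_gr <- GenomicRanges::promoters(
    GenomicRanges::resize(gene_gr, width = 1,
                          fix = "start"),
    upstream = -promoter_window[1], downstream = promoter_window[2] + 1L)
  prom_gr <- GenomicRanges::trim(prom_gr)
  exon_gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    bundle$exons$chrom,
    IRanges::IRanges(bundle$exons$start + 1L, bundle$exons$end)))
  intron_gr <- GenomicRanges::setdiff(
    GenomicRanges::GRanges(genes$chrom,
                           IRanges::IRanges(genes$start + 1L, genes$end)),
    exon_gr)
  make_gr <- function(tab) {
    if (is.null(tab) || nrow(tab) == 0) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(tab$chrom,
                           IRanges::IRanges(tab$start + 1L, tab$end))
  }
  enh_gr <- make_gr(bundle$enhancers)
  cgi_gr <- make_gr(bundle$cpg_islands)

  label <- rep("intergenic", nrow(x))
  tracks <- list(cpg_island = cgi_gr, enhancer = enh_gr,
                 intron = intron_gr, exon = exon_gr, promoter = prom_gr)
  for (nm in names(tracks)) {   # reverse precedence; later wins
    # sites on unknown chromosomes simply never overlap (warning-free)
    hit <- suppressWarnings(
      IRanges::overlapsAny(sg, tracks[[nm]], ignore.strand = TRUE))
    label[hit] <- nm
  }
  enhancer_overlap <- suppressWarnings(
    IRanges::overlapsAny(sg, enh_gr, ignore.strand = TRUE))

  near <- nearest_gene_tss(x$chrom, x$pos, genes)
  raw <- x$pos - near$tss
  signed <- ifelse(near$gene_strand == "-", -raw, raw)
  out <- data.table(
    chrom = x$chrom, pos = x$pos,
    site_id = paste(x$chrom, x$pos, sep = ":"),
    primary_label = factor(label, levels = FEATURE_LEVELS),
    enhancer_overlap = enhancer_overlap,
    nearest_gene = near$nearest_gene,
    tss_distance = signed,
    orientation = ifelse(is.na(signed), NA_character_,
                         ifelse(signed < 0, "upstream", "downstream")))
  data.table::setattr(out, "n_unknown_chrom", n_unknown)
  out
}

#' TSS-distance histogram
#'
#' Bins |signed TSS distance| of assigned sites by `bin_edges` separately
#' for upstream and downstream orientation.
#'
#' @param assignments Output of [assign_features()].
#' @param bin_edges Increasing non-negative bp edges; a final `Inf` edge
#'   is appended if absent. Default `c(0, 1e3, 1e4, 1e5, 5e5, Inf)`.
#' @return `data.table` with `bin`, `orientation`, `count`; counts sum to
#'   the number of sites with a defined distance.
#' @export
tss_distance_bins <- function(assignments,
                              bin_edges = c(0, 1e3, 1e4, 1e5, 5e5, Inf)) {
  if (all(is.na(assignments$tss_distance))) {
    stop("no TSS distances available (empty gene set?)")
  }
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop("bin_edges must be strictly increasing")
  }
  if (is.finite(bin_edges[length(bin_edges)])) {
    bin_edges <- c(bin_edges, Inf)
  }
  x <- data.table::as.data.table(assignments)[!is.na(tss_distance)]
  binf <- cut(abs(x$tss_distance), breaks = bin_edges, right = FALSE,
              include.lowest = TRUE)
  x[, bin := as.character(binf)]
  grid <- data.table::CJ(bin = levels(binf),
                         orientation = c("upstream", "downstream"))
  counts <- x[, list(count = .N), by = list(bin, orientation)]
  out <- counts[grid, on = c("bin", "orientation")]
  out[is.na(count), count := 0L]
  out[order(bin, -orientation)]
}

utils::globalVariables(c("bin", "count", "tss_distance", "tss"))

#' Coverage-matched background sampling
#'
#' Bins all tested sites into `n_strata` coverage quantiles and samples a
#' background set (without replacement, excluding the query sites)
#' matching the query's stratum proportions, of size `multiplier` times
#' the query (capped by availability per stratum, with a warning).
#'
#' @param dm_sites Query sites with `chrom`, `pos`, `cov_mean`.
#' @param all_tested_sites All tested sites, same columns.
#' @param n_strata Number of coverage quantile strata, default 10.
#' @param multiplier Background size as a multiple of the query, default 10.
#' @param seed Integer seed for the sampling.
#' @return `data.table` of background sites (subset of
#'   `all_tested_sites` rows).
#' @export
coverage_matched_background <- function(dm_sites, all_tested_sites,
                                        n_strata = 10, multiplier = 10,
                                        seed = 1L) {
  dm <- data.table::as.data.table(dm_sites)
  all_s <- data.table::as.data.table(all_tested_sites)
  stopifnot(all(c("chrom", "pos", "cov_mean") %in% names(all_s)),
            nrow(dm) > 0, nrow(all_s) > 0)
  set.seed(as.integer(seed))
  qs <- stats::quantile(all_s$cov_mean, probs = seq(0, 1, 1 / n_strata))
  brk <- unique(qs)
  strat <- function(v) cut(v, breaks = brk, include.lowest = TRUE,
                           labels = FALSE)
  all_s[, stratum := strat(cov_mean)]
  dm[, stratum := strat(cov_mean)]
  dm_key <- paste(dm$chrom, dm$pos)
  pool <- all_s[!paste(chrom, pos) %in% dm_key]
  want <- dm[, list(n_want = .N * multiplier), by = stratum]
  picks <- list()
  short <- FALSE
  for (i in seq_len(nrow(want))) {
    st <- want$stratum[i]
    avail <- which(pool$stratum == st)
    n_take <- min(length(avail), want$n_want[i])
    if (n_take < want$n_want[i]) short <- TRUE
    picks[[i]] <- avail[sample.int(length(avail), n_take)]
  }
  if (short) {
    warning("background pool smaller than requested; using all available ",
            "sites in depleted strata")
  }
  pool[sort(unlist(picks))]
}

utils::globalVariables(c("n_want"))

#' Feature enrichment of a query site set against a background
#'
#' Builds a 2x2 table per feature label (query-in/out vs background-in/out)
#' plus one orthogonal row for enhancer overlap, and computes the
#' Haldane-corrected odds ratio, Woolf 95% CI, two-sided Fisher p, and BH
#' q across features.
#'
#' @param query_assign,bg_assign Outputs of [assign_features()] for the
#'   query (e.g. DM CpGs) and background sets.
#' @return [enrichment_table()] rows, one per feature plus
#'   `enhancer_overlap`.
#' @export
feature_enrichment <- function(query_assign, bg_assign) {
  if (nrow(query_assign) == 0 || nrow(bg_assign) == 0) {
    stop("query and background assignments must be non-empty")
  }
  nq <- nrow(query_assign)
  nb <- nrow(bg_assign)
  labels <- FEATURE_LEVELS
  a <- vapply(labels, function(l) sum(query_assign$primary_label == l),
              integer(1))
  c_ <- vapply(labels, function(l) sum(bg_assign$primary_label == l),
               integer(1))
  labels <- c(labels, "enhancer_overlap")
  a <- c(a, sum(query_assign$enhancer_overlap))
  c_ <- c(c_, sum(bg_assign$enhancer_overlap))
  enrichment_table(labels, a, nq - a, c_, nb - c_)
}

#' Enhancer proximity of DM CpGs
#'
#' Distance from each site to its nearest enhancer, measured as the
#' coordinate difference to the closest enhancer base (0 for overlap),
#' with relation `overlap` (distance 0), `proximal` (within `max_dist`)
#' or `distal`; each matched enhancer is associated with the gene whose
#' TSS is nearest to it.
#'
#' @param dm_sites `data.table` with `chrom`, `pos`.
#' @param enhancers Interval table (`chrom`, `start`, `end`, `name`).
#' @param max_dist Proximity threshold in bp, default 1000.
#' @param genes Gene table with `gene_id`, `chrom`, `tss`.
#' @return `data.table`: `chrom, pos, relation, distance, enhancer,
#'   associated_gene` (distance `Inf` when the chromosome has no
#'   enhancer).
#' @export
enhancer_proximity <- function(dm_sites, enhancers, max_dist = 1000,
                               genes = NULL) {
  x <- data.table::as.data.table(dm_sites)
  enh <- data.table::as.data.table(enhancers)
  n <- nrow(x)
  res <- data.table(chrom = x$chrom, pos = x$pos,
                    relation = rep("distal", n),
                    distance = rep(Inf, n),
                    enhancer = rep(NA_character_, n),
                    associated_gene = rep(NA_character_, n))
  if (nrow(enh) == 0 || n == 0) return(res)
  if (!"name" %in% names(enh)) enh[, name := sprintf("enh%04d", .I)]
  # associated gene per enhancer: nearest TSS to the enhancer interval
  assoc <- rep(NA_character_, nrow(enh))
  if (!is.null(genes) && nrow(genes) > 0) {
    mid <- (enh$start + enh$end - 1L) %/% 2L
    near <- nearest_gene_tss(enh$chrom, mid, genes)
    assoc <- near$nearest_gene
  }
  for (ch in unique(x$chrom)) {
    e <- enh[enh$chrom == ch]
    qi <- which(x$chrom == ch)
    if (nrow(e) == 0) next
    eg <- GenomicRanges::GRanges(ch, IRanges::IRanges(e$start + 1L, e$end))
    sgg <- GenomicRanges::GRanges(ch,
                                  IRanges::IRanges(x$pos[qi] + 1L, width = 1))
    hit <- GenomicRanges::distanceToNearest(sgg, eg)
    qh <- S4Vectors::queryHits(hit)
    sh <- S4Vectors::subjectHits(hit)
    d <- S4Vectors::mcols(hit)$distance
    ov <- IRanges::overlapsAny(sgg, eg)
    dist_spec <- ifelse(ov[qh], 0, d + 1L)
    res$distance[qi[qh]] <- dist_spec
    res$relation[qi[qh]] <- ifelse(dist_spec == 0, "overlap",
                                   ifelse(dist_spec <= max_dist,
                                          "proximal", "distal"))
    eidx <- which(enh$chrom == ch)[sh]
    res$enhancer[qi[qh]] <- enh$name[eidx]
    res$associated_gene[qi[qh]] <- assoc[eidx]
  }
  res
}
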