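#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator in one validated
#' object. Defaults describe a small two-chromosome genome that is dense
#' enough in CpGs to exercise every pipeline stage in seconds while keeping
#' the statistical structure of a WGBS experiment: negative-binomial
#' coverage, beta-binomial replicate counts over a bimodal (hypo/hyper)
#' baseline methylome, planted DMRs preferentially in introns and
#' enhancers, AP-1-style motif instances written into the sequence near
#' planted DM CpGs, and a DE table with an enriched gene set.
#'
#' @param seed Integer seed; all stochastic draws flow from it.
#' @param n_chromosomes,chrom_length Genome shape (chromosomes x bp).
#' @param gc_fraction Genome GC content in \[0, 1\]; CpG sites are the
#'   emergent CG dinucleotides.
#' @param n_genes Number of non-overlapping protein-coding gene models.
#' @param exons_per_gene Integer range (min, max) of exons per gene.
#' @param gene_span Range (min, max) of gene lengths in bp.
#' @param n_enhancers,n_tads,n_cage_clusters,n_cpg_islands Track sizes.
#' @param n_lncrna_candidates Candidate transcripts emitted for the lncRNA
#'   classifier, covering all rule branches.
#' @param n_replicates_per_condition Replicates per condition (uncut/cut).
#' @param mean_depth Mean per-site read coverage (negative binomial mean).
#' @param depth_dispersion Negative-binomial size parameter for coverage.
#' @param baseline_meth_mixture Two-component Beta mixture for per-site
#'   baseline methylation: list(hypo = c(shape1, shape2),
#'   hyper = c(shape1, shape2), weight_hypo).
#' @param replicate_concentration Beta concentration for replicate-level
#'   methylation probabilities (overdispersion; binomial as conc -> Inf).
#' @param n_planted_dmrs,dmr_n_cpgs Number of planted DMRs and CpGs each.
#' @param dmr_delta_pp Planted methylation difference (cut minus uncut) in
#'   percentage points, in (-100, 100); recycled across DMRs.
#' @param dmr_feature_weights Named weights (intron, enhancer, other) for
#'   placing planted DMRs, making feature-enrichment recovery testable.
#' @param motif_consensus IUPAC consensus written into the genome near
#'   planted DM CpGs (default the AP-1 heptamer TGACTCA).
#' @param motif_planting_fraction Fraction of planted DM CpGs that receive
#'   a motif instance within +/-20 bp.
#' @param motif_background_fraction Fraction of non-DM CpGs that receive a
#'   motif instance, setting the background hit rate.
#' @param n_expression_genes Size of the expression universe (bundle genes
#'   first, then synthetic ids).
#' @param n_de_genes Expected number of DE genes in the emitted table.
#' @param de_log2fc Mean |log2 fold change| of planted DE genes.
#' @param emt_set_size Size of the designated EMT gene set.
#' @param emt_de_or Planted odds ratio of EMT membership among DE genes.
#' @param ortholog_unmapped_fraction Fraction of EMT human symbols left
#'   without an ortholog row.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length = 5e5,
                       gc_fraction = 0.42,
                       n_genes = 80L,
                       exons_per_gene = c(2L, 6L),
                       gene_span = c(3000L, 9000L),
                       n_enhancers = 60L,
                       n_tads = 8L,
                       n_cage_clusters = 120L,
                       n_cpg_islands = 40L,
                       n_lncrna_candidates = 24L,
                       n_replicates_per_condition = 3L,
                       mean_depth = 30,
                       depth_dispersion = 8,
                       baseline_meth_mixture = list(hypo = c(0.8, 6),
                                                    hyper = c(6, 1.2),
                                                    weight_hypo = 0.25),
                       replicate_concentration = 150,
                       n_planted_dmrs = 30L,
                       dmr_n_cpgs = 5L,
                       dmr_delta_pp = 40,
                       dmr_feature_weights = c(intron = 3, enhancer = 3,
                                               other = 1),
                       motif_consensus = "TGACTCA",
                       motif_planting_fraction = 0.4,
                       motif_background_fraction = 0.05,
                       n_expression_genes = 2000L,
                       n_de_genes = 300L,
                       de_log2fc = 2,
                       emt_set_size = 40L,
                       emt_de_or = 3,
                       ortholog_unmapped_fraction = 0) {
  cfg <- as.list(environment())
  stop_if_not_scalar_number(seed, "seed", 0, 2^31 - 1)
  stop_if_not_scalar_number(n_chromosomes, "n_chromosomes", 1)
  stop_if_not_scalar_number(chrom_length, "chrom_length", 1000)
  stop_if_not_scalar_number(gc_fraction, "gc_fraction", 0, 1)
  stop_if_not_scalar_number(mean_depth, "mean_depth", 0)
  stop_if_not_scalar_number(motif_planting_fraction,
                            "motif_planting_fraction", 0, 1)
  stop_if_not_scalar_number(motif_background_fraction,
                            "motif_background_fraction", 0, 1)
  stop_if_not_scalar_number(ortholog_unmapped_fraction,
                            "ortholog_unmapped_fraction", 0, 1)
  if (any(abs(dmr_delta_pp) >= 100)) {
    stop("dmr_delta_pp must lie strictly inside (-100, 100)")
  }
  if (emt_set_size > n_expression_genes) {
    stop("emt_set_size must not exceed n_expression_genes")
  }
  if (length(exons_per_gene) != 2 || exons_per_gene[1] > exons_per_gene[2]) {
    stop("exons_per_gene must be an increasing (min, max) pair")
  }
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", motif_consensus)) {
    stop("motif_consensus must be a non-empty IUPAC DNA string")
  }
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  cfg
}

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

# one concrete realisation of an IUPAC consensus
realize_iupac <- function(consensus) {
  letters <- strsplit(consensus, "")[[1]]
  paste0(vapply(IUPAC_SETS[letters],
                function(s) if (length(s) == 1) s else sample(s, 1),
                character(1)), collapse = "")
}

# partition `extra` into n non-negative integer parts, uniformly at random
random_partition <- function(extra, n) {
  if (n == 1) return(extra)
  cuts <- sort(sample.int(extra + n - 1, n - 1))
  diff(c(0, cuts, extra + n - 1)) - 1L
}

#' Simulate an annotation bundle and genome
#'
#' Generates an i.i.d. random genome at the requested GC fraction,
#' non-overlapping multi-exon gene models on both strands, enhancer /
#' CpG-island / TAD / CAGE interval tracks, and a set of lncRNA candidate
#' transcripts covering every classifier rule branch. Deterministic given
#' `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @return An `AnnotationBundle`: list with `chrom_lengths`, `genome`
#'   (named `DNAStringSet`), `genes`, `exons`, `enhancers`, `cpg_islands`,
#'   `tads`, `cage`, `lnc_exons`, `lnc_meta` (all 0-based half-open
#'   `data.table`s), and the echoed `config`.
#' @export
simulate_annotation_bundle <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- as.integer(config$chrom_length)
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  chrom_lengths <- stats::setNames(rep(L, length(chroms)), chroms)

  bases <- c("A", "C", "G", "T")
  pr <- c((1 - config$gc_fraction) / 2, config$gc_fraction / 2,
          config$gc_fraction / 2, (1 - config$gc_fraction) / 2)
  genome <- Biostrings::DNAStringSet(vapply(chroms, function(ch) {
    paste0(sample(bases, L, replace = TRUE, prob = pr), collapse = "")
  }, character(1)))
  names(genome) <- chroms

  # --- genes: random chromosome, then random non-overlapping placement ---
  n_genes <- as.integer(config$n_genes)
  gene_chrom <- sort(sample(chroms, n_genes, replace = TRUE))
  spans <- as.integer(round(stats::runif(n_genes, config$gene_span[1],
                                         config$gene_span[2])))
  genes_list <- list()
  exons_list <- list()
  margin <- 200L   # minimum spacing between genes
  for (ch in chroms) {
    idx <- which(gene_chrom == ch)
    if (!length(idx)) next
    sp <- spans[idx]
    need <- sum(sp) + (length(idx) + 1L) * margin
    if (need > L) {
      stop(sprintf(
        "cannot place %d genes (total span %d bp + spacing) on %s (%d bp)",
        length(idx), sum(sp), ch, L))
    }
    gaps <- random_partition(L - sum(sp) - (length(idx) + 1L) * margin,
                             length(idx) + 1L) + margin
    starts <- cumsum(c(gaps[1],
                       if (length(sp) > 1)
                         sp[-length(sp)] + gaps[2:length(sp)]))
    for (j in seq_along(idx)) {
      gid <- sprintf("gene%05d", idx[j])
      strand <- sample(c("+", "-"), 1)
      gstart <- as.integer(starts[j])
      gend <- gstart + sp[j]
      k <- sample(seq(config$exons_per_gene[1], config$exons_per_gene[2]), 1)
      min_exon <- 80L; min_intron <- 100L
      total_min <- k * min_exon + (k - 1L) * min_intron
      stopifnot(total_min <= sp[j])
      extra <- random_partition(sp[j] - total_min, 2L * k - 1L)
      widths <- rep(c(min_exon, min_intron), length.out = 2L * k - 1L) + extra
      offs <- cumsum(c(0L, widths))
      exon_starts <- gstart + offs[seq(1, 2 * k - 1, by = 2)]
      exon_ends <- gstart + offs[seq(2, 2 * k, by = 2)]
      exon_ends[k] <- gend   # last exon absorbs rounding
      genes_list[[gid]] <- data.table(
        gene_id = gid, chrom = ch, start = gstart, end = gend,
        strand = strand,
        tss = if (strand == "+") gstart else gend - 1L)
      exons_list[[gid]] <- data.table(
        gene_id = gid, exon_number = seq_len(k), chrom = ch,
        start = as.integer(exon_starts), end = as.integer(exon_ends),
        strand = strand)
    }
  }
  genes <- data.table::rbindlist(genes_list)
  exons <- data.table::rbindlist(exons_list)
  data.table::setorder(genes, chrom, start)

  rand_track <- function(n, wmin, wmax, prefix) {
    ch <- sample(chroms, n, replace = TRUE)
    w <- as.integer(round(stats::runif(n, wmin, wmax)))
    s <- vapply(w, function(wi) sample.int(L - wi, 1), integer(1))
    data.table(chrom = ch, start = s, end = s + w,
               name = sprintf("%s%04d", prefix, seq_len(n)),
               score = 0L, strand = ".")[order(chrom, start)]
  }
  enhancers <- rand_track(config$n_enhancers, 300, 1500, "enh")
  cpg_islands <- rand_track(config$n_cpg_islands, 300, 1000, "cgi")

  # TADs tile each chromosome (non-overlapping by construction)
  per_chrom <- diff(round(seq(0, config$n_tads,
                              length.out = config$n_chromosomes + 1)))
  tads_list <- list()
  ti <- 0L
  for (ci in seq_along(chroms)) {
    k <- max(1L, per_chrom[ci])
    brk <- sort(sample.int(L - 2L, k - 1L))
    bounds <- c(0L, brk, L)
    tads_list[[ci]] <- data.table(
      chrom = chroms[ci], start = bounds[-length(bounds)], end = bounds[-1],
      name = sprintf("tad%03d", ti + seq_len(k)), score = 0L, strand = ".")
    ti <- ti + k
  }
  tads <- data.table::rbindlist(tads_list)

  # CAGE clusters: most gene TSSs get one (jittered), plus random clusters
  tss_cage <- genes[stats::runif(.N) < 0.8]
  cage_tss <- if (nrow(tss_cage)) data.table(
    chrom = tss_cage$chrom,
    start = pmax(0L, tss_cage$tss - 10L +
                   as.integer(sample(0:10, nrow(tss_cage), TRUE))),
    strand = tss_cage$strand) else data.table()
  n_rand_cage <- max(0L, config$n_cage_clusters - nrow(cage_tss))
  cage_rand <- data.table(
    chrom = sample(chroms, n_rand_cage, replace = TRUE),
    start = sample.int(L - 30L, n_rand_cage, replace = TRUE),
    strand = sample(c("+", "-"), n_rand_cage, replace = TRUE))
  cage <- rbind(cage_tss, cage_rand)
  cage[, end := start + 20L]
  cage <- cage[, list(chrom, start, end,
                      name = sprintf("cage%05d", seq_len(.N)),
                      score = 0L, strand)][order(chrom, start)]

  lnc <- simulate_lncrna_candidates(genes, exons, chrom_lengths,
                                    config$n_lncrna_candidates)
  # CAGE support for candidates marked as such: cluster at the 5' end
  sup <- lnc$meta[lnc$meta$cage_support == TRUE]
  if (nrow(sup)) {
    first <- lnc$exons[, list(start = min(start), end = max(end)),
                       by = list(transcript_id, chrom, strand)]
    first <- first[sup, on = "transcript_id"]
    cage_lnc <- data.table(
      chrom = first$chrom,
      start = ifelse(first$strand == "+", first$start, first$end - 1L) - 5L,
      strand = first$strand)
    cage_lnc[, start := pmax(0L, as.integer(start))]
    cage_lnc[, end := start + 20L]
    cage_lnc <- cage_lnc[, list(chrom, start, end,
                                name = sprintf("cagel%04d", seq_len(.N)),
                                score = 0L, strand)]
    cage <- rbind(cage, cage_lnc)[order(chrom, start)]
  }

  bundle <- list(config = config, chrom_lengths = chrom_lengths,
                 genome = genome, genes = genes, exons = exons,
                 enhancers = enhancers, cpg_islands = cpg_islands,
                 tads = tads, cage = cage,
                 lnc_exons = lnc$exons, lnc_meta = lnc$meta)
  class(bundle) <- "AnnotationBundle"
  bundle
}

# candidate transcripts spanning every classifier rule branch:
# antisense, intergenic, too_short, coding_potential, sense_overlap;
# roughly 60% of the valid ones get CAGE support
simulate_lncrna_candidates <- function(genes, exons, chrom_lengths, n) {
  n <- as.integer(n)
  kinds <- rep(c("antisense", "intergenic", "too_short", "coding_potential",
                 "sense_overlap"), length.out = n)
  ex_list <- list()
  meta_list <- list()
  for (i in seq_len(n)) {
    tid <- sprintf("lnc%04d", i)
    kind <- kinds[i]
    g <- genes[sample.int(nrow(genes), 1)]
    flip <- c("+" = "-", "-" = "+")
    if (kind %in% c("antisense", "sense_overlap", "coding_potential")) {
      # overlap the first exon of a coding gene
      e1 <- exons[gene_id == g$gene_id][1]
      strand <- if (kind == "sense_overlap") g$strand else flip[[g$strand]]
      if (kind == "coding_potential") strand <- flip[[g$strand]]
      start <- max(0L, e1$start - 200L)
      end <- min(chrom_lengths[[g$chrom]], e1$end + 400L)
    } else {
      # place in the gap upstream of a gene, away from any gene body
      gch <- genes[chrom == g$chrom]
      prev_end <- max(c(0L, gch[end <= g$start]$end))
      gap <- g$start - 200L - (prev_end + 200L)
      len <- if (kind == "too_short") 150L else min(800L, max(300L, gap - 10L))
      if (gap < len + 10L) { start <- NA } else {
        start <- prev_end + 200L + sample.int(gap - len, 1)
      }
      end <- start + len
      strand <- sample(c("+", "-"), 1)
    }
    if (is.na(start) || end - start < 120L) next
    if (kind == "too_short") {
      ex <- data.table(transcript_id = tid, chrom = g$chrom,
                       start = as.integer(start), end = as.integer(start + 150L),
                       strand = strand)
    } else {
      # two exons with a small intron when the span allows it
      span <- end - start
      if (span >= 500L) {
        w1 <- as.integer(span * 0.4); gapw <- as.integer(span * 0.2)
        ex <- data.table(
          transcript_id = tid, chrom = g$chrom,
          start = as.integer(c(start, start + w1 + gapw)),
          end = as.integer(c(start + w1, end)), strand = strand)
      } else {
        ex <- data.table(transcript_id = tid, chrom = g$chrom,
                         start = as.integer(start), end = as.integer(end),
                         strand = strand)
      }
    }
    ex_list[[tid]] <- ex
    meta_list[[tid]] <- data.table(
      transcript_id = tid, kind = kind,
      coding_potential = kind == "coding_potential",
      cage_support = kind %in% c("antisense", "intergenic") &&
        stats::runif(1) < 0.6)
  }
  list(exons = data.table::rbindlist(ex_list),
       meta = data.table::rbindlist(meta_list))
}

#' Locate CpG sites in a genome
#'
#' @param genome Named `DNAStringSet`.
#' @return `data.table` with `chrom` and 0-based `pos` of the C of each CG
#'   dinucleotide on the + strand, ordered by (chrom, pos).
#' @export
find_cpg_sites <- function(genome) {
  out <- lapply(names(genome), function(ch) {
    m <- Biostrings::matchPattern("CG", genome[[ch]])
    data.table(chrom = ch, pos = Biostrings::start(m) - 1L)
  })
  data.table::rbindlist(out)[order(chrom, pos)]
}

#' Simulate a bisulfite methylome experiment over an annotation bundle
#'
#' Plants `n_planted_dmrs` regions of `dmr_n_cpgs` consecutive CpGs each
#' (placement weighted towards introns and enhancers), writes motif
#' instances into the genome within +/-20 bp of a fraction of planted DM
#' CpGs (and of a background fraction of other CpGs), then draws per-CpG
#' per-sample counts: coverage ~ NB(mean_depth, depth_dispersion) and
#' methylated reads ~ beta-binomial around the site's condition-specific
#' methylation probability. Baselines of planted sites are drawn so the
#' full configured shift fits inside \[0, 1\] (no clamping of the planted
#' effect); all other sites are exchangeable between conditions.
#'
#' @param bundle An `AnnotationBundle` from [simulate_annotation_bundle()].
#' @param config The same [sim_config()] used for the bundle.
#' @return List with `methylome` (long per-strand count table: chrom, pos,
#'   strand, sample_id, condition, meth, unmeth), `truth` (list with
#'   `planted_dmrs`, `planted_motif_sites`), and `bundle` (input bundle
#'   with the motif-edited genome).
#' @export
simulate_methylome_experiment <- function(bundle, config) {
  stopifnot(inherits(bundle, "AnnotationBundle"),
            inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  cpgs <- find_cpg_sites(bundle$genome)
  if (nrow(cpgs) == 0 && config$n_planted_dmrs > 0) {
    stop("genome contains no CpG sites; cannot plant DMRs")
  }

  # placement weights from intron/enhancer membership
  w <- rep(config$dmr_feature_weights[["other"]], nrow(cpgs))
  if (nrow(cpgs)) {
    sites_gr <- GenomicRanges::GRanges(cpgs$chrom,
                                       IRanges::IRanges(cpgs$pos + 1L, width = 1))
    exon_gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      bundle$exons$chrom,
      IRanges::IRanges(bundle$exons$start + 1L, bundle$exons$end)))
    gene_gr <- GenomicRanges::GRanges(
      bundle$genes$chrom,
      IRanges::IRanges(bundle$genes$start + 1L, bundle$genes$end))
    intron_gr <- GenomicRanges::setdiff(gene_gr, exon_gr)
    enh_gr <- GenomicRanges::GRanges(
      bundle$enhancers$chrom,
      IRanges::IRanges(bundle$enhancers$start + 1L, bundle$enhancers$end))
    in_intron <- IRanges::overlapsAny(sites_gr, intron_gr)
    in_enh <- IRanges::overlapsAny(sites_gr, enh_gr)
    w[in_intron] <- config$dmr_feature_weights[["intron"]]
    w[in_enh] <- pmax(w[in_enh], config$dmr_feature_weights[["enhancer"]])
  }

  # --- choose planted regions: runs of dmr_n_cpgs consecutive CpGs -------
  m <- as.integer(config$dmr_n_cpgs)
  deltas <- rep(config$dmr_delta_pp, length.out = config$n_planted_dmrs)
  regions <- list()
  member_idx <- integer(0)
  if (config$n_planted_dmrs > 0) {
    max_span <- 400L
    buffer <- 1000L
    # candidate runs of m consecutive CpGs, weighted by their mean
    # member weight so whole regions (not just anchors) carry the
    # intron/enhancer preference
    n_cpg <- nrow(cpgs)
    if (n_cpg < m) stop("fewer CpGs in the genome than dmr_n_cpgs")
    starts_ok <- seq_len(n_cpg - m + 1L)
    jj <- starts_ok + m - 1L
    valid <- cpgs$chrom[starts_ok] == cpgs$chrom[jj] &
      (cpgs$pos[jj] + 2L - cpgs$pos[starts_ok]) <= max_span
    cw <- cumsum(w)
    run_w <- (cw[jj] - c(0, cw)[starts_ok]) / m
    run_w[!valid] <- 0
    if (sum(run_w) == 0) {
      stop(sprintf(
        "could not place planted DMRs: no run of %d CpGs within %d bp available",
        m, max_span))
    }
    taken <- data.table(chrom = character(0), start = integer(0),
                        end = integer(0))
    tries <- 0L
    k <- 1L
    while (k <= config$n_planted_dmrs) {
      tries <- tries + 1L
      if (tries > 20000L) {
        stop(sprintf(
          "could not place planted DMR %d: no run of %d CpGs within %d bp available",
          k, m, max_span))
      }
      i <- sample.int(length(run_w), 1, prob = run_w)
      j <- i + m - 1L
      span_start <- cpgs$pos[i]
      span_end <- cpgs$pos[j] + 2L
      clash <- taken[chrom == cpgs$chrom[i] &
                       start < span_end + buffer &
                       end > span_start - buffer]
      if (nrow(clash)) next
      taken <- rbind(taken, data.table(chrom = cpgs$chrom[i],
                                       start = span_start, end = span_end))
      regions[[k]] <- list(chrom = cpgs$chrom[i], start = span_start,
                           end = span_end, delta_pp = deltas[k],
                           member_pos = cpgs$pos[i:j])
      member_idx <- c(member_idx, i:j)
      k <- k + 1L
    }
  }

  # --- motif planting ----------------------------------------------------
  consensus_len <- nchar(config$motif_consensus)
  member_flag <- rep(FALSE, nrow(cpgs))
  member_flag[member_idx] <- TRUE
  dm_targets <- member_idx[stats::runif(length(member_idx)) <
                             config$motif_planting_fraction]
  bg_pool <- which(!member_flag)
  bg_targets <- bg_pool[stats::runif(length(bg_pool)) <
                          config$motif_background_fraction]
  prot_idx <- c(member_idx, bg_targets)
  prot_dt <- data.table(chrom = rep(cpgs$chrom[prot_idx], 2L),
                        pos = c(cpgs$pos[prot_idx], cpgs$pos[prot_idx] + 1L))
  prot_by_chrom <- lapply(split(prot_dt$pos, prot_dt$chrom),
                          function(p) sort(unique(p)))
  genome_chr <- lapply(as.character(bundle$genome), identity)
  motif_sites <- list()
  for (i in c(dm_targets, bg_targets)) {
    ch <- cpgs$chrom[i]
    pos <- cpgs$pos[i]
    cand <- seq(max(0L, pos - 20L),
                min(bundle$chrom_lengths[[ch]] - consensus_len, pos + 20L))
    prot <- prot_by_chrom[[ch]]
    local <- prot[prot >= pos - 20L - consensus_len & prot <= pos + 20L +
                    consensus_len]
    ok <- vapply(cand, function(s) {
      !any(local >= s & local < s + consensus_len)
    }, logical(1))
    cand <- cand[ok]
    if (!length(cand)) next
    s <- cand[sample.int(length(cand), 1)]
    inst <- realize_iupac(config$motif_consensus)
    substr(genome_chr[[ch]], s + 1L, s + consensus_len) <- inst
    # protect the inserted instance from later overlapping insertions
    prot_by_chrom[[ch]] <- c(prot_by_chrom[[ch]],
                             seq(s, s + consensus_len - 1L))
    motif_sites[[length(motif_sites) + 1L]] <-
      data.table(chrom = ch, position = s, strand = "+",
                 near_dm = member_flag[i])
  }
  genome2 <- Biostrings::DNAStringSet(unlist(genome_chr))
  names(genome2) <- names(bundle$genome)
  bundle$genome <- genome2

  # re-enumerate CpGs on the edited genome; planted members must survive
  cpgs <- find_cpg_sites(genome2)
  if (length(member_idx)) {
    member_key <- unlist(lapply(regions, function(r)
      paste(r$chrom, r$member_pos)))
    stopifnot(all(member_key %in% paste(cpgs$chrom, cpgs$pos)))
    member_flag <- paste(cpgs$chrom, cpgs$pos) %in% member_key
  } else {
    member_flag <- rep(FALSE, nrow(cpgs))
  }

  # --- baselines and planted shifts --------------------------------------
  mix <- config$baseline_meth_mixture
  nsite <- nrow(cpgs)
  comp_hypo <- stats::runif(nsite) < mix$weight_hypo
  baseline <- ifelse(comp_hypo,
                     stats::rbeta(nsite, mix$hypo[1], mix$hypo[2]),
                     stats::rbeta(nsite, mix$hyper[1], mix$hyper[2]))
  delta_site <- rep(0, nsite)
  if (length(regions)) {
    key <- paste(cpgs$chrom, cpgs$pos)
    for (r in regions) {
      ii <- match(paste(r$chrom, r$member_pos), key)
      d <- r$delta_pp / 100
      lo <- max(0.02, 0.02 - d)
      hi <- min(0.98, 0.98 - d)
      baseline[ii] <- stats::runif(length(ii), lo, hi)
      delta_site[ii] <- d
    }
  }

  # --- counts ------------------------------------------------------------
  nrep <- as.integer(config$n_replicates_per_condition)
  samples <- c(sprintf("uncut_%d", seq_len(nrep)),
               sprintf("cut_%d", seq_len(nrep)))
  conditions <- rep(c("uncut", "cut"), each = nrep)
  conc <- config$replicate_concentration
  tabs <- vector("list", length(samples))
  for (si in seq_along(samples)) {
    pi_site <- baseline + if (conditions[si] == "cut") delta_site else 0
    pi_site <- pmin(1, pmax(0, pi_site))
    cov <- stats::rnbinom(nsite, size = config$depth_dispersion,
                          mu = config$mean_depth)
    pi_rep <- ifelse(pi_site <= 0 | pi_site >= 1, pi_site,
                     stats::rbeta(nsite, pi_site * conc,
                                  (1 - pi_site) * conc))
    meth <- stats::rbinom(nsite, cov, pi_rep)
    # split the dyad's reads between the two strand records
    cov_p <- stats::rbinom(nsite, cov, 0.5)
    meth_p <- suppressWarnings(stats::rhyper(nsite, meth, cov - meth, cov_p))
    meth_p[is.na(meth_p)] <- 0L
    plus <- data.table(chrom = cpgs$chrom, pos = cpgs$pos, strand = "+",
                       sample_id = samples[si], condition = conditions[si],
                       meth = meth_p, unmeth = cov_p - meth_p)
    minus <- data.table(chrom = cpgs$chrom, pos = cpgs$pos + 1L,
                        strand = "-",
                        sample_id = samples[si], condition = conditions[si],
                        meth = meth - meth_p,
                        unmeth = (cov - cov_p) - (meth - meth_p))
    tab <- rbind(plus, minus)
    tabs[[si]] <- tab[meth + unmeth > 0]
  }
  methylome <- data.table::rbindlist(tabs)[order(chrom, pos, sample_id)]

  truth <- list(
    planted_dmrs = if (length(regions)) data.table(
      chrom = vapply(regions, `[[`, character(1), "chrom"),
      start = vapply(regions, `[[`, numeric(1), "start"),
      end = vapply(regions, `[[`, numeric(1), "end"),
      delta_pp = vapply(regions, `[[`, numeric(1), "delta_pp"),
      member_pos = I(lapply(regions, `[[`, "member_pos"))
    ) else data.table(chrom = character(0), start = numeric(0),
                      end = numeric(0), delta_pp = numeric(0),
                      member_pos = I(list())),
    planted_motif_sites = if (length(motif_sites))
      data.table::rbindlist(motif_sites)
    else data.table(chrom = character(0), position = integer(0),
                    strand = character(0), near_dm = logical(0)))
  list(methylome = methylome, truth = truth, bundle = bundle)
}

#' Simulate differential-expression tables, gene sets, and ortholog maps
#'
#' Emits a DE table over a configurable gene universe in which membership
#' of the designated EMT set multiplies a gene's odds of being DE by
#' `emt_de_or`; the baseline DE odds are solved so the expected number of
#' DE genes equals `n_de_genes`. Also emits the EMT set as human symbols,
#' a human-to-mouse ortholog map with a configurable unmapped fraction,
#' and the ground truth.
#'
#' @param bundle An `AnnotationBundle` (its gene ids head the universe).
#' @param config A [sim_config()].
#' @return List with `de_table` (id, log2fc, padj, de), `emt_human_symbols`,
#'   `ortholog_map` (human, mouse), and `truth` (planted_de_ids table and
#'   the planted odds ratio).
#' @export
simulate_expression_tables <- function(bundle, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  n_univ <- as.integer(config$n_expression_genes)
  ids <- sprintf("gene%05d", seq_len(n_univ))
  if (!is.null(bundle$genes) && nrow(bundle$genes) > 0) {
    stopifnot(nrow(bundle$genes) <= n_univ)
    ids[seq_len(nrow(bundle$genes))] <- bundle$genes$gene_id
  }
  n_de <- config$n_de_genes
  if (n_de >= n_univ) stop("n_de_genes must be smaller than the universe")

  emt_mouse <- sort(sample(ids, config$emt_set_size))
  in_emt <- ids %in% emt_mouse
  or <- config$emt_de_or
  s <- sum(in_emt)
  f <- function(o) {
    p_out <- o / (1 + o)
    p_in <- (or * o) / (1 + or * o)
    (n_univ - s) * p_out + s * p_in - n_de
  }
  root <- tryCatch(stats::uniroot(f, c(1e-9, 1e9), tol = 1e-12),
                   error = function(e) stop(
                     "requested EMT enrichment odds ratio infeasible for the given margins"))
  o <- root$root
  p_de <- ifelse(in_emt, (or * o) / (1 + or * o), o / (1 + o))
  de <- stats::runif(n_univ) < p_de

  sign <- sample(c(-1, 1), n_univ, replace = TRUE)
  log2fc <- ifelse(de,
                   sign * pmax(0.5, config$de_log2fc +
                                 stats::rnorm(n_univ, 0, 0.5)),
                   stats::rnorm(n_univ, 0, 0.2))
  padj <- ifelse(de, stats::runif(n_univ, 0, 0.049),
                 stats::runif(n_univ, 0.05, 1))
  de_table <- data.table(id = ids, log2fc = round(log2fc, 4),
                         padj = signif(padj, 4), de = de)
  # lncRNA candidates appear in the DE table too (a third of them DE)
  if (!is.null(bundle$lnc_meta) && nrow(bundle$lnc_meta) > 0) {
    lid <- bundle$lnc_meta$transcript_id
    lde <- stats::runif(length(lid)) < 1 / 3
    de_table <- rbind(de_table, data.table(
      id = lid,
      log2fc = round(ifelse(lde, sample(c(-1, 1), length(lid), TRUE) *
                              pmax(0.5, config$de_log2fc +
                                     stats::rnorm(length(lid), 0, 0.5)),
                            stats::rnorm(length(lid), 0, 0.2)), 4),
      padj = signif(ifelse(lde, stats::runif(length(lid), 0, 0.049),
                           stats::runif(length(lid), 0.05, 1)), 4),
      de = lde))
  }

  # human symbols for the EMT set; ortholog map human -> mouse
  human <- toupper(emt_mouse)
  unmapped <- stats::runif(length(human)) < config$ortholog_unmapped_fraction
  ortholog_map <- data.table(human = human[!unmapped],
                             mouse = emt_mouse[!unmapped])
  truth <- list(
    planted_de_ids = data.table(id = ids[de], log2fc = log2fc[de],
                                in_emt_set = in_emt[de]),
    emt_mouse_ids = emt_mouse,
    emt_de_or = or)
  list(de_table = de_table, emt_human_symbols = human,
       ortholog_map = ortholog_map, truth = truth)
}
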