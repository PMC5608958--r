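# Independent oracles used by unit and acceptance tests. They deliberately
# avoid the code paths they check: exact enumeration with choose(), the BH
# definition written out in O(m^2), and graph-component single linkage.

# Two-sided Fisher exact p by exhaustive enumeration over the support of
# the table's margins. choose() values are exact integers for the margins
# used here, so the tie comparison is exact.
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c
  if (r1 == 0 || r2 == 0 || k == 0 || (b + d) == 0) return(1)
  xs <- max(0, k - r2):min(k, r1)
  num <- choose(r1, xs) * choose(r2, k - xs)
  obs <- choose(r1, a) * choose(r2, k - a)
  sum(num[num <= obs]) / choose(r1 + r2, k)
}

# BH from its definition: q_i = min over j with p_(j) >= p_(i) of
# p_(j) * m / rank(j), capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  sp <- sort(p)
  vapply(p, function(pi) {
    js <- which(sp >= pi)
    min(1, min(sp[js] * m / js))
  }, numeric(1))
}

# Single-linkage clustering at a distance cutoff as connected components of
# the pairwise adjacency graph, O(n^2); returns a list of member position
# vectors for components with >= min_sites members.
oracle_cluster <- function(pos, max_gap, min_sites = 2) {
  n <- length(pos)
  if (n == 0) return(list())
  adj <- abs(outer(pos, pos, "-")) <= max_gap
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  out <- split(pos, comp)
  out <- lapply(out, sort)
  unname(out[vapply(out, length, integer(1)) >= min_sites])
}

# small deterministic annotation bundle built by hand for feature tests:
# one 100 kb chromosome, two genes, one enhancer inside gene1's intron,
# one free-standing enhancer, one CpG island
toy_bundle <- function() {
  genes <- data.table::data.table(
    gene_id = c("geneA", "geneB"),
    chrom = "chr1",
    start = c(10000L, 50000L), end = c(20000L, 60000L),
    strand = c("+", "-"),
    tss = c(10000L, 59999L))
  exons <- data.table::data.table(
    gene_id = c("geneA", "geneA", "geneB", "geneB"),
    exon_number = c(1L, 2L, 1L, 2L),
    chrom = "chr1",
    start = c(10000L, 18000L, 50000L, 58000L),
    end = c(11000L, 20000L, 52000L, 60000L),
    strand = c("+", "+", "-", "-"))
  enhancers <- data.table::data.table(
    chrom = "chr1", start = c(15000L, 40000L), end = c(15500L, 40500L),
    name = c("enh1", "enh2"), score = 0L, strand = ".")
  cpg_islands <- data.table::data.table(
    chrom = "chr1", start = 70000L, end = 70800L,
    name = "cgi1", score = 0L, strand = ".")
  list(chrom_lengths = c(chr1 = 100000L),
       genes = genes, exons = exons,
       enhancers = enhancers, cpg_islands = cpg_islands,
       tads = NULL, cage = NULL)
}

# 10-transcript toy annotation covering every lncRNA classifier branch,
# with hand-derived expected labels
toy_lncrna_case <- function() {
  genes <- data.table::data.table(
    gene_id = "gene1", chrom = "chr1", start = 10000L, end = 14000L,
    strand = "+", tss = 10000L)
  t <- function(id, starts, ends, strand) {
    data.table::data.table(transcript_id = id, chrom = "chr1",
                           start = as.integer(starts),
                           end = as.integer(ends), strand = strand)
  }
  exons <- rbind(
    t("tx01", 11000, 11900, "-"),                      # antisense, CAGE at 5'
    t("tx02", c(30000, 31000), c(30400, 31400), "+"),  # intergenic, CAGE
    t("tx03", 40000, 40150, "+"),                      # too short (150 nt)
    t("tx04", 50000, 50800, "+"),                      # coding potential
    t("tx05", 11000, 11900, "+"),                      # sense overlap
    t("tx06", 12500, 13300, "-"),                      # antisense, no CAGE
    t("tx07", 60000, 60800, "-"),                      # intergenic, no CAGE
    t("tx08", 70000, 70201, "+"),                      # 201 nt: > 200, keeps
    t("tx09", 9000, 9800, "-"),                        # upstream, intergenic
    t("tx10", 13900, 14300, "+"))                      # sense overlap at tail
  meta <- data.table::data.table(
    transcript_id = sprintf("tx%02d", 1:10),
    coding_potential = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                         FALSE, FALSE, FALSE))
  cage <- data.table::data.table(
    chrom = "chr1",
    start = c(11880L, 29990L, 70000L),
    end = c(11920L, 30020L, 70010L),
    name = c("c1", "c2", "c3"), score = 0L,
    strand = c("-", "+", "+"))
  expected <- data.table::data.table(
    transcript_id = sprintf("tx%02d", 1:10),
    klass = c("antisense", "intergenic", "rejected", "rejected", "rejected",
              "antisense", "intergenic", "intergenic", "intergenic",
              "rejected"),
    reject_reason = c(NA, NA, "too_short", "coding_potential",
                      "sense_overlap", NA, NA, NA, NA, "sense_overlap"),
    high_confidence = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                        TRUE, FALSE, FALSE))
  list(genes = genes, exons = exons, meta = meta, cage = cage,
       expected = expected)
}

small_sim_config <- function(seed = 1L, ...) {
  defaults <- list(seed = seed, n_chromosomes = 1L, chrom_length = 1e5,
                   n_genes = 10L, n_planted_dmrs = 5L, n_enhancers = 10L,
                   n_tads = 3L, n_cage_clusters = 30L, n_cpg_islands = 8L,
                   n_lncrna_candidates = 15L, n_expression_genes = 500L,
                   n_de_genes = 80L, emt_set_size = 25L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
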