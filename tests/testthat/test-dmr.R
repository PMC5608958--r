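dm_dt <- function(pos, delta = 30, chrom = "chr1") {
  data.table::data.table(chrom = chrom, pos = as.integer(pos),
                         delta_pp = rep_len(delta, length(pos)))
}

test_that("chaining reproduces the worked example", {
  out <- cluster_dmrs(dm_dt(c(100, 480, 900, 2000, 2400)))
  expect_equal(nrow(out), 2)
  expect_equal(out$member_pos[[1]], c(100L, 480L, 900L))
  expect_equal(out$member_pos[[2]], c(2000L, 2400L))
  expect_equal(out$start, c(100L, 2000L))
  expect_equal(out$end, c(902L, 2402L))   # last member + 2 covers the dyad
  expect_equal(out$n_sites, c(3L, 2L))
})

test_that("single sites and boundary gaps behave as specified", {
  expect_equal(nrow(cluster_dmrs(dm_dt(100))), 0)
  expect_equal(nrow(cluster_dmrs(data.table::data.table(
    chrom = character(0), pos = integer(0), delta_pp = numeric(0)))), 0)
  # gap of exactly 500 is inclusive
  out <- cluster_dmrs(dm_dt(c(0, 500)))
  expect_equal(nrow(out), 1)
  expect_equal(out$n_sites, 2L)
  # gap 501 splits
  expect_equal(nrow(cluster_dmrs(dm_dt(c(0, 501)))), 0)
})

test_that("direction is hyper/hypo/mixed by member delta signs", {
  expect_equal(cluster_dmrs(dm_dt(c(0, 100), delta = 30))$direction, "hyper")
  expect_equal(cluster_dmrs(dm_dt(c(0, 100), delta = -30))$direction, "hypo")
  expect_equal(cluster_dmrs(dm_dt(c(0, 100),
                                  delta = c(30, -30)))$direction, "mixed")
})

test_that("chaining equals the O(n^2) single-linkage oracle", {
  set.seed(19)
  for (i in 1:100) {
    n <- sample(1:200, 1)
    pos <- sort(sample.int(20000, n))
    got <- cluster_dmrs(dm_dt(pos))
    want <- oracle_cluster(pos, 500, 2)
    expect_equal(length(got$member_pos), length(want))
    expect_equal(lapply(got$member_pos, as.integer),
                 lapply(want, as.integer))
    # invariants: member gaps <= max_gap, members do not exceed input
    expect_true(all(unlist(lapply(got$member_pos,
                                  function(m) diff(m) <= 500))))
    expect_lte(sum(got$n_sites), n)
    # regions pairwise disjoint
    if (nrow(got) > 1) {
      expect_true(all(got$start[-1] > got$end[-nrow(got)]))
    }
  }
})

test_that("per-TAD DM fractions cover the arithmetic and NA cases", {
  tads <- data.table::data.table(
    chrom = "chr1", start = c(0L, 10000L, 20000L),
    end = c(10000L, 20000L, 30000L),
    name = c("t1", "t2", "t3"), score = 0L, strand = ".")
  all_sites <- data.table::data.table(
    chrom = "chr1", pos = c(seq(0, 9999, by = 10), seq(10000, 19999, by = 10)))
  dm_sites <- data.table::data.table(chrom = "chr1",
                                     pos = c(10005L, 10015L, 10025L, 10035L))
  genes <- data.table::data.table(gene_id = c("gA", "gB"), chrom = "chr1",
                                  tss = c(500L, 10500L))
  out <- tad_dm_fraction(all_sites, dm_sites, tads, genes)
  expect_equal(out$pct_dm, c(0, 0.4, NA))
  expect_equal(out$n_tested, c(1000L, 1000L, 0L))
  expect_equal(out$genes, c("gA", "gB", ""))
  # overlapping TADs rejected
  bad <- data.table::data.table(chrom = "chr1", start = c(0L, 5000L),
                                end = c(10000L, 15000L), name = c("a", "b"))
  expect_error(tad_dm_fraction(all_sites, dm_sites, bad), "overlap")
})

test_that("planted DMRs are recovered on simulator output", {
  cfg <- small_sim_config(seed = 14L)
  b <- simulate_annotation_bundle(cfg)
  m <- simulate_methylome_experiment(b, cfg)
  called <- call_dm(test_dm_sites(collapse_and_filter(m$methylome)))
  dmrs <- cluster_dmrs(called[called$is_dm])
  truth <- m$truth$planted_dmrs
  tg <- GenomicRanges::GRanges(truth$chrom,
                               IRanges::IRanges(truth$start + 1, truth$end))
  pg <- GenomicRanges::GRanges(dmrs$chrom,
                               IRanges::IRanges(dmrs$start + 1, dmrs$end))
  expect_gte(mean(GenomicRanges::countOverlaps(tg, pg) > 0), 0.8)
  expect_gte(mean(GenomicRanges::countOverlaps(pg, tg) > 0), 0.8)
})
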