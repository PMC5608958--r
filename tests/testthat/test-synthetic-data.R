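test_that("annotation bundle simulation is deterministic", {
  cfg <- small_sim_config(seed = 3L)
  b1 <- simulate_annotation_bundle(cfg)
  b2 <- simulate_annotation_bundle(cfg)
  expect_identical(as.character(b1$genome), as.character(b2$genome))
  expect_identical(b1$genes, b2$genes)
  expect_identical(b1$enhancers, b2$enhancers)
  expect_identical(b1$cage, b2$cage)
})

test_that("gc_fraction = 0 yields a genome with no C/G and no CpGs", {
  cfg <- small_sim_config(gc_fraction = 0, n_planted_dmrs = 0L,
                          n_cage_clusters = 5L)
  b <- simulate_annotation_bundle(cfg)
  comp <- Biostrings::alphabetFrequency(b$genome[[1]])
  expect_equal(unname(comp["C"] + comp["G"]), 0)
  expect_equal(nrow(find_cpg_sites(b$genome)), 0)
})

test_that("gene models are pairwise disjoint and within bounds", {
  cfg <- small_sim_config(seed = 9L)
  b <- simulate_annotation_bundle(cfg)
  g <- b$genes[order(chrom, start)]
  expect_equal(nrow(g), 10)
  expect_true(all(g$start >= 0 & g$end <= 1e5))
  # interval sweep per chromosome: starts strictly after previous ends
  for (ch in unique(g$chrom)) {
    gc <- g[g$chrom == ch]
    if (nrow(gc) > 1) {
      expect_true(all(gc$start[-1] >= gc$end[-nrow(gc)]))
    }
  }
  # exons lie within their gene and tile without overlap
  for (gid in g$gene_id) {
    ex <- b$exons[b$exons$gene_id == gid][order(start)]
    gg <- g[g$gene_id == gid]
    expect_true(all(ex$start >= gg$start & ex$end <= gg$end))
    if (nrow(ex) > 1) expect_true(all(ex$start[-1] > ex$end[-nrow(ex)]))
  }
})

test_that("unplaceable gene sets raise a capacity error", {
  cfg <- small_sim_config(n_genes = 30L, gene_span = c(4000L, 5000L))
  expect_error(simulate_annotation_bundle(cfg), "cannot place")
})

test_that("methylome counts have the configured mean depth", {
  cfg <- small_sim_config(seed = 2L, mean_depth = 30,
                          n_planted_dmrs = 0L)
  b <- simulate_annotation_bundle(cfg)
  m <- simulate_methylome_experiment(b, cfg)
  coll <- collapse_and_filter(m$methylome, min_cov = 0, scope = "pooled")
  cov <- coll[, list(cov = sum(meth + unmeth) /
                       length(unique(coll$sample_id))),
              by = list(chrom, pos)]
  expect_gt(nrow(cov), 1e3)
  expect_lt(abs(mean(cov$cov) - 30), 3)   # within 10% of 30
})

test_that("no planted DMRs gives an empty truth set and exchangeable arms", {
  cfg <- small_sim_config(seed = 4L, n_planted_dmrs = 0L)
  b <- simulate_annotation_bundle(cfg)
  m <- simulate_methylome_experiment(b, cfg)
  expect_equal(nrow(m$truth$planted_dmrs), 0)
  coll <- collapse_and_filter(m$methylome)
  pooled <- coll[, list(frac = sum(meth) / sum(meth + unmeth)),
                 by = condition]
  expect_lt(abs(diff(pooled$frac)), 0.01)
})

test_that("planted delta is recovered without bias (Monte Carlo)", {
  # depth 100, n = 5: pooled cut-minus-uncut within +/-5 pp of +40
  cfg <- small_sim_config(seed = 6L, mean_depth = 100,
                          n_replicates_per_condition = 5L,
                          n_planted_dmrs = 8L, dmr_delta_pp = 40)
  b <- simulate_annotation_bundle(cfg)
  m <- simulate_methylome_experiment(b, cfg)
  coll <- collapse_and_filter(m$methylome)
  tests <- test_dm_sites(coll)
  key <- paste(tests$chrom, tests$pos)
  truth <- m$truth$planted_dmrs
  mem <- unlist(lapply(seq_len(nrow(truth)), function(i)
    paste(truth$chrom[i], truth$member_pos[[i]])))
  d <- tests$delta_pp[match(mem, key)]
  expect_gt(sum(!is.na(d)), 20)
  expect_lt(abs(mean(d, na.rm = TRUE) - 40), 5)
})

test_that("planted DMR members are CG dinucleotides in the emitted FASTA", {
  cfg <- small_sim_config(seed = 8L)
  b <- simulate_annotation_bundle(cfg)
  m <- simulate_methylome_experiment(b, cfg)
  truth <- m$truth$planted_dmrs
  for (i in seq_len(nrow(truth))) {
    seqs <- vapply(truth$member_pos[[i]], function(p) {
      as.character(Biostrings::subseq(m$bundle$genome[[truth$chrom[i]]],
                                      p + 1, p + 2))
    }, character(1))
    expect_true(all(seqs == "CG"))
  }
  # planted motif instances are present in the genome
  ms <- m$truth$planted_motif_sites
  expect_gt(nrow(ms), 0)
  inst <- vapply(seq_len(nrow(ms)), function(i) {
    as.character(Biostrings::subseq(m$bundle$genome[[ms$chrom[i]]],
                                    ms$position[i] + 1,
                                    ms$position[i] + 7))
  }, character(1))
  expect_true(all(inst == "TGACTCA"))
})

test_that("expression tables are deterministic and respect the config", {
  cfg <- small_sim_config(seed = 5L)
  b <- simulate_annotation_bundle(cfg)
  e1 <- simulate_expression_tables(b, cfg)
  e2 <- simulate_expression_tables(b, cfg)
  expect_identical(e1$de_table, e2$de_table)
  # unmapped fraction 0: every EMT human symbol maps to exactly one mouse id
  expect_equal(e1$ortholog_map$human, toupper(e1$ortholog_map$mouse))
  expect_equal(sort(e1$ortholog_map$mouse), e1$truth$emt_mouse_ids)
  expect_equal(anyDuplicated(e1$ortholog_map$human), 0)
  # unmapped fraction drops rows
  cfg2 <- small_sim_config(seed = 5L, ortholog_unmapped_fraction = 0.5)
  e3 <- simulate_expression_tables(b, cfg2)
  expect_lt(nrow(e3$ortholog_map), nrow(e1$ortholog_map))
})

test_that("planted null gene-set enrichment estimates OR near 1", {
  ors <- vapply(1:20, function(i) {
    cfg <- small_sim_config(seed = 100L + i, emt_de_or = 1)
    e <- simulate_expression_tables(list(genes = NULL), cfg)
    det <- e$de_table
    fisher_set_enrichment(e$truth$emt_mouse_ids, det$id[det$de],
                          det$id)$odds_ratio
  }, numeric(1))
  gm <- exp(mean(log(ors)))
  expect_gt(gm, 0.7)
  expect_lt(gm, 1.4)
})

test_that("infeasible expression configurations error", {
  cfg <- small_sim_config(n_de_genes = 600L)  # exceeds universe
  expect_error(simulate_expression_tables(list(genes = NULL), cfg),
               "smaller than the universe")
  expect_error(small_sim_config(emt_set_size = 600L), "n_expression_genes")
  expect_error(small_sim_config(dmr_delta_pp = 100), "dmr_delta_pp")
  expect_error(small_sim_config(gc_fraction = 1.2), "gc_fraction")
})
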