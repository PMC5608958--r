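test_that("feature precedence and orthogonal enhancer overlap", {
  b <- toy_bundle()
  sites <- data.table::data.table(
    chrom = "chr1",
    pos = c(10200L,  # promoter window AND first exon -> promoter
            15100L,  # intron of geneA AND enh1 -> intron, overlap flag
            40100L,  # enh2 only -> enhancer
            70100L,  # cgi only -> cpg_island
            95000L,  # nothing -> intergenic
            12000L)) # intron only
  asg <- assign_features(sites, b)
  expect_equal(as.character(asg$primary_label),
               c("promoter", "intron", "enhancer", "cpg_island",
                 "intergenic", "intron"))
  expect_equal(asg$enhancer_overlap, c(FALSE, TRUE, TRUE, FALSE, FALSE,
                                       FALSE))
  # exactly one primary label each; percentages sum to 100
  tab <- table(asg$primary_label)
  expect_equal(sum(tab), nrow(sites))
})

test_that("signed TSS distances follow gene strand", {
  b <- toy_bundle()
  # geneA TSS at 10000 (+): site 9400 is 600 bp upstream
  asg <- assign_features(data.table::data.table(chrom = "chr1",
                                                pos = 9400L), b)
  expect_equal(asg$tss_distance, -600)
  expect_equal(asg$orientation, "upstream")
  expect_equal(asg$nearest_gene, "geneA")
  # geneB TSS at 59999 (-): site 59399 is downstream (+600)
  asg2 <- assign_features(data.table::data.table(chrom = "chr1",
                                                 pos = 59399L), b)
  expect_equal(asg2$tss_distance, 600)
  expect_equal(asg2$orientation, "downstream")
  # equidistant between the two TSSs: lower gene id wins
  mid <- (10000L + 59999L) %/% 2L  # 34999, distances 24999/25000 -> geneA
  asg3 <- assign_features(data.table::data.table(
    chrom = "chr1", pos = c(mid, mid + 1L)), b)
  expect_equal(asg3$nearest_gene, c("geneA", "geneB"))
  # exact tie resolves to the lexicographically lower gene id
  tie_genes <- data.table::data.table(
    gene_id = c("gB", "gA"), chrom = "chr1", start = c(300L, 100L),
    end = c(400L, 200L), strand = "+", tss = c(300L, 100L))
  near <- dmrkit:::nearest_gene_tss("chr1", 200L, tie_genes)
  expect_equal(near$nearest_gene, "gA")
  # unknown chromosome: intergenic with a warning counter
  asg4 <- assign_features(data.table::data.table(chrom = "chrUn",
                                                 pos = 5L), b)
  expect_equal(as.character(asg4$primary_label), "intergenic")
  expect_equal(attr(asg4, "n_unknown_chrom"), 1)
})

test_that("TSS distance bins count sites by |distance| and orientation", {
  b <- toy_bundle()
  sites <- data.table::data.table(
    chrom = "chr1", pos = c(9400L, 9900L, 5000L, 30000L))
  asg <- assign_features(sites, b)
  bins <- tss_distance_bins(asg)
  expect_equal(sum(bins$count), nrow(sites))
  # 9400 and 9900 are upstream within [0, 1k)
  expect_equal(bins[bins$bin == "[0,1e+03)" &
                      bins$orientation == "upstream"]$count, 2L)
  expect_error(tss_distance_bins(asg, bin_edges = c(5, 1)), "increasing")
})

test_that("coverage-matched background matches strata and is deterministic", {
  set.seed(1)
  all_s <- data.table::data.table(
    chrom = "chr1", pos = seq_len(5000),
    cov_mean = c(runif(2500, 5, 15), runif(2500, 30, 60)))
  dm <- all_s[pos %in% sample(2501:5000, 80)]  # all high coverage
  bg <- coverage_matched_background(dm, all_s, n_strata = 2,
                                    multiplier = 5, seed = 42)
  expect_equal(nrow(bg), 400)
  expect_true(all(bg$cov_mean >= 30))          # drawn from the DM stratum
  expect_false(any(paste(bg$chrom, bg$pos) %in% paste(dm$chrom, dm$pos)))
  bg2 <- coverage_matched_background(dm, all_s, n_strata = 2,
                                     multiplier = 5, seed = 42)
  expect_identical(bg, bg2)
  # degenerate single stratum, multiplier 1: simple random sample
  bg3 <- coverage_matched_background(dm, all_s, n_strata = 1,
                                     multiplier = 1, seed = 1)
  expect_equal(nrow(bg3), nrow(dm))
  # per-stratum proportions track the query within 2 pp
  bg4 <- coverage_matched_background(dm, all_s, n_strata = 10,
                                     multiplier = 10, seed = 3)
  qs <- quantile(all_s$cov_mean, probs = seq(0, 1, 0.1))
  pq <- table(cut(dm$cov_mean, qs, include.lowest = TRUE)) / nrow(dm)
  pb <- table(cut(bg4$cov_mean, qs, include.lowest = TRUE)) / nrow(bg4)
  expect_true(all(abs(pq - pb) <= 0.02))
})

test_that("feature enrichment uses the shared Fisher/Woolf machinery", {
  qa <- data.table::data.table(
    primary_label = factor(rep(c("intron", "intergenic"), c(3, 1)),
                           levels = dmrkit:::FEATURE_LEVELS),
    enhancer_overlap = FALSE)
  ba <- data.table::data.table(
    primary_label = factor(rep(c("intron", "intergenic"), c(1, 3)),
                           levels = dmrkit:::FEATURE_LEVELS),
    enhancer_overlap = FALSE)
  enr <- feature_enrichment(qa, ba)
  intron <- enr[enr$label == "intron"]
  expect_equal(intron$odds_ratio, 9)
  expect_equal(intron$p, 34 / 70, tolerance = 1e-12)
  expect_equal(intron$p, oracle_fisher_p(3, 1, 1, 3), tolerance = 1e-12)
  # zero cells stay finite through Haldane correction
  expect_true(all(is.finite(enr$odds_ratio)))
  expect_error(feature_enrichment(qa[0], ba), "non-empty")
})

test_that("enhancer proximity relations and distances", {
  enh <- data.table::data.table(chrom = "chr1", start = 4900L, end = 5100L,
                                name = "enhX", score = 0L, strand = ".")
  genes <- data.table::data.table(gene_id = "gZ", chrom = "chr1",
                                  tss = 4000L)
  sites <- data.table::data.table(chrom = c("chr1", "chr1", "chr2"),
                                  pos = c(5000L, 6050L, 100L))
  out <- enhancer_proximity(sites, enh, max_dist = 1000, genes = genes)
  expect_equal(out$relation, c("overlap", "proximal", "distal"))
  expect_equal(out$distance, c(0, 951, Inf))
  expect_equal(out$associated_gene, c("gZ", "gZ", NA))
  # distance just past the threshold is distal
  out2 <- enhancer_proximity(data.table::data.table(chrom = "chr1",
                                                    pos = 6101L),
                             enh, max_dist = 1000)
  expect_equal(out2$relation, "distal")
})
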