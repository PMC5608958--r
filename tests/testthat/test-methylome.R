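make_meth <- function(...) {
  data.table::rbindlist(list(...))
}

rec <- function(chrom, pos, strand, sample_id, condition, meth, unmeth) {
  data.table::data.table(chrom = chrom, pos = as.integer(pos),
                         strand = strand, sample_id = sample_id,
                         condition = condition, meth = as.integer(meth),
                         unmeth = as.integer(unmeth))
}

test_that("dyad collapse sums strand records at the + anchor", {
  tab <- make_meth(
    rec("chr1", 100, "+", "s1", "uncut", 3, 1),
    rec("chr1", 101, "-", "s1", "uncut", 2, 2))
  out <- collapse_and_filter(tab, min_cov = 0)
  expect_equal(nrow(out), 1)
  expect_equal(out$pos, 100)
  expect_equal(out$meth, 5)
  expect_equal(out$unmeth, 3)
  expect_false(out$one_sided)

  # lone minus record stays at its own position, flagged
  lone <- collapse_and_filter(rec("chr1", 101, "-", "s1", "uncut", 2, 2),
                              min_cov = 0)
  expect_equal(lone$pos, 101)
  expect_true(lone$one_sided)
})

test_that("collapse without a strand column pairs adjacent positions", {
  tab <- data.table::data.table(
    chrom = "chr1", pos = c(100L, 101L, 105L),
    sample_id = "s1", condition = "uncut",
    meth = c(3L, 2L, 1L), unmeth = c(1L, 2L, 4L))
  out <- collapse_and_filter(tab, min_cov = 0)
  expect_equal(out$pos, c(100L, 105L))
  expect_equal(out$meth, c(5L, 1L))
  expect_equal(out$one_sided, c(FALSE, TRUE))
})

test_that("every-sample coverage filter applies the >=5 threshold", {
  totals_ok <- c(5, 7, 9, 6, 5, 8)
  totals_bad <- c(4, 7, 9, 6, 5, 8)
  build <- function(totals) {
    data.table::rbindlist(lapply(seq_along(totals), function(i) {
      rec("chr1", 200, "+", sprintf("s%d", i),
          ifelse(i <= 3, "uncut", "cut"), totals[i] - 1, 1)
    }))
  }
  expect_equal(nrow(collapse_and_filter(build(totals_ok))), 6)
  expect_equal(nrow(collapse_and_filter(build(totals_bad))), 0)
  # pooled scope keeps the site either way
  expect_equal(nrow(collapse_and_filter(build(totals_bad),
                                        scope = "pooled")), 6)
  # a sample with an absent record fails every-sample scope
  partial <- build(totals_ok)[-2]
  expect_equal(nrow(collapse_and_filter(
    partial, samples = sprintf("s%d", 1:6))), 0)
})

test_that("empty tables collapse to empty tables", {
  out <- collapse_and_filter(data.table::data.table(
    chrom = character(0), pos = integer(0), sample_id = character(0),
    condition = character(0), meth = integer(0), unmeth = integer(0)))
  expect_equal(nrow(out), 0)
})

test_that("per-site test reproduces the pooled Fisher example", {
  tab <- make_meth(
    rec("chr1", 100, "+", "u1", "uncut", 18, 2),
    rec("chr1", 100, "+", "c1", "cut", 4, 16))
  res <- test_dm_sites(collapse_and_filter(tab, min_cov = 0))
  expect_equal(res$delta_pp, -70)
  expect_equal(res$p, oracle_fisher_p(4, 16, 18, 2), tolerance = 1e-12)

  # identical pooled counts: delta 0, p 1
  tab2 <- make_meth(
    rec("chr1", 100, "+", "u1", "uncut", 7, 3),
    rec("chr1", 100, "+", "c1", "cut", 7, 3))
  res2 <- test_dm_sites(collapse_and_filter(tab2, min_cov = 0))
  expect_equal(res2$delta_pp, 0)
  expect_equal(res2$p, 1)
})

test_that("zero coverage in a condition excludes the site with a reason", {
  tab <- make_meth(
    rec("chr1", 100, "+", "u1", "uncut", 5, 5),
    rec("chr1", 100, "+", "c1", "cut", 0, 0))
  res <- test_dm_sites(collapse_and_filter(tab, min_cov = 0,
                                           scope = "pooled"))
  expect_equal(res$reason, "zero_coverage_cut")
  expect_true(is.na(res$p))
})

test_that("logistic LRT agrees with pooled Fisher direction on clear effects", {
  tab <- make_meth(
    rec("chr1", 100, "+", "u1", "uncut", 18, 2),
    rec("chr1", 100, "+", "u2", "uncut", 17, 3),
    rec("chr1", 100, "+", "c1", "cut", 4, 16),
    rec("chr1", 100, "+", "c2", "cut", 5, 15))
  coll <- collapse_and_filter(tab, min_cov = 0)
  pf <- test_dm_sites(coll, method = "pooled-fisher")
  ll <- test_dm_sites(coll, method = "logistic-lrt")
  expect_equal(ll$delta_pp, pf$delta_pp)
  expect_lt(ll$p, 0.001)
})

test_that("DM calls apply both thresholds strictly", {
  # BH on these p gives q = (0.00075, 0.00003, 0.06): site 1 passes both
  # thresholds, site 2 fails |delta| > 20, site 3 fails q < 0.05
  tests <- data.table::data.table(
    chrom = "chr1", pos = c(1L, 2L, 3L),
    delta_pp = c(25, 15, -70),
    p = c(0.0005, 0.00001, 0.06),
    reason = NA_character_)
  called <- call_dm(tests, q_threshold = 0.05, delta_threshold = 20)
  expect_equal(called$q, c(0.00075, 0.00003, 0.06), tolerance = 1e-12)
  expect_equal(called$is_dm, c(TRUE, FALSE, FALSE))
  s <- dm_summary(called)
  expect_equal(s$n_dm, 1)
  expect_equal(s$n_hyper, 1)
  expect_equal(s$n_hypo, 0)
  expect_error(call_dm(tests, q_threshold = 1.5), "q_threshold")
  expect_error(call_dm(tests, delta_threshold = 120), "delta_threshold")
})

test_that("BH within call_dm matches the oracle on random site sets", {
  set.seed(11)
  tests <- data.table::data.table(
    chrom = "chr1", pos = seq_len(200),
    delta_pp = runif(200, -60, 60), p = runif(200),
    reason = NA_character_)
  called <- call_dm(tests)
  expect_equal(called$q, oracle_bh(tests$p), tolerance = 1e-12)
})

test_that("concordance r2 behaves as specified", {
  a <- c(s1 = 0, s2 = 50, s3 = 100)
  b <- c(s1 = 10, s2 = 60, s3 = 90)
  r <- concordance_r2(a, b)
  expect_equal(r$r2, 0.9795918, tolerance = 1e-6)
  expect_equal(r$n, 3)
  expect_equal(concordance_r2(a, a)$r2, 1)
  expect_error(concordance_r2(a, c(x1 = 1, x2 = 2, x3 = 3)), "shared")
  expect_error(concordance_r2(a, c(s1 = 5, s2 = 5, s3 = 5)), "variance")
})
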