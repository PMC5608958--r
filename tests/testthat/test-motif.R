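toy_genome <- function() {
  set.seed(99)
  g <- Biostrings::DNAStringSet(paste0(
    sample(c("A", "C", "G", "T"), 3000, replace = TRUE), collapse = ""))
  names(g) <- "chr1"
  g
}

win_dt <- function(seqs) {
  data.table::data.table(site_id = sprintf("w%03d", seq_along(seqs)),
                         chrom = "chr1", start = 0L,
                         end = nchar(seqs[1]), sequence = seqs,
                         cpg_offset = nchar(seqs[1]) %/% 2L,
                         truncated = FALSE)
}

pad40 <- function(core) {
  w <- 40 - nchar(core)
  paste0(strrep("A", ceiling(w / 2)), core, strrep("T", floor(w / 2)))
}

test_that("window extraction geometry, padding, and validation", {
  g <- toy_genome()
  w <- extract_windows(data.table::data.table(chrom = "chr1", pos = 1000L),
                       g, width = 40)
  expect_equal(w$start, 980L)
  expect_equal(w$end, 1020L)
  expect_equal(w$cpg_offset, 20L)
  expect_equal(nchar(w$sequence), 40)
  expect_false(w$truncated)
  expect_equal(w$sequence,
               as.character(Biostrings::subseq(g[[1]], 981, 1020)))
  # near the chromosome start: left-padded with 15 N and flagged
  w2 <- extract_windows(data.table::data.table(chrom = "chr1", pos = 5L),
                        g, width = 40)
  expect_true(w2$truncated)
  expect_equal(substr(w2$sequence, 1, 15), strrep("N", 15))
  expect_error(extract_windows(data.table::data.table(chrom = "chr1",
                                                      pos = 5L), g,
                               width = 0), "width")
  expect_error(extract_windows(data.table::data.table(chrom = "chr1",
                                                      pos = 5000L), g, 40),
               "beyond")
})

test_that("PWM construction validates and scores its consensus maximally", {
  expect_error(make_pwm("bad", matrix(c(0.5, 0.5, 0.5, 0.5), 4, 1)),
               "sum to 1")
  pwms <- read_meme(system.file("extdata", "motifs_synthetic.meme",
                                package = "dmrkit"))
  expect_gte(length(pwms), 12)
  expect_true("AP-1" %in% names(pwms))
  for (p in pwms) {
    expect_true(all(abs(colSums(p$matrix) - 1) < 1e-9))
    # the consensus sequence attains the maximum score
    cons <- paste0(c("A", "C", "G", "T")[apply(p$matrix, 2, which.max)],
                   collapse = "")
    expect_equal(pwm_max_scores(p, pad40(cons)), p$max_score,
                 tolerance = 1e-9)
  }
})

test_that("PWM hits are reverse-complement symmetric", {
  ap1 <- consensus_pwm("AP-1", "TGACTCA")
  fwd <- pad40("TGACTCA")
  rev <- pad40("TGAGTCA")  # reverse complement of the consensus
  expect_equal(pwm_max_scores(ap1, fwd), ap1$max_score, tolerance = 1e-9)
  expect_equal(pwm_max_scores(ap1, rev), ap1$max_score, tolerance = 1e-9)
  none <- pad40("TTTTTTT")
  expect_lt(pwm_max_scores(ap1, none), 0.8 * ap1$max_score)
})

test_that("PWM enrichment arithmetic on constructed window sets", {
  ap1 <- consensus_pwm("AP-1", "TGACTCA")
  mk <- function(n_hit, n_tot) {
    win_dt(c(replicate(n_hit, pad40("TGACTCA")),
             replicate(n_tot - n_hit, pad40("AAAAAAA"))))
  }
  dmw <- mk(40, 100)
  bgw <- mk(50, 1000)
  res <- pwm_window_enrichment(dmw, bgw, list(ap1))
  expect_equal(res$a, 40L)
  expect_equal(res$c, 50L)
  expect_equal(res$odds_ratio, (40 * 950) / (60 * 50), tolerance = 1e-9)
  # identical sets: OR ~ 1, q ~ 1
  same <- pwm_window_enrichment(dmw, dmw, list(ap1))
  expect_equal(same$odds_ratio, 1, tolerance = 1e-9)
  expect_equal(same$q, 1, tolerance = 1e-9)
  expect_error(pwm_window_enrichment(dmw[0], bgw, list(ap1)), "non-empty")
})

test_that("enrichment is invariant under reverse-complementing all windows", {
  set.seed(4)
  seqs <- vapply(1:60, function(i) paste0(
    sample(c("A", "C", "G", "T"), 40, TRUE), collapse = ""), character(1))
  seqs[1:20] <- vapply(seqs[1:20], function(s) {
    substr(s, 10, 16) <- "TGACTCA"; s
  }, character(1))
  dmw <- win_dt(seqs[1:30])
  bgw <- win_dt(seqs[31:60])
  rc <- function(w) { w2 <- data.table::copy(w)
    w2$sequence <- dmrkit:::revcomp(w$sequence); w2 }
  pwms <- list(consensus_pwm("AP-1", "TGACTCA"),
               consensus_pwm("Oct", "ATGCAAAT"))
  r1 <- pwm_window_enrichment(dmw, bgw, pwms)
  r2 <- pwm_window_enrichment(rc(dmw), rc(bgw), pwms)
  expect_equal(r1$a, r2$a)
  expect_equal(r1$p, r2$p)
  k1 <- kmer_enrichment(dmw, bgw, k_range = 6, top_n = Inf)
  k2 <- kmer_enrichment(rc(dmw), rc(bgw), k_range = 6, top_n = Inf)
  expect_equal(k1[order(kmer)], k2[order(kmer)])
})

test_that("k-mer counting uses presence and canonical forms", {
  # two occurrences in one window still count once
  w1 <- win_dt(paste0("TGACTCA", strrep("A", 10), "TGACTCA",
                      strrep("A", 16)))
  bg <- win_dt(strrep("C", 40))
  k <- kmer_enrichment(w1, bg, k_range = 7, top_n = Inf)
  expect_equal(k[kmer == "TGACTCA"]$n_dm, 1L)
  # palindromic k-mer: canonical form counted once per window
  w2 <- win_dt(paste0("GGTACC", strrep("A", 34)))
  k2 <- kmer_enrichment(w2, bg, k_range = 6, top_n = Inf)
  expect_equal(k2[kmer == "GGTACC"]$n_dm, 1L)
  # a k-mer seen only as its reverse complement maps to the canonical form
  w3 <- win_dt(paste0("TGAGTCA", strrep("G", 33)))  # rc(TGACTCA)
  k3 <- kmer_enrichment(w3, bg, k_range = 7, top_n = Inf)
  expect_equal(k3[kmer == "TGACTCA"]$n_dm, 1L)
  expect_error(kmer_enrichment(w1, bg, k_range = 41), "window width")
})
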