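#' Collapse CpG dyads and apply the coverage filter
#'
#' Per-strand cytosine records of the same CpG dyad (positions p on + and
#' p+1 on -) are summed into one record anchored at p. A minus-strand
#' record whose plus partner is absent in every sample is retained at its
#' own position and flagged `one_sided` (likewise a lone plus record).
#' Sites are then retained iff their total coverage meets `min_cov` under
#' the chosen scope: `"every-sample"` (default; every sample present with
#' coverage >= min_cov, absent counts are absent, not zero) or `"pooled"`
#' (sum across samples >= min_cov).
#'
#' When the table has no `strand` column (Bismark coverage files do not
#' record strand) dyads are recovered by greedy left-to-right pairing of
#' adjacent positions in the union of sites across samples.
#'
#' @param table Long methylome `data.table` with columns `chrom`, `pos`
#'   (0-based), optionally `strand`, `sample_id`, `condition`, `meth`,
#'   `unmeth`.
#' @param min_cov Minimum coverage (reads), default 5 (">= 5", i.e. "at
#'   least five times").
#' @param scope `"every-sample"` or `"pooled"`.
#' @param samples Sample universe for the every-sample scope; defaults to
#'   the samples present in the table. A site missing any of these
#'   samples fails the every-sample filter (absent counts are absent,
#'   not zero).
#' @return Collapsed, filtered long `data.table` with columns `chrom`,
#'   `pos`, `sample_id`, `condition`, `meth`, `unmeth`, `one_sided`.
#' @export
collapse_and_filter <- function(table, min_cov = 5,
                                scope = c("every-sample", "pooled"),
                                samples = NULL) {
  scope <- match.arg(scope)
  stop_if_not_scalar_number(min_cov, "min_cov", 0)
  x <- data.table::as.data.table(table)
  req <- c("chrom", "pos", "sample_id", "condition", "meth", "unmeth")
  if (!all(req %in% names(x))) {
    stop("methylome table must have columns ",
         paste(req, collapse = ", "))
  }
  if (nrow(x) == 0) {
    return(data.table(chrom = character(0), pos = integer(0),
                      sample_id = character(0), condition = character(0),
                      meth = integer(0), unmeth = integer(0),
                      one_sided = logical(0)))
  }
  if (any(x$meth < 0) || any(x$unmeth < 0)) {
    stop("negative counts in methylome table")
  }

  if ("strand" %in% names(x)) {
    # anchor of the dyad is the + strand C
    x[, anchor := ifelse(strand == "-", pos - 1L, pos)]
    # lone minus records (anchor position never seen on +) stay put
    plus_keys <- unique(x[strand == "+", paste(chrom, pos)])
    lone <- x$strand == "-" & !(paste(x$chrom, x$anchor) %in% plus_keys)
    x[lone, anchor := pos]
    x[, one_sided := FALSE]
    x[lone, one_sided := TRUE]
    plus_lone <- x$strand == "+" &
      !(paste(x$chrom, x$pos + 1L) %in%
          unique(x[strand == "-", paste(chrom, pos)]))
    x[plus_lone, one_sided := TRUE]
  } else {
    # greedy pairing of adjacent positions in the cross-sample union
    upos <- unique(x[, list(chrom, pos)])[order(chrom, pos)]
    anchor_map <- upos[, {
      u <- pos
      a <- u
      i <- 1L
      while (i < length(u)) {
        if (u[i + 1L] == u[i] + 1L) {
          a[i + 1L] <- u[i]
          i <- i + 2L
        } else i <- i + 1L
      }
      list(pos = u, anchor = a)
    }, by = chrom]
    x <- anchor_map[x, on = c("chrom", "pos")]
    pair_n <- anchor_map[, list(nmem = .N), by = list(chrom, anchor)]
    x <- pair_n[x, on = c("chrom", "anchor")]
    x[, one_sided := nmem == 1L]
    x[, nmem := NULL]
  }

  out <- x[, list(meth = sum(meth), unmeth = sum(unmeth),
                  one_sided = all(one_sided)),
           by = list(chrom, pos = anchor, sample_id, condition)]

  n_samples <- length(unique(samples %||% x$sample_id))
  cov_dt <- out[, list(n_present = .N, min_cov_s = min(meth + unmeth),
                       pooled = sum(meth + unmeth)),
                by = list(chrom, pos)]
  keep_sites <- if (scope == "every-sample") {
    cov_dt[n_present == n_samples & min_cov_s >= min_cov, list(chrom, pos)]
  } else {
    cov_dt[pooled >= min_cov, list(chrom, pos)]
  }
  out[keep_sites, on = c("chrom", "pos")][order(chrom, pos, sample_id)]
}

utils::globalVariables(c("anchor", "nmem", "n_present", "min_cov_s",
                         "pooled", "plus_keys"))

#' Per-site differential methylation tests
#'
#' Pools replicate counts per condition at each CpG site and computes the
#' methylation difference in percentage points, `delta_pp = 100 *
#' (pooled cut fraction - pooled uncut fraction)`, together with a
#' two-sided p-value: either the Fisher exact test on the pooled 2x2 table
#' (default) or a replicate-aware binomial logistic regression
#' likelihood-ratio test. Sites with zero total coverage in either
#' condition are excluded with a reason code (`p` = NA).
#'
#' @param collapsed Output of [collapse_and_filter()].
#' @param method `"pooled-fisher"` or `"logistic-lrt"`.
#' @param cut_label,uncut_label Condition labels (default "cut"/"uncut").
#' @return `data.table` with one row per site: pooled counts, `cov_mean`
#'   (mean per-sample coverage), `delta_pp`, `p`, and `reason` (NA unless
#'   excluded).
#' @export
test_dm_sites <- function(collapsed, method = c("pooled-fisher",
                                                "logistic-lrt"),
                          cut_label = "cut", uncut_label = "uncut") {
  method <- match.arg(method)
  x <- data.table::as.data.table(collapsed)
  if (!all(x$condition %in% c(cut_label, uncut_label))) {
    stop("conditions other than the cut/uncut labels present")
  }
  pooled <- x[, list(
    meth_cut = sum(meth[condition == cut_label]),
    unmeth_cut = sum(unmeth[condition == cut_label]),
    meth_uncut = sum(meth[condition == uncut_label]),
    unmeth_uncut = sum(unmeth[condition == uncut_label]),
    cov_mean = mean(meth + unmeth)),
    by = list(chrom, pos)]
  tot_cut <- pooled$meth_cut + pooled$unmeth_cut
  tot_uncut <- pooled$meth_uncut + pooled$unmeth_uncut
  pooled[, reason := NA_character_]
  pooled[tot_cut == 0, reason := "zero_coverage_cut"]
  pooled[tot_uncut == 0, reason := "zero_coverage_uncut"]
  pooled[, delta_pp := ifelse(is.na(reason),
                              100 * (meth_cut / (meth_cut + unmeth_cut) -
                                       meth_uncut / (meth_uncut + unmeth_uncut)),
                              NA_real_)]
  ok <- is.na(pooled$reason)
  pooled[, p := NA_real_]
  if (method == "pooled-fisher") {
    pooled[ok, p := fisher_exact_vec(meth_cut, unmeth_cut,
                                     meth_uncut, unmeth_uncut)]
  } else {
    key <- paste(x$chrom, x$pos)
    grp <- split(seq_len(nrow(x)), key)
    pkey <- paste(pooled$chrom, pooled$pos)
    pvals <- rep(NA_real_, nrow(pooled))
    for (i in which(ok)) {
      rows <- x[grp[[pkey[i]]]]
      fit1 <- stats::glm(cbind(meth, unmeth) ~ condition,
                         family = stats::binomial(), data = rows)
      fit0 <- stats::glm(cbind(meth, unmeth) ~ 1,
                         family = stats::binomial(), data = rows)
      dev <- fit0$deviance - fit1$deviance
      pvals[i] <- stats::pchisq(max(0, dev), df = 1, lower.tail = FALSE)
    }
    pooled[, p := pvals]
  }
  pooled[order(chrom, pos)]
}

utils::globalVariables(c("meth_cut", "unmeth_cut", "meth_uncut",
                         "unmeth_uncut", "tot_cut", "tot_uncut"))

#' Call differentially methylated CpGs
#'
#' Applies Benjamini-Hochberg correction across all tested sites and flags
#' a site DM iff `q < q_threshold` and `|delta_pp| > delta_threshold`
#' (both strict, matching "p-adj < 0.05; differential methylation
#' difference >20%").
#'
#' @param tests Output of [test_dm_sites()].
#' @param q_threshold BH-adjusted p-value threshold, default 0.05.
#' @param delta_threshold Methylation-difference threshold in percentage
#'   points, default 20.
#' @return The input table with added `q` and `is_dm` columns.
#' @seealso [dm_summary()]
#' @export
call_dm <- function(tests, q_threshold = 0.05, delta_threshold = 20) {
  stop_if_not_scalar_number(q_threshold, "q_threshold", 0, 1)
  stop_if_not_scalar_number(delta_threshold, "delta_threshold", 0, 100)
  x <- data.table::as.data.table(tests)
  x[, q := NA_real_]
  ok <- !is.na(x$p)
  x[ok, q := adjust_bh(p)]
  x[, is_dm := !is.na(q) & q < q_threshold & abs(delta_pp) > delta_threshold]
  x[]
}

#' Summary counts of a DM call set
#'
#' @param called Output of [call_dm()].
#' @return List with `n_tested`, `n_dm`, `n_hyper` (delta > 0), `n_hypo`.
#' @export
dm_summary <- function(called) {
  list(n_tested = sum(!is.na(called$p)),
       n_dm = sum(called$is_dm),
       n_hyper = sum(called$is_dm & called$delta_pp > 0),
       n_hypo = sum(called$is_dm & called$delta_pp < 0))
}

#' Squared Pearson correlation between two methylation percentage maps
#'
#' Cross-platform concordance (e.g. WGBS vs bisulfite-Sanger) at shared
#' CpG sites.
#'
#' @param a,b Named numeric vectors mapping site ids to methylation
#'   percentages.
#' @return List with `r2` and `n` (number of shared sites).
#' @export
concordance_r2 <- function(a, b) {
  shared <- intersect(names(a), names(b))
  if (length(shared) < 3) {
    stop("need at least 3 shared sites, got ", length(shared))
  }
  va <- a[shared]; vb <- b[shared]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop("zero variance in one of the methylation vectors")
  }
  list(r2 = stats::cor(va, vb)^2, n = length(shared))
}
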