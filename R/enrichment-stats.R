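#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Computes the two-sided Fisher exact test p-value for the table
#' `rbind(c(a, b), c(c, d))` by summing, over the hypergeometric support
#' implied by the table margins, the probabilities of all tables at most as
#' probable as the observed one. Degenerate tables (an empty margin) return
#' p = 1.
#'
#' @param a,b,c,d Non-negative integer cell counts. The rows of the table
#'   are the two groups being compared (e.g. condition), the columns the two
#'   outcomes (e.g. methylated / unmethylated).
#' @return Two-sided p-value in (0, 1].
#' @examples
#' fisher_exact_2x2(3, 1, 1, 3) # = 34/70
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  stopifnot(length(a) == 1, length(b) == 1, length(c) == 1, length(d) == 1)
  if (anyNA(c(a, b, c, d)) || any(c(a, b, c, d) < 0)) {
    stop("cell counts must be non-negative and non-missing")
  }
  r1 <- a + b
  r2 <- c + d
  k <- a + c
  if (r1 == 0 || r2 == 0 || k == 0 || (b + d) == 0) {
    return(1)
  }
  lo <- max(0, k - r2)
  hi <- min(k, r1)
  dens <- stats::dhyper(lo:hi, r1, r2, k)
  # relative tolerance on the tie comparison, as in stats::fisher.test,
  # absorbs floating-point noise in dhyper
  p <- sum(dens[dens <= dens[a - lo + 1] * (1 + 1e-07)])
  min(1, p)
}

#' Vectorised two-sided Fisher exact p-values
#'
#' @param a,b,c,d Equal-length non-negative integer vectors of cell counts.
#' @return Numeric vector of two-sided p-values.
#' @export
fisher_exact_vec <- function(a, b, c, d) {
  n <- length(a)
  stopifnot(length(b) == n, length(c) == n, length(d) == n)
  if (n == 0) return(numeric(0))
  vapply(seq_len(n), function(i) fisher_exact_2x2(a[i], b[i], c[i], d[i]),
         numeric(1))
}

#' Odds ratio with Woolf confidence interval
#'
#' Sample odds ratio (a*d)/(b*c) with the Woolf (log) 95% confidence
#' interval `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. When any
#' cell is zero, the Haldane-Anscombe correction (+0.5 to every cell) is
#' applied to both the point estimate and the interval so the result is
#' finite.
#'
#' @inheritParams fisher_exact_2x2
#' @param conf_level Confidence level, default 0.95.
#' @return Named list with `odds_ratio`, `ci_low`, `ci_high`, and
#'   `haldane` (whether the correction was applied).
#' @export
odds_ratio_woolf <- function(a, b, c, d, conf_level = 0.95) {
  if (anyNA(c(a, b, c, d)) || any(c(a, b, c, d) < 0)) {
    stop("cell counts must be non-negative and non-missing")
  }
  haldane <- any(c(a, b, c, d) == 0)
  if (haldane) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  or <- (a * d) / (b * c)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(odds_ratio = or,
       ci_low = exp(log(or) - z * se),
       ci_high = exp(log(or) + z * se),
       haldane = haldane)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH procedure: `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1,
#' returned in the input order. Ties are handled by the standard
#' min-cummin formulation.
#'
#' @param p Numeric vector of p-values in \[0, 1\]; `NA` is rejected.
#' @return Vector of BH-adjusted p-values (q-values), same length/order.
#' @examples
#' adjust_bh(c(0.005, 0.02, 0.9)) # c(0.015, 0.03, 0.9)
#' @export
adjust_bh <- function(p) {
  if (anyNA(p)) stop("NA p-values are not allowed")
  if (length(p) && (min(p) < 0 || max(p) > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  pmin(1, cummin(p[o] * m / (m:1)))[order(o)]
}

#' Build an enrichment table from 2x2 counts
#'
#' Shared backend for feature, motif, and gene-set enrichment: one row per
#' tested unit, with the full 2x2 table (`a` = query in feature, `b` =
#' query out, `c` = background in, `d` = background out), the
#' Haldane-corrected odds ratio, the Woolf 95% CI, the two-sided Fisher
#' p-value, and the BH q-value computed across the rows.
#'
#' @param labels Character vector naming each tested unit.
#' @param a,b,c,d Integer vectors of 2x2 cell counts, one per label.
#' @return `data.table` with columns `label, a, b, c, d, odds_ratio,
#'   ci_low, ci_high, p, q`, ordered as given.
#' @export
enrichment_table <- function(labels, a, b, c, d) {
  n <- length(labels)
  stopifnot(length(a) == n, length(b) == n, length(c) == n, length(d) == n)
  ors <- lapply(seq_len(n), function(i) odds_ratio_woolf(a[i], b[i], c[i], d[i]))
  out <- data.table::data.table(
    label = as.character(labels),
    a = as.integer(a), b = as.integer(b),
    c = as.integer(c), d = as.integer(d),
    odds_ratio = vapply(ors, `[[`, numeric(1), "odds_ratio"),
    ci_low = vapply(ors, `[[`, numeric(1), "ci_low"),
    ci_high = vapply(ors, `[[`, numeric(1), "ci_high"),
    p = fisher_exact_vec(a, b, c, d)
  )
  out$q <- adjust_bh(out$p)
  out[]
}
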