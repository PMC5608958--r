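#' Map a human gene set to mouse ids through an ortholog table
#'
#' One-to-one rows map directly; many-to-many rows expand to all mouse
#' targets (set semantics, duplicates removed); symbols absent from the
#' table are counted as unmapped and excluded.
#'
#' @param human_set Character vector of human symbols.
#' @param ortholog_table Two-column table (`human`, `mouse`; the first two
#'   columns are used whatever their names).
#' @return List with `mouse_ids` (sorted unique), `unmapped` (symbols),
#'   and `n_unmapped`.
#' @export
map_orthologs <- function(human_set, ortholog_table) {
  tab <- data.table::as.data.table(ortholog_table)
  if (nrow(tab) == 0) stop("ortholog table is empty")
  data.table::setnames(tab, 1:2, c("human", "mouse"))
  tab <- unique(tab[, list(human, mouse)])
  human_set <- unique(human_set)
  mapped <- tab[tab$human %in% human_set]
  unmapped <- setdiff(human_set, tab$human)
  list(mouse_ids = sort(unique(mapped$mouse)),
       unmapped = sort(unmapped),
       n_unmapped = length(unmapped))
}

utils::globalVariables(c("human", "mouse"))

#' Fisher over-representation of a gene set among DE genes
#'
#' 2x2 table: `a` = set members that are DE, `b` = set members not DE,
#' `c` = DE genes outside the set, `d` = the rest of the universe. The
#' universe defaults to all tested genes (every id in the DE table).
#'
#' @param set_ids Gene set (must be a subset of `universe_ids`).
#' @param de_ids DE genes (must be a subset of `universe_ids`).
#' @param universe_ids All tested genes.
#' @return List with `n_set_mapped`, `n_set_de`, `universe`, the 2x2
#'   cells, `odds_ratio`, `ci_low`, `ci_high` (Woolf 95%), and `p`
#'   (two-sided Fisher).
#' @export
fisher_set_enrichment <- function(set_ids, de_ids, universe_ids) {
  set_ids <- unique(set_ids)
  de_ids <- unique(de_ids)
  universe_ids <- unique(universe_ids)
  if (length(set_ids) == 0) stop("gene set is empty")
  off <- setdiff(set_ids, universe_ids)
  if (length(off)) {
    stop("set ids outside the universe: ",
         paste(utils::head(off, 10), collapse = ", "))
  }
  off_de <- setdiff(de_ids, universe_ids)
  if (length(off_de)) {
    stop("DE ids outside the universe: ",
         paste(utils::head(off_de, 10), collapse = ", "))
  }
  a <- length(intersect(set_ids, de_ids))
  b <- length(set_ids) - a
  c_ <- length(setdiff(de_ids, set_ids))
  d <- length(universe_ids) - a - b - c_
  orw <- odds_ratio_woolf(a, b, c_, d)
  list(n_set_mapped = length(set_ids), n_set_de = a,
       universe = length(universe_ids),
       a = a, b = b, c = c_, d = d,
       odds_ratio = orw$odds_ratio, ci_low = orw$ci_low,
       ci_high = orw$ci_high,
       p = fisher_exact_2x2(a, b, c_, d))
}

#' Methylation-expression correlation by feature class
#'
#' Pairs each DM CpG's methylation difference (delta, percentage points)
#' with the log2 fold change of its nearest gene (within `max_dist` of
#' the TSS) and computes the Spearman correlation per primary feature
#' class. Classes with fewer than `min_pairs` pairs, or with a constant
#' delta vector, are reported as NA. P-values are exact (permutation
#' distribution of the rank statistic) for n <= 10 without ties,
#' asymptotic otherwise.
#'
#' @param dm_sites DM sites with `chrom`, `pos`, `delta_pp`.
#' @param assignments [assign_features()] output covering the DM sites.
#' @param de_table DE table with `id`, `log2fc`.
#' @param max_dist Maximum |TSS distance| for pairing, default 500 kb.
#' @param min_pairs Minimum pairs per class, default 5.
#' @return `data.table`: `feature, n, rho, p`.
#' @export
meth_expr_correlation <- function(dm_sites, assignments, de_table,
                                  max_dist = 5e5, min_pairs = 5) {
  dm <- data.table::as.data.table(dm_sites)
  asg <- data.table::as.data.table(assignments)
  de <- data.table::as.data.table(de_table)
  x <- asg[dm, on = c("chrom", "pos")]
  x <- x[!is.na(tss_distance) & abs(tss_distance) <= max_dist]
  x[, log2fc := de$log2fc[match(nearest_gene, de$id)]]
  x <- x[!is.na(log2fc)]
  feats <- FEATURE_LEVELS
  out <- lapply(feats, function(f) {
    sub <- x[primary_label == f]
    if (nrow(sub) < min_pairs ||
        stats::sd(sub$delta_pp) == 0 || stats::sd(sub$log2fc) == 0) {
      return(data.table(feature = f, n = nrow(sub), rho = NA_real_,
                        p = NA_real_))
    }
    rho <- stats::cor(sub$delta_pp, sub$log2fc, method = "spearman")
    ct <- suppressWarnings(stats::cor.test(
      sub$delta_pp, sub$log2fc, method = "spearman",
      exact = nrow(sub) <= 10))
    data.table(feature = f, n = nrow(sub), rho = rho, p = ct$p.value)
  })
  data.table::rbindlist(out)
}

utils::globalVariables(c("primary_label", "nearest_gene"))

#' Relative expression as percentage of summed copy numbers
#'
#' qPCR-style cell-type fractions: each gene's copy-number values across
#' cell types are scaled to percentages of their sum.
#'
#' @param copy_numbers Numeric matrix or data.frame, genes in rows, cell
#'   types in columns; values must be non-negative with at least one
#'   positive value per gene.
#' @return Matrix of percentages, rows summing to 100.
#' @export
cell_type_fraction <- function(copy_numbers) {
  m <- as.matrix(copy_numbers)
  if (!is.numeric(m)) stop("copy numbers must be numeric")
  if (any(m < 0)) stop("copy numbers must be non-negative")
  rs <- rowSums(m)
  if (any(rs == 0)) {
    stop("all-zero rows: ",
         paste(utils::head(which(rs == 0), 10), collapse = ", "))
  }
  sweep(m, 1, rs, "/") * 100
}
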