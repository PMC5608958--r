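#' Construct a position weight matrix
#'
#' @param name Motif name.
#' @param matrix 4 x w numeric matrix of per-position base probabilities,
#'   rows in A, C, G, T order; every column must sum to 1 (tolerance
#'   1e-9 before the pseudocount is applied).
#' @param background Background base frequencies (A, C, G, T), summing
#'   to 1; default uniform.
#' @param pseudocount Additive pseudocount applied to the probability
#'   matrix (then renormalised) before log-odds scoring, default 0.01.
#' @return Object of class `pwm`: list with the validated fields plus the
#'   log2-odds `score_matrix` and its `max_score`.
#' @export
make_pwm <- function(name, matrix, background = rep(0.25, 4),
                     pseudocount = 0.01) {
  stopifnot(is.matrix(matrix), nrow(matrix) == 4, ncol(matrix) >= 1)
  if (any(abs(colSums(matrix) - 1) > 1e-9)) {
    stop("PWM columns must each sum to 1")
  }
  if (abs(sum(background) - 1) > 1e-9 || any(background <= 0)) {
    stop("background frequencies must be positive and sum to 1")
  }
  rownames(matrix) <- c("A", "C", "G", "T")
  m2 <- sweep(matrix + pseudocount, 2, colSums(matrix + pseudocount), "/")
  s <- log2(m2 / background)
  structure(list(name = name, matrix = matrix, background = background,
                 pseudocount = pseudocount, score_matrix = s,
                 max_score = sum(apply(s, 2, max))),
            class = "pwm")
}

#' PWM from an IUPAC consensus
#'
#' Builds a sharply peaked PWM: allowed bases at each position share
#' `1 - soft` of the mass, disallowed bases share `soft`.
#'
#' @param name Motif name.
#' @param consensus IUPAC DNA string.
#' @param soft Total probability given to disallowed bases, default 0.06.
#' @inheritParams make_pwm
#' @export
consensus_pwm <- function(name, consensus, soft = 0.06,
                          background = rep(0.25, 4), pseudocount = 0.01) {
  letters <- strsplit(toupper(consensus), "")[[1]]
  stopifnot(all(letters %in% names(IUPAC_SETS)))
  m <- vapply(letters, function(l) {
    allowed <- c("A", "C", "G", "T") %in% IUPAC_SETS[[l]]
    p <- rep(soft / max(1, sum(!allowed)), 4)
    if (all(allowed)) p[] <- 0.25
    else p[allowed] <- (1 - soft) / sum(allowed)
    p / sum(p)
  }, numeric(4))
  make_pwm(name, m, background, pseudocount)
}

#' Read PWMs from a MEME minimal motif file
#'
#' Parses `MOTIF` blocks with their `letter-probability matrix` sections
#' and the optional `Background letter frequencies` line.
#'
#' @param path MEME minimal format file.
#' @param pseudocount Passed to [make_pwm()].
#' @return Named list of `pwm` objects.
#' @export
read_meme <- function(path, pseudocount = 0.01) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i)) {
    toks <- strsplit(trimws(lines[bg_i[1] + 1]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    named <- stats::setNames(vals[!is.na(vals)],
                             toks[which(!is.na(vals)) - 1])
    bg <- unname(named[c("A", "C", "G", "T")])
  }
  motif_i <- grep("^MOTIF", lines)
  if (!length(motif_i)) stop("no MOTIF blocks found in ", path)
  pwms <- list()
  for (mi in motif_i) {
    name <- strsplit(trimws(lines[mi]), "\\s+")[[1]][2]
    li <- mi
    repeat {
      li <- li + 1
      if (li > length(lines)) stop("missing probability matrix for ", name)
      if (grepl("^letter-probability matrix", lines[li])) break
    }
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[li]))
    rows <- lines[(li + 1):(li + w)]
    m <- t(vapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), "\\s+")[[1]][1:4])
    }, numeric(4)))
    # renormalise rounded rows before validation
    m <- m / rowSums(m)
    pwms[[name]] <- make_pwm(name, t(m), background = bg,
                             pseudocount = pseudocount)
  }
  pwms
}

#' Read a PWM from a simple TSV matrix file
#'
#' Expects a header `A C G T` (tab separated) and one probability row per
#' motif position.
#'
#' @param path TSV file.
#' @param name Motif name; defaults to the file name without extension.
#' @inheritParams make_pwm
#' @export
read_pwm_tsv <- function(path, name = NULL, background = rep(0.25, 4),
                         pseudocount = 0.01) {
  x <- data.table::fread(path, sep = "\t", header = TRUE)
  stopifnot(all(c("A", "C", "G", "T") %in% names(x)))
  m <- t(as.matrix(x[, c("A", "C", "G", "T"), with = FALSE]))
  make_pwm(name %||% tools::file_path_sans_ext(basename(path)), m,
           background, pseudocount)
}

#' Extract fixed-width sequence windows centered on CpG sites
#'
#' Window = `[pos - width/2, pos + width/2)` with the anchor C at offset
#' `width/2` (0-based). Windows truncated by a chromosome end are padded
#' with N and flagged.
#'
#' @param sites `data.table` with `chrom`, `pos`.
#' @param genome Named `DNAStringSet`.
#' @param width Even window width in bp, default 40.
#' @return `data.table`: `site_id, chrom, start, end, sequence,
#'   cpg_offset, truncated`.
#' @export
extract_windows <- function(sites, genome, width = 40) {
  stop_if_not_scalar_number(width, "width", 2)
  if (width %% 2 != 0) stop("window width must be even")
  x <- data.table::as.data.table(sites)
  half <- width %/% 2
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  if (any(!x$chrom %in% names(genome))) {
    stop("sites on chromosomes absent from the genome")
  }
  if (any(x$pos < 0 | x$pos >= lens[x$chrom])) {
    stop("site position beyond chromosome bounds")
  }
  ws <- x$pos - half
  we <- x$pos + half
  cs <- pmax(ws, 0L)
  ce <- pmin(we, lens[x$chrom])
  seqs <- character(nrow(x))
  for (ch in unique(x$chrom)) {
    qi <- which(x$chrom == ch)
    seqs[qi] <- as.character(Biostrings::subseq(
      rep(genome[ch], length(qi)), start = cs[qi] + 1L, end = ce[qi]))
  }
  padl <- cs - ws
  padr <- we - ce
  seqs <- paste0(strrep("N", padl), seqs, strrep("N", padr))
  data.table(site_id = paste(x$chrom, x$pos, sep = ":"),
             chrom = x$chrom, start = as.integer(ws), end = as.integer(we),
             sequence = seqs, cpg_offset = half,
             truncated = padl > 0 | padr > 0)
}

#' Write sequence windows as FASTA
#'
#' @param windows Output of [extract_windows()].
#' @param path Output FASTA path.
#' @export
write_windows_fasta <- function(windows, path) {
  ss <- Biostrings::DNAStringSet(windows$sequence)
  names(ss) <- windows$site_id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# integer codes A=1 C=2 G=3 T=4 N/other=5, one row per sequence
seqs_to_codes <- function(seqs) {
  n <- length(seqs)
  w <- nchar(seqs[1])
  stopifnot(all(nchar(seqs) == w))
  code <- match(unlist(strsplit(toupper(seqs), "")),
                c("A", "C", "G", "T"))
  code[is.na(code)] <- 5L
  matrix(code, nrow = n, ncol = w, byrow = TRUE)
}

#' Maximum PWM log-odds score per sequence
#'
#' Scans both strands at every offset; N bases contribute 0 (background
#' expectation) to the score.
#'
#' @param pwm A `pwm` object.
#' @param seqs Character vector of equal-length sequences (length >=
#'   motif width).
#' @return Numeric vector of per-sequence maximum scores.
#' @export
pwm_max_scores <- function(pwm, seqs) {
  code <- seqs_to_codes(seqs)
  w <- ncol(pwm$score_matrix)
  W <- ncol(code)
  if (w > W) stop("motif wider than the sequences")
  s_fwd <- rbind(pwm$score_matrix, 0)
  s_rev <- s_fwd[c(4, 3, 2, 1, 5), w:1, drop = FALSE]
  best <- rep(-Inf, nrow(code))
  for (S in list(s_fwd, s_rev)) {
    for (off in seq_len(W - w + 1L)) {
      acc <- numeric(nrow(code))
      for (i in seq_len(w)) {
        acc <- acc + S[cbind(code[, off + i - 1L], i)]
      }
      best <- pmax(best, acc)
    }
  }
  best
}

#' PWM enrichment in DM windows versus background windows
#'
#' A window "has a hit" for a PWM when its maximum log2-odds score over
#' both strands and all offsets reaches `score_fraction` of the PWM's
#' maximum attainable score. Per PWM, a 2x2 Fisher test (hit x set) with
#' Haldane-corrected odds ratio, Woolf CI, and BH correction across PWMs.
#'
#' @param dm_windows,bg_windows Outputs of [extract_windows()].
#' @param pwms List of `pwm` objects.
#' @param score_fraction Hit threshold as a fraction of the maximum
#'   attainable score, default 0.8.
#' @return [enrichment_table()] with one row per PWM (label = name),
#'   ordered by q then descending odds ratio; extra columns `n_dm`,
#'   `n_bg` give the set sizes.
#' @export
pwm_window_enrichment <- function(dm_windows, bg_windows, pwms,
                                  score_fraction = 0.8) {
  stop_if_not_scalar_number(score_fraction, "score_fraction", 0, 1)
  if (nrow(dm_windows) == 0 || nrow(bg_windows) == 0) {
    stop("both window sets must be non-empty")
  }
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  nd <- nrow(dm_windows)
  nb <- nrow(bg_windows)
  hits <- vapply(pwms, function(p) {
    thr <- score_fraction * p$max_score
    c(sum(pwm_max_scores(p, dm_windows$sequence) >= thr),
      sum(pwm_max_scores(p, bg_windows$sequence) >= thr))
  }, numeric(2))
  labels <- vapply(pwms, `[[`, character(1), "name")
  out <- enrichment_table(labels, hits[1, ], nd - hits[1, ],
                          hits[2, ], nb - hits[2, ])
  out[, n_dm := nd]
  out[, n_bg := nb]
  out[order(q, -odds_ratio)]
}

utils::globalVariables(c("odds_ratio"))

# canonical form: lexicographic min of k-mer and its reverse complement
canonical_kmer <- function(kmers) {
  rc <- revcomp(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

count_kmer_windows <- function(seqs, k) {
  n <- length(seqs)
  W <- nchar(seqs[1])
  offs <- seq_len(W - k + 1L)
  km <- vapply(offs, function(o) substring(seqs, o, o + k - 1L),
               character(n))
  dt <- data.table(window = rep(seq_len(n), times = length(offs)),
                   kmer = as.vector(km))
  dt <- dt[!grepl("N", kmer, fixed = TRUE)]
  if (nrow(dt) == 0) return(data.table(kmer = character(0), n = integer(0)))
  dt[, kmer := canonical_kmer(kmer)]
  unique(dt)[, list(n = .N), by = kmer]
}

#' K-mer over-representation in DM windows
#'
#' De-novo motif discovery stand-in: for each canonical k-mer (k over
#' `k_range`), counts windows containing at least one occurrence
#' (presence, not frequency), tests the 2x2 hit-by-set table with the
#' Fisher exact test, applies BH within each k, and ranks by q then
#' descending odds ratio.
#'
#' @param dm_windows,bg_windows Outputs of [extract_windows()].
#' @param k_range Integer vector of k values, default `6:8`.
#' @param top_n Rows returned per k, default 20 (`Inf` for all).
#' @return `data.table`: `k, kmer, n_dm, n_bg, odds_ratio, ci_low,
#'   ci_high, p, q`, ranked within k.
#' @export
kmer_enrichment <- function(dm_windows, bg_windows, k_range = 6:8,
                            top_n = 20) {
  if (any(k_range > nchar(dm_windows$sequence[1]))) {
    stop("k exceeds the window width")
  }
  nd <- nrow(dm_windows)
  nb <- nrow(bg_windows)
  out <- list()
  for (k in k_range) {
    cd <- count_kmer_windows(dm_windows$sequence, k)
    cb <- count_kmer_windows(bg_windows$sequence, k)
    data.table::setnames(cd, "n", "n_dm")
    data.table::setnames(cb, "n", "n_bg")
    tab <- merge(cd, cb, by = "kmer", all = TRUE)
    tab[is.na(n_dm), n_dm := 0L]
    tab[is.na(n_bg), n_bg := 0L]
    et <- enrichment_table(tab$kmer, tab$n_dm, nd - tab$n_dm,
                           tab$n_bg, nb - tab$n_bg)
    et[, k := as.integer(k)]
    data.table::setnames(et, "label", "kmer")
    et[, `:=`(n_dm = a, n_bg = c)]
    et <- et[order(q, -odds_ratio)]
    if (is.finite(top_n)) et <- utils::head(et, top_n)
    out[[as.character(k)]] <- et
  }
  data.table::rbindlist(out)[
    , list(k, kmer, n_dm, n_bg, odds_ratio, ci_low, ci_high, p, q)]
}

utils::globalVariables(c("a", "ci_low", "ci_high"))
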