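#' Read Bismark-coverage methylome files into a long count table
#'
#' Each file is 6-column TSV: chrom, start (1-based), end, methylation
#' percentage (ignored in favour of the raw counts), count methylated,
#' count unmethylated. Positions are converted to 0-based. Sites absent
#' from a sample are absent from the table (never imputed as zero).
#'
#' @param paths Character vector of per-sample coverage files.
#' @param conditions Condition label per file (e.g. "uncut"/"cut").
#' @param sample_ids Sample names; default the file names sans extension.
#' @return Long `data.table`: `chrom, pos, sample_id, condition, meth,
#'   unmeth`.
#' @export
read_methylome_table <- function(paths, conditions, sample_ids = NULL) {
  stopifnot(length(paths) == length(conditions))
  if (is.null(sample_ids)) {
    sample_ids <- tools::file_path_sans_ext(basename(paths))
  }
  out <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    x <- data.table::fread(paths[i], sep = "\t", header = FALSE,
                           colClasses = list(character = 1),
                           fill = TRUE)
    if (ncol(x) != 6) {
      stop(sprintf("%s: expected 6 columns, found %d", paths[i], ncol(x)))
    }
    data.table::setnames(x, c("chrom", "start1", "end1", "pct", "meth",
                              "unmeth"))
    bad <- which(!is.finite(x$meth) | !is.finite(x$unmeth) |
                   x$meth < 0 | x$unmeth < 0 |
                   x$meth != floor(x$meth) | x$unmeth != floor(x$unmeth))
    if (length(bad)) {
      stop(sprintf("%s line %d: malformed counts", paths[i], bad[1]))
    }
    out[[i]] <- data.table(chrom = x$chrom, pos = x$start1 - 1L,
                           sample_id = sample_ids[i],
                           condition = conditions[i],
                           meth = as.integer(x$meth),
                           unmeth = as.integer(x$unmeth))
  }
  data.table::rbindlist(out)[order(chrom, pos, sample_id)]
}

#' Write a long methylome table as per-sample Bismark-coverage files
#'
#' @param methylome Long table from [simulate_methylome_experiment()] (the
#'   `strand` column, if present, is dropped; each record is written at
#'   its own 1-based position).
#' @param dir Output directory.
#' @return Named character vector of file paths (by sample), with the
#'   condition labels as attribute `conditions`.
#' @export
write_bismark_cov <- function(methylome, dir) {
  x <- data.table::as.data.table(methylome)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  samples <- sort(unique(x$sample_id))
  paths <- character(0)
  conds <- character(0)
  for (s in samples) {
    sub <- x[sample_id == s][order(chrom, pos)]
    bis <- data.table(chrom = sub$chrom, start1 = sub$pos + 1L,
                      end1 = sub$pos + 1L,
                      pct = round(100 * sub$meth /
                                    pmax(1L, sub$meth + sub$unmeth), 4),
                      meth = sub$meth, unmeth = sub$unmeth)
    p <- file.path(dir, paste0(s, ".cov"))
    data.table::fwrite(bis, p, sep = "\t", col.names = FALSE,
                       scipen = 50)
    paths <- c(paths, p)
    conds <- c(conds, sub$condition[1])
  }
  names(paths) <- samples
  attr(paths, "conditions") <- conds
  paths
}

# --- GTF -------------------------------------------------------------------

#' Write gene models as GTF (1-based, closed)
#'
#' Emits gene, transcript (one per gene, `<gene_id>.t1`), and exon lines.
#'
#' @param genes,exons Gene/exon tables in 0-based half-open coordinates.
#' @param path Output file.
#' @param source Second GTF column, default "dmrkit".
#' @export
write_gtf <- function(genes, exons, path, source = "dmrkit") {
  lines <- character(0)
  genes <- data.table::as.data.table(genes)[order(chrom, start)]
  exons <- data.table::as.data.table(exons)
  id_col <- if ("gene_id" %in% names(genes)) "gene_id" else "transcript_id"
  for (i in seq_len(nrow(genes))) {
    g <- genes[i]
    gid <- g[[id_col]]
    tid <- if (id_col == "transcript_id") gid else paste0(gid, ".t1")
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', gid, tid)
    lines <- c(lines,
               sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
                       g$chrom, source, g$start + 1L, g$end, g$strand, gid),
               sprintf("%s\t%s\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                       g$chrom, source, g$start + 1L, g$end, g$strand,
                       attrs))
    ex <- exons[exons[[id_col]] == gid]
    ex <- ex[order(start)]
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, sprintf(
        "%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s exon_number \"%d\";",
        ex$chrom[j], source, ex$start[j] + 1L, ex$end[j], ex$strand[j],
        attrs, j))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a GTF into gene and exon tables
#'
#' Uses `rtracklayer::import` and converts to the internal 0-based
#' half-open convention. The TSS of each gene is derived from its strand.
#'
#' @param path GTF file.
#' @param id_field Attribute naming the grouping id, default "gene_id".
#' @return List with `genes` (`gene_id, chrom, start, end, strand, tss`)
#'   and `exons` (`gene_id, chrom, start, end, strand`).
#' @export
read_gtf <- function(path, id_field = "gene_id") {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("rtracklayer is required to read GTF files")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  dt <- data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(md$type),
    gid = as.character(md[[id_field]]))
  ex <- dt[type == "exon",
           list(gene_id = gid, chrom, start, end, strand)]
  gtab <- dt[type == "gene"]
  if (nrow(gtab) == 0) {
    gtab <- ex[, list(chrom = chrom[1], start = min(start),
                      end = max(end), strand = strand[1]),
               by = list(gid)]
    gtab[, type := "gene"]
    data.table::setcolorder(gtab, c("chrom", "start", "end", "strand",
                                    "type", "gid"))
  }
  genes <- gtab[, list(gene_id = gid, chrom, start, end, strand,
                       tss = ifelse(strand == "-", end - 1L, start))]
  list(genes = genes[order(chrom, start)], exons = ex[order(chrom, start)])
}

utils::globalVariables(c("type", "gid", "start1"))

# --- pipeline configuration ------------------------------------------------

#' Pipeline configuration
#'
#' Collects input paths and analysis thresholds. Threshold ranges are
#' validated immediately; file existence is checked when the pipeline
#' runs.
#'
#' @param fasta,gtf Genome FASTA and coding gene models GTF.
#' @param methylome_files Per-sample Bismark-coverage files.
#' @param sample_conditions Condition label per methylome file.
#' @param enhancers_bed,cpg_islands_bed,tads_bed,cage_bed Interval tracks.
#' @param lnc_gtf,lnc_meta lncRNA candidate models and coding-potential
#'   flags (TSV: transcript_id, coding_potential).
#' @param de_table,gene_set,ortholog_map Expression-side inputs.
#' @param pwm_meme MEME minimal motif file.
#' @param out_dir Output directory.
#' @param min_cov,cov_scope Coverage filter (default >= 5, every sample).
#' @param dm_method Per-site test, "pooled-fisher" or "logistic-lrt".
#' @param q_threshold,delta_threshold DM call thresholds (0.05, 20 pp).
#' @param max_gap,min_sites DMR chaining parameters (500 bp, 2 sites).
#' @param window_width Motif window width (40 bp).
#' @param score_fraction PWM hit threshold fraction (0.8).
#' @param kmer_range K-mer sizes for de-novo search (6:8).
#' @param min_lnc_len,cage_max_dist lncRNA rules (200 nt, 50 bp).
#' @param promoter_window Promoter window around the TSS.
#' @param n_strata,bg_multiplier Coverage-matched background parameters.
#' @param pair_max_dist,corr_max_dist Pairing windows (100 kb, 500 kb).
#' @param seed Seed for the stochastic steps (background sampling).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(fasta = NULL, gtf = NULL,
                            methylome_files = character(0),
                            sample_conditions = character(0),
                            enhancers_bed = NULL, cpg_islands_bed = NULL,
                            tads_bed = NULL, cage_bed = NULL,
                            lnc_gtf = NULL, lnc_meta = NULL,
                            de_table = NULL, gene_set = NULL,
                            ortholog_map = NULL, pwm_meme = NULL,
                            out_dir = "dmrkit_out",
                            min_cov = 5, cov_scope = "every-sample",
                            dm_method = "pooled-fisher",
                            q_threshold = 0.05, delta_threshold = 20,
                            max_gap = 500, min_sites = 2,
                            window_width = 40, score_fraction = 0.8,
                            kmer_range = 6:8,
                            min_lnc_len = 200, cage_max_dist = 50,
                            promoter_window = c(-1500, 500),
                            n_strata = 10, bg_multiplier = 10,
                            pair_max_dist = 1e5, corr_max_dist = 5e5,
                            seed = 1L) {
  cfg <- as.list(environment())
  stop_if_not_scalar_number(q_threshold, "q_threshold", 0, 1)
  stop_if_not_scalar_number(delta_threshold, "delta_threshold", 0, 100)
  stop_if_not_scalar_number(min_cov, "min_cov", 0)
  stop_if_not_scalar_number(max_gap, "max_gap", 0)
  stop_if_not_scalar_number(min_sites, "min_sites", 1)
  stop_if_not_scalar_number(window_width, "window_width", 2)
  stop_if_not_scalar_number(score_fraction, "score_fraction", 0, 1)
  stopifnot(cov_scope %in% c("every-sample", "pooled"),
            dm_method %in% c("pooled-fisher", "logistic-lrt"),
            length(methylome_files) == length(sample_conditions))
  cfg$seed <- as.integer(seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write a pipeline configuration as a flat TOML file
#'
#' @param config A [pipeline_config()].
#' @param path Output path.
#' @export
write_pipeline_config <- function(config, path) {
  fmt <- function(k, v) {
    if (is.null(v) || length(v) == 0) return(NULL)
    val <- if (is.character(v) && length(v) == 1) sprintf('"%s"', v)
    else if (is.character(v)) {
      sprintf("[%s]", paste(sprintf('"%s"', v), collapse = ", "))
    } else if (length(v) > 1) {
      sprintf("[%s]", paste(format(v, scientific = FALSE), collapse = ", "))
    } else format(v, scientific = FALSE)
    sprintf("%s = %s", k, val)
  }
  keys <- setdiff(names(config), character(0))
  lines <- unlist(lapply(keys, function(k) fmt(k, config[[k]])))
  writeLines(lines, path)
  invisible(path)
}

#' Read a flat TOML pipeline configuration
#'
#' Supports the dialect written by [write_pipeline_config()]: scalar
#' strings, numbers, booleans, and one-line arrays.
#'
#' @param path Config file.
#' @return A validated [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parse_val <- function(s) {
    s <- trimws(s)
    if (grepl("^\\[", s)) {
      inner <- sub("^\\[", "", sub("\\]$", "", s))
      parts <- trimws(strsplit(inner, ",")[[1]])
      return(unlist(lapply(parts, parse_val)))
    }
    if (grepl('^".*"$', s)) return(sub('^"', "", sub('"$', "", s)))
    if (s %in% c("true", "false")) return(s == "true")
    as.numeric(s)
  }
  kv <- list()
  for (l in lines) {
    eq <- regexpr("=", l, fixed = TRUE)
    if (eq < 0) stop("malformed config line: ", l)
    k <- trimws(substr(l, 1, eq - 1))
    kv[[k]] <- parse_val(substr(l, eq + 1, nchar(l)))
  }
  do.call(pipeline_config, kv)
}

#' Read and validate all annotation inputs of a pipeline configuration
#'
#' @param config A [pipeline_config()].
#' @return An `AnnotationBundle`-style list (genes, exons, tracks, genome,
#'   lncRNA candidates).
#' @export
read_annotation_inputs <- function(config) {
  genome <- Biostrings::readDNAStringSet(config$fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gm <- read_gtf(config$gtf)
  read_track <- function(p) if (is.null(p)) NULL else read_bed(p)
  bundle <- list(
    config = NULL,
    chrom_lengths = stats::setNames(Biostrings::width(genome),
                                    names(genome)),
    genome = genome, genes = gm$genes, exons = gm$exons,
    enhancers = read_track(config$enhancers_bed),
    cpg_islands = read_track(config$cpg_islands_bed),
    tads = read_track(config$tads_bed),
    cage = read_track(config$cage_bed),
    lnc_exons = NULL, lnc_meta = NULL)
  if (!is.null(config$lnc_gtf)) {
    lm <- read_gtf(config$lnc_gtf, id_field = "transcript_id")
    bundle$lnc_exons <- data.table::setnames(lm$exons, "gene_id",
                                             "transcript_id")
    if (!is.null(config$lnc_meta)) {
      bundle$lnc_meta <- read_tsv(config$lnc_meta)
    }
  }
  used <- unique(c(bundle$genes$chrom, bundle$enhancers$chrom,
                   bundle$cpg_islands$chrom, bundle$tads$chrom,
                   bundle$cage$chrom, bundle$lnc_exons$chrom))
  missing_chrom <- setdiff(used, names(genome))
  if (length(missing_chrom)) {
    stop("chromosomes absent from the FASTA: ",
         paste(missing_chrom, collapse = ", "))
  }
  class(bundle) <- "AnnotationBundle"
  bundle
}

#' Write all simulated study inputs to a directory
#'
#' Runs the three simulators and writes genome FASTA, gene and lncRNA
#' GTFs, BED tracks, per-sample Bismark-coverage files, DE table, gene
#' set, ortholog map, a bundled PWM file path reference, the ground-truth
#' JSON, and a ready-to-run pipeline config (TOML).
#'
#' @param dir Output directory.
#' @param config A [sim_config()].
#' @return The [pipeline_config()] pointing at the written files, with the
#'   truth attached as attribute `truth`.
#' @export
simulate_study <- function(dir, config = sim_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bundle <- simulate_annotation_bundle(config)
  meth <- simulate_methylome_experiment(bundle, config)
  bundle <- meth$bundle
  expr <- simulate_expression_tables(bundle, config)

  fasta <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(bundle$genome, fasta)
  gtf <- file.path(dir, "genes.gtf")
  write_gtf(bundle$genes, bundle$exons, gtf)
  lnc_gtf <- file.path(dir, "lncrna_candidates.gtf")
  lnc_spans <- bundle$lnc_exons[, list(
    chrom = chrom[1], start = min(start), end = max(end),
    strand = strand[1]), by = transcript_id]
  write_gtf(lnc_spans, bundle$lnc_exons, lnc_gtf)
  lnc_meta <- file.path(dir, "lncrna_meta.tsv")
  write_tsv(bundle$lnc_meta[, list(transcript_id, coding_potential)],
            lnc_meta)
  beds <- list(enhancers = bundle$enhancers,
               cpg_islands = bundle$cpg_islands,
               tads = bundle$tads, cage = bundle$cage)
  bed_paths <- lapply(names(beds), function(nm) {
    p <- file.path(dir, paste0(nm, ".bed"))
    write_bed6(beds[[nm]], p)
    p
  })
  names(bed_paths) <- names(beds)
  cov_paths <- write_bismark_cov(meth$methylome, file.path(dir, "methylome"))
  de_path <- file.path(dir, "de_table.tsv")
  write_tsv(expr$de_table, de_path)
  set_path <- file.path(dir, "emt_set.txt")
  writeLines(expr$emt_human_symbols, set_path)
  orth_path <- file.path(dir, "orthologs.tsv")
  write_tsv(expr$ortholog_map, orth_path)
  truth <- list(
    planted_dmrs = meth$truth$planted_dmrs[, list(
      chrom, start, end, delta_pp,
      member_pos = vapply(member_pos, paste, character(1), collapse = ","))],
    planted_motif_sites = meth$truth$planted_motif_sites,
    planted_de = expr$truth$planted_de_ids,
    emt_mouse_ids = expr$truth$emt_mouse_ids)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE,
                       digits = NA)
  pwm_path <- system.file("extdata", "motifs_synthetic.meme",
                          package = "dmrkit")
  cfg <- pipeline_config(
    fasta = fasta, gtf = gtf,
    methylome_files = unname(cov_paths),
    sample_conditions = attr(cov_paths, "conditions"),
    enhancers_bed = bed_paths$enhancers,
    cpg_islands_bed = bed_paths$cpg_islands,
    tads_bed = bed_paths$tads, cage_bed = bed_paths$cage,
    lnc_gtf = lnc_gtf, lnc_meta = lnc_meta,
    de_table = de_path, gene_set = set_path, ortholog_map = orth_path,
    pwm_meme = if (nzchar(pwm_path)) pwm_path else NULL,
    out_dir = file.path(dir, "results"),
    seed = config$seed)
  write_pipeline_config(cfg, file.path(dir, "pipeline_config.toml"))
  attr(cfg, "truth") <- meth$truth
  attr(cfg, "expr_truth") <- expr$truth
  cfg
}

# run one pipeline stage, aborting with its name on failure
run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes collapse/filter, per-site DM testing, BH correction, DM
#' calling, DMR chaining, feature assignment and enrichment (with a
#' coverage-matched background), TSS-distance binning, per-TAD summaries,
#' enhancer proximity, PWM and k-mer motif enrichment, lncRNA
#' classification and neighbour pairing, gene-set enrichment, and
#' methylation-expression correlation, writing every result as
#' TSV/BED/JSON under `config$out_dir`. Identical config and seed produce
#' byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisible list of the main in-memory results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  bundle <- run_stage("read-annotation", read_annotation_inputs(config))
  meth <- run_stage("read-methylome", read_methylome_table(
    config$methylome_files, config$sample_conditions))

  collapsed <- run_stage("collapse-filter", collapse_and_filter(
    meth, min_cov = config$min_cov, scope = config$cov_scope,
    samples = tools::file_path_sans_ext(basename(config$methylome_files))))
  tests <- run_stage("dm-test", test_dm_sites(collapsed,
                                              method = config$dm_method))
  called <- run_stage("dm-call", call_dm(tests, config$q_threshold,
                                         config$delta_threshold))
  write_tsv(called, file.path(out, "dm_sites.tsv"))
  dm <- called[is_dm == TRUE]
  write_bed6(data.table(chrom = dm$chrom, start = dm$pos,
                        end = dm$pos + 2L,
                        name = format(dm$q, digits = 6, scientific = TRUE,
                                      trim = TRUE),
                        score = round(abs(dm$delta_pp), 2), strand = "."),
             file.path(out, "dm_sites.bed"))

  dmrs <- run_stage("dmr", cluster_dmrs(dm, max_gap = config$max_gap,
                                        min_sites = config$min_sites))
  write_bed6(data.table(chrom = dmrs$chrom, start = dmrs$start,
                        end = dmrs$end, name = dmrs$direction,
                        score = round(abs(dmrs$mean_delta_pp), 2),
                        strand = "."),
             file.path(out, "dmrs.bed"))
  write_tsv(dmrs[, list(chrom, start, end, n_sites,
                        mean_delta_pp = round(mean_delta_pp, 4), direction)],
            file.path(out, "dmrs.tsv"))
  if (!is.null(bundle$tads)) {
    tad_tab <- run_stage("tad", tad_dm_fraction(called, dm, bundle$tads,
                                                bundle$genes))
    write_tsv(tad_tab, file.path(out, "tad_dm.tsv"))
  }

  asg_all <- run_stage("annotate", assign_features(
    called, bundle, promoter_window = config$promoter_window))
  asg_dm <- asg_all[called$is_dm]
  bg <- run_stage("background", coverage_matched_background(
    dm, called, n_strata = config$n_strata,
    multiplier = config$bg_multiplier, seed = config$seed))
  asg_bg <- asg_all[match(paste(bg$chrom, bg$pos, sep = ":"),
                          asg_all$site_id)]
  enr <- run_stage("feature-enrichment", feature_enrichment(asg_dm, asg_bg))
  write_tsv(enr, file.path(out, "feature_enrichment.tsv"))
  bins <- run_stage("tss-bins", tss_distance_bins(asg_dm))
  write_tsv(bins, file.path(out, "tss_distance_bins.tsv"))
  if (!is.null(bundle$enhancers)) {
    prox <- run_stage("enhancer-proximity", enhancer_proximity(
      dm, bundle$enhancers, max_dist = 1000, genes = bundle$genes))
    write_tsv(prox, file.path(out, "enhancer_proximity.tsv"))
  }

  motif_res <- NULL
  if (!is.null(config$pwm_meme) && nrow(dm) > 0) {
    motif_res <- run_stage("motif", {
      pwms <- read_meme(config$pwm_meme)
      dm_win <- extract_windows(dm, bundle$genome,
                                width = config$window_width)
      bg_win <- extract_windows(bg, bundle$genome,
                                width = config$window_width)
      pwm_tab <- pwm_window_enrichment(dm_win, bg_win, pwms,
                                       score_fraction = config$score_fraction)
      kmer_tab <- kmer_enrichment(dm_win, bg_win,
                                  k_range = config$kmer_range)
      write_tsv(pwm_tab, file.path(out, "pwm_enrichment.tsv"))
      write_tsv(kmer_tab, file.path(out, "kmer_enrichment.tsv"))
      list(pwm = pwm_tab, kmer = kmer_tab)
    })
  }

  lnc_res <- NULL
  if (!is.null(bundle$lnc_exons) && !is.null(bundle$cage)) {
    lnc_res <- run_stage("lncrna", {
      calls <- classify_lncrnas(bundle$lnc_exons, bundle$lnc_meta,
                                bundle$genes, bundle$cage,
                                min_len = config$min_lnc_len,
                                cage_max_dist = config$cage_max_dist)
      write_tsv(calls, file.path(out, "lncrna_calls.tsv"))
      calls
    })
  }

  de <- NULL
  genesets_res <- NULL
  if (!is.null(config$de_table)) {
    de <- run_stage("read-de-table", read_tsv(config$de_table))
    if (!"de" %in% names(de)) de[, de := padj < 0.05]
    if (!is.null(lnc_res)) {
      pairs <- run_stage("lncrna-pairs", pair_with_neighbor_genes(
        lnc_res, bundle$lnc_exons, bundle$genes, de,
        max_dist = config$pair_max_dist))
      write_tsv(pairs, file.path(out, "lncrna_pairs.tsv"))
    }
    if (!is.null(config$gene_set) && !is.null(config$ortholog_map)) {
      genesets_res <- run_stage("genesets", {
        human <- readLines(config$gene_set)
        orth <- read_tsv(config$ortholog_map)
        mapped <- map_orthologs(human, orth)
        gse <- fisher_set_enrichment(
          intersect(mapped$mouse_ids, de$id), de$id[de$de], de$id)
        gse$n_unmapped_symbols <- mapped$n_unmapped
        write_tsv(data.table::as.data.table(gse),
                  file.path(out, "geneset_enrichment.tsv"))
        gse
      })
    }
    corr <- run_stage("meth-expr-correlation", meth_expr_correlation(
      dm, asg_dm, de, max_dist = config$corr_max_dist))
    write_tsv(corr, file.path(out, "meth_expr_correlation.tsv"))
  }

  summary <- list(
    n_sites_tested = sum(!is.na(called$p)),
    n_dm = nrow(dm),
    n_hyper = sum(dm$delta_pp > 0),
    n_hypo = sum(dm$delta_pp < 0),
    n_dmrs = nrow(dmrs))
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  log_lines <- c(
    sprintf("dmrkit version: %s",
            as.character(utils::packageVersion("dmrkit"))),
    sprintf("seed: %d", config$seed),
    sprintf("min_cov: %s (%s)", config$min_cov, config$cov_scope),
    sprintf("dm thresholds: q < %s, |delta| > %s pp",
            config$q_threshold, config$delta_threshold),
    sprintf("dmr chaining: max_gap %s bp, min_sites %s",
            config$max_gap, config$min_sites),
    sprintf("motif window: %s bp, score fraction %s",
            config$window_width, config$score_fraction),
    sprintf("sites tested: %d, DM: %d, DMRs: %d",
            summary$n_sites_tested, summary$n_dm, summary$n_dmrs))
  writeLines(log_lines, file.path(out, "run_log.txt"))

  invisible(list(called = called, dmrs = dmrs, enrichment = enr,
                 tss_bins = bins, motif = motif_res, lncrna = lnc_res,
                 genesets = genesets_res, summary = summary))
}
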