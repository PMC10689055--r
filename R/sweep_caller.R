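#' Scan configuration
#'
#' Bundles the parameters of a full sweep scan: window geometry, SNP filter,
#' outlier fraction, evidence rule and the population triple. Defaults follow
#' the standard design: 500-kb windows sliding in 125-kb steps, at least five
#' SNPs per retained window, top-5% outliers, and a sweep call requiring
#' support from at least two of the three statistics.
#'
#' @param size_bp,step_bp window size and step (bp).
#' @param min_snps minimum segregating SNPs per retained window.
#' @param top_fraction outlier tail fraction per method (0 < q < 1).
#' @param methods subset of `c("pbs", "piratio", "xpclr")`.
#' @param min_methods minimum number of supporting methods for a candidate.
#' @param focal,baseline focal (scanned) and baseline group labels.
#' @param third third population for PBS: a group label, or `"pooled"` to
#'   pool every remaining group.
#' @param xpclr an [xpclr_params()] used when `"xpclr"` is among the methods.
#' @return list of class `scan_config`.
#' @export
scan_config <- function(size_bp = 500000, step_bp = 125000, min_snps = 5,
                        top_fraction = 0.05,
                        methods = c("pbs", "piratio", "xpclr"),
                        min_methods = 2, focal = NULL, baseline = NULL,
                        third = "pooled", xpclr = xpclr_params()) {
  methods <- match.arg(methods, c("pbs", "piratio", "xpclr"), several.ok = TRUE)
  if (top_fraction <= 0 || top_fraction >= 1)
    stopf("top_fraction must be in (0, 1)")
  if (min_methods > length(methods))
    stopf("min_methods (%d) exceeds number of methods (%d)",
          min_methods, length(methods))
  if (min_methods < 1) stopf("min_methods must be >= 1")
  structure(list(size_bp = size_bp, step_bp = step_bp, min_snps = min_snps,
                 top_fraction = top_fraction, methods = methods,
                 min_methods = min_methods, focal = focal,
                 baseline = baseline, third = third, xpclr = xpclr),
            class = "scan_config")
}

#' Flag the top fraction of a statistic's distribution
#'
#' Flags the `ceiling(q * N)` largest rankable values, where `N` counts
#' non-missing values (`Inf` sentinels rank above every finite value; `NaN`
#' and `NA` are excluded). The threshold is the smallest flagged value; ties
#' at a finite threshold are all flagged, while an infinite threshold does
#' not pull in further infinities (sort stability: ascending position breaks
#' ties among equal values).
#'
#' @param values numeric vector of per-window statistic values.
#' @param q outlier tail fraction.
#' @return list with `threshold`, logical `flags` aligned with `values`, and
#'   `n_flagged`.
#' @export
threshold_top_fraction <- function(values, q = 0.05) {
  if (q <= 0 || q >= 1) stopf("q must be in (0, 1)")
  rankable <- !is.na(values)           # NaN and NA excluded; +-Inf kept
  N <- sum(rankable)
  if (N < ceiling(1 / q))
    stopf("need at least %d rankable values for a top-%.3g threshold (have %d)",
          ceiling(1 / q), q, N)
  m <- ceiling(q * N)
  idx <- which(rankable)
  ord <- idx[order(-values[idx], idx)]
  flagged <- ord[seq_len(m)]
  thr <- values[flagged[m]]
  if (is.finite(thr)) flagged <- union(flagged, idx[values[idx] == thr])
  fin <- values[is.finite(values)]
  if (length(fin) && max(fin) == min(fin))
    warnf("degenerate statistic distribution: all finite values equal")
  flags <- logical(length(values))
  flags[flagged] <- TRUE
  list(threshold = thr, flags = flags, n_flagged = sum(flags))
}

#' Combine per-method outlier flags into candidate-window evidence
#'
#' @param flag_list named list of logical vectors (one per method), all
#'   evaluated on the same retained-window set; a length mismatch is a hard
#'   error, never a silent intersection.
#' @param min_methods minimum supporting methods for a candidate window.
#' @return data.frame with one logical column per method, `support_count`,
#'   and `candidate`.
#' @export
combine_evidence <- function(flag_list, min_methods = 2) {
  lens <- vapply(flag_list, length, integer(1))
  if (length(unique(lens)) != 1L)
    stopf("methods evaluated on different window sets (lengths: %s)",
          paste(lens, collapse = ", "))
  flags <- as.data.frame(flag_list)
  support <- rowSums(flags)
  flags$support_count <- as.integer(support)
  flags$candidate <- support >= min_methods
  flags
}

#' Merge candidate windows into sweep intervals
#'
#' Overlapping or book-ended candidate windows (adjacent windows of the
#' sliding grid touch by construction) are merged into maximal intervals;
#' supporting methods are unioned and the per-window support count is
#' maximized over the merged windows.
#'
#' @param windows data.frame with `chrom`, `start`, `end`, logical method
#'   columns, and `support_count`; only rows to be merged (the candidates)
#'   should be passed.
#' @param methods names of the method columns present in `windows`.
#' @return data.frame of class `sweep_intervals`: `chrom`, `start`, `end`,
#'   `length_bp`, `n_windows`, `support`, `methods` (comma-joined labels).
#' @export
merge_candidate_windows <- function(windows,
                                    methods = intersect(
                                      c("pbs", "piratio", "xpclr"),
                                      names(windows))) {
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      length_bp = numeric(), n_windows = integer(),
                      support = integer(), methods = character(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("sweep_intervals", "data.frame")
  if (!nrow(windows)) return(empty)
  windows <- windows[order(windows$chrom, windows$start), , drop = FALSE]
  out <- list()
  cur <- NULL
  flush <- function(cur) {
    data.frame(chrom = cur$chrom, start = cur$start, end = cur$end,
               length_bp = cur$end - cur$start, n_windows = cur$n,
               support = cur$support,
               methods = paste(methods[cur$meth], collapse = ","),
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    meth <- if (length(methods)) unlist(w[methods]) else logical(0)
    if (!is.null(cur) && w$chrom == cur$chrom && w$start <= cur$end) {
      cur$end <- max(cur$end, w$end)
      cur$n <- cur$n + 1L
      cur$support <- max(cur$support, w$support_count)
      cur$meth <- cur$meth | meth
    } else {
      if (!is.null(cur)) out[[length(out) + 1L]] <- flush(cur)
      cur <- list(chrom = w$chrom, start = w$start, end = w$end, n = 1L,
                  support = w$support_count, meth = meth)
    }
  }
  out[[length(out) + 1L]] <- flush(cur)
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  class(res) <- c("sweep_intervals", "data.frame")
  res
}

#' Annotate sweep intervals with overlapping genes
#'
#' A gene is assigned to a sweep if they overlap by at least 1 bp (both in
#' 0-based half-open coordinates, strand-agnostic).
#'
#' @param sweeps a [merge_candidate_windows()] result.
#' @param genes a [gene_models()] table.
#' @return list with `sweeps` (input plus `genes` and `n_genes` columns) and
#'   `gene_table` (flat data.frame: `gene_id`, `chrom`, sweep coordinates).
#' @export
annotate_genes <- function(sweeps, genes) {
  gl <- character(nrow(sweeps)); ng <- integer(nrow(sweeps))
  flat <- list()
  for (i in seq_len(nrow(sweeps))) {
    hit <- genes$chrom == sweeps$chrom[i] &
      genes$start < sweeps$end[i] & genes$end > sweeps$start[i]
    ids <- genes$gene_id[hit]
    gl[i] <- paste(ids, collapse = ",")
    ng[i] <- length(ids)
    if (length(ids))
      flat[[length(flat) + 1L]] <- data.frame(
        gene_id = ids, chrom = sweeps$chrom[i],
        sweep_start = sweeps$start[i], sweep_end = sweeps$end[i],
        stringsAsFactors = FALSE)
  }
  sweeps$genes <- gl
  sweeps$n_genes <- ng
  gene_table <- if (length(flat))
    do.call(rbind, c(flat, list(make.row.names = FALSE)))
  else data.frame(gene_id = character(), chrom = character(),
                  sweep_start = numeric(), sweep_end = numeric())
  list(sweeps = sweeps, gene_table = gene_table)
}

#' Shared genome and genes between two sweep sets
#'
#' Total base pairs of pairwise interval intersection between two merged
#' sweep sets, and the genes overlapping both.
#'
#' @param sweeps_a,sweeps_b merged sweep interval tables.
#' @param genes optional [gene_models()] table for the shared-gene report.
#' @return list with `shared_bp` and `shared_genes` (character vector; empty
#'   when `genes` is NULL).
#' @export
sweep_overlap <- function(sweeps_a, sweeps_b, genes = NULL) {
  shared <- 0
  pieces <- list()
  for (cn in intersect(unique(sweeps_a$chrom), unique(sweeps_b$chrom))) {
    a <- sweeps_a[sweeps_a$chrom == cn, ]
    b <- sweeps_b[sweeps_b$chrom == cn, ]
    for (i in seq_len(nrow(a))) {
      s <- pmax(a$start[i], b$start); e <- pmin(a$end[i], b$end)
      ov <- e > s
      shared <- shared + sum((e - s)[ov])
      if (any(ov))
        pieces[[length(pieces) + 1L]] <- data.frame(
          chrom = cn, start = s[ov], end = e[ov], stringsAsFactors = FALSE)
    }
  }
  shared_genes <- character(0)
  if (!is.null(genes) && length(pieces)) {
    in_set <- function(sw) {
      hits <- logical(nrow(genes))
      for (i in seq_len(nrow(sw)))
        hits <- hits | (genes$chrom == sw$chrom[i] &
                          genes$start < sw$end[i] & genes$end > sw$start[i])
      hits
    }
    shared_genes <- genes$gene_id[in_set(sweeps_a) & in_set(sweeps_b)]
  }
  list(shared_bp = shared, shared_genes = shared_genes)
}

#' Per-sweep diversity-loss summaries
#'
#' For each sweep interval, the ratio of baseline to focal diversity over the
#' windows overlapping the sweep, under two conventions: the ratio of
#' window-mean diversities (`"mean"`, the default) and the ratio of
#' window-summed diversities (`"sum"`). The two differ only when windows are
#' unevenly informative; both are reported by published per-sweep summaries
#' without the convention always being stated.
#'
#' @param windows retained-window statistic table (from a [sweep_scan()]
#'   result) with `pi_<group>` columns.
#' @param sweeps merged sweep interval table.
#' @param baseline,focal group labels naming the `pi_` columns.
#' @param method `"mean"` or `"sum"`.
#' @return Numeric vector of per-sweep diversity ratios (possibly `Inf` when
#'   focal diversity in the sweep is zero).
#' @export
sweep_pi_ratio <- function(windows, sweeps, baseline, focal,
                           method = c("mean", "sum")) {
  method <- match.arg(method)
  pb <- windows[[paste0("pi_", baseline)]]
  pf <- windows[[paste0("pi_", focal)]]
  if (is.null(pb) || is.null(pf))
    stopf("windows table lacks pi_%s / pi_%s columns", baseline, focal)
  agg <- if (method == "mean") mean else sum
  vapply(seq_len(nrow(sweeps)), function(i) {
    hit <- windows$chrom == sweeps$chrom[i] &
      windows$start < sweeps$end[i] & windows$end > sweeps$start[i]
    if (!any(hit)) return(NA_real_)
    agg(pb[hit]) / agg(pf[hit])
  }, numeric(1))
}

#' Run the full selective-sweep scan
#'
#' End-to-end orchestration: ingest genotypes, population map and gene
#' models; build the sliding-window grid; compute windowed diversity,
#' pairwise Weir-Cockerham FST, PBS of the focal group, the log2 ratio of
#' baseline to focal diversity, and the window-mapped XP-CLR score; flag the
#' top fraction per method; call candidate windows supported by at least
#' `min_methods` statistics; merge and annotate sweeps. Deterministic given
#' inputs and configuration.
#'
#' @param vcf path to a VCF, or a [genotype_matrix()].
#' @param popmap path to a population map, or a [population_map()].
#' @param gff optional path to a GFF3, or a [gene_models()] table.
#' @param config a [scan_config()]; `focal` and `baseline` must be set.
#' @param outdir optional output directory; when given, writes
#'   `windows.tsv`, `outliers.<method>.bed`, `sweeps.bed` (BED6, score =
#'   support count), `sweep_genes.tsv` and `run.log`.
#' @param chrom_lengths optional named chromosome lengths (bp); defaults to
#'   lengths carried by the VCF header.
#' @return object of class `sweep_scan`: list with `windows` (statistic table
#'   with flags), `thresholds`, `sweeps`, `gene_table`, `xpclr_scores`,
#'   `config` and `counts`.
#' @export
sweep_scan <- function(vcf, popmap, gff = NULL, config = scan_config(),
                       outdir = NULL, chrom_lengths = NULL) {
  stopifnot(inherits(config, "scan_config"))
  if (is.null(config$focal) || is.null(config$baseline))
    stopf("scan stage config: focal and baseline groups must be set")
  gm <- if (inherits(vcf, "genotype_matrix")) vcf else
    tryCatch(read_vcf(vcf), error = function(e)
      stopf("scan stage ingest: %s", conditionMessage(e)))
  pm <- if (inherits(popmap, "population_map")) popmap else
    tryCatch(read_population_map(popmap), error = function(e)
      stopf("scan stage ingest: %s", conditionMessage(e)))
  genes <- NULL
  if (!is.null(gff))
    genes <- if (inherits(gff, "gene_models")) gff else
      tryCatch(read_gff_genes(gff), error = function(e)
        stopf("scan stage ingest: %s", conditionMessage(e)))
  if (is.null(chrom_lengths)) chrom_lengths <- gm$chrom_lengths
  focal <- config$focal; baseline <- config$baseline
  third <- config$third
  if (identical(third, "pooled")) {
    rest <- setdiff(attr(pm, "groups"), c(focal, baseline))
    if (!length(rest))
      stopf("scan stage config: no remaining groups to pool as the third population")
    pm <- pool_groups(pm, rest, "POOLED")
    third <- "POOLED"
  }
  grid <- make_windows(chrom_lengths, config$size_bp, config$step_bp)
  piw <- tryCatch(
    window_pi(gm, grid, pm, min_snps = config$min_snps,
              groups = c(baseline, focal)),
    error = function(e) stopf("scan stage diversity: %s", conditionMessage(e)))
  retained <- paste(piw$chrom, piw$start)
  keep <- paste(grid$chrom, grid$start) %in% retained
  stats <- piw
  fst_fb <- window_fst(gm, grid, pm, focal, baseline)[keep]
  fst_ft <- window_fst(gm, grid, pm, focal, third)[keep]
  fst_bt <- window_fst(gm, grid, pm, baseline, third)[keep]
  stats$fst_focal_baseline <- fst_fb
  stats$fst_focal_third <- fst_ft
  stats$fst_baseline_third <- fst_bt
  stats$pbs <- pbs(fst_fb, fst_ft, fst_bt)
  stats$log2_ratio <- pi_ratio(stats[[paste0("pi_", baseline)]],
                               stats[[paste0("pi_", focal)]])
  xp_scores <- NULL
  if ("xpclr" %in% config$methods) {
    xp_scores <- tryCatch(
      xpclr_scan(gm, pm, reference = baseline, object = focal,
                 params = config$xpclr, chrom_lengths = chrom_lengths),
      error = function(e) stopf("scan stage xpclr: %s", conditionMessage(e)))
    stats$xpclr <- xpclr_window_max(xp_scores, grid)[keep]
  }
  stat_col <- c(pbs = "pbs", piratio = "log2_ratio", xpclr = "xpclr")
  thresholds <- list(); flag_list <- list()
  for (m in config$methods) {
    th <- tryCatch(threshold_top_fraction(stats[[stat_col[[m]]]],
                                          config$top_fraction),
                   error = function(e) stopf("scan stage threshold (%s): %s",
                                             m, conditionMessage(e)))
    thresholds[[m]] <- th$threshold
    flag_list[[m]] <- th$flags
  }
  ev <- combine_evidence(flag_list, config$min_methods)
  stats <- cbind(stats, setNames(ev[config$methods],
                                 paste0("flag_", config$methods)))
  stats$support_count <- ev$support_count
  stats$candidate <- ev$candidate
  cand <- cbind(stats[ev$candidate, c("chrom", "start", "end"), drop = FALSE],
                setNames(ev[ev$candidate, config$methods, drop = FALSE],
                         config$methods),
                support_count = ev$support_count[ev$candidate])
  sweeps <- merge_candidate_windows(cand, methods = config$methods)
  gene_table <- NULL
  if (!is.null(genes)) {
    ann <- annotate_genes(sweeps, genes)
    sweeps <- ann$sweeps
    gene_table <- ann$gene_table
  }
  counts <- list(n_windows = nrow(grid), n_retained = nrow(stats),
                 n_flagged = vapply(flag_list, sum, integer(1)),
                 n_candidates = sum(ev$candidate), n_sweeps = nrow(sweeps),
                 sweep_bp = sum(sweeps$length_bp),
                 n_genes = if (is.null(gene_table)) NA_integer_ else
                   length(unique(gene_table$gene_id)))
  res <- structure(list(windows = stats, thresholds = thresholds,
                        sweeps = sweeps, gene_table = gene_table,
                        xpclr_scores = xp_scores, config = config,
                        grid = grid, counts = counts),
                   class = "sweep_scan")
  if (!is.null(outdir)) write_scan_outputs(res, outdir)
  res
}

#' Write the output bundle of a sweep scan
#'
#' @param scan a [sweep_scan()] result.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_scan_outputs <- function(scan, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wpath <- file.path(outdir, "windows.tsv")
  con <- file(wpath, open = "wb")
  writeLines(c("# per-window scan statistics (0-based half-open windows)",
               "# pi_*: per-bp nucleotide diversity; fst_*: windowed Weir-Cockerham FST",
               "# pbs: population branch statistic of the focal group",
               "# log2_ratio: log2(pi_baseline / pi_focal); xpclr: max grid-point CLR",
               paste(names(scan$windows), collapse = "\t")), con, sep = "\n")
  write.table(scan$windows, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  close(con)
  stat_col <- c(pbs = "pbs", piratio = "log2_ratio", xpclr = "xpclr")
  for (m in scan$config$methods) {
    flags <- scan$windows[[paste0("flag_", m)]]
    bed <- scan$windows[flags, c("chrom", "start", "end"), drop = FALSE]
    bed$name <- m
    bed$score <- format(scan$windows[[stat_col[[m]]]][flags], digits = 8,
                        trim = TRUE, scientific = FALSE)
    bed$strand <- "."
    .write_tsv(bed, file.path(outdir, sprintf("outliers.%s.bed", m)),
               col.names = FALSE)
  }
  bed <- scan$sweeps[, c("chrom", "start", "end", "methods", "support")]
  bed$strand <- "."
  .write_tsv(bed, file.path(outdir, "sweeps.bed"), col.names = FALSE)
  if (!is.null(scan$gene_table))
    .write_tsv(scan$gene_table, file.path(outdir, "sweep_genes.tsv"))
  cfg <- scan$config
  cfg_lines <- c(sprintf("popsweep %s", as.character(packageVersion("popsweep"))),
                 sprintf("config: size_bp=%d step_bp=%d min_snps=%d top=%g methods=%s min_methods=%d focal=%s baseline=%s third=%s",
                         cfg$size_bp, cfg$step_bp, cfg$min_snps,
                         cfg$top_fraction, paste(cfg$methods, collapse = ","),
                         cfg$min_methods, cfg$focal, cfg$baseline, cfg$third))
  tf <- tempfile(); writeLines(cfg_lines[2], tf)
  cfg_hash <- unname(md5sum(tf)); unlink(tf)
  cnt <- scan$counts
  log_lines <- c(cfg_lines, sprintf("config_md5: %s", cfg_hash),
                 sprintf("windows: %d grid, %d retained", cnt$n_windows,
                         cnt$n_retained),
                 sprintf("flagged: %s",
                         paste(sprintf("%s=%d", names(cnt$n_flagged),
                                       cnt$n_flagged), collapse = " ")),
                 sprintf("candidates: %d", cnt$n_candidates),
                 sprintf("sweeps: %d spanning %.0f bp", cnt$n_sweeps,
                         cnt$sweep_bp),
                 sprintf("genes_in_sweeps: %s",
                         ifelse(is.na(cnt$n_genes), "NA", cnt$n_genes)))
  con <- file(file.path(outdir, "run.log"), open = "wb")
  writeLines(log_lines, con, sep = "\n")
  close(con)
  invisible(outdir)
}

# internal: deterministic TSV writer (binary connection, fixed newlines)
.write_tsv <- function(df, path, col.names = TRUE) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = col.names)
  invisible(path)
}
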