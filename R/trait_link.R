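#' Enumerate unphased haplotypes in a region
#'
#' The "haplotype" of a sample is its genotype-dosage string across the
#' variants of the region (unphased multilocus genotype; heterozygous sites
#' are kept as `1`, missing calls as `.`). Samples whose missing fraction in
#' the region exceeds `max_missing` are excluded. Distinct strings are
#' counted overall and per group.
#'
#' @param gm a [genotype_matrix()].
#' @param chrom,start,end region in 0-based half-open coordinates.
#' @param popmap optional [population_map()] for per-group counts.
#' @param max_missing maximum tolerated per-sample missing fraction.
#' @return list of class `haplotype_table`: `haplotypes` (named character
#'   vector per included sample), `table` (haplotype, count, freq),
#'   `per_group` (data.frame group, haplotype, count; NULL without a map),
#'   `n_variants`, `excluded` (sample ids dropped for missingness).
#' @export
enumerate_haplotypes <- function(gm, chrom, start, end, popmap = NULL,
                                 max_missing = 0.5) {
  stopifnot(inherits(gm, "genotype_matrix"))
  idx <- which(gm$chrom == chrom & (gm$pos - 1L) >= start &
                 (gm$pos - 1L) < end)
  if (!length(idx)) stopf("region %s:%d-%d contains no variants",
                          chrom, start, end)
  sub <- gm$geno[idx, , drop = FALSE]
  miss_frac <- colMeans(is.na(sub))
  excluded <- gm$samples[miss_frac > max_missing]
  keep <- setdiff(gm$samples, excluded)
  if (!length(keep)) stopf("all samples exceed max_missing = %g", max_missing)
  chr_sub <- sub[, keep, drop = FALSE]
  chr_sub[is.na(chr_sub)] <- "."
  haps <- apply(chr_sub, 2L, paste, collapse = "")
  tab <- sort(table(haps), decreasing = TRUE)
  table_df <- data.frame(haplotype = names(tab), count = as.integer(tab),
                         freq = as.numeric(tab) / length(haps),
                         stringsAsFactors = FALSE)
  per_group <- NULL
  if (!is.null(popmap)) {
    grp <- unclass(popmap)[keep]
    per_group <- as.data.frame(table(group = grp, haplotype = haps),
                               stringsAsFactors = FALSE)
    per_group <- per_group[per_group$Freq > 0, ]
    names(per_group)[3] <- "count"
    rownames(per_group) <- NULL
  }
  structure(list(haplotypes = haps, table = table_df, per_group = per_group,
                 n_variants = length(idx), excluded = excluded),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("haplotype_table: %d distinct haplotype(s) over %d variant(s), %d sample(s) (%d excluded)\n",
              nrow(x$table), x$n_variants, length(x$haplotypes),
              length(x$excluded)))
  print(utils::head(x$table, 10), row.names = FALSE)
  invisible(x)
}

#' Assign allele classes at a designated variant
#'
#' Dosage 0 is wild-type, 1 heterozygous, 2 mutant (e.g. homozygous for an
#' exonic deletion), missing is unknown.
#'
#' @param gm a [genotype_matrix()].
#' @param chrom,pos 1-based position of the designated variant.
#' @return Named factor over samples with levels `wild-type`, `heterozygous`,
#'   `mutant`, `unknown`.
#' @export
assign_allele_classes <- function(gm, chrom, pos) {
  i <- which(gm$chrom == chrom & gm$pos == pos)
  if (length(i) != 1L)
    stopf("designated variant %s:%d not found (or not unique)", chrom, pos)
  lev <- c("wild-type", "heterozygous", "mutant", "unknown")
  d <- gm$geno[i, ]
  cls <- lev[ifelse(is.na(d), 4L, d + 1L)]
  setNames(factor(cls, levels = lev), gm$samples)
}

#' Phenotype comparison between allele classes
#'
#' Pairwise two-sample location test of each non-wild-type class against the
#' wild-type class (Welch's t, unequal variances; two-sided by default, with
#' a one-sided option for directional hypotheses such as later bolting in
#' carriers). Classes with fewer than `min_n` phenotyped samples are skipped
#' with a warning. Raw p-values are reported alongside a Bonferroni column.
#'
#' @param classes named factor/character of allele classes per sample (see
#'   [assign_allele_classes()]).
#' @param phenotype named numeric vector of trait values per sample.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`
#'   (class mean relative to wild-type).
#' @param min_n minimum phenotyped samples per class (default 3).
#' @return data.frame: `class`, `n`, `n_wt`, `mean_diff`, `t`, `df`, `p`,
#'   `p_bonferroni`.
#' @export
class_phenotype_test <- function(classes, phenotype,
                                 alternative = c("two.sided", "greater",
                                                 "less"),
                                 min_n = 3) {
  alternative <- match.arg(alternative)
  common <- intersect(names(classes), names(phenotype))
  cls <- as.character(classes[common])
  phe <- phenotype[common]
  ok <- !is.na(phe) & cls != "unknown"
  cls <- cls[ok]; phe <- phe[ok]
  wt <- phe[cls == "wild-type"]
  if (length(wt) < min_n)
    stopf("wild-type class has %d phenotyped sample(s); need >= %d",
          length(wt), min_n)
  others <- setdiff(unique(cls), "wild-type")
  if (!length(others)) stopf("need at least two allele classes to compare")
  rows <- list()
  for (g in others) {
    x <- phe[cls == g]
    if (length(x) < min_n) {
      warnf("class '%s' has %d phenotyped sample(s); pair skipped", g,
            length(x))
      next
    }
    tt <- t.test(x, wt, alternative = alternative, var.equal = FALSE)
    rows[[g]] <- data.frame(class = g, n = length(x), n_wt = length(wt),
                            mean_diff = mean(x) - mean(wt),
                            t = unname(tt$statistic),
                            df = unname(tt$parameter), p = tt$p.value,
                            stringsAsFactors = FALSE)
  }
  if (!length(rows)) stopf("no class pair satisfied the size requirement")
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$p_bonferroni <- pmin(out$p * nrow(out), 1)
  out
}

#' Expression-phenotype correlation
#'
#' Pearson (default) or Spearman correlation between one gene's expression
#' and a phenotype, paired by sample id intersection after removing missing
#' values. At least 4 complete pairs are required.
#'
#' @param expression named numeric vector of expression values per sample.
#' @param phenotype named numeric vector of trait values per sample.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return list: `estimate` (coefficient), `p` (two-sided), `n` (pairs used),
#'   `method`.
#' @export
expression_phenotype_correlation <- function(expression, phenotype,
                                             method = c("pearson",
                                                        "spearman")) {
  method <- match.arg(method)
  common <- intersect(names(expression), names(phenotype))
  x <- expression[common]; y <- phenotype[common]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4)
    stopf("need >= 4 paired observations (have %d)", length(x))
  ct <- suppressWarnings(cor.test(x, y, method = method))
  list(estimate = unname(ct$estimate), p = ct$p.value, n = length(x),
       method = method)
}

#' Read an association-locus table
#'
#' Loci are consumed from a table (chrom, pos, p, trait) rather than
#' recomputed; positions are 1-based in the file and converted to the
#' internal 0-based convention on import.
#'
#' @param path TSV with columns chrom, pos, p, trait (header required).
#' @return data.frame with `chrom`, `pos` (0-based), `p_value`, `trait`.
#' @export
read_loci_table <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  need <- c("chrom", "pos", "p", "trait")
  if (!all(need %in% names(tab)))
    stopf("loci table must have columns: %s", paste(need, collapse = ", "))
  if (any(tab$p <= 0 | tab$p > 1)) stopf("p-values must lie in (0, 1]")
  data.frame(chrom = as.character(tab$chrom), pos = as.numeric(tab$pos) - 1,
             p_value = tab$p, trait = as.character(tab$trait),
             stringsAsFactors = FALSE)
}

#' Overlap association loci with sweep intervals
#'
#' A locus overlaps a sweep iff its (0-based) position lies in
#' `[start, end)`; a locus exactly at a sweep's end coordinate is outside.
#'
#' @param loci data.frame with `chrom` and `pos` (0-based; see
#'   [read_loci_table()]).
#' @param sweeps merged sweep interval table.
#' @return `loci` with columns `in_sweep` (logical), `sweep_start`,
#'   `sweep_end` (NA when unassigned).
#' @export
locus_sweep_overlap <- function(loci, sweeps) {
  loci$in_sweep <- FALSE
  loci$sweep_start <- NA_real_
  loci$sweep_end <- NA_real_
  for (i in seq_len(nrow(loci))) {
    hit <- which(sweeps$chrom == loci$chrom[i] &
                   sweeps$start <= loci$pos[i] & loci$pos[i] < sweeps$end)
    if (length(hit)) {
      loci$in_sweep[i] <- TRUE
      loci$sweep_start[i] <- sweeps$start[hit[1]]
      loci$sweep_end[i] <- sweeps$end[hit[1]]
    }
  }
  loci
}
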