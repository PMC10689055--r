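#' Biallelic SNP genotype matrix
#'
#' Container for unphased biallelic SNP genotypes across a panel of samples.
#' Genotypes are stored as alt-allele dosages: 0 (homozygous reference),
#' 1 (heterozygous), 2 (homozygous alternate), or `NA` for a missing call.
#' Variant positions are 1-based (as in VCF) and must be strictly increasing
#' within each chromosome; chromosomes must form contiguous blocks.
#'
#' @param chrom character vector, chromosome id per variant.
#' @param pos integer vector, 1-based position per variant.
#' @param ref,alt single-base reference and alternate alleles per variant.
#' @param samples ordered sample ids.
#' @param geno integer matrix (variants x samples) of alt-allele dosages in
#'   \{0, 1, 2, NA\}.
#' @param chrom_lengths optional named vector of chromosome lengths in bp;
#'   defaults to the largest observed position per chromosome.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(chrom, pos, ref, alt, samples, geno,
                            chrom_lengths = NULL) {
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  n <- length(chrom)
  if (length(pos) != n || length(ref) != n || length(alt) != n)
    stopf("chrom/pos/ref/alt must have equal length")
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != n || ncol(geno) != length(samples))
    stopf("geno must be a %d x %d matrix", n, length(samples))
  bad <- !(geno %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stopf("genotype dosages must be 0, 1, 2 or NA")
  ok_base <- function(x) nchar(x) == 1L & x %in% c("A", "C", "G", "T")
  if (n > 0 && (!all(ok_base(ref)) || !all(ok_base(alt))))
    stopf("ref/alt must be single bases (biallelic SNPs only)")
  # chromosomes must be contiguous runs with strictly increasing positions
  runs <- rle(chrom)
  if (anyDuplicated(runs$values))
    stopf("variants of one chromosome must be contiguous")
  for (i in seq_along(runs$values)) {
    idx <- seq.int(sum(head(runs$lengths, i - 1L)) + 1L,
                   length.out = runs$lengths[i])
    p <- pos[idx]
    if (length(p) > 1L && any(diff(p) <= 0L))
      stopf("positions not strictly increasing on chromosome '%s'",
            runs$values[i])
  }
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(split(pos, factor(chrom, levels = runs$values)),
                            function(p) as.numeric(max(p)), numeric(1))
  }
  dimnames(geno) <- list(NULL, samples)
  structure(list(chrom = chrom, pos = pos,
                 ref = as.character(ref), alt = as.character(alt),
                 samples = as.character(samples), geno = geno,
                 chrom_lengths = chrom_lengths),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d biallelic SNPs x %d samples on %d chromosome(s)\n",
              length(x$pos), length(x$samples), length(unique(x$chrom))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Subset a genotype matrix by variant index and/or samples
#'
#' @param gm a [genotype_matrix()].
#' @param variants integer or logical index over variants.
#' @param samples character vector of sample ids to keep.
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(gm, variants = NULL, samples = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  vi <- if (is.null(variants)) seq_along(gm$pos) else seq_along(gm$pos)[variants]
  si <- gm$samples
  if (!is.null(samples)) {
    missing <- setdiff(samples, gm$samples)
    if (length(missing))
      stopf("sample(s) not present: %s", paste(missing, collapse = ", "))
    si <- samples
  }
  genotype_matrix(gm$chrom[vi], gm$pos[vi], gm$ref[vi], gm$alt[vi],
                  si, gm$geno[vi, si, drop = FALSE],
                  chrom_lengths = gm$chrom_lengths)
}

#' Read biallelic SNPs from a VCF file
#'
#' Parses a VCF 4.x file (plain or bgzipped) via \pkg{vcfR} and retains only
#' biallelic SNP records (single-base REF and ALT). GT fields are mapped to
#' alt-allele dosage; missing calls (`./.` or `.`) become `NA`. Record order
#' is preserved and positions are required to be strictly increasing within
#' each chromosome. `##contig` header lines with a `length` attribute are
#' carried over as chromosome lengths.
#'
#' @param path path to a VCF file.
#' @param keep_samples optional character vector of sample ids to retain
#'   (in the given order); an absent sample is an error.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, keep_samples = NULL) {
  if (!file.exists(path)) stopf("VCF not found: %s", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stopf("malformed VCF '%s': %s",
                                          path, conditionMessage(e)))
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0L) stopf("VCF '%s' contains no records", path)
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  bases <- c("A", "C", "G", "T")
  keep <- !is.na(ref) & !is.na(alt) & ref %in% bases & alt %in% bases
  if (!any(keep)) stopf("no biallelic SNP records in '%s'", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  samples <- colnames(gt)
  if (!is.null(keep_samples)) {
    absent <- setdiff(keep_samples, samples)
    if (length(absent))
      stopf("requested sample(s) absent from VCF: %s",
            paste(absent, collapse = ", "))
    gt <- gt[, keep_samples, drop = FALSE]
    samples <- keep_samples
  }
  # dosage = number of '1' alleles; tolerate phased separators
  dose <- matrix(NA_integer_, nrow(gt), ncol(gt))
  clean <- gsub("\\|", "/", gt)
  dose[clean %in% c("0/0", "0")] <- 0L
  dose[clean %in% c("0/1", "1/0")] <- 1L
  dose[clean %in% c("1/1", "1")] <- 2L
  unseen <- !is.na(clean) & !(clean %in% c("0/0", "0/1", "1/0", "1/1", "0", "1",
                                           "./.", "."))
  if (any(unseen))
    stopf("unparseable GT value(s) in '%s' (first: %s)",
          path, clean[unseen][1])
  lens <- .contig_lengths(v@meta)
  genotype_matrix(fix[keep, "CHROM"], as.integer(fix[keep, "POS"]),
                  ref[keep], alt[keep], samples, dose,
                  chrom_lengths = if (length(lens)) lens else NULL)
}

.contig_lengths <- function(meta) {
  m <- regmatches(meta,
                  regexec("^##contig=<ID=([^,>]+),length=([0-9]+)", meta))
  m <- m[vapply(m, length, integer(1)) == 3L]
  setNames(vapply(m, function(x) as.numeric(x[3]), numeric(1)),
           vapply(m, `[`, character(1), 2L))
}

#' Write a genotype matrix as VCF 4.2
#'
#' Emits a minimal plain-text VCF with GT-only genotype fields and
#' `##contig` lines carrying chromosome lengths, so that
#' `read_vcf(write_vcf(gm))` round-trips chrom/pos/ref/alt/dosage exactly.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  gt_str <- matrix("./.", nrow(gm$geno), ncol(gm$geno))
  gt_str[gm$geno == 0L] <- "0/0"
  gt_str[gm$geno == 1L] <- "0/1"
  gt_str[gm$geno == 2L] <- "1/1"
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=popsweep",
    sprintf("##contig=<ID=%s,length=%d>", names(gm$chrom_lengths),
            as.integer(gm$chrom_lengths)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t"))
  body <- paste(gm$chrom, gm$pos, ".", gm$ref, gm$alt, ".", "PASS", ".", "GT",
                apply(gt_str, 1L, paste, collapse = "\t"), sep = "\t")
  con <- file(path, open = "wb")  # fixed newline convention for determinism
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}

#' Read a sample-to-group population map
#'
#' Two-column delimited text (sample id, group label); a `sample group`
#' header row is skipped if present. A sample listed twice is an error.
#'
#' @param path path to the map file.
#' @return A `population_map`: named character vector mapping sample id to
#'   group label, with a `groups` attribute.
#' @export
read_population_map <- function(path) {
  tab <- read.table(path, header = FALSE, sep = "", stringsAsFactors = FALSE,
                    col.names = c("sample", "group"),
                    colClasses = "character")
  if (nrow(tab) && tolower(tab$sample[1]) %in% c("sample", "sample_id") &&
      tolower(tab$group[1]) %in% c("group", "pop", "population"))
    tab <- tab[-1L, , drop = FALSE]
  if (!nrow(tab)) stopf("empty population map: %s", path)
  population_map(setNames(tab$group, tab$sample))
}

#' Construct a population map from a named vector
#'
#' @param assignment named character vector: names are sample ids, values are
#'   group labels.
#' @return A `population_map`.
#' @export
population_map <- function(assignment) {
  if (is.null(names(assignment)) || any(names(assignment) == ""))
    stopf("assignment must be a named vector (sample -> group)")
  dup <- unique(names(assignment)[duplicated(names(assignment))])
  if (length(dup))
    stopf("sample(s) listed more than once in population map: %s",
          paste(dup, collapse = ", "))
  assignment <- vapply(assignment, as.character, character(1))
  structure(assignment, groups = sort(unique(unname(assignment))),
            class = "population_map")
}

#' @export
print.population_map <- function(x, ...) {
  tab <- table(unname(unclass(x)))
  cat(sprintf("population_map: %d samples in %d group(s)\n", length(x),
              length(tab)))
  for (g in names(tab)) cat(sprintf("  %s: %d\n", g, tab[[g]]))
  invisible(x)
}

#' Samples belonging to one group
#'
#' @param popmap a [population_map()].
#' @param group group label.
#' @param min_n minimum group size required (default 2, the smallest size any
#'   diversity statistic accepts).
#' @return Character vector of sample ids.
#' @export
group_samples <- function(popmap, group, min_n = 2L) {
  stopifnot(inherits(popmap, "population_map"))
  s <- names(popmap)[unclass(popmap) == group]
  if (!length(s)) stopf("group '%s' absent from population map", group)
  if (length(s) < min_n)
    stopf("group '%s' has %d sample(s); at least %d required",
          group, length(s), min_n)
  s
}

#' Pool several groups into one label
#'
#' Used to build the third population for PBS when it is configured as the
#' pooled complement of the focal/baseline pair.
#'
#' @param popmap a [population_map()].
#' @param labels group labels to pool.
#' @param new_label label for the pooled group.
#' @return A `population_map` with `labels` replaced by `new_label`.
#' @export
pool_groups <- function(popmap, labels, new_label = "POOLED") {
  stopifnot(inherits(popmap, "population_map"))
  a <- unclass(popmap)
  attr(a, "groups") <- NULL
  hit <- a %in% labels
  if (!any(hit)) stopf("no samples in groups: %s", paste(labels, collapse = ", "))
  a[hit] <- new_label
  population_map(a)
}
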