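# shared fixture builders: everything is generated in code, nothing on disk

# small genotype matrix straight from a dosage matrix
tiny_gm <- function(geno, chrom = "chr1", pos = seq_len(nrow(geno)) * 100L,
                    samples = sprintf("s%02d", seq_len(ncol(geno))),
                    chrom_lengths = NULL) {
  n <- nrow(geno)
  genotype_matrix(rep(chrom, length.out = n), pos,
                  rep("A", n), rep("G", n), samples, geno,
                  chrom_lengths = chrom_lengths)
}

write_lines_raw <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  path
}

# hand-written VCF fixture: 3 records, one multiallelic, one missing call
fixture_vcf <- function(path = tempfile(fileext = ".vcf"),
                        positions = c(100L, 200L, 300L)) {
  write_lines_raw(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=10000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsA\tsB\tsC",
    sprintf("chr1\t%d\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1", positions[1]),
    sprintf("chr1\t%d\t.\tA\tC,T\t.\tPASS\t.\tGT\t0/0\t0/1\t0/2", positions[2]),
    sprintf("chr1\t%d\t.\tT\tC\t.\tPASS\t.\tGT\t./.\t0/0\t1/1", positions[3])),
    path)
}

# exhaustive per-site diversity: count differing chromosome pairs directly
site_pi_brute <- function(c_alt, n_called) {
  alleles <- c(rep(1L, c_alt), rep(0L, n_called - c_alt))
  pairs <- utils::combn(n_called, 2)
  mean(alleles[pairs[1, ]] != alleles[pairs[2, ]])
}

# independently coded Weir & Cockerham (1984) two-population estimator,
# scalar form following the published equations term by term
wc_oracle <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  n_bar <- (n1 + n2) / r
  n_c <- (r * n_bar - (n1^2 + n2^2) / (r * n_bar)) / (r - 1)
  p_bar <- (n1 * p1 + n2 * p2) / (r * n_bar)
  s_sq <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (n1 * h1 + n2 * h2) / (r * n_bar)
  a <- (n_bar / n_c) *
    (s_sq - (1 / (n_bar - 1)) *
       (p_bar * (1 - p_bar) - ((r - 1) / r) * s_sq - h_bar / 4))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - ((r - 1) / r) * s_sq -
       ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
  cc <- h_bar / 2
  list(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

# balanced three-dosage-class genotype matrix for trait-linking tests
class_fixture_gm <- function(n_per_class = 20L) {
  dose <- matrix(rep(c(0L, 1L, 2L), each = n_per_class), nrow = 1)
  tiny_gm(dose, pos = 500L,
          samples = sprintf("s%03d", seq_len(3L * n_per_class)))
}
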