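test_that("haplotype enumeration counts distinct genotype strings", {
  geno <- matrix(c(0L, 1L, 2L,
                   0L, 1L, 2L,
                   0L, 1L, 2L,
                   0L, 1L, 2L), nrow = 3)   # four identical columns
  gm <- tiny_gm(geno, pos = c(100L, 200L, 300L),
                samples = sprintf("s%d", 1:4), chrom_lengths = c(chr1 = 1e3))
  h <- enumerate_haplotypes(gm, "chr1", 0, 1000)
  expect_equal(nrow(h$table), 1L)
  expect_equal(h$table$count, 4L)

  distinct <- tiny_gm(matrix(c(0L, 1L, 2L, 0L, 1L,
                               0L, 0L, 0L, 1L, 2L), nrow = 2, byrow = TRUE),
                      pos = c(100L, 200L), samples = sprintf("s%d", 1:5))
  h5 <- enumerate_haplotypes(distinct, "chr1", 0, 1000)
  expect_equal(nrow(h5$table), 5L)
  expect_error(enumerate_haplotypes(distinct, "chr1", 5000, 6000),
               "no variants")
})

test_that("samples over the missing-fraction cap are excluded", {
  geno <- matrix(c(0L, NA, NA, NA, NA,
                   0L, 1L, NA, 1L, 1L), nrow = 5)
  gm <- tiny_gm(geno, pos = (1:5) * 100L, samples = c("lost", "kept"))
  h <- enumerate_haplotypes(gm, "chr1", 0, 1000, max_missing = 0.5)
  expect_equal(h$excluded, "lost")
  expect_equal(unname(h$haplotypes["kept"]), "01.11")
})

test_that("haplotype count never grows when restricting to a subgroup", {
  set.seed(19)
  geno <- matrix(sample(c(0:2, NA), 8 * 30, replace = TRUE,
                        prob = c(.35, .3, .3, .05)), 8, 30)
  gm <- tiny_gm(geno, pos = (1:8) * 50L,
                samples = sprintf("s%02d", 1:30))
  pm <- population_map(setNames(rep(c("A", "B", "C"), each = 10),
                                gm$samples))
  h <- enumerate_haplotypes(gm, "chr1", 0, 1000, popmap = pm,
                            max_missing = 1)
  total <- nrow(h$table)
  expect_lte(total, 30L)
  for (g in c("A", "B", "C")) {
    sub <- subset_genotypes(gm, samples = group_samples(pm, g))
    hs <- enumerate_haplotypes(sub, "chr1", 0, 1000, max_missing = 1)
    expect_lte(nrow(hs$table), total)
  }
  # order invariance
  rev_gm <- subset_genotypes(gm, samples = rev(gm$samples))
  expect_equal(nrow(enumerate_haplotypes(rev_gm, "chr1", 0, 1000,
                                         max_missing = 1)$table), total)
})

test_that("allele classes map dosages to WT/het/mutant/unknown", {
  gm <- tiny_gm(matrix(c(0L, 1L, 2L, NA), nrow = 1), pos = 500L,
                samples = sprintf("s%d", 1:4))
  cls <- assign_allele_classes(gm, "chr1", 500)
  expect_equal(as.character(cls),
               c("wild-type", "heterozygous", "mutant", "unknown"))
  expect_error(assign_allele_classes(gm, "chr1", 999), "not found")
})

test_that("class test equals the closed-form Welch t on balanced data", {
  gm <- class_fixture_gm(10)
  cls <- assign_allele_classes(gm, "chr1", 500)
  set.seed(4)
  phe <- setNames(rnorm(30, 100, 5), gm$samples)
  phe[cls == "mutant"] <- phe[cls == "mutant"] + 8
  res <- class_phenotype_test(cls, phe)
  mut <- res[res$class == "mutant", ]
  x <- phe[cls == "mutant"]; y <- phe[cls == "wild-type"]
  se <- sqrt(var(x) / 10 + var(y) / 10)
  t_manual <- (mean(x) - mean(y)) / se
  df_manual <- se^4 / ((var(x) / 10)^2 / 9 + (var(y) / 10)^2 / 9)
  p_manual <- 2 * pt(abs(t_manual), df_manual, lower.tail = FALSE)
  expect_equal(mut$t, t_manual, tolerance = 1e-12)
  expect_equal(mut$df, df_manual, tolerance = 1e-12)
  expect_equal(mut$p, p_manual, tolerance = 1e-12)
  expect_equal(mut$mean_diff, mean(x) - mean(y), tolerance = 1e-12)
})

test_that("large separation detects, tiny classes are skipped", {
  gm <- class_fixture_gm(10)
  cls <- assign_allele_classes(gm, "chr1", 500)
  set.seed(6)
  phe <- setNames(rnorm(30, 100, 0.5), gm$samples)
  phe[cls != "wild-type"] <- phe[cls != "wild-type"] + 10
  res <- class_phenotype_test(cls, phe)
  expect_true(all(res$p < 0.001))

  small <- cls
  phe2 <- phe
  phe2[which(cls == "heterozygous")[-(1:2)]] <- NA   # het class shrinks to 2
  expect_warning(res2 <- class_phenotype_test(small, phe2), "skipped")
  expect_false("heterozygous" %in% res2$class)
})

test_that("correlation: exact limits, symmetry, scaling invariance", {
  x <- setNames(1:10, sprintf("s%d", 1:10))
  expect_equal(expression_phenotype_correlation(x, 2 * x)$estimate, 1)
  set.seed(2)
  y <- setNames(-(1:10) + rnorm(10, 0, 1e-8), names(x))
  expect_equal(expression_phenotype_correlation(x, y)$estimate, -1,
               tolerance = 1e-6)
  set.seed(12)
  a <- setNames(rnorm(20), sprintf("s%d", 1:20))
  b <- setNames(rnorm(20), sprintf("s%d", 1:20))
  expect_equal(expression_phenotype_correlation(a, b)$estimate,
               expression_phenotype_correlation(b, a)$estimate)
  expect_equal(expression_phenotype_correlation(a * 1000, b)$estimate,
               expression_phenotype_correlation(a, b)$estimate)
  expect_error(expression_phenotype_correlation(a[1:3], b[1:3]), ">= 4")
})

test_that("association loci land inside sweeps by the half-open rule", {
  sweeps <- data.frame(chrom = "chr5", start = 381600000, end = 382700000)
  loci <- data.frame(chrom = c("chr5", "chr5", "chr1"),
                     pos = c(381700000, 382700000, 500),
                     p_value = c(1e-9, 1e-9, 1e-8),
                     trait = "bolting")
  out <- locus_sweep_overlap(loci, sweeps)
  expect_equal(out$in_sweep, c(TRUE, FALSE, FALSE))  # end coordinate outside
  none <- locus_sweep_overlap(loci, sweeps[0, ])
  expect_false(any(none$in_sweep))
})

test_that("loci table import validates p-values and shifts coordinates", {
  path <- write_lines_raw(c("chrom\tpos\tp\ttrait",
                            "chr5\t381700001\t1e-9\tbolting"), tempfile())
  loci <- read_loci_table(path)
  expect_equal(loci$pos, 381700000)
  bad <- write_lines_raw(c("chrom\tpos\tp\ttrait",
                           "chr5\t100\t0\tbolting"), tempfile())
  expect_error(read_loci_table(bad), "p-values")
})
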