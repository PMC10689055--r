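test_that("top-fraction threshold: counts, ties, infinite sentinels", {
  th <- threshold_top_fraction(1:100, 0.05)
  expect_equal(th$threshold, 96)
  expect_equal(which(th$flags), 96:100)

  expect_warning(all_eq <- threshold_top_fraction(rep(7, 40), 0.05),
                 "degenerate")
  expect_true(all(all_eq$flags))

  vals <- c(Inf, 1:17, Inf, 18)          # 20 rankable values, m = 1
  th_inf <- threshold_top_fraction(vals, 0.05)
  expect_equal(which(th_inf$flags), 1L)  # first infinity by position only
  expect_equal(th_inf$n_flagged, 1L)

  # NaN (undefined ratio) excluded from ranking and from N
  vals2 <- c(1:39, NaN)
  th2 <- threshold_top_fraction(vals2, 0.05)
  expect_equal(sum(th2$flags), 2L)       # ceil(0.05 * 39)
  expect_error(threshold_top_fraction(1:10, 0.05), "rankable values")
})

test_that("flagged count is never below ceil(q * N) for random inputs", {
  set.seed(23)
  for (i in 1:20) {
    v <- round(rnorm(sample(40:300, 1)), 2)   # rounding invites ties
    th <- threshold_top_fraction(v, 0.05)
    expect_gte(th$n_flagged, ceiling(0.05 * length(v)))
    expect_true(all(v[th$flags] >= th$threshold))
  }
})

test_that("evidence combination implements the 2-of-3 rule strictly", {
  fl <- list(pbs = c(TRUE, FALSE, TRUE), piratio = c(TRUE, FALSE, TRUE),
             xpclr = c(FALSE, TRUE, TRUE))
  ev <- combine_evidence(fl, 2)
  expect_equal(ev$candidate, c(TRUE, FALSE, TRUE))    # (T,T,F) in, (F,F,T) out
  expect_equal(ev$support_count, c(2L, 1L, 3L))
  expect_error(combine_evidence(list(pbs = c(TRUE, FALSE),
                                     piratio = TRUE), 2),
               "different window sets")
})

test_that("candidate windows merge book-ended, split at gaps", {
  w <- data.frame(chrom = "chr1", start = c(0, 125000, 625000),
                  end = c(500000, 625000, 1125000),
                  pbs = TRUE, piratio = c(TRUE, FALSE, TRUE), xpclr = FALSE,
                  support_count = c(2L, 1L, 2L))
  m <- merge_candidate_windows(w)
  expect_equal(nrow(m), 1L)               # [0,625k) book-ends [625k,1.125M)
  expect_equal(c(m$start, m$end), c(0, 1125000))
  expect_equal(m$support, 2L)
  expect_equal(m$methods, "pbs,piratio")

  w2 <- w[c(1, 3), ]
  w2$end[1] <- 500000; w2$start[2] <- 625000
  m2 <- merge_candidate_windows(w2)
  expect_equal(nrow(m2), 2L)
  expect_equal(sum(m2$length_bp), sum(m2$end - m2$start))
  expect_equal(nrow(merge_candidate_windows(w[0, ])), 0L)
})

test_that("gene annotation uses the 1-bp overlap rule", {
  sweeps <- merge_candidate_windows(
    data.frame(chrom = "chr1", start = 0, end = 625000, pbs = TRUE,
               piratio = TRUE, xpclr = FALSE, support_count = 2L))
  genes <- gene_models(c("inside", "straddle", "outside", "otherchrom"),
                       c("chr1", "chr1", "chr1", "chr9"),
                       c(100000, 624999, 700000, 100000),
                       c(110000, 640000, 710000, 110000))
  ann <- annotate_genes(sweeps, genes)
  expect_setequal(strsplit(ann$sweeps$genes, ",")[[1]],
                  c("inside", "straddle"))
  expect_equal(sort(ann$gene_table$gene_id), c("inside", "straddle"))
})

test_that("sweep overlap: partial, disjoint and identical sets", {
  a <- data.frame(chrom = "chr1", start = 0, end = 1e6)
  b <- data.frame(chrom = "chr1", start = 5e5, end = 1.5e6)
  expect_equal(sweep_overlap(a, b)$shared_bp, 5e5)
  expect_equal(sweep_overlap(a, data.frame(chrom = "chr1", start = 2e6,
                                           end = 3e6))$shared_bp, 0)
  expect_equal(sweep_overlap(a, a)$shared_bp, 1e6)
  genes <- gene_models(c("g1", "g2"), "chr1", c(600000, 1.8e6),
                       c(620000, 1.9e6))
  ov <- sweep_overlap(a, b, genes)
  expect_equal(ov$shared_genes, "g1")
})

test_that("full scan on a planted-sweep fixture recovers the truth region", {
  cfg <- sim_config(groups = data.frame(label = c("BG", "FOC", "OTH"),
                                        n = c(25, 25, 25),
                                        F = c(0.1, 0.1, 0.1)),
                    genome = c(chr1 = 2e7), snp_density = 0.001,
                    sweeps = data.frame(group = "FOC", chrom = "chr1",
                                        start = 5e6, end = 5.5e6,
                                        F_sweep = 0.95),
                    seed = 77)
  sim <- simulate_genotypes(cfg)
  scan <- sweep_scan(sim$gm, sim$popmap,
                     config = scan_config(focal = "FOC", baseline = "BG",
                                          third = "OTH"))
  expect_s3_class(scan, "sweep_scan")
  hit <- scan$sweeps$start < 5.5e6 & scan$sweeps$end > 5e6
  expect_true(any(hit))
  # every candidate window lies under some per-method flag
  w <- scan$windows
  any_flag <- Reduce(`|`, w[paste0("flag_", scan$config$methods)])
  expect_true(all(!w$candidate | any_flag))
  # every sweep interval contains at least one candidate window
  for (i in seq_len(nrow(scan$sweeps)))
    expect_true(any(w$candidate & w$chrom == scan$sweeps$chrom[i] &
                      w$start >= scan$sweeps$start[i] &
                      w$end <= scan$sweeps$end[i]))
  # no statistic is computed on a window another statistic skipped
  expect_true(all(w$n_snps >= scan$config$min_snps))
  expect_equal(nrow(w), length(unique(paste(w$chrom, w$start))))
})

test_that("per-sweep diversity ratios under both aggregation conventions", {
  w <- data.frame(chrom = "chr1", start = c(0, 125000), end = c(5e5, 625000),
                  pi_BG = c(6e-4, 4e-4), pi_FOC = c(2e-5, 1e-5))
  sw <- data.frame(chrom = "chr1", start = 0, end = 625000)
  expect_equal(sweep_pi_ratio(w, sw, "BG", "FOC", "mean"),
               mean(c(6e-4, 4e-4)) / mean(c(2e-5, 1e-5)))
  expect_equal(sweep_pi_ratio(w, sw, "BG", "FOC", "sum"),
               (6e-4 + 4e-4) / (2e-5 + 1e-5))
  w0 <- w; w0$pi_FOC <- 0
  expect_identical(sweep_pi_ratio(w0, sw, "BG", "FOC"), Inf)
  expect_true(is.na(sweep_pi_ratio(w, data.frame(chrom = "chr2", start = 0,
                                                 end = 1e5), "BG", "FOC")))
})

test_that("scan config validation catches impossible evidence rules", {
  expect_error(scan_config(methods = "pbs", min_methods = 2), "exceeds")
  expect_error(scan_config(top_fraction = 0), "top_fraction")
  expect_error(sweep_scan(tiny_gm(matrix(0L, 1, 2)),
                          population_map(c(s01 = "A", s02 = "A")),
                          config = scan_config(focal = "A", baseline = "A",
                                               third = "pooled")),
               "no remaining groups")
})
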