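test_that("ld_weights: full clique, no linkage, single-linkage chain", {
  g1 <- c(0, 0, 1, 1, 2, 2, 0, 1, 2, 1)
  all_linked <- rbind(g1, g1, g1)
  expect_equal(ld_weights(all_linked, 0.95), rep(1 / 3, 3))

  set.seed(3)
  unlinked <- matrix(sample(0:2, 30, replace = TRUE), 3, 10)
  r2 <- suppressWarnings(cor(t(unlinked)))^2
  expect_true(all(r2[upper.tri(r2)] < 0.95))   # premise frozen by the seed
  expect_equal(ld_weights(unlinked, 0.95), rep(1, 3))

  # chain: A-B and B-C above threshold, A-C below -> one clique of three
  set.seed(17)
  a <- as.numeric(rep(0:2, each = 10))
  repeat {
    b <- a + rnorm(30, 0, 0.16)
    c_ <- b + rnorm(30, 0, 0.16)
    r <- cor(cbind(a, b, c_))^2
    if (r["a", "b"] > 0.95 && r["b", "c_"] > 0.95 && r["a", "c_"] < 0.95)
      break
  }
  expect_equal(ld_weights(rbind(a, b, c_), 0.95), rep(1 / 3, 3))
  # weights within a clique always sum to one
  expect_equal(sum(ld_weights(all_linked, 0.95)), 1)
})

test_that("omega estimate: floor when object mirrors reference, BN recovery", {
  set.seed(21)
  half <- matrix(rbinom(1500 * 10, 2, 0.4), 1500, 10)
  gm <- tiny_gm(cbind(half, half), pos = seq_len(1500) * 10L,
                samples = sprintf("s%02d", 1:20))
  pm <- population_map(setNames(rep(c("R", "O"), each = 10),
                                sprintf("s%02d", 1:20)))
  expect_equal(estimate_omega(gm, pm, "R", "O"), 1e-6)

  cfg <- sim_config(groups = data.frame(label = c("R", "O"), n = c(30, 30),
                                        F = c(1e-4, 0.2)),
                    genome = c(chr1 = 5e6), snp_density = 0.004,
                    sweeps = NULL, seed = 31)
  sim <- simulate_genotypes(cfg)
  om <- estimate_omega(sim$gm, sim$popmap, "R", "O")
  expect_lt(abs(om - 0.2) / 0.2, 0.2)
  # second seed agrees within sampling error
  cfg2 <- sim_config(groups = cfg$groups, genome = cfg$genome,
                     snp_density = 0.004, sweeps = NULL, seed = 32)
  om2 <- estimate_omega(simulate_genotypes(cfg2)$gm, sim$popmap, "R", "O")
  expect_lt(abs(om - om2), 0.05)
  expect_error(estimate_omega(subset_genotypes(gm, variants = 1:50),
                              pm, "R", "O"), "usable SNPs")
})

test_that("site log-likelihood: mode at the mean, continuity, sweep benefit", {
  par <- xpclr_params(omega = 0.05)
  # s = 0: observed count matching p_ref maximizes the contribution
  lls <- vapply(0:20, function(k)
    xpclr_site_loglik(0.5, k, 20, 0.005, 0, par), numeric(1))
  expect_equal(which.max(lls) - 1L, 10L)
  # s -> 0+ approaches the neutral likelihood
  ll0 <- xpclr_site_loglik(0.5, 12, 20, 0.005, 0, par)
  ll_eps <- xpclr_site_loglik(0.5, 12, 20, 0.005, 1e-8, par)
  expect_equal(ll_eps, ll0, tolerance = 1e-6)
  # fixed object allele near the grid point favors a strong sweep
  ll_neutral <- xpclr_site_loglik(0.4, 20, 20, 0.001, 0, par)
  ll_sweep <- xpclr_site_loglik(0.4, 20, 20, 0.001, 0.1, par)
  expect_gt(ll_sweep, ll_neutral)
  expect_error(xpclr_site_loglik(NaN, 1, 10, 0, 0, par), "non-finite")
})

test_that("scan: degenerate s-grid gives zero everywhere, clr never negative", {
  cfg <- sim_config(groups = data.frame(label = c("R", "O"), n = c(15, 15),
                                        F = c(0.1, 0.2)),
                    genome = c(chr1 = 2e6), snp_density = 0.002,
                    sweeps = NULL, seed = 8)
  sim <- simulate_genotypes(cfg)
  null_only <- xpclr_scan(sim$gm, sim$popmap, "R", "O",
                          xpclr_params(s_grid = 0, omega = 0.1))
  expect_true(all(null_only$clr[!is.na(null_only$clr)] == 0))
  full <- xpclr_scan(sim$gm, sim$popmap, "R", "O", xpclr_params(omega = 0.1))
  expect_true(all(full$clr >= -1e-9, na.rm = TRUE))
  expect_true(all(full$s_hat %in% xpclr_params()$s_grid |
                    is.na(full$s_hat)))
  expect_true(all(full$n_snps_used <= xpclr_params()$max_snps))
})

test_that("scan score is invariant to sample order and allele relabeling", {
  cfg <- sim_config(groups = data.frame(label = c("R", "O"), n = c(12, 12),
                                        F = c(0.1, 0.25)),
                    genome = c(chr1 = 1e6), snp_density = 0.002,
                    sweeps = NULL, seed = 13, missing_rate = 0)
  sim <- simulate_genotypes(cfg)
  par <- xpclr_params(omega = 0.15)
  base <- xpclr_scan(sim$gm, sim$popmap, "R", "O", par)
  shuf <- subset_genotypes(sim$gm, samples = rev(sim$gm$samples))
  expect_equal(xpclr_scan(shuf, sim$popmap, "R", "O", par)$clr, base$clr,
               tolerance = 1e-9)
  flip <- sim$gm
  flip$geno <- 2L - flip$geno
  expect_equal(xpclr_scan(flip, sim$popmap, "R", "O", par)$clr, base$clr,
               tolerance = 1e-6)
})

test_that("window mapping takes the maximum contained grid-point score", {
  scores <- data.frame(chrom = "chr1", pos = c(50000, 100000, 150000, 600000),
                       clr = c(1, 5, 2, 9), s_hat = 0.01, n_snps_used = 10L)
  grid <- make_windows(c(chr1 = 1.5e6), 500000, 125000)
  mapped <- xpclr_window_max(scores, grid)
  expect_equal(mapped[1], 5)          # window [0, 500k) holds points 1-3
  expect_equal(mapped[2], 9)          # [125k, 625k) includes pos 600000
  expect_true(is.na(mapped[nrow(grid)]))
})
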