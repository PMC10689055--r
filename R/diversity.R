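#' Per-group allele counts at every site
#'
#' For each group, counts over called chromosomes at each variant: alt-allele
#' count, number of called chromosomes, and number of heterozygous
#' individuals. These are the sufficient inputs for per-site diversity and
#' the Weir-Cockerham variance components.
#'
#' @param gm a [genotype_matrix()].
#' @param popmap a [population_map()].
#' @param groups group labels to tabulate (default: all groups in the map).
#' @return Named list; per group a list with numeric vectors `c_alt`,
#'   `n_called`, `n_het` (one entry per variant).
#' @export
group_site_counts <- function(gm, popmap, groups = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(groups)) groups <- attr(popmap, "groups")
  out <- lapply(groups, function(g) {
    ids <- group_samples(popmap, g)
    absent <- setdiff(ids, gm$samples)
    if (length(absent))
      stopf("group '%s': sample(s) absent from genotype matrix: %s",
            g, paste(absent, collapse = ", "))
    sub <- gm$geno[, ids, drop = FALSE]
    list(c_alt = rowSums(sub, na.rm = TRUE),
         n_called = 2 * rowSums(!is.na(sub)),
         n_het = rowSums(sub == 1L, na.rm = TRUE))
  })
  names(out) <- groups
  out
}

#' Per-site nucleotide diversity
#'
#' Mean pairwise difference among called chromosomes at one site:
#' `2 * c * (n - c) / (n * (n - 1))` for alt count `c` of `n` called
#' chromosomes. Sites with fewer than two called chromosomes yield `NA`
#' (skipped, not fatal).
#'
#' @param c_alt alt-allele count(s) over called chromosomes.
#' @param n_called number(s) of called chromosomes.
#' @return Numeric vector of per-site diversity values.
#' @export
#' @examples
#' site_pi(3, 10)  # 21 differing pairs of C(10,2) = 45 -> 0.4667
site_pi <- function(c_alt, n_called) {
  if (any(c_alt < 0 | c_alt > n_called, na.rm = TRUE))
    stopf("c_alt must lie in [0, n_called]")
  out <- 2 * c_alt * (n_called - c_alt) / (n_called * (n_called - 1))
  out[n_called < 2] <- NA_real_
  out
}

#' Windowed nucleotide diversity per group
#'
#' Theta-pi per window and group: the sum of per-site diversity over variants
#' in the window divided by the full window length in bp. Windows containing
#' fewer than `min_snps` SNPs segregating in the full cohort are dropped;
#' that retained-window set is shared by every downstream statistic.
#'
#' @param gm a [genotype_matrix()].
#' @param grid a [make_windows()] grid.
#' @param popmap a [population_map()].
#' @param min_snps minimum segregating SNPs per retained window (default 5).
#' @param groups groups to compute (default all).
#' @return data.frame: `chrom`, `start`, `end`, `n_snps`, then one `pi_<group>`
#'   column per group (per-bp diversity).
#' @export
window_pi <- function(gm, grid, popmap, min_snps = 5, groups = NULL) {
  stopifnot(inherits(grid, "window_grid"))
  if (is.null(groups)) groups <- attr(popmap, "groups")
  counts <- group_site_counts(gm, popmap, groups)
  ranges <- .window_site_ranges(gm, grid)
  size_bp <- attr(grid, "size_bp")
  persite <- vapply(counts, function(ct) site_pi(ct$c_alt, ct$n_called),
                    numeric(length(gm$pos)))
  persite <- matrix(persite, ncol = length(groups))
  pi_w <- .window_sums(persite, ranges) / size_bp
  seg <- .segregating_sites(gm)
  n_snps <- as.integer(.window_sums(seg, ranges))
  out <- data.frame(chrom = grid$chrom, start = grid$start, end = grid$end,
                    n_snps = n_snps, stringsAsFactors = FALSE)
  for (j in seq_along(groups)) out[[paste0("pi_", groups[j])]] <- pi_w[, j]
  out <- out[out$n_snps >= min_snps, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# internal: indicator of sites segregating across the full sample set
.segregating_sites <- function(gm) {
  c_all <- rowSums(gm$geno, na.rm = TRUE)
  n_all <- 2 * rowSums(!is.na(gm$geno))
  as.numeric(c_all > 0 & c_all < n_all)
}

#' Weir-Cockerham per-site variance components (two populations)
#'
#' Implements the Weir & Cockerham (1984) estimator for two populations:
#' returns the between-population component `a` and the combined
#' within-population components `bc = b + c` per site, computed from sample
#' sizes (in individuals), allele frequencies, and observed heterozygosity.
#' The per-site estimate is `a / (a + bc)`; windowed estimates use the
#' ratio-of-sums (see [window_fst()]). Sites where either group has fewer
#' than two called chromosomes yield `NA` components.
#'
#' @param counts1,counts2 per-group site counts as produced by
#'   [group_site_counts()] (lists with `c_alt`, `n_called`, `n_het`).
#' @return list with numeric vectors `a` and `bc`.
#' @export
wc_fst_site <- function(counts1, counts2) {
  n1 <- counts1$n_called / 2; n2 <- counts2$n_called / 2
  ok <- counts1$n_called >= 2 & counts2$n_called >= 2
  p1 <- counts1$c_alt / counts1$n_called
  p2 <- counts2$c_alt / counts2$n_called
  h1 <- ifelse(n1 > 0, counts1$n_het / n1, 0)
  h2 <- ifelse(n2 > 0, counts2$n_het / n2, 0)
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  bad <- !ok | nbar <= 1 | !is.finite(a)
  a[bad] <- NA_real_
  bc <- b + cc
  bc[bad] <- NA_real_
  list(a = a, bc = bc)
}

#' Windowed Weir-Cockerham FST (ratio of sums)
#'
#' Sums the per-site variance components over each window and returns
#' `sum(a) / sum(a + bc)`. Negative windowed estimates are floored at 0 so
#' the downstream branch-length transform stays defined; windows with no
#' informative site (or a zero denominator) are `NA`.
#'
#' @param gm a [genotype_matrix()].
#' @param grid a [make_windows()] grid.
#' @param popmap a [population_map()].
#' @param group1,group2 the two group labels.
#' @return Numeric vector of windowed FST, aligned with `grid` rows.
#' @export
window_fst <- function(gm, grid, popmap, group1, group2) {
  counts <- group_site_counts(gm, popmap, c(group1, group2))
  comp <- wc_fst_site(counts[[1]], counts[[2]])
  ranges <- .window_site_ranges(gm, grid)
  sums <- .window_sums(cbind(comp$a, comp$a + comp$bc,
                             as.numeric(!is.na(comp$a))), ranges)
  fst <- ifelse(sums[, 3] > 0 & sums[, 2] != 0, sums[, 1] / sums[, 2], NA_real_)
  fst[sums[, 3] > 0 & sums[, 2] == 0] <- NA_real_  # uninformative window pair
  pmax(fst, 0)
}

#' Population branch statistic
#'
#' `PBS_A = (T_AB + T_AC - T_BC) / 2` with `T = -log(1 - FST)`. Inputs are
#' clamped to `[0, 1 - eps]` so all branch lengths are finite; values outside
#' `[0, 1]` beyond `tol` are an error. Vectorized over windows.
#'
#' @param fst_ab,fst_ac,fst_bc pairwise FST of the focal group A with B and C,
#'   and between B and C.
#' @param eps cap so that `FST <= 1 - eps` before the log transform.
#' @param tol tolerance for out-of-range inputs before clamping.
#' @return PBS of the focal group A.
#' @export
#' @examples
#' pbs(0.5, 0.5, 0.2)  # 0.581575
pbs <- function(fst_ab, fst_ac, fst_bc, eps = 1e-6, tol = 1e-8) {
  check <- function(x, nm) {
    if (any(x < -tol | x > 1 + tol, na.rm = TRUE))
      stopf("%s outside [0, 1] beyond tolerance", nm)
    pmin(pmax(x, 0), 1 - eps)
  }
  t_ab <- -log(1 - check(fst_ab, "fst_ab"))
  t_ac <- -log(1 - check(fst_ac, "fst_ac"))
  t_bc <- -log(1 - check(fst_bc, "fst_bc"))
  (t_ab + t_ac - t_bc) / 2
}

#' Log2 diversity-ratio statistic
#'
#' `log2(pi_a / pi_b)`; a large positive value indicates diversity loss in
#' population B relative to A (a putative sweep in B when A is the baseline).
#' `pi_b = 0` with `pi_a > 0` returns `Inf` (still rankable, sorts above all
#' finite values); both zero returns `NaN` (excluded from ranking).
#'
#' @param pi_a,pi_b non-negative per-window diversities (vectorized).
#' @return Numeric vector of log2 ratios with `Inf`/`NaN` sentinels.
#' @export
pi_ratio <- function(pi_a, pi_b) {
  if (any(pi_a < 0 | pi_b < 0, na.rm = TRUE))
    stopf("diversities must be non-negative")
  out <- log2(pi_a / pi_b)
  out[pi_a == 0 & pi_b == 0] <- NaN
  out
}
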