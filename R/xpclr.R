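#' XP-CLR scan parameters
#'
#' Parameters of the cross-population composite-likelihood-ratio scan.
#' The defaults reproduce the configuration used throughout the package:
#' assessment windows of half-width 0.01 cM around grid points spaced 50 kb
#' apart, at most 100 SNPs per window, and LD down-weighting of SNP pairs
#' with genotype correlation above 0.95.
#'
#' @param window_cM assessment-window half-width in centimorgans.
#' @param grid_bp spacing of evaluation grid points in bp.
#' @param max_snps maximum SNPs contributing per grid point.
#' @param r2_max genotype r-squared above which SNPs share weight.
#' @param rec_rate_cM_per_Mb uniform genetic-map rate converting bp to cM.
#' @param s_grid selection-coefficient grid; must contain 0 (the null).
#' @param omega genome-wide drift parameter; `NULL` means estimate it from
#'   the data via [estimate_omega()].
#' @param quad_n Gauss-Legendre quadrature order for the latent-frequency
#'   integral.
#' @param eps_sel starting frequency of the beneficial allele in the sweep
#'   model; the probability that a lineage at recombination distance `r`
#'   (Morgans) escapes a sweep of strength `s` is `1 - eps_sel^(r/s)`.
#' @return list of class `xpclr_params`.
#' @export
xpclr_params <- function(window_cM = 0.01, grid_bp = 50000, max_snps = 100,
                         r2_max = 0.95, rec_rate_cM_per_Mb = 1.0,
                         s_grid = c(0, 10^seq(log10(1e-4), log10(0.5),
                                              length.out = 12)),
                         omega = NULL, quad_n = 64, eps_sel = 1e-3) {
  if (window_cM <= 0) stopf("window_cM must be positive")
  if (grid_bp <= 0) stopf("grid_bp must be positive")
  if (r2_max <= 0 || r2_max > 1) stopf("r2_max must be in (0, 1]")
  if (!any(s_grid == 0)) stopf("s_grid must contain 0 (the neutral model)")
  if (any(s_grid < 0)) stopf("selection coefficients must be >= 0")
  if (!is.null(omega) && omega <= 0) stopf("omega must be positive")
  structure(list(window_cM = window_cM, grid_bp = grid_bp,
                 max_snps = max_snps, r2_max = r2_max,
                 rec_rate_cM_per_Mb = rec_rate_cM_per_Mb,
                 s_grid = sort(unique(s_grid)), omega = omega,
                 quad_n = quad_n, eps_sel = eps_sel),
            class = "xpclr_params")
}

#' Estimate the genome-wide drift parameter omega
#'
#' Method-of-moments estimate of the neutral drift variance scale: under the
#' model the object-population frequency `q` satisfies
#' `Var(q - p) = omega * p * (1 - p)` around the reference frequency `p`.
#' Sampling noise in both frequency estimates is subtracted and the estimate
#' is a ratio of sums over all usable SNPs, floored at 1e-6.
#'
#' @param gm a [genotype_matrix()].
#' @param popmap a [population_map()].
#' @param reference,object group labels of the reference and object
#'   populations.
#' @param min_snps minimum usable SNPs required (default 1000).
#' @return Scalar omega estimate.
#' @export
estimate_omega <- function(gm, popmap, reference, object, min_snps = 1000) {
  counts <- group_site_counts(gm, popmap, c(reference, object))
  cr <- counts[[reference]]; co <- counts[[object]]
  use <- cr$n_called >= 4 & co$n_called >= 4
  p <- cr$c_alt[use] / cr$n_called[use]
  q <- co$c_alt[use] / co$n_called[use]
  np <- cr$n_called[use]; nq <- co$n_called[use]
  poly <- p > 0 & p < 1
  p <- p[poly]; q <- q[poly]; np <- np[poly]; nq <- nq[poly]
  if (length(p) < min_snps)
    stopf("only %d usable SNPs for omega estimation (need >= %d)",
          length(p), min_snps)
  num <- (q - p)^2 - q * (1 - q) / (nq - 1) - p * (1 - p) / (np - 1)
  den <- p * (1 - p) * np / (np - 1)
  max(sum(num) / sum(den), 1e-6)
}

#' LD-based SNP weights within an assessment window
#'
#' SNPs are grouped into high-LD cliques by single linkage on pairwise
#' genotype r-squared exceeding `r2_max` (i.e. connected components of the
#' thresholded correlation graph); each SNP in a clique of size `m` receives
#' weight `1/m`, so every clique contributes total weight 1. Monomorphic
#' SNPs have undefined correlation and are treated as unlinked (weight 1).
#'
#' @param geno genotype dosage matrix, variants x samples.
#' @param r2_max correlation threshold.
#' @return Numeric vector of per-SNP weights.
#' @export
ld_weights <- function(geno, r2_max = 0.95) {
  m <- nrow(geno)
  if (m == 0L) return(numeric(0))
  if (m == 1L) return(1)
  r <- suppressWarnings(stats::cor(t(geno), use = "pairwise.complete.obs"))
  r[!is.finite(r)] <- 0
  adj <- r^2 > r2_max
  diag(adj) <- FALSE
  comp <- integer(m)
  cur <- 0L
  for (i in seq_len(m)) {
    if (comp[i]) next
    cur <- cur + 1L
    stack <- i
    while (length(stack)) {
      j <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (comp[j]) next
      comp[j] <- cur
      stack <- c(stack, which(adj[j, ] & comp == 0L))
    }
  }
  sizes <- tabulate(comp)
  1 / sizes[comp]
}

#' XP-CLR per-site log-likelihood
#'
#' Log-likelihood of the observed object-population allele count at one SNP
#' under the neutral (`s = 0`) or sweep (`s > 0`) model. Neutral model: the
#' latent object frequency is Normal(`p_ref`, `omega * p_ref * (1-p_ref)`)
#' truncated to (0, 1) with the escaped mass placed as atoms at the
#' boundaries; the binomial sampling likelihood of the observed count is
#' integrated over that distribution by Gauss-Legendre quadrature. Sweep
#' model: each lineage escapes the sweep with probability
#' `c = 1 - eps_sel^(r/s)` (`r` in Morgans); conditional on pre-sweep
#' frequency `q1`, the post-sweep frequency is `c*q1 + (1-c)` if the
#' beneficial mutation arose on the focal-allele background (probability
#' `q1`) and `c*q1` otherwise. As `s -> 0` the sweep model tends to the
#' neutral one.
#'
#' @param p_ref reference-population allele frequency (vectorized over SNPs).
#' @param q_obs_count observed alt count in the object population.
#' @param n_obs called chromosomes in the object population.
#' @param r_cM genetic distance of each SNP to the grid point (cM).
#' @param s selection coefficient (scalar; 0 = neutral).
#' @param params an [xpclr_params()] with non-NULL `omega`.
#' @return Numeric vector of per-SNP log-likelihoods.
#' @export
xpclr_site_loglik <- function(p_ref, q_obs_count, n_obs, r_cM, s, params) {
  if (any(!is.finite(p_ref)) || any(!is.finite(q_obs_count)) ||
      any(!is.finite(n_obs)) || any(!is.finite(r_cM)) || !is.finite(s))
    stopf("non-finite inputs to xpclr_site_loglik")
  if (is.null(params$omega)) stopf("params$omega must be set")
  gq <- .gauss_legendre01(params$quad_n)
  lik <- .xpclr_lik(p_ref, q_obs_count, n_obs, r_cM, s,
                    params$omega, params$eps_sel, gq)
  log(pmax(lik, 1e-300))
}

# cached Gauss-Legendre nodes/weights on (0, 1)
.gq_cache <- new.env(parent = emptyenv())
.gauss_legendre01 <- function(n) {
  key <- as.character(n)
  if (is.null(.gq_cache[[key]])) {
    gl <- pracma::gaussLegendre(n, 0, 1)
    .gq_cache[[key]] <- list(x = gl$x, w = gl$w)
  }
  .gq_cache[[key]]
}

# internal: vectorized likelihood over SNPs for one s
.xpclr_lik <- function(p, k, n, r_cM, s, omega, eps_sel, gq) {
  m <- length(p)
  sdv <- sqrt(omega * p * (1 - p))
  # escape probability; s = 0 (or r -> Inf) collapses to the neutral model
  cc <- if (s > 0) 1 - exp(-(pmax(r_cM, 0) / 100) / s * log(1 / eps_sel))
        else rep(1, m)
  nq <- length(gq$x)
  X <- matrix(gq$x, nq, m)                     # latent pre-sweep frequency q1
  P <- matrix(p, nq, m, byrow = TRUE)
  S <- matrix(sdv, nq, m, byrow = TRUE)
  C <- matrix(cc, nq, m, byrow = TRUE)
  K <- matrix(k, nq, m, byrow = TRUE)
  N <- matrix(n, nq, m, byrow = TRUE)
  dens <- matrix(0, nq, m)
  pos <- sdv > 0
  if (any(pos)) dens[, pos] <- dnorm(X[, pos], P[, pos], S[, pos])
  qa <- C * X + (1 - C)                        # hitchhiked branch
  qb <- C * X                                  # escaped branch
  integrand <- dens * (X * dbinom(K, N, qa) + (1 - X) * dbinom(K, N, qb))
  lik <- as.vector(gq$w %*% integrand)
  # boundary atoms of the truncated normal (invariant under the sweep map)
  mass0 <- ifelse(pos, pnorm(0, p, sdv), as.numeric(p <= 0))
  mass1 <- ifelse(pos, pnorm(1, p, sdv, lower.tail = FALSE),
                  as.numeric(p >= 1))
  lik <- lik + mass0 * as.numeric(k == 0) + mass1 * as.numeric(k == n)
  # degenerate interior case (p fixed but polymorphic impossible): sd = 0 and
  # 0 < p < 1 means the latent frequency is exactly p
  deg <- !pos & p > 0 & p < 1
  if (any(deg)) {
    qa <- cc[deg] * p[deg] + (1 - cc[deg])
    qb <- cc[deg] * p[deg]
    lik[deg] <- p[deg] * dbinom(k[deg], n[deg], qa) +
      (1 - p[deg]) * dbinom(k[deg], n[deg], qb)
  }
  lik
}

#' Cross-population composite-likelihood-ratio scan
#'
#' Evaluates the XP-CLR statistic on a grid of points spaced `grid_bp` apart
#' along each chromosome. At each point, the SNPs within `window_cM` (genetic
#' half-width, uniform map) contribute LD-weighted log-likelihoods; when more
#' than `max_snps` fall inside, the nearest by genetic distance are kept
#' (ties broken by lower bp position). The score is
#' `2 * (max over s_grid of l(s) - l(0))`, which is non-negative because the
#' grid contains the null.
#'
#' @param gm a [genotype_matrix()].
#' @param popmap a [population_map()].
#' @param reference,object group labels: sweeps are sought in `object`
#'   relative to `reference`.
#' @param params an [xpclr_params()]; `omega = NULL` triggers estimation.
#' @param chrom_lengths optional named lengths; defaults to those carried by
#'   `gm`.
#' @return data.frame of class `xpclr_scores`: `chrom`, `pos` (1-based grid
#'   point), `clr`, `s_hat`, `n_snps_used`; grid points with no usable SNP
#'   are reported with `clr = NA`. The omega used is attached as an
#'   attribute.
#' @export
xpclr_scan <- function(gm, popmap, reference, object, params = xpclr_params(),
                       chrom_lengths = NULL) {
  stopifnot(inherits(params, "xpclr_params"))
  if (is.null(chrom_lengths)) chrom_lengths <- gm$chrom_lengths
  omega <- params$omega
  if (is.null(omega))
    omega <- estimate_omega(gm, popmap, reference, object)
  params$omega <- omega
  counts <- group_site_counts(gm, popmap, c(reference, object))
  cr <- counts[[reference]]; co <- counts[[object]]
  usable <- cr$n_called >= 2 & co$n_called >= 2
  gq <- .gauss_legendre01(params$quad_n)
  obj_ids <- group_samples(popmap, object)
  cm_per_bp <- params$rec_rate_cM_per_Mb / 1e6
  s_grid <- params$s_grid
  i_null <- which(s_grid == 0)
  res <- list()
  for (cn in names(chrom_lengths)) {
    ci <- which(gm$chrom == cn & usable)
    gpos <- gm$pos[ci] * cm_per_bp
    pts <- seq.int(params$grid_bp, chrom_lengths[[cn]], by = params$grid_bp)
    if (!length(pts)) next
    clr <- rep(NA_real_, length(pts))
    shat <- rep(NA_real_, length(pts))
    nuse <- integer(length(pts))
    for (ip in seq_along(pts)) {
      gpt <- pts[ip] * cm_per_bp
      lo <- findInterval(gpt - params$window_cM, gpos)
      hi <- findInterval(gpt + params$window_cM, gpos)
      if (hi <= lo) next
      idx <- ci[(lo + 1L):hi]
      d <- abs(gm$pos[idx] * cm_per_bp - gpt)
      if (length(idx) > params$max_snps) {
        o <- order(d, gm$pos[idx])[seq_len(params$max_snps)]
        idx <- idx[o]; d <- d[o]
      }
      p <- cr$c_alt[idx] / cr$n_called[idx]
      k <- co$c_alt[idx]; n <- co$n_called[idx]
      w <- ld_weights(gm$geno[idx, obj_ids, drop = FALSE], params$r2_max)
      ll <- vapply(s_grid, function(s) {
        sum(w * log(pmax(.xpclr_lik(p, k, n, d, s, omega,
                                    params$eps_sel, gq), 1e-300)))
      }, numeric(1))
      clr[ip] <- 2 * (max(ll) - ll[i_null])
      shat[ip] <- s_grid[which.max(ll)]
      nuse[ip] <- length(idx)
    }
    res[[cn]] <- data.frame(chrom = cn, pos = pts, clr = clr, s_hat = shat,
                            n_snps_used = nuse, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  attr(out, "omega") <- omega
  class(out) <- c("xpclr_scores", "data.frame")
  out
}

#' Map per-grid-point XP-CLR scores onto a window grid
#'
#' The per-window score is the maximum score over the grid points contained
#' in the window (`NA` if none carries a score).
#'
#' @param scores an [xpclr_scan()] result.
#' @param grid a [make_windows()] grid.
#' @return Numeric vector of per-window scores aligned with `grid` rows.
#' @export
xpclr_window_max <- function(scores, grid) {
  out <- rep(NA_real_, nrow(grid))
  for (cn in unique(grid$chrom)) {
    wi <- which(grid$chrom == cn)
    si <- which(scores$chrom == cn & !is.na(scores$clr))
    if (!length(si)) next
    pos0 <- scores$pos[si] - 1
    for (i in wi) {
      inw <- si[pos0 >= grid$start[i] & pos0 < grid$end[i]]
      if (length(inw)) out[i] <- max(scores$clr[inw])
    }
  }
  out
}
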