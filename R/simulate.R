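#' Simulation configuration
#'
#' Parameters of the Balding-Nichols multi-population genotype simulator.
#' Each SNP draws an ancestral frequency `p` from a neutral-shaped site
#' frequency spectrum (probability proportional to `1/x` over the allele
#' count `x` of a `2 * n_anc`-chromosome ancestral pool); each group's
#' frequency is `Beta(p(1-F)/F, (1-p)(1-F)/F)` with that group's drift `F`,
#' elevated to `F_sweep` inside that group's planted sweep intervals; diploid
#' genotypes are binomial draws. The defaults emulate a five-group crop
#' resequencing panel: a diverse basal group and four derived groups with
#' per-bp diversity near 5e-4 to 7e-4 and pairwise FST in the 0.2-0.4 range.
#' `mu` and `generation_years` are carried for documentation and scaling
#' parity; the engine is parameterized by `F` directly.
#'
#' @param groups data.frame with columns `label`, `n` (diploids), `F`
#'   (drift in (0, 1)).
#' @param genome named numeric vector of chromosome lengths (bp).
#' @param snp_density SNPs per bp (default 0.0048, giving basal-group
#'   diversity near 6.9e-4/bp under the default spectrum).
#' @param sweeps data.frame with columns `group`, `chrom`, `start`, `end`
#'   (0-based half-open), `F_sweep` (> the group's background `F`); NULL for
#'   none.
#' @param mu mutation rate per nucleotide per year (annotation only).
#' @param generation_years generation time in years (annotation only).
#' @param missing_rate per-genotype missing probability.
#' @param n_anc diploid size of the notional ancestral pool for the SFS.
#' @param seed RNG seed recorded in all outputs.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(groups = data.frame(
                         label = c("BG", "CG1", "CG2", "G3", "G4"),
                         n = c(28L, 27L, 46L, 16L, 17L),
                         F = c(0.15, 0.35, 0.40, 0.25, 0.30)),
                       genome = c(chr1 = 8e6, chr2 = 6e6),
                       snp_density = 0.0048,
                       sweeps = data.frame(
                         group = c("CG1", "CG1"),
                         chrom = c("chr1", "chr2"),
                         start = c(2000000, 1000000),
                         end = c(3000000, 1750000),
                         F_sweep = c(0.95, 0.95)),
                       mu = 2.5e-9, generation_years = 1,
                       missing_rate = 0.02, n_anc = 100L, seed = 1L) {
  if (any(groups$F <= 0 | groups$F >= 1)) stopf("drift F must lie in (0, 1)")
  if (any(groups$n < 2)) stopf("every group needs >= 2 diploids")
  if (anyDuplicated(groups$label)) stopf("duplicate group labels")
  if (!is.null(sweeps) && nrow(sweeps)) {
    if (any(sweeps$F_sweep <= 0 | sweeps$F_sweep >= 1))
      stopf("F_sweep must lie in (0, 1)")
    bgF <- groups$F[match(sweeps$group, groups$label)]
    if (anyNA(bgF)) stopf("sweep group not among simulated groups")
    if (any(sweeps$F_sweep <= bgF))
      stopf("F_sweep must exceed the group's background drift")
    if (any(!(sweeps$chrom %in% names(genome))) ||
        any(sweeps$start < 0) ||
        any(sweeps$end > genome[sweeps$chrom]))
      stopf("sweep interval outside genome bounds")
  }
  structure(list(groups = groups, genome = genome, snp_density = snp_density,
                 sweeps = sweeps, mu = mu,
                 generation_years = generation_years,
                 missing_rate = missing_rate, n_anc = as.integer(n_anc),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# run code under a seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Simulate multi-population genotypes under the Balding-Nichols model
#'
#' See [sim_config()] for the model. Fully reproducible from the seed in the
#' configuration.
#'
#' @param config a [sim_config()].
#' @return list: `gm` (a [genotype_matrix()]), `popmap` (a
#'   [population_map()]), `truth` (data.frame of planted sweep intervals with
#'   `group`, `chrom`, `start`, `end`, `F_sweep`), `config`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, {
    bases <- c("A", "C", "G", "T")
    groups <- config$groups
    sample_ids <- unlist(lapply(seq_len(nrow(groups)), function(i)
      sprintf("%s_%03d", groups$label[i], seq_len(groups$n[i]))))
    popmap <- population_map(setNames(
      rep(groups$label, groups$n), sample_ids))
    cnt_probs <- 1 / seq_len(2L * config$n_anc - 1L)
    chrom_v <- list(); pos_v <- list(); geno_v <- list()
    ref_v <- list(); alt_v <- list()
    for (cn in names(config$genome)) {
      L <- config$genome[[cn]]
      n <- round(config$snp_density * L)
      pos <- sort(sample.int(L, n))
      x <- sample.int(2L * config$n_anc - 1L, n, replace = TRUE,
                      prob = cnt_probs)
      p <- x / (2 * config$n_anc)
      gmat <- matrix(NA_integer_, n, 0L)
      for (i in seq_len(nrow(groups))) {
        Fv <- rep(groups$F[i], n)
        sw <- config$sweeps
        if (!is.null(sw) && nrow(sw)) {
          sw <- sw[sw$group == groups$label[i] & sw$chrom == cn, ,
                   drop = FALSE]
          for (k in seq_len(nrow(sw))) {
            inside <- (pos - 1) >= sw$start[k] & (pos - 1) < sw$end[k]
            Fv[inside] <- sw$F_sweep[k]
          }
        }
        q <- rbeta(n, p * (1 - Fv) / Fv, (1 - p) * (1 - Fv) / Fv)
        m <- groups$n[i]
        g <- matrix(rbinom(n * m, 2L, q), n, m)
        gmat <- cbind(gmat, g)
      }
      if (config$missing_rate > 0) {
        drop <- runif(length(gmat)) < config$missing_rate
        gmat[drop] <- NA_integer_
      }
      ri <- sample.int(4L, n, replace = TRUE)
      ai <- (ri + sample.int(3L, n, replace = TRUE) - 1L) %% 4L + 1L
      chrom_v[[cn]] <- rep(cn, n); pos_v[[cn]] <- pos
      ref_v[[cn]] <- bases[ri]; alt_v[[cn]] <- bases[ai]
      geno_v[[cn]] <- gmat
    }
    gm <- genotype_matrix(unlist(chrom_v, use.names = FALSE),
                          unlist(pos_v, use.names = FALSE),
                          unlist(ref_v, use.names = FALSE),
                          unlist(alt_v, use.names = FALSE),
                          sample_ids, do.call(rbind, geno_v),
                          chrom_lengths = config$genome)
    truth <- if (is.null(config$sweeps)) {
      data.frame(group = character(), chrom = character(), start = numeric(),
                 end = numeric(), F_sweep = numeric())
    } else config$sweeps
    list(gm = gm, popmap = popmap, truth = truth, config = config)
  })
}

#' Simulate phenotypes from a causal variant
#'
#' `phenotype = baseline + effect * dosage + Normal(0, noise_sd)`; samples
#' with a missing causal genotype receive `NA`.
#'
#' @param gm a [genotype_matrix()].
#' @param causal_chrom,causal_pos 1-based position of the causal variant.
#' @param effect additive effect per alt allele, in trait units.
#' @param noise_sd residual standard deviation.
#' @param seed RNG seed.
#' @param baseline trait value of a wild-type sample without noise.
#' @return list: `phenotype` (named numeric per sample), `truth` (causal
#'   variant, effect, noise_sd, baseline).
#' @export
simulate_phenotypes <- function(gm, causal_chrom, causal_pos, effect,
                                noise_sd, seed = 1L, baseline = 180) {
  i <- which(gm$chrom == causal_chrom & gm$pos == causal_pos)
  if (length(i) != 1L)
    stopf("causal variant %s:%d not found", causal_chrom, causal_pos)
  .with_seed(seed, {
    dose <- gm$geno[i, ]
    phe <- baseline + effect * dose + rnorm(length(dose), 0, noise_sd)
    phe[is.na(dose)] <- NA_real_
    list(phenotype = setNames(phe, gm$samples),
         truth = list(chrom = causal_chrom, pos = causal_pos,
                      effect = effect, noise_sd = noise_sd,
                      baseline = baseline))
  })
}

#' Simulate an expression table correlated with a phenotype
#'
#' One linked gene's expression is generated with Pearson correlation close
#' to `corr_target` with the phenotype; the remaining genes are independent
#' noise.
#'
#' @param phenotype named numeric vector per sample.
#' @param linked_gene id of the correlated gene.
#' @param corr_target target correlation in (-1, 1).
#' @param n_genes total number of genes in the table.
#' @param seed RNG seed.
#' @return list: `expression` (matrix genes x samples), `truth` (linked gene
#'   and target correlation).
#' @export
simulate_expression <- function(phenotype, linked_gene, corr_target,
                                n_genes = 20, seed = 1L) {
  if (abs(corr_target) >= 1) stopf("corr_target must lie in (-1, 1)")
  ok <- is.finite(phenotype)
  .with_seed(seed, {
    n <- length(phenotype)
    z <- rep(0, n)
    z[ok] <- as.numeric(scale(phenotype[ok]))
    linked <- corr_target * z + sqrt(1 - corr_target^2) * rnorm(n)
    others <- matrix(rnorm(n * (n_genes - 1L)), n_genes - 1L, n,
                     byrow = TRUE)
    expr <- rbind(5 + linked, 5 + others)
    gene_ids <- c(linked_gene,
                  sprintf("gene_bg%03d", seq_len(n_genes - 1L)))
    dimnames(expr) <- list(gene_ids, names(phenotype))
    list(expression = expr,
         truth = list(linked_gene = linked_gene,
                      corr_target = corr_target))
  })
}

#' Write a self-contained simulated fixture bundle
#'
#' Simulates genotypes under `config` and writes everything the scan and
#' trait-linking stages consume: a VCF 4.2, a two-column population map, a
#' toy GFF3 with genes tiled along the genome (so some fall inside planted
#' sweeps), phenotype and expression tables tied to a causal variant inside
#' the first planted sweep, JSON truth tables, and the configuration as
#' YAML. Byte-identical across reruns with the same configuration.
#'
#' @param outdir output directory (created if needed).
#' @param config a [sim_config()].
#' @param pheno_effect,pheno_noise_sd causal effect (trait units per alt
#'   allele) and residual sd of the simulated phenotype.
#' @param expr_corr target expression-phenotype correlation for the linked
#'   gene.
#' @return list with the simulated objects and a `files` vector of paths.
#' @export
write_fixture_bundle <- function(outdir, config = sim_config(),
                                 pheno_effect = 10, pheno_noise_sd = 5,
                                 expr_corr = -0.4) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outdir, 2) != 0) stopf("cannot write to '%s'", outdir)
  sim <- simulate_genotypes(config)
  gm <- sim$gm
  files <- c(vcf = file.path(outdir, "genotypes.vcf"),
             popmap = file.path(outdir, "popmap.tsv"),
             gff = file.path(outdir, "genes.gff3"),
             phenotype = file.path(outdir, "phenotype.tsv"),
             expression = file.path(outdir, "expression.tsv"),
             truth = file.path(outdir, "truth.json"),
             config = file.path(outdir, "config.yaml"))
  write_vcf(gm, files[["vcf"]])
  .write_tsv(data.frame(sample = names(sim$popmap),
                        group = unname(unclass(sim$popmap))),
             files[["popmap"]])
  # genes tiled every 250 kb, 20 kb long, so planted sweeps contain several
  genes <- do.call(rbind, lapply(names(config$genome), function(cn) {
    starts <- seq(100000, config$genome[[cn]] - 20000, by = 250000)
    data.frame(chrom = cn, start = starts, end = starts + 20000,
               stringsAsFactors = FALSE)
  }))
  genes <- gene_models(sprintf("gene_%s_%04d", genes$chrom,
                               as.integer(genes$start / 1000)),
                       genes$chrom, genes$start, genes$end, "+")
  write_gff_genes(genes, files[["gff"]])
  # causal variant: the variant nearest the midpoint of the first planted
  # sweep (or of the genome when no sweep is configured)
  if (nrow(sim$truth)) {
    tcn <- sim$truth$chrom[1]
    t_start <- sim$truth$start[1]; t_end <- sim$truth$end[1]
  } else {
    tcn <- names(config$genome)[1]
    t_start <- 0; t_end <- config$genome[[1]]
  }
  mid <- (t_start + t_end) / 2
  cand <- which(gm$chrom == tcn)
  ci <- cand[which.min(abs(gm$pos[cand] - mid))]
  ph <- simulate_phenotypes(gm, gm$chrom[ci], gm$pos[ci],
                            effect = pheno_effect,
                            noise_sd = pheno_noise_sd,
                            seed = config$seed + 1L)
  .write_tsv(data.frame(sample = names(ph$phenotype),
                        bolting_days = sprintf("%.6f", ph$phenotype)),
             files[["phenotype"]])
  in_sweep <- genes$chrom == tcn & genes$start < t_end & genes$end > t_start
  linked <- if (any(in_sweep)) genes$gene_id[which(in_sweep)[1]] else
    genes$gene_id[1]
  ex <- simulate_expression(ph$phenotype, linked, expr_corr,
                            seed = config$seed + 2L)
  expr_df <- data.frame(gene = rownames(ex$expression),
                        round(ex$expression, 6), check.names = FALSE)
  .write_tsv(expr_df, files[["expression"]])
  truth <- list(seed = config$seed, sweeps = sim$truth,
                causal_variant = ph$truth, expression = ex$truth)
  jsonlite::write_json(truth, files[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  cfg <- unclass(config)
  cfg$groups <- as.list(as.data.frame(cfg$groups))
  cfg$genome <- as.list(cfg$genome)
  if (!is.null(cfg$sweeps)) cfg$sweeps <- as.list(as.data.frame(cfg$sweeps))
  yaml::write_yaml(cfg, files[["config"]])
  list(gm = gm, popmap = sim$popmap, truth = truth, genes = genes,
       phenotype = ph$phenotype, expression = ex$expression, files = files)
}
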