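#' @export
print.sweep_scan <- function(x, ...) {
  cfg <- x$config
  cat("Selective sweep scan\n")
  cat(sprintf("  comparison: %s (focal) vs %s (baseline), third = %s\n",
              cfg$focal, cfg$baseline, cfg$third))
  cat(sprintf("  windows: %d bp sliding by %d bp; %d on grid, %d retained (>= %d SNPs)\n",
              cfg$size_bp, cfg$step_bp, x$counts$n_windows,
              x$counts$n_retained, cfg$min_snps))
  cat(sprintf("  methods: %s (top %.1f%%, >= %d supporting)\n",
              paste(cfg$methods, collapse = ", "), 100 * cfg$top_fraction,
              cfg$min_methods))
  cat(sprintf("  sweeps: %d intervals spanning %.2f Mb\n",
              x$counts$n_sweeps, x$counts$sweep_bp / 1e6))
  if (!is.na(x$counts$n_genes))
    cat(sprintf("  genes in sweeps: %d\n", x$counts$n_genes))
  invisible(x)
}

#' @export
summary.sweep_scan <- function(object, ...) {
  print(object)
  cat("\nPer-method outlier thresholds:\n")
  for (m in names(object$thresholds))
    cat(sprintf("  %-8s >= %.6g  (%d windows flagged)\n", m,
                object$thresholds[[m]], object$counts$n_flagged[[m]]))
  if (nrow(object$sweeps)) {
    cat("\nLargest sweep intervals:\n")
    sw <- object$sweeps[order(-object$sweeps$length_bp), ]
    print(utils::head(as.data.frame(sw), 5), row.names = FALSE)
  }
  invisible(object)
}

#' Plot sweep-scan statistic tracks
#'
#' One panel per scan statistic (PBS, log2 diversity ratio, XP-CLR) against
#' window midpoint, with the outlier threshold as a dashed line and called
#' sweep intervals shaded.
#'
#' @param x a [sweep_scan()] result.
#' @param chrom chromosome to plot (default: the first one).
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.sweep_scan <- function(x, chrom = NULL, ...) {
  w <- x$windows
  if (is.null(chrom)) chrom <- w$chrom[1]
  w <- w[w$chrom == chrom, ]
  stat_col <- c(pbs = "pbs", piratio = "log2_ratio", xpclr = "xpclr")
  methods <- x$config$methods
  old <- par(mfrow = c(length(methods), 1), mar = c(3.5, 4, 1.5, 1))
  on.exit(par(old))
  mid <- (w$start + w$end) / 2 / 1e6
  sw <- x$sweeps[x$sweeps$chrom == chrom, ]
  for (m in methods) {
    y <- w[[stat_col[[m]]]]
    fin <- is.finite(y)
    plot(mid[fin], y[fin], type = "p", pch = 16, cex = 0.5,
         xlab = "", ylab = stat_col[[m]], main = "")
    if (nrow(sw))
      rect(sw$start / 1e6, par("usr")[3], sw$end / 1e6, par("usr")[4],
           col = grDevices::adjustcolor("red", 0.15), border = NA)
    thr <- x$thresholds[[m]]
    if (is.finite(thr)) abline(h = thr, lty = 2)
    mtext(sprintf("%s (%s)", m, chrom), side = 3, line = 0.2, cex = 0.8)
  }
  mtext("position (Mb)", side = 1, line = 2.2, cex = 0.8)
  invisible(x)
}
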