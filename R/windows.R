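#' Build a sliding-window grid
#'
#' Emits all windows `[k*step, k*step + size)` (0-based half-open) that are
#' fully contained in their chromosome; trailing partial windows are dropped
#' so every window has identical length. The default 500-kb windows sliding
#' in 125-kb steps are the grid shared by all scan statistics.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param size_bp window length in bp (default 500000).
#' @param step_bp step between window starts in bp (default 125000); must not
#'   exceed `size_bp`, otherwise gaps would break sweep merging.
#' @return A `window_grid`: data.frame with columns `chrom`, `start`, `end`
#'   and attributes `size_bp`, `step_bp`.
#' @export
#' @examples
#' make_windows(c(chr1 = 1e6), 500000, 125000)
make_windows <- function(chrom_lengths, size_bp = 500000, step_bp = 125000) {
  if (!is_count(size_bp) || size_bp <= 0) stopf("size_bp must be a positive integer")
  if (!is_count(step_bp) || step_bp <= 0) stopf("step_bp must be a positive integer")
  if (step_bp > size_bp)
    stopf("step_bp (%d) must not exceed size_bp (%d)", step_bp, size_bp)
  if (is.null(names(chrom_lengths)) || any(names(chrom_lengths) == ""))
    stopf("chrom_lengths must be a named vector")
  out <- lapply(names(chrom_lengths), function(cn) {
    L <- chrom_lengths[[cn]]
    if (L < size_bp) return(NULL)
    starts <- seq.int(0L, floor((L - size_bp) / step_bp) * step_bp, by = step_bp)
    data.frame(chrom = cn, start = starts, end = starts + size_bp,
               stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (is.null(grid))
    grid <- data.frame(chrom = character(), start = numeric(), end = numeric())
  structure(grid, size_bp = size_bp, step_bp = step_bp,
            class = c("window_grid", "data.frame"))
}

# internal: for each window, the index range of variants it contains.
# Returns a list(lo, hi) of integer vectors into the variant order of `gm`;
# window i contains variants (lo[i]+1):hi[i] (empty when lo == hi).
.window_site_ranges <- function(gm, grid) {
  n_win <- nrow(grid)
  lo <- integer(n_win); hi <- integer(n_win)
  pos0 <- gm$pos - 1L
  for (cn in unique(grid$chrom)) {
    wi <- which(grid$chrom == cn)
    ci <- which(gm$chrom == cn)
    if (!length(ci)) { lo[wi] <- 0L; hi[wi] <- 0L; next }
    off <- ci[1] - 1L
    p <- pos0[ci]
    lo[wi] <- off + findInterval(grid$start[wi] - 0.5, p)
    hi[wi] <- off + findInterval(grid$end[wi] - 0.5, p)
  }
  list(lo = lo, hi = hi)
}

# internal: windowed sums of per-site values via prefix sums.
# x is a vector (or matrix, sites x k) aligned to gm's variant order; NA
# treated as 0. Returns a matrix n_windows x k of sums over contained sites.
.window_sums <- function(x, ranges) {
  x <- as.matrix(x)
  x[is.na(x)] <- 0
  cs <- apply(x, 2L, cumsum)
  cs <- rbind(0, as.matrix(cs))
  cs[ranges$hi + 1L, , drop = FALSE] - cs[ranges$lo + 1L, , drop = FALSE]
}
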