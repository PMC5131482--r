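#' Generate sliding genome windows
#'
#' Windows are 0-based half-open intervals `[start, end)` anchored at 0 on
#' each chromosome, with starts at `0, step_size, 2*step_size, ...` while
#' `start < chromosome length`. The terminal window of a chromosome is
#' truncated at the chromosome end and flagged `terminal`. The defaults
#' (150 kb windows sliding by 75 kb) give 50% overlap between consecutive
#' windows.
#'
#' @param chroms A [chrom_table()] data.frame.
#' @param window_size Window width in bp (default 150000).
#' @param step_size Slide in bp, `0 < step_size <= window_size`
#'   (default 75000).
#' @return A data.frame with columns `chrom`, `start`, `end`, `terminal`,
#'   ordered by chromosome-table order then start.
#' @export
make_windows <- function(chroms, window_size = 150000, step_size = 75000) {
  if (window_size <= 0 || step_size <= 0)
    stop("window_size and step_size must be positive")
  if (step_size > window_size)
    stop("step_size must not exceed window_size")
  per_chrom <- lapply(seq_len(nrow(chroms)), function(i) {
    len <- chroms$length[i]
    starts <- seq(0, len - 1, by = step_size)
    ends <- pmin(starts + window_size, len)
    data.frame(chrom = chroms$chrom[i], start = starts, end = ends,
               terminal = ends - starts < window_size,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_chrom)
  rownames(out) <- NULL
  out
}

#' Assign sites to windows
#'
#' A site at 1-based position `pos` belongs to window `[start, end)` iff
#' `start <= pos - 1 < end`. With 50% window overlap every interior site
#' falls in exactly two windows.
#'
#' @param windows Window data.frame from [make_windows()].
#' @param sites A [pooled_sites()] data.frame sorted by (chrom, pos).
#' @return `windows` with an added list-column `site_idx` of integer indices
#'   into `sites`, and an integer column `snp_count`.
#' @export
assign_sites <- function(windows, sites) {
  if (nrow(sites) > 0) {
    if (any(vapply(split(sites$pos, sites$chrom), is.unsorted, TRUE)))
      stop("sites must be sorted by position within each chromosome")
    unknown <- setdiff(unique(sites$chrom), unique(windows$chrom))
    if (length(unknown))
      stop("site(s) on chromosome(s) absent from the window grid: ",
           paste(unknown, collapse = ", "))
  }
  win_gr <- GenomicRanges::GRanges(windows$chrom,
                                   IRanges::IRanges(windows$start + 1,
                                                    windows$end))
  if (nrow(sites) == 0) {
    windows$site_idx <- replicate(nrow(windows), integer(), simplify = FALSE)
    windows$snp_count <- 0L
    return(windows)
  }
  site_gr <- GenomicRanges::GRanges(sites$chrom,
                                    IRanges::IRanges(sites$pos, sites$pos))
  hits <- GenomicRanges::findOverlaps(win_gr, site_gr)
  idx_by_win <- split(S4Vectors::subjectHits(hits),
                      factor(S4Vectors::queryHits(hits),
                             levels = seq_len(nrow(windows))))
  windows$site_idx <- lapply(idx_by_win, function(x) sort(as.integer(x)))
  windows$snp_count <- lengths(windows$site_idx)
  windows
}

#' Survey per-window SNP counts over candidate window sizes
#'
#' For each candidate size the genome is tiled non-overlappingly and the
#' distribution of per-window SNP counts is summarised, so the smallest
#' size whose minimum count clears a chosen floor (e.g. 20 SNPs) can be
#' picked for the sweep scan.
#'
#' @param sites A [pooled_sites()] data.frame.
#' @param chroms A [chrom_table()] data.frame.
#' @param sizes Numeric vector of window sizes in bp.
#' @return A data.frame with one row per size: `size`, `n_windows`,
#'   `min_snps`, `median_snps`, `mean_snps`.
#' @export
window_size_scan <- function(sites, chroms, sizes) {
  if (length(sizes) == 0) stop("sizes must be non-empty")
  rows <- lapply(sizes, function(sz) {
    w <- assign_sites(make_windows(chroms, sz, sz), sites)
    data.frame(size = sz, n_windows = nrow(w),
               min_snps = if (nrow(w)) min(w$snp_count) else 0L,
               median_snps = if (nrow(w)) stats::median(w$snp_count) else 0,
               mean_snps = if (nrow(w)) mean(w$snp_count) else 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
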