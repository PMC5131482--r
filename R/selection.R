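#' Select candidate sweep windows by quantile intersection
#'
#' A window is a candidate for a pool when its ZHp lies at or below the
#' empirical `zhp_quantile` quantile of that pool's ZHp (the low tail:
#' highest homozygosity) *and* its ZFst lies at or above the upper
#' `zfst_quantile` tail of ZFst (highest differentiation). Quantiles are
#' computed over windows passing the minimum-SNP filter, by linear
#' interpolation of order statistics ([stats::quantile()] type 7).
#'
#' @param stats Window statistics from [compute_window_stats()].
#' @param pool Pool selector, 1 or 2 (or pool label).
#' @param zhp_quantile Lower-tail mass for ZHp (default 0.05).
#' @param zfst_quantile Upper-tail mass for ZFst (default 0.05).
#' @return The candidate rows of `stats`, with attribute `thresholds`
#'   (named vector `zhp`, `zfst`). A quantile of 0 selects nothing.
#' @export
select_candidates <- function(stats, pool, zhp_quantile = 0.05,
                              zfst_quantile = 0.05) {
  if (zhp_quantile < 0 || zhp_quantile >= 1 ||
      zfst_quantile < 0 || zfst_quantile >= 1)
    stop("quantiles must lie in [0, 1)")
  i <- if (is.numeric(pool)) as.integer(pool) else resolve_pool(stats, pool)
  zhp <- stats[[sprintf("zhp%d", i)]]
  elig <- stats$eligible
  if (sum(elig) < 20L)
    stop("fewer than 20 eligible windows; quantile thresholds are meaningless")
  if (stats::sd(zhp[elig]) == 0 || stats::sd(stats$zfst[elig]) == 0)
    warning("degenerate window statistics: all eligible windows identical")
  if (zhp_quantile == 0 || zfst_quantile == 0) {
    out <- stats[integer(), , drop = FALSE]
    attr(out, "thresholds") <- c(zhp = -Inf, zfst = Inf)
    return(out)
  }
  zhp_cut <- stats::quantile(zhp[elig], zhp_quantile, names = FALSE, type = 7)
  zfst_cut <- stats::quantile(stats$zfst[elig], 1 - zfst_quantile,
                              names = FALSE, type = 7)
  keep <- elig & !is.na(zhp) & zhp <= zhp_cut &
    !is.na(stats$zfst) & stats$zfst >= zfst_cut
  out <- stats[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "thresholds") <- c(zhp = zhp_cut, zfst = zfst_cut)
  out
}

#' Merge a set of windows into maximal intervals
#'
#' Overlapping or book-ended (adjacent) windows are merged, so a sweep
#' spanning several sliding windows is represented once.
#'
#' @param windows Data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return A data.frame `chrom`, `start`, `end` of merged intervals in
#'   genome order.
#' @export
merge_windows <- function(windows) {
  if (nrow(windows) == 0L)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  gr <- GenomicRanges::GRanges(windows$chrom,
                               IRanges::IRanges(windows$start + 1,
                                                windows$end))
  red <- GenomicRanges::reduce(gr)
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                    start = GenomicRanges::start(red) - 1,
                    end = as.numeric(GenomicRanges::end(red)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition two candidate sets into group-unique and shared intervals
#'
#' Candidate windows of each group are first merged into maximal intervals
#' ([merge_windows()]). An interval is *shared* when it overlaps (by at
#' least 1 bp) a merged interval of the other group; the remainder are
#' unique to their group.
#'
#' @param set1,set2 Candidate window data.frames (e.g. from
#'   [select_candidates()] for pool 1 and pool 2).
#' @param labels Group display names for the `group` column.
#' @return A list with data.frames `unique1`, `unique2` and `shared`
#'   (the latter with a `group` column); `unique1` plus the group-1 rows
#'   of `shared` reconstitute the merged group-1 candidates.
#' @export
partition_unique_shared <- function(set1, set2,
                                    labels = c("pool1", "pool2")) {
  m1 <- merge_windows(set1)
  m2 <- merge_windows(set2)
  levs <- union(m1$chrom, m2$chrom)
  as_gr <- function(m) GenomicRanges::GRanges(
    factor(m$chrom, levels = levs),
    IRanges::IRanges(m$start + 1, m$end))
  if (nrow(m1) && nrow(m2)) {
    hits <- GenomicRanges::findOverlaps(as_gr(m1), as_gr(m2))
    sh1 <- seq_len(nrow(m1)) %in% S4Vectors::queryHits(hits)
    sh2 <- seq_len(nrow(m2)) %in% S4Vectors::subjectHits(hits)
  } else {
    sh1 <- rep(FALSE, nrow(m1))
    sh2 <- rep(FALSE, nrow(m2))
  }
  tag <- function(m, keep, lab) {
    m <- m[keep, , drop = FALSE]
    m$group <- rep_len(lab, nrow(m))
    m
  }
  shared <- rbind(tag(m1, sh1, labels[1]), tag(m2, sh2, labels[2]))
  rownames(shared) <- NULL
  list(unique1 = m1[!sh1, , drop = FALSE],
       unique2 = m2[!sh2, , drop = FALSE],
       shared = shared)
}

#' Attach overlapping genes to candidate windows
#'
#' A gene is a hit for a window when their 0-based half-open intervals
#' overlap by at least 1 bp. Genes on chromosomes absent from the window
#' set produce a warning and are skipped.
#'
#' @param window_set Data.frame with `chrom`, `start`, `end`.
#' @param genes Gene intervals from [read_bed()] (`chrom`, `start`, `end`,
#'   `name`).
#' @return A list, one element per window (named `chrom:start-end`), each a
#'   character vector of overlapping gene names in coordinate order.
#' @export
overlap_genes <- function(window_set, genes) {
  key <- sprintf("%s:%s-%s", window_set$chrom,
                 format(window_set$start, scientific = FALSE, trim = TRUE),
                 format(window_set$end, scientific = FALSE, trim = TRUE))
  out <- stats::setNames(replicate(nrow(window_set), character(),
                                   simplify = FALSE), key)
  if (nrow(window_set) == 0L || nrow(genes) == 0L) return(out)
  unknown <- setdiff(unique(genes$chrom), unique(window_set$chrom))
  if (length(unknown)) {
    warning("gene(s) on chromosome(s) with no candidate window skipped: ",
            paste(unknown, collapse = ", "))
    genes <- genes[!genes$chrom %in% unknown, , drop = FALSE]
    if (nrow(genes) == 0L) return(out)
  }
  genes <- genes[order(genes$chrom, genes$start, genes$end), , drop = FALSE]
  wgr <- GenomicRanges::GRanges(window_set$chrom,
                                IRanges::IRanges(window_set$start + 1,
                                                 window_set$end))
  ggr <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(genes$start + 1, genes$end))
  hits <- GenomicRanges::findOverlaps(wgr, ggr)
  for (w in unique(S4Vectors::queryHits(hits))) {
    g <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == w]
    out[[w]] <- genes$name[sort(g)]
  }
  out
}

#' Per-group phenotype summary (mean and SD)
#'
#' Arithmetic mean and n-1 sample standard deviation per group, reported
#' to two decimals — the form in which pool phenotype composition (e.g.
#' litter sizes) is conventionally tabulated. A single-observation group
#' gets SD 0.00 and is flagged.
#'
#' @param groups Named list of numeric vectors, one per group; every group
#'   must be non-empty.
#' @return A data.frame `group`, `n`, `mean`, `sd`, `sd_degenerate`.
#' @export
summarize_phenotypes <- function(groups) {
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  if (any(lengths(groups) == 0L)) stop("every group must be non-empty")
  data.frame(
    group = names(groups),
    n = lengths(groups),
    mean = round(vapply(groups, mean, 0), 2),
    sd = round(vapply(groups, function(x)
      if (length(x) < 2L) 0 else stats::sd(x), 0), 2),
    sd_degenerate = lengths(groups) < 2L,
    row.names = NULL, stringsAsFactors = FALSE
  )
}
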