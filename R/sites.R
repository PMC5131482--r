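#' Construct a table of biallelic pooled sites
#'
#' The central row container of the package: one biallelic SNP per row with
#' per-pool allele read counts. Pool 1 and pool 2 are the two sequenced pools
#' (conventionally the low-fecundity and high-fecundity pool, in that order);
#' their display names are carried in the `pool_labels` attribute.
#'
#' @param chrom Chromosome name (character).
#' @param pos 1-based position (integer, >= 1).
#' @param ref,alt Reference and alternate alleles, single characters in
#'   `A/C/G/T`, `ref != alt` row-wise.
#' @param p1_ref,p1_alt,p2_ref,p2_alt Non-negative read counts supporting the
#'   ref and alt allele in pool 1 and pool 2.
#' @param qual Phred-scaled call quality, non-negative; `NA` when the source
#'   format carries no quality (e.g. sync).
#' @param pool_labels Character vector of length 2 naming the pools.
#'
#' @return A `data.frame` with columns `chrom, pos, ref, alt, p1_ref, p1_alt,
#'   p2_ref, p2_alt, qual` and attribute `pool_labels`.
#' @export
pooled_sites <- function(chrom = character(), pos = integer(),
                         ref = character(), alt = character(),
                         p1_ref = integer(), p1_alt = integer(),
                         p2_ref = integer(), p2_alt = integer(),
                         qual = NA_real_,
                         pool_labels = c("pool1", "pool2")) {
  n <- length(pos)
  df <- data.frame(
    chrom = as.character(chrom),
    pos = as.integer(pos),
    ref = as.character(ref),
    alt = as.character(alt),
    p1_ref = as.integer(p1_ref),
    p1_alt = as.integer(p1_alt),
    p2_ref = as.integer(p2_ref),
    p2_alt = as.integer(p2_alt),
    qual = rep_len(as.numeric(qual), n),
    stringsAsFactors = FALSE
  )
  validate_pooled_sites(df)
  attr(df, "pool_labels") <- as.character(pool_labels)
  df
}

validate_pooled_sites <- function(df) {
  bases <- c("A", "C", "G", "T")
  if (nrow(df) == 0L) return(invisible(df))
  if (any(df$pos < 1L)) stop("site positions must be >= 1 (1-based)")
  if (!all(df$ref %in% bases) || !all(df$alt %in% bases))
    stop("ref/alt alleles must be one of A, C, G, T")
  if (any(df$ref == df$alt)) stop("ref and alt allele must differ")
  cnt <- as.matrix(df[, c("p1_ref", "p1_alt", "p2_ref", "p2_alt")])
  if (any(cnt < 0L)) stop("read counts must be non-negative")
  if (any(!is.na(df$qual) & df$qual < 0)) stop("qual must be non-negative")
  invisible(df)
}

#' Extract per-pool ref/alt read counts
#'
#' @param sites A `pooled_sites` data.frame.
#' @param pool Pool selector: `1`, `2`, or a label matching the
#'   `pool_labels` attribute.
#' @return A two-column matrix `ref`, `alt`.
#' @export
pool_counts <- function(sites, pool) {
  i <- resolve_pool(sites, pool)
  m <- cbind(ref = sites[[sprintf("p%d_ref", i)]],
             alt = sites[[sprintf("p%d_alt", i)]])
  m
}

resolve_pool <- function(sites, pool) {
  if (is.numeric(pool)) {
    if (!pool %in% c(1, 2)) stop("pool must be 1 or 2 (or a pool label)")
    return(as.integer(pool))
  }
  labs <- attr(sites, "pool_labels")
  if (is.null(labs)) labs <- c("pool1", "pool2")
  i <- match(pool, labs)
  if (is.na(i)) stop("unknown pool label '", pool, "'; have: ",
                     paste(labs, collapse = ", "))
  i
}

#' Filter sites on per-pool depth and call quality
#'
#' Keeps sites whose read depth strictly exceeds `min_depth` in *every* pool
#' and whose call quality is at least `min_qual`. The defaults encode the
#' common pool-seq calling filter "reads > 4 and quality >= 20". Sites with
#' `NA` quality (sync input carries none) pass the quality test.
#'
#' @param sites A `pooled_sites` data.frame.
#' @param min_depth Depth must be `> min_depth` in each pool (default 4).
#' @param min_qual Quality must be `>= min_qual` (default 20).
#' @return The filtered sites, input order preserved.
#' @export
filter_sites <- function(sites, min_depth = 4, min_qual = 20) {
  stopifnot(min_depth >= 0, min_qual >= 0)
  d1 <- sites$p1_ref + sites$p1_alt
  d2 <- sites$p2_ref + sites$p2_alt
  keep <- d1 > min_depth & d2 > min_depth &
    (is.na(sites$qual) | sites$qual >= min_qual)
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pool_labels") <- attr(sites, "pool_labels")
  out
}
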