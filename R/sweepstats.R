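#' Pooled heterozygosity (Hp) of one window
#'
#' Per site the major and minor allele read counts in the chosen pool are
#' `n_maj = max(ref, alt)` and `n_min = min(ref, alt)`; with
#' `S_maj = sum(n_maj)` and `S_min = sum(n_min)` over the window,
#' `Hp = 2 * S_maj * S_min / (S_maj + S_min)^2`. Hp lies in `[0, 0.5]`:
#' 0.5 when major and minor read mass balance, 0 when the pool is fixed at
#' every site.
#'
#' @param sites Sites in the window (a [pooled_sites()] data.frame subset).
#' @param pool Pool selector (see [pool_counts()]).
#' @return Hp, or `NA` when the pool has zero depth across the window
#'   (undefined, deliberately not 0).
#' @export
window_hp <- function(sites, pool) {
  cnt <- pool_counts(sites, pool)
  n_maj <- pmax(cnt[, "ref"], cnt[, "alt"])
  n_min <- pmin(cnt[, "ref"], cnt[, "alt"])
  s_maj <- sum(n_maj)
  s_min <- sum(n_min)
  tot <- s_maj + s_min
  if (tot == 0) return(NA_real_)
  2 * s_maj * s_min / tot^2
}

#' Per-site heterozygosity components for pool-Fst
#'
#' From the alt-allele read frequencies `f1`, `f2` of the two pools:
#' within-pool heterozygosities `h1 = 2 f1 (1-f1)`, `h2 = 2 f2 (1-f2)`,
#' their mean `h_s`, and the total heterozygosity `h_t = 2 fbar (1-fbar)`
#' at the pooled mean frequency `fbar = (f1+f2)/2`. The per-site Fst is
#' `(h_t - h_s) / h_t` where `h_t > 0`. Sites with zero depth in either
#' pool get `NA` components (skipped for Fst).
#'
#' @param ref1,alt1 Pool-1 ref/alt read counts (vectors).
#' @param ref2,alt2 Pool-2 ref/alt read counts.
#' @return A data.frame with columns `h_t`, `h_s`, `fst`.
#' @export
site_fst <- function(ref1, alt1, ref2, alt2) {
  d1 <- ref1 + alt1
  d2 <- ref2 + alt2
  f1 <- ifelse(d1 > 0, alt1 / d1, NA_real_)
  f2 <- ifelse(d2 > 0, alt2 / d2, NA_real_)
  h1 <- 2 * f1 * (1 - f1)
  h2 <- 2 * f2 * (1 - f2)
  h_s <- (h1 + h2) / 2
  fbar <- (f1 + f2) / 2
  h_t <- 2 * fbar * (1 - fbar)
  fst <- ifelse(!is.na(h_t) & h_t > 0, (h_t - h_s) / h_t, NA_real_)
  data.frame(h_t = h_t, h_s = h_s, fst = fst)
}

#' Window Fst (ratio-of-sums estimator)
#'
#' Aggregates the per-site components of [site_fst()] over a window as
#' `sum(h_t - h_s) / sum(h_t)`, over sites covered in both pools. The
#' result is clipped to `[0, 1]` (sampling noise can push the raw ratio
#' slightly negative).
#'
#' @param sites Sites in the window.
#' @return Window Fst in `[0, 1]`, or `NA` when no site contributes
#'   (`sum(h_t) == 0`).
#' @export
window_fst <- function(sites) {
  comp <- site_fst(sites$p1_ref, sites$p1_alt, sites$p2_ref, sites$p2_alt)
  ok <- !is.na(comp$h_t)
  st <- sum(comp$h_t[ok])
  if (!any(ok) || st == 0) return(NA_real_)
  min(max(sum(comp$h_t[ok] - comp$h_s[ok]) / st, 0), 1)
}

#' Genome-wide Z-transformation
#'
#' `z = (x - mean(x)) / sd(x)` with the sample (n-1) standard deviation,
#' computed over the non-`NA` values; `NA`s are passed through.
#'
#' @param values Numeric vector (the per-window values of one statistic).
#' @return Z-scores, same length as `values`.
#' @export
z_transform <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2L)
    stop("z_transform needs at least two defined values")
  s <- stats::sd(values[ok])
  if (s == 0)
    stop("z_transform: zero dispersion (all values identical)")
  (values - mean(values[ok])) / s
}

#' Compute per-window sweep statistics
#'
#' Runs the full window-statistics stage: per-pool Hp, window Fst, the
#' genome-wide Z-transforms ZHp (per pool) and ZFst over windows passing
#' the minimum-SNP filter, and the differential statistic
#' `D-ZHp = ZHp(pool 2) - ZHp(pool 1)`. With pool 1 the low-fecundity
#' pool and pool 2 the high-fecundity pool, strongly negative D-ZHp marks
#' windows homozygous specifically in pool 2.
#'
#' @param windows Windows with assigned sites (from [assign_sites()]).
#' @param sites The [pooled_sites()] data.frame the windows index into.
#' @param min_snps Windows with fewer SNPs are excluded from the
#'   Z-transforms and from downstream selection (default 20).
#' @return A data.frame with columns `chrom`, `start`, `end`, `terminal`,
#'   `snp_count`, `hp1`, `hp2`, `fst`, `zhp1`, `zhp2`, `zfst`, `d_zhp`,
#'   `eligible`.
#' @export
compute_window_stats <- function(windows, sites, min_snps = 20) {
  if (is.null(windows$site_idx))
    stop("windows lack site assignments; call assign_sites() first")
  n <- nrow(windows)
  hp1 <- hp2 <- fst <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    idx <- windows$site_idx[[i]]
    if (length(idx) == 0L) next
    w_sites <- sites[idx, , drop = FALSE]
    hp1[i] <- window_hp(w_sites, 1)
    hp2[i] <- window_hp(w_sites, 2)
    fst[i] <- window_fst(w_sites)
  }
  eligible <- windows$snp_count >= min_snps &
    !is.na(hp1) & !is.na(hp2) & !is.na(fst)
  zhp1 <- zhp2 <- zfst <- rep(NA_real_, n)
  if (sum(eligible) >= 2L) {
    zhp1[eligible] <- z_transform(hp1[eligible])
    zhp2[eligible] <- z_transform(hp2[eligible])
    zfst[eligible] <- z_transform(fst[eligible])
  }
  out <- data.frame(
    chrom = windows$chrom, start = windows$start, end = windows$end,
    terminal = windows$terminal, snp_count = windows$snp_count,
    hp1 = hp1, hp2 = hp2, fst = fst,
    zhp1 = zhp1, zhp2 = zhp2, zfst = zfst,
    d_zhp = zhp2 - zhp1, eligible = eligible,
    stringsAsFactors = FALSE
  )
  attr(out, "min_snps") <- min_snps
  attr(out, "pool_labels") <- attr(sites, "pool_labels")
  out
}

#' Differential heterozygosity D-ZHp
#'
#' `D-ZHp = ZHp(pool 2) - ZHp(pool 1)`. Antisymmetric under pool exchange;
#' `NA` when either side is undefined.
#'
#' @param zhp1,zhp2 Per-window ZHp of pool 1 and pool 2.
#' @return The per-window difference.
#' @export
d_zhp <- function(zhp1, zhp2) zhp2 - zhp1
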