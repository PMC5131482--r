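#' Configure the two-pool sweep simulator
#'
#' The simulator emulates the statistical structure of a two-pool
#' resequencing experiment: pools of 20 and 14 diploid individuals
#' sequenced to ~25x mean depth, a U-shaped neutral allele-frequency
#' spectrum (symmetric Beta), and optional planted sweep intervals inside
#' which one pool's allele frequencies are pushed toward fixation —
#' producing the low-Hp / high-Fst signature a sweep scan looks for.
#'
#' @param seed Integer RNG seed; the whole simulation is a pure function
#'   of the config including this seed.
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp
#'   (default: three 10-Mb chromosomes).
#' @param snp_density Expected SNP sites per bp (default 0.005, i.e.
#'   5 SNPs/kb).
#' @param pool_sizes Diploid individuals per pool (default `c(20, 14)`).
#' @param mean_depth Mean per-pool read depth (default 25).
#' @param beta_shape Shape of the symmetric Beta allele-frequency model
#'   (default 0.2: U-shaped spectrum).
#' @param sweeps Data.frame of planted sweeps with columns `chrom`,
#'   `start`, `end` (0-based half-open), `pool` (1 or 2) and `s`
#'   (fixation strength in `[0, 1]`); default none.
#' @param fixed_depth If `TRUE`, every site gets exactly `mean_depth`
#'   reads (otherwise Poisson around the mean).
#' @param qual_mean,qual_sd Call-quality model: phred qualities drawn
#'   normal and truncated at 0 (defaults 40 and 5).
#' @param ts_tv Target transition/transversion ratio used when drawing
#'   ref/alt allele pairs (default 2.3, typical of mammalian SNP calls).
#' @param pool_labels Display names of the two pools.
#' @return A validated config object of class `sweep_sim_config`.
#' @export
sweep_sim_config <- function(seed = 1L,
                             chrom_lengths = c(chr1 = 10e6, chr2 = 10e6,
                                               chr3 = 10e6),
                             snp_density = 0.005,
                             pool_sizes = c(20L, 14L),
                             mean_depth = 25,
                             beta_shape = 0.2,
                             sweeps = NULL,
                             fixed_depth = FALSE,
                             qual_mean = 40, qual_sd = 5,
                             ts_tv = 2.3,
                             pool_labels = c("LF", "HF")) {
  if (is.null(names(chrom_lengths)))
    stop("chrom_lengths must be a named vector")
  if (any(chrom_lengths < 1)) stop("chromosome lengths must be >= 1")
  if (snp_density <= 0) stop("snp_density must be positive")
  if (length(pool_sizes) != 2L || any(pool_sizes < 1))
    stop("pool_sizes must be two positive integers")
  if (mean_depth <= 0) stop("mean_depth must be positive")
  if (beta_shape <= 0) stop("beta_shape must be positive")
  if (is.null(sweeps))
    sweeps <- data.frame(chrom = character(), start = numeric(),
                         end = numeric(), pool = integer(), s = numeric(),
                         stringsAsFactors = FALSE)
  sweeps <- as.data.frame(sweeps)
  if (nrow(sweeps)) {
    if (!all(c("chrom", "start", "end", "pool", "s") %in% names(sweeps)))
      stop("sweeps needs columns chrom, start, end, pool, s")
    if (any(!sweeps$chrom %in% names(chrom_lengths)))
      stop("sweep interval on unknown chromosome")
    if (any(sweeps$start < 0 |
            sweeps$end > chrom_lengths[sweeps$chrom] |
            sweeps$end <= sweeps$start))
      stop("sweep intervals must lie within chromosome bounds")
    if (any(sweeps$s < 0 | sweeps$s > 1)) stop("sweep strength s must be in [0, 1]")
    if (any(!sweeps$pool %in% c(1L, 2L))) stop("sweep pool must be 1 or 2")
  }
  structure(list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
                 snp_density = snp_density, pool_sizes = as.integer(pool_sizes),
                 mean_depth = mean_depth, beta_shape = beta_shape,
                 sweeps = sweeps, fixed_depth = isTRUE(fixed_depth),
                 qual_mean = qual_mean, qual_sd = qual_sd, ts_tv = ts_tv,
                 pool_labels = pool_labels),
            class = "sweep_sim_config")
}

#' Plant evenly spaced sweep intervals
#'
#' Deterministically places `n` non-overlapping sweep intervals of equal
#' width across the genome, allocated to chromosomes proportionally to
#' length and centred on an even within-chromosome grid.
#'
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param n Number of intervals (default 20).
#' @param width Interval width in bp (default 300000).
#' @param pool Swept pool, 1 or 2 (default 2).
#' @param s Fixation strength (default 0.95).
#' @return A sweeps data.frame for [sweep_sim_config()].
#' @export
plant_sweeps <- function(chrom_lengths, n = 20, width = 300000, pool = 2,
                         s = 0.95) {
  alloc <- diff(round(cumsum(c(0, chrom_lengths)) / sum(chrom_lengths) * n))
  rows <- lapply(seq_along(chrom_lengths), function(i) {
    k <- alloc[i]
    if (k == 0) return(NULL)
    len <- chrom_lengths[i]
    centres <- (seq_len(k) - 0.5) / k * len
    start <- pmax(0, pmin(round(centres - width / 2), len - width))
    data.frame(chrom = names(chrom_lengths)[i], start = start,
               end = start + width, pool = pool, s = s,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate two-pool allele counts with planted sweeps
#'
#' Sites are placed uniformly at the configured density. Each site's
#' ancestral frequency `p` is drawn from `Beta(shape, shape)`; each pool's
#' frequency arises by binomial resampling of `2N` chromosomes. Inside a
#' sweep interval for pool `g` the pool frequency is pushed toward the
#' nearer of 0/1 by factor `s` (`f*(1-s)` below 0.5, `f + s*(1-f)`
#' otherwise). Read counts are binomial at a per-site depth (Poisson
#' around the mean, or fixed). Sites at which neither pool shows an
#' alternate read are not emitted (they would not be called as SNPs);
#' every emitted site's true frequencies are recorded in the truth table.
#'
#' @param config A [sweep_sim_config()].
#' @return A list of class `sweep_sim` with elements `sites`
#'   (a [pooled_sites()] data.frame), `truth` (data.frame `chrom`, `pos`,
#'   `p`, `f1`, `f2`), `sweeps` and `config`. Fully reproducible from the
#'   config seed; the caller's RNG state is left untouched.
#' @export
simulate_pools <- function(config) {
  if (!inherits(config, "sweep_sim_config"))
    stop("config must come from sweep_sim_config()")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  p_ts <- config$ts_tv / (config$ts_tv + 1)
  per_chrom <- lapply(names(config$chrom_lengths), function(cn) {
    len <- config$chrom_lengths[[cn]]
    n <- round(len * config$snp_density)
    pos <- sort(sample.int(len, n))
    p <- stats::rbeta(n, config$beta_shape, config$beta_shape)
    n1 <- 2L * config$pool_sizes[1]
    n2 <- 2L * config$pool_sizes[2]
    f1 <- stats::rbinom(n, n1, p) / n1
    f2 <- stats::rbinom(n, n2, p) / n2
    sw <- config$sweeps[config$sweeps$chrom == cn, , drop = FALSE]
    for (j in seq_len(nrow(sw))) {
      in_sw <- pos - 1 >= sw$start[j] & pos - 1 < sw$end[j]
      s <- sw$s[j]
      if (sw$pool[j] == 1L)
        f1[in_sw] <- ifelse(f1[in_sw] < 0.5, f1[in_sw] * (1 - s),
                            f1[in_sw] + s * (1 - f1[in_sw]))
      else
        f2[in_sw] <- ifelse(f2[in_sw] < 0.5, f2[in_sw] * (1 - s),
                            f2[in_sw] + s * (1 - f2[in_sw]))
    }
    d1 <- if (config$fixed_depth) rep(round(config$mean_depth), n)
          else stats::rpois(n, config$mean_depth)
    d2 <- if (config$fixed_depth) rep(round(config$mean_depth), n)
          else stats::rpois(n, config$mean_depth)
    a1 <- stats::rbinom(n, d1, f1)
    a2 <- stats::rbinom(n, d2, f2)
    # ref/alt pair: random ref base, alt a transition with prob ts/(ts+1)
    bases <- c("A", "C", "G", "T")
    transition <- c(A = "G", G = "A", C = "T", T = "C")
    ref <- sample(bases, n, replace = TRUE)
    is_ts <- stats::runif(n) < p_ts
    alt <- character(n)
    alt[is_ts] <- transition[ref[is_ts]]
    tv_pick <- stats::runif(n) < 0.5
    tv_opts <- rbind(c("C", "T"), c("A", "G"), c("C", "T"), c("A", "G"))
    alt[!is_ts] <- tv_opts[cbind(match(ref[!is_ts], bases),
                                 1L + tv_pick[!is_ts])]
    qual <- pmax(0, round(stats::rnorm(n, config$qual_mean, config$qual_sd)))
    list(chrom = rep(cn, n), pos = pos, ref = ref, alt = alt,
         p = p, f1 = f1, f2 = f2,
         p1_ref = d1 - a1, p1_alt = a1, p2_ref = d2 - a2, p2_alt = a2,
         qual = qual)
  })
  g <- function(fld) unlist(lapply(per_chrom, `[[`, fld), use.names = FALSE)
  called <- g("p1_alt") > 0 | g("p2_alt") > 0
  sites <- pooled_sites(
    chrom = g("chrom")[called], pos = g("pos")[called],
    ref = g("ref")[called], alt = g("alt")[called],
    p1_ref = g("p1_ref")[called], p1_alt = g("p1_alt")[called],
    p2_ref = g("p2_ref")[called], p2_alt = g("p2_alt")[called],
    qual = g("qual")[called], pool_labels = config$pool_labels
  )
  truth <- data.frame(chrom = g("chrom")[called], pos = g("pos")[called],
                      p = g("p")[called], f1 = g("f1")[called],
                      f2 = g("f2")[called], stringsAsFactors = FALSE)
  structure(list(sites = sites, truth = truth, sweeps = config$sweeps,
                 config = config), class = "sweep_sim")
}

#' Sweep-recovery experiment
#'
#' Runs the full scan on one simulated dataset and scores it against the
#' planted truth: *sensitivity* is the fraction of planted sweep intervals
#' overlapped by at least one candidate window of the swept pool;
#' the *false positive rate* is the fraction of candidate windows (of the
#' swept pools) overlapping no planted interval. With no planted sweeps
#' the sensitivity is `NA` and the per-pool candidate-window fraction is
#' reported instead (null calibration).
#'
#' @param config A [sweep_sim_config()].
#' @param window_size,step_size Window scheme in bp (defaults 150000 and
#'   75000).
#' @param min_snps Minimum SNPs per window (default 20).
#' @param zhp_quantile,zfst_quantile Selection quantiles (defaults 0.05).
#' @param min_depth,min_qual Site filters (defaults 4 and 20).
#' @return A list: `sensitivity`, `false_positive_rate`,
#'   `candidate_fraction` (candidates / eligible windows, per pool),
#'   `n_candidates`, `n_sweeps_recovered`, `n_sweeps`, `n_windows_eligible`,
#'   `seed`.
#' @export
recovery_experiment <- function(config, window_size = 150000,
                                step_size = 75000, min_snps = 20,
                                zhp_quantile = 0.05, zfst_quantile = 0.05,
                                min_depth = 4, min_qual = 20) {
  sim <- simulate_pools(config)
  chroms <- chrom_table(names(config$chrom_lengths), config$chrom_lengths)
  sites <- filter_sites(sim$sites, min_depth, min_qual)
  win <- assign_sites(make_windows(chroms, window_size, step_size), sites)
  stats <- compute_window_stats(win, sites, min_snps)

  cand <- lapply(1:2, function(pl)
    select_candidates(stats, pl, zhp_quantile, zfst_quantile))
  n_elig <- sum(stats$eligible)
  cand_frac <- vapply(cand, nrow, 0L) / n_elig

  sw <- sim$sweeps
  if (nrow(sw) == 0L) {
    return(list(sensitivity = NA_real_, false_positive_rate = NA_real_,
                candidate_fraction = cand_frac,
                n_candidates = vapply(cand, nrow, 0L),
                n_sweeps_recovered = 0L, n_sweeps = 0L,
                n_windows_eligible = n_elig, seed = config$seed))
  }
  overlaps <- function(w, iv)  # any 0-based half-open overlap, same chrom
    any(w$chrom == iv$chrom & w$start < iv$end & iv$start < w$end)
  swept_pools <- unique(sw$pool)
  recovered <- vapply(seq_len(nrow(sw)), function(j) {
    cw <- cand[[sw$pool[j]]]
    nrow(cw) > 0 && overlaps(cw, sw[j, ])
  }, TRUE)
  all_cand <- do.call(rbind, lapply(swept_pools, function(pl)
    cand[[pl]][, c("chrom", "start", "end")]))
  fp <- if (nrow(all_cand)) {
    hits_truth <- vapply(seq_len(nrow(all_cand)), function(k)
      any(all_cand$chrom[k] == sw$chrom & all_cand$start[k] < sw$end &
            sw$start < all_cand$end[k]), TRUE)
    mean(!hits_truth)
  } else NA_real_
  list(sensitivity = mean(recovered), false_positive_rate = fp,
       candidate_fraction = cand_frac,
       n_candidates = vapply(cand, nrow, 0L),
       n_sweeps_recovered = sum(recovered), n_sweeps = nrow(sw),
       n_windows_eligible = n_elig, seed = config$seed)
}
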