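#' Build a pipeline configuration
#'
#' Either an explicit list of arguments or a YAML file (every key below a
#' top-level `sweepscan:` mapping or at top level). Input is one of:
#' `sync` (+ `pool_labels`), `vcf` (+ `sample_names`), or `simulate`
#' (a [sweep_sim_config()] or a list of its arguments).
#'
#' @param ... Configuration fields: `sync`, `vcf`, `sample_names`,
#'   `pool_labels`, `chrom_table` (path, required for file input),
#'   `genes` (BED path, optional), `simulate`, `window_size`, `step_size`,
#'   `min_snps`, `zhp_quantile`, `zfst_quantile`, `min_depth`, `min_qual`,
#'   `out_dir`.
#' @param yaml Optional path to a YAML file supplying the fields.
#' @return A `pipeline_config` list with defaults filled in.
#' @export
pipeline_config <- function(..., yaml = NULL) {
  cfg <- list(...)
  if (!is.null(yaml)) {
    y <- yaml::read_yaml(yaml)
    if (!is.null(y$sweepscan)) y <- y$sweepscan
    cfg <- utils::modifyList(y, cfg)
  }
  defaults <- list(window_size = 150000, step_size = 75000, min_snps = 20,
                   zhp_quantile = 0.05, zfst_quantile = 0.05,
                   min_depth = 4, min_qual = 20,
                   pool_labels = c("pool1", "pool2"), out_dir = ".")
  cfg <- utils::modifyList(defaults, cfg)
  n_inputs <- sum(!is.null(cfg$sync), !is.null(cfg$vcf), !is.null(cfg$simulate))
  if (n_inputs != 1L)
    stop("exactly one input must be given: sync, vcf, or simulate")
  if (!is.null(cfg$simulate) && !inherits(cfg$simulate, "sweep_sim_config"))
    cfg$simulate <- do.call(sweep_sim_config, cfg$simulate)
  structure(cfg, class = "pipeline_config")
}

#' Run the full sweep-scan pipeline
#'
#' Executes ingest -> site filter -> windows -> window statistics ->
#' candidate selection -> unique/shared partition -> gene overlap, writes
#' all tables plus a JSON run manifest (parameters, input checksums, and
#' record counts at every stage) into `config$out_dir`, and returns the
#' results invisibly. The pipeline is a pure function of (inputs, config):
#' identical runs produce byte-identical tables.
#'
#' @param config A [pipeline_config()] (or a YAML path).
#' @return Invisibly, a list: `sites`, `stats`, `candidates` (per pool),
#'   `partition`, `gene_hits`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- pipeline_config(yaml = config)
  if (!inherits(config, "pipeline_config"))
    stop("config must come from pipeline_config()")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(parameters = config[setdiff(names(config),
                                               c("simulate"))],
                   inputs = list(), counts = list())

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }

  if (!is.null(config$simulate)) {
    sim <- stage("simulate", simulate_pools(config$simulate))
    sites_raw <- sim$sites
    chroms <- chrom_table(names(config$simulate$chrom_lengths),
                          config$simulate$chrom_lengths)
    manifest$inputs$simulate_seed <- config$simulate$seed
    manifest$counts$simulated_sites <- nrow(sites_raw)
  } else {
    if (is.null(config$chrom_table))
      stop("file input requires a chrom_table path")
    chroms <- stage("ingest", read_chrom_table(config$chrom_table))
    manifest$inputs$chrom_table_md5 <-
      unname(tools::md5sum(config$chrom_table))
    if (!is.null(config$sync)) {
      sites_raw <- stage("ingest", read_sync(config$sync, config$pool_labels))
      manifest$inputs$sync_md5 <- unname(tools::md5sum(config$sync))
    } else {
      sites_raw <- stage("ingest",
                         read_vcf_allele_depths(config$vcf,
                                                config$sample_names))
      manifest$inputs$vcf_md5 <- unname(tools::md5sum(config$vcf))
    }
    manifest$counts$sites_skipped_on_read <-
      as.list(attr(sites_raw, "skipped"))
  }
  manifest$counts$sites_read <- nrow(sites_raw)

  sites <- stage("filter",
                 filter_sites(sites_raw, config$min_depth, config$min_qual))
  manifest$counts$sites_after_filter <- nrow(sites)

  win <- stage("windows",
               assign_sites(make_windows(chroms, config$window_size,
                                         config$step_size), sites))
  manifest$counts$windows <- nrow(win)

  stats <- stage("stats", compute_window_stats(win, sites, config$min_snps))
  manifest$counts$windows_eligible <- sum(stats$eligible)
  if (sum(stats$eligible) == 0L)
    stop("pipeline stage 'stats': no eligible windows ",
         "(min_snps = ", config$min_snps, " exceeds every window's SNP count)")

  cands <- stage("select", lapply(1:2, function(pl)
    select_candidates(stats, pl, config$zhp_quantile, config$zfst_quantile)))
  labs <- attr(sites, "pool_labels")
  if (is.null(labs)) labs <- config$pool_labels
  names(cands) <- labs
  manifest$counts$candidates <- lapply(cands, nrow)

  part <- stage("partition",
                partition_unique_shared(cands[[1]], cands[[2]], labs))

  genes <- NULL
  gene_hits <- NULL
  if (!is.null(config$genes)) {
    genes <- stage("genes", read_bed(config$genes))
    manifest$inputs$genes_md5 <- unname(tools::md5sum(config$genes))
    all_cand <- merge_windows(rbind(cands[[1]][, c("chrom", "start", "end")],
                                    cands[[2]][, c("chrom", "start", "end")]))
    gene_hits <- stage("genes",
                       suppressWarnings(overlap_genes(all_cand, genes)))
    manifest$counts$candidate_genes <-
      length(unique(unlist(gene_hits, use.names = FALSE)))
  }

  # artifacts
  write_window_table(stats, file.path(config$out_dir, "windows.tsv"))
  for (pl in 1:2) {
    p <- file.path(config$out_dir,
                   sprintf("candidates_%s.tsv", labs[pl]))
    write_window_table(cands[[pl]], p)
  }
  write_partition <- function(part, path) {
    rows <- rbind(
      if (nrow(part$unique1)) cbind(part$unique1, group = labs[1], status = "unique"),
      if (nrow(part$unique2)) cbind(part$unique2, group = labs[2], status = "unique"),
      if (nrow(part$shared)) cbind(part$shared, status = "shared")
    )
    if (is.null(rows))
      rows <- data.frame(chrom = character(), start = numeric(),
                         end = numeric(), group = character(),
                         status = character())
    if (!is.null(gene_hits)) {
      key <- sprintf("%s:%s-%s", rows$chrom,
                     format(rows$start, scientific = FALSE, trim = TRUE),
                     format(rows$end, scientific = FALSE, trim = TRUE))
      rows$genes <- vapply(key, function(k)
        paste(gene_hits[[k]], collapse = ","), "", USE.NAMES = FALSE)
      rows$genes[is.na(rows$genes)] <- ""
    }
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_partition(part, file.path(config$out_dir, "report.tsv"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")

  invisible(list(sites = sites, stats = stats, candidates = cands,
                 partition = part, gene_hits = gene_hits,
                 manifest = manifest))
}

#' Manhattan-style plots of the scan statistics
#'
#' Writes two genome-wide plots — D-ZHp and ZFst against cumulative genome
#' coordinate — with candidate windows highlighted. Purely presentational.
#'
#' @param stats Window statistics from [compute_window_stats()].
#' @param out_dir Output directory.
#' @param candidates Optional candidate window data.frame to highlight.
#' @return Character vector of the files written, invisibly.
#' @export
plot_scan <- function(stats, out_dir = ".", candidates = NULL) {
  if (nrow(stats) == 0L) stop("stats is empty")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  chroms <- unique(stats$chrom)
  offs <- stats::setNames(cumsum(c(0, vapply(chroms, function(cn)
    max(stats$end[stats$chrom == cn]), 0)))[seq_along(chroms)], chroms)
  df <- stats
  df$gpos <- (df$start + df$end) / 2 + offs[df$chrom]
  df$cand <- FALSE
  if (!is.null(candidates) && nrow(candidates))
    df$cand <- mapply(function(cn, s, e) any(
      candidates$chrom == cn & candidates$start < e & s < candidates$end),
      df$chrom, df$start, df$end)
  ext <- if (isTRUE(capabilities("png")) || isTRUE(capabilities("cairo")))
    "png" else "pdf"
  dev <- if (ext == "pdf") grDevices::pdf else NULL
  files <- character()
  for (statname in c("d_zhp", "zfst")) {
    dd <- df[!is.na(df[[statname]]), ]
    dd$y <- dd[[statname]]
    p <- ggplot2::ggplot(dd,
                         ggplot2::aes(x = gpos, y = y, colour = chrom)) +
      ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
      ggplot2::geom_point(data = dd[dd$cand, ], colour = "red",
                          size = 1.2) +
      ggplot2::labs(x = "genome position (bp, cumulative)",
                    y = toupper(gsub("_", "-", statname))) +
      ggplot2::theme_minimal()
    f <- file.path(out_dir, paste0("scan_", statname, ".", ext))
    ggplot2::ggsave(f, p, width = 9, height = 3, dpi = 150, device = dev)
    files <- c(files, f)
  }
  invisible(files)
}
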