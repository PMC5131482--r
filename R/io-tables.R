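#' Read a chromosome length table
#'
#' Two-column tab-separated text: chromosome name, length in bp. Order is
#' preserved; it defines the genome order used by the window generator.
#'
#' @param path Path to the TSV (no header).
#' @return A data.frame with columns `chrom`, `length`.
#' @export
read_chrom_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"),
                          stringsAsFactors = FALSE)
  chrom_table(df$chrom, df$length)
}

#' Construct and validate a chromosome table
#'
#' @param chrom Chromosome names (unique).
#' @param length Lengths in bp (>= 1).
#' @return A data.frame with columns `chrom`, `length`.
#' @export
chrom_table <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom))
    stop("duplicate chromosome name(s): ",
         paste(unique(chrom[duplicated(chrom)]), collapse = ", "))
  if (any(length < 1) || anyNA(length))
    stop("chromosome lengths must be >= 1")
  data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE)
}

#' Read gene intervals from a BED file
#'
#' Standard BED semantics: 0-based half-open `[start, end)` intervals.
#' Only the first four columns (chrom, start, end, name) are used.
#'
#' @param path Path to a BED file.
#' @return A data.frame with columns `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED file must have at least 3 columns")
  out <- data.frame(chrom = as.character(df[[1]]),
                    start = as.numeric(df[[2]]),
                    end = as.numeric(df[[3]]),
                    name = if (ncol(df) >= 4L) as.character(df[[4]])
                           else paste0("feature", seq_len(nrow(df))),
                    stringsAsFactors = FALSE)
  if (any(out$end <= out$start)) stop("BED intervals must have end > start")
  out
}

# column layout of the window report (shared by writer and reader)
window_table_cols <- function() {
  c("chrom", "start", "end", "snp_count", "hp1", "hp2", "zhp1", "zhp2",
    "fst", "zfst", "d_zhp", "eligible")
}

#' Write the per-window statistics report
#'
#' Tab-separated, one row per window, full double precision (round-trips
#' losslessly through [read_window_table()]).
#'
#' @param stats A window statistics data.frame from [compute_window_stats()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_window_table <- function(stats, path) {
  cols <- window_table_cols()
  missing <- setdiff(cols, names(stats))
  if (length(missing))
    stop("window stats lack column(s): ", paste(missing, collapse = ", "))
  out <- stats[, cols, drop = FALSE]
  num <- vapply(out, is.double, TRUE)
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  out[num] <- lapply(out[num], function(x) { x[x == "nan" | x == "NA"] <- "NA"; x })
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a window statistics report written by [write_window_table()]
#'
#' @param path Path to the TSV.
#' @return A data.frame with the window report columns.
#' @export
read_window_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  df$eligible <- as.logical(df$eligible)
  df
}
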