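#' Read a FASTQ file into a list of reads
#'
#' Each read is a list with `id`, `bases` (character string over A/C/G/T/N)
#' and `quals` (integer phred scores, one per base, phred+33 on disk).
#'
#' @param path Path to an uncompressed or gzipped FASTQ.
#' @return A list of reads.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  q <- S4Vectors::mcols(x)$qualities
  qlist <- as(Biostrings::PhredQuality(q), "IntegerList")
  ids <- names(x)
  lapply(seq_along(x), function(i)
    list(id = ids[i], bases = as.character(x[[i]]), quals = as.integer(qlist[[i]])))
}

#' Write reads to FASTQ (phred+33)
#'
#' @param reads A list of reads as produced by [read_fastq()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in reads) {
    writeLines(c(paste0("@", r$id), r$bases, "+",
                 intToUtf8(r$quals + 33L)), con)
  }
  invisible(path)
}

# longest exact substring of `adapter` occurring in `bases`
longest_adapter_match <- function(bases, adapter) {
  la <- nchar(adapter)
  lb <- nchar(bases)
  for (len in seq(min(la, lb), 1L)) {
    subs <- unique(substring(adapter, seq_len(la - len + 1L),
                             seq_len(la - len + 1L) + len - 1L))
    for (s in subs)
      if (grepl(s, bases, fixed = TRUE)) return(len)
  }
  0L
}

read_fails_qc <- function(read, max_lowq_frac, lowq_threshold, max_n_frac,
                          adapter_seq, max_adapter_nt) {
  n <- nchar(read$bases)
  if (n == 0L) return(TRUE)
  # (a) more than max_lowq_frac of bases at phred <= lowq_threshold
  if (mean(read$quals <= lowq_threshold) > max_lowq_frac) return(TRUE)
  # (b) at least max_n_frac of bases uncalled (N)
  n_frac <- lengths(regmatches(read$bases, gregexpr("N", read$bases, fixed = TRUE))) / n
  if (n_frac >= max_n_frac) return(TRUE)
  # (c) longest exact adapter match strictly longer than max_adapter_nt
  if (!is.null(adapter_seq) &&
      longest_adapter_match(read$bases, adapter_seq) > max_adapter_nt)
    return(TRUE)
  FALSE
}

#' Quality-filter raw reads
#'
#' Removes a read when any of three rules fires:
#' (a) more than `max_lowq_frac` of its bases have phred quality
#' `<= lowq_threshold`; (b) at least `max_n_frac` of its bases are `N`;
#' (c) its longest exact substring match to the adapter sequence is longer
#' than `max_adapter_nt` nucleotides. The defaults encode the common
#' resequencing pre-alignment filter (> 50% of bases at phred <= 5;
#' >= 10% N; > 10 nt of adapter). For paired input pass the mates in
#' `mates`: if either member of a pair fails, the pair is removed.
#'
#' @param reads List of reads (see [read_fastq()]).
#' @param max_lowq_frac Rule (a) fraction, strict `>` (default 0.5).
#' @param lowq_threshold Rule (a) phred cutoff, `<=` (default 5).
#' @param max_n_frac Rule (b) fraction, `>=` (default 0.10).
#' @param adapter_seq Adapter sequence for rule (c); `NULL` disables (c).
#' @param max_adapter_nt Rule (c) length, strict `>` (default 10).
#' @param mates Optional list of mate reads, same length as `reads`.
#' @return The kept reads, or if `mates` is given a list with elements
#'   `first` and `second` (kept pairs).
#' @export
filter_reads <- function(reads, max_lowq_frac = 0.5, lowq_threshold = 5,
                         max_n_frac = 0.10, adapter_seq = NULL,
                         max_adapter_nt = 10, mates = NULL) {
  if (!is.null(adapter_seq) && !nzchar(adapter_seq))
    stop("adapter_seq must be a non-empty sequence (or NULL to disable rule c)")
  fails <- vapply(reads, read_fails_qc, TRUE, max_lowq_frac, lowq_threshold,
                  max_n_frac, adapter_seq, max_adapter_nt)
  if (is.null(mates)) return(reads[!fails])
  if (length(mates) != length(reads))
    stop("mates must have the same length as reads")
  fails2 <- vapply(mates, read_fails_qc, TRUE, max_lowq_frac, lowq_threshold,
                   max_n_frac, adapter_seq, max_adapter_nt)
  keep <- !(fails | fails2)
  list(first = reads[keep], second = mates[keep])
}
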