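#' Read transcript models from a GFF/GTF file
#'
#' Builds [transcript_model()] objects from `exon` and `CDS` records,
#' grouped by transcript identifier (`transcript_id` attribute for GTF,
#' `Parent` for GFF3). Transcripts without CDS records are skipped with a
#' warning (the effect classifier needs a coding frame).
#'
#' @param path Path to a GFF3 or GTF file.
#' @param genome Optional named [Biostrings::DNAStringSet] (e.g. from
#'   [Biostrings::readDNAStringSet()]) used to validate start/stop codons.
#' @return A named list of [transcript_model()] objects.
#' @export
read_transcript_models <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path)
  mc <- S4Vectors::mcols(gr)
  tx_id <- if (!is.null(mc$transcript_id)) as.character(mc$transcript_id)
           else if (!is.null(mc$Parent)) as.character(mc$Parent)
           else stop("GFF/GTF records carry neither transcript_id nor Parent")
  type <- as.character(mc$type)
  keep <- type %in% c("exon", "CDS")
  gr <- gr[keep]
  tx_id <- tx_id[keep]
  type <- type[keep]
  out <- list()
  for (id in unique(tx_id)) {
    sel <- tx_id == id
    ex <- gr[sel & type == "exon"]
    cds <- gr[sel & type == "CDS"]
    if (length(cds) == 0L) {
      warning("transcript ", id, " has no CDS records; skipped")
      next
    }
    if (length(ex) == 0L) ex <- cds
    out[[id]] <- transcript_model(
      name = id,
      chrom = as.character(GenomicRanges::seqnames(ex))[1],
      strand = as.character(BiocGenerics::strand(ex))[1],
      exons = data.frame(start = GenomicRanges::start(ex) - 1,
                         end = as.numeric(GenomicRanges::end(ex))),
      cds_start = min(GenomicRanges::start(cds)) - 1,
      cds_end = max(GenomicRanges::end(cds)),
      genome = genome
    )
  }
  out
}
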