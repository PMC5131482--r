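#' Read pooled allele depths from a VCF
#'
#' Alternate ingestion route to [read_sync()] for variant callers that emit
#' one VCF sample per pool with per-sample allele depths (`FORMAT/AD`).
#' Only biallelic SNP records are used; indels, multiallelic records and
#' records lacking an AD value in either pool are skipped and tallied in
#' the `skipped` attribute.
#'
#' @param path Path to a VCF (plain text or bgzip).
#' @param sample_names Length-2 character vector: the VCF sample names of
#'   pool 1 and pool 2, in that order.
#' @return A [pooled_sites()] data.frame (`qual` from the VCF QUAL column)
#'   with attribute `skipped`.
#' @export
read_vcf_allele_depths <- function(path, sample_names) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  if (length(sample_names) != 2L)
    stop("sample_names must name exactly two pool samples")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  have <- colnames(v@gt)[-1]
  missing <- setdiff(sample_names, have)
  if (length(missing))
    stop("sample(s) not in VCF: ", paste(missing, collapse = ", "),
         " (have: ", paste(have, collapse = ", "), ")")

  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = 7L, dimnames = list(NULL, colnames(vcfR::getFIX(v))))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(alt) & ref %in% c("A", "C", "G", "T") &
    alt %in% c("A", "C", "G", "T")
  skip <- c(non_snp = sum(!snp), missing_ad = 0L)

  ad <- vcfR::extract.gt(v, element = "AD")
  parse_ad <- function(x) {
    parts <- strsplit(x, ",", fixed = TRUE)
    r <- suppressWarnings(as.integer(vapply(parts, function(p) p[1], "")))
    a <- suppressWarnings(as.integer(vapply(parts, function(p)
      if (length(p) >= 2L) p[2] else NA_character_, "")))
    cbind(ref = r, alt = a)
  }
  ad1 <- parse_ad(ad[, sample_names[1]])
  ad2 <- parse_ad(ad[, sample_names[2]])
  has_ad <- !is.na(ad1[, 1]) & !is.na(ad1[, 2]) &
    !is.na(ad2[, 1]) & !is.na(ad2[, 2])
  skip["missing_ad"] <- sum(snp & !has_ad)
  keep <- snp & has_ad

  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  out <- pooled_sites(
    chrom = fix[keep, "CHROM"], pos = as.integer(fix[keep, "POS"]),
    ref = ref[keep], alt = alt[keep],
    p1_ref = ad1[keep, 1], p1_alt = ad1[keep, 2],
    p2_ref = ad2[keep, 1], p2_alt = ad2[keep, 2],
    qual = qual[keep], pool_labels = sample_names
  )
  if (sum(skip) > 0L)
    message("read_vcf_allele_depths: skipped ", sum(skip), " record(s) (",
            paste(names(skip), skip, sep = "=", collapse = ", "), ")")
  attr(out, "skipped") <- skip
  out
}
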