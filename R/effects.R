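#' Construct a transcript model
#'
#' Coordinates are 0-based half-open genomic intervals. The CDS is the
#' part of the exon chain between `cds_start` and `cds_end`; its spliced
#' length must be a multiple of 3. When a genome is supplied the CDS is
#' additionally checked for a leading start codon and trailing stop codon
#' on the coding strand (warning only — annotation sets routinely contain
#' incomplete models).
#'
#' @param name Transcript identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Data.frame/matrix with columns `start`, `end`: disjoint,
#'   sorted exon intervals.
#' @param cds_start,cds_end Genomic bounds of the CDS (0-based half-open).
#' @param genome Optional named [Biostrings::DNAStringSet] for validation.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(name, chrom, strand, exons, cds_start, cds_end,
                             genome = NULL) {
  exons <- as.data.frame(exons)[, c("start", "end")]
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (any(exons$end <= exons$start)) stop("exon intervals must have end > start")
  if (nrow(exons) > 1L && any(exons$start[-1] < exons$end[-nrow(exons)]))
    stop("exons must be non-overlapping")
  if (cds_end <= cds_start) stop("cds_end must exceed cds_start")
  tx <- structure(list(name = name, chrom = chrom, strand = strand,
                       exons = exons, cds_start = cds_start,
                       cds_end = cds_end),
                  class = "transcript_model")
  cds_len <- sum(pmax(0, pmin(exons$end, cds_end) - pmax(exons$start, cds_start)))
  if (cds_len %% 3 != 0)
    stop("CDS length (", cds_len, ") is not a multiple of 3 for ", name)
  if (!is.null(genome)) {
    cds <- spliced_cds(tx, genome)
    if (substr(cds, 1, 3) != "ATG")
      warning(name, ": CDS does not begin with a start codon")
    last <- substr(cds, nchar(cds) - 2, nchar(cds))
    if (!last %in% c("TAA", "TAG", "TGA"))
      warning(name, ": CDS does not end with a stop codon")
  }
  tx
}

# CDS exon intervals (genomic, 0-based half-open), 5'->3' on the genome
cds_intervals <- function(tx) {
  s <- pmax(tx$exons$start, tx$cds_start)
  e <- pmin(tx$exons$end, tx$cds_end)
  keep <- e > s
  data.frame(start = s[keep], end = e[keep])
}

# spliced CDS on the coding strand, as a character string
spliced_cds <- function(tx, genome) {
  iv <- cds_intervals(tx)
  chrseq <- genome[[tx$chrom]]
  parts <- vapply(seq_len(nrow(iv)), function(i)
    as.character(Biostrings::subseq(chrseq, iv$start[i] + 1, iv$end[i])), "")
  cds <- paste(parts, collapse = "")
  if (tx$strand == "-")
    cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  cds
}

# genomic position (1-based) -> 0-based offset into the spliced CDS
# (coding-strand orientation); NA if outside the CDS
cds_offset <- function(tx, pos) {
  iv <- cds_intervals(tx)
  p0 <- pos - 1
  off <- NA_integer_
  cum <- 0L
  for (i in seq_len(nrow(iv))) {
    if (p0 >= iv$start[i] && p0 < iv$end[i]) {
      off <- cum + as.integer(p0 - iv$start[i])
      break
    }
    cum <- cum + as.integer(iv$end[i] - iv$start[i])
  }
  if (is.na(off)) return(NA_integer_)
  total <- sum(iv$end - iv$start)
  if (tx$strand == "-") off <- as.integer(total - off - 1L)
  off
}

comp_base <- c(A = "T", C = "G", G = "C", T = "A")

#' Coding consequence of a SNP within a CDS
#'
#' Builds the reference codon from the spliced CDS (reverse-complemented
#' for minus-strand transcripts), substitutes the alternate base, and
#' translates both with the standard nuclear genetic code.
#'
#' @param site One-row [pooled_sites()] data.frame (or list with `chrom`,
#'   `pos`, `ref`, `alt`).
#' @param tx A [transcript_model()].
#' @param genome Named [Biostrings::DNAStringSet].
#' @return One of `"synonymous"`, `"nonsynonymous"`, `"stopgain"`,
#'   `"stoploss"`.
#' @export
coding_effect <- function(site, tx, genome) {
  if (site$chrom != tx$chrom)
    stop("site chromosome does not match transcript ", tx$name)
  off <- cds_offset(tx, site$pos)
  if (is.na(off)) stop("site at ", site$pos, " is not within the CDS of ", tx$name)
  cds <- spliced_cds(tx, genome)
  ref_b <- site$ref
  alt_b <- site$alt
  if (tx$strand == "-") {
    ref_b <- comp_base[[ref_b]]
    alt_b <- comp_base[[alt_b]]
  }
  if (substr(cds, off + 1, off + 1) != ref_b)
    stop("reference allele mismatch at CDS offset ", off, " of ", tx$name,
         " (CDS has ", substr(cds, off + 1, off + 1), ", site ref is ", ref_b, ")")
  codon_i <- off %/% 3L
  codon <- substr(cds, codon_i * 3L + 1L, codon_i * 3L + 3L)
  mut <- codon
  substr(mut, off %% 3L + 1L, off %% 3L + 1L) <- alt_b
  aa_ref <- Biostrings::GENETIC_CODE[[codon]]
  aa_alt <- Biostrings::GENETIC_CODE[[mut]]
  if (aa_ref != "*" && aa_alt == "*") return("stopgain")
  if (aa_ref == "*" && aa_alt != "*") return("stoploss")
  if (aa_ref == aa_alt) "synonymous" else "nonsynonymous"
}

#' Classify a site by genic context
#'
#' Categories follow standard variant-annotation conventions, with
#' precedence `exonic > splicing > intronic > upstream/downstream >
#' intergenic` across all transcripts: *splicing* is within 2 bp of an
#' exon-intron boundary on the intron side; *upstream*/*downstream* is
#' within `flank` bp of the transcript start/end respecting strand; a site
#' upstream of one transcript and downstream of another is
#' `"upstream/downstream"`.
#'
#' @param chrom,pos Site coordinates (`pos` 1-based).
#' @param transcripts List of [transcript_model()] objects.
#' @param flank Upstream/downstream window in bp (default 1000).
#' @param splice_bp Splicing window in bp into the intron (default 2).
#' @return One of `"exonic"`, `"splicing"`, `"intronic"`, `"upstream"`,
#'   `"downstream"`, `"upstream/downstream"`, `"intergenic"`.
#' @export
classify_site <- function(chrom, pos, transcripts, flank = 1000,
                          splice_bp = 2) {
  p0 <- pos - 1
  any_splice <- any_intron <- FALSE
  up <- down <- FALSE
  for (tx in transcripts) {
    if (tx$chrom != chrom) next
    ex <- tx$exons
    tx_start <- min(ex$start)
    tx_end <- max(ex$end)
    if (p0 >= tx_start && p0 < tx_end) {
      in_exon <- any(p0 >= ex$start & p0 < ex$end)
      if (in_exon) return("exonic")
      # intronic; splice-site if within splice_bp of a flanking exon edge
      d_left <- p0 - ex$end[ex$end <= p0]       # distance past an exon end
      d_right <- ex$start[ex$start > p0] - p0   # distance to next exon start
      near <- c(d_left + 1, d_right)            # 1-based depth into intron
      if (any(near <= splice_bp)) any_splice <- TRUE else any_intron <- TRUE
    } else {
      before <- p0 < tx_start && tx_start - p0 <= flank
      after <- p0 >= tx_end && p0 - tx_end < flank
      if (tx$strand == "+") {
        if (before) up <- TRUE
        if (after) down <- TRUE
      } else {
        if (before) down <- TRUE
        if (after) up <- TRUE
      }
    }
  }
  if (any_splice) return("splicing")
  if (any_intron) return("intronic")
  if (up && down) return("upstream/downstream")
  if (up) return("upstream")
  if (down) return("downstream")
  "intergenic"
}

#' Transition/transversion ratio
#'
#' Transitions are `A<->G` and `C<->T`; all other ref/alt pairs are
#' transversions.
#'
#' @param sites A [pooled_sites()] data.frame.
#' @return `(#transitions) / (#transversions)`; `NA` with a warning when
#'   there are no transversions.
#' @export
ts_tv_ratio <- function(sites) {
  pair <- paste0(sites$ref, sites$alt)
  ts <- pair %in% c("AG", "GA", "CT", "TC")
  n_tv <- sum(!ts)
  if (n_tv == 0L) {
    warning("no transversions: ts/tv undefined")
    return(NA_real_)
  }
  sum(ts) / n_tv
}

#' Heterozygosity rate per thousand bp
#'
#' Number of sites at which the chosen pool carries *both* alleles at
#' non-zero read count, per kb of genome.
#'
#' @param sites A [pooled_sites()] data.frame.
#' @param genome_length Denominator in bp (> 0).
#' @param pool Pool selector.
#' @return Heterozygous-site rate in permille.
#' @export
het_rate_permille <- function(sites, genome_length, pool) {
  stopifnot(genome_length > 0)
  cnt <- pool_counts(sites, pool)
  sum(cnt[, "ref"] > 0 & cnt[, "alt"] > 0) / genome_length * 1000
}

annotation_categories <- function() {
  c("upstream", "exonic_stopgain", "exonic_stoploss", "exonic_synonymous",
    "exonic_nonsynonymous", "exonic_noncoding", "intronic", "splicing",
    "downstream", "upstream/downstream", "intergenic")
}

#' Annotate and tabulate SNPs
#'
#' Classifies every site with [classify_site()]; exonic sites falling in a
#' CDS are refined with [coding_effect()] (exonic sites outside any CDS —
#' UTR exons — are counted as `exonic_noncoding`). The category counts
#' partition the input (they sum to the number of sites); ts/tv and the
#' per-pool heterozygosity rates are appended as summary statistics.
#'
#' @param sites A [pooled_sites()] data.frame.
#' @param transcripts List of [transcript_model()] objects.
#' @param genome Named [Biostrings::DNAStringSet].
#' @param genome_length Denominator for the het rate (default: total
#'   length of `genome`).
#' @param flank Upstream/downstream flank in bp (default 1000).
#' @return A list with `counts` (named integer vector over the annotation
#'   categories), `per_site` (character vector of per-site categories),
#'   `ts_tv`, `het_rate_permille` (length-2, per pool).
#' @export
tabulate_annotation <- function(sites, transcripts, genome,
                                genome_length = sum(Biostrings::width(genome)),
                                flank = 1000) {
  cats <- annotation_categories()
  per_site <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    cl <- classify_site(sites$chrom[i], sites$pos[i], transcripts, flank)
    if (cl == "exonic") {
      eff <- NA_character_
      for (tx in transcripts) {
        if (tx$chrom != sites$chrom[i]) next
        if (!is.na(cds_offset(tx, sites$pos[i]))) {
          eff <- coding_effect(sites[i, , drop = FALSE], tx, genome)
          break
        }
      }
      cl <- if (is.na(eff)) "exonic_noncoding" else paste0("exonic_", eff)
    }
    per_site[i] <- cl
  }
  counts <- stats::setNames(integer(length(cats)), cats)
  tab <- table(factor(per_site, levels = cats))
  counts[names(tab)] <- as.integer(tab)
  list(counts = counts,
       per_site = per_site,
       ts_tv = if (nrow(sites)) suppressWarnings(ts_tv_ratio(sites)) else NA_real_,
       het_rate_permille = c(
         pool1 = if (nrow(sites)) het_rate_permille(sites, genome_length, 1) else 0,
         pool2 = if (nrow(sites)) het_rate_permille(sites, genome_length, 2) else 0))
}
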