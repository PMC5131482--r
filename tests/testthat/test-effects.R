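# one hand-built plus-strand transcript on a 600 bp toy chromosome:
# exon1 [100,160) coding from 103, intron [160,300), exon2 [300,460)
# coding to 399 then 3' UTR. Spliced CDS = 57 + 99 = 156 bp, ATG ... TAA,
# with a repeating non-stop codon body so the frame is unambiguous.
toy_tx_case <- function() {
  set.seed(99)
  g <- sample(c("A", "C", "G", "T"), 600, replace = TRUE)
  g[104:106] <- c("A", "T", "G")
  g[107:160] <- rep(c("G", "C", "T"), length.out = 54)
  g[301:396] <- rep(c("A", "C", "C"), length.out = 96)
  g[397:399] <- c("T", "A", "A")
  seq <- paste(g, collapse = "")
  genome <- toy_genome(seq)
  tx <- transcript_model(
    "tx1", "chr1", "+",
    data.frame(start = c(100, 300), end = c(160, 460)),
    cds_start = 103, cds_end = 399, genome = genome)
  list(genome = genome, seq = seq, tx = tx)
}

test_that("classify_site applies the documented precedence", {
  tc <- toy_tx_case()
  cls <- function(pos) classify_site("chr1", pos, list(tc$tx))
  expect_equal(cls(130), "exonic")          # inside exon 1
  expect_equal(cls(161), "splicing")        # 1 bp into the intron
  expect_equal(cls(162), "splicing")        # 2 bp in (edge of the 2 bp rule)
  expect_equal(cls(163), "intronic")        # 3 bp in
  expect_equal(cls(299), "splicing")        # 2 bp before exon 2 (0-based 298)
  expect_equal(cls(200), "intronic")
  expect_equal(cls(50), "upstream")         # 0-based 49, 51 bp before start
  expect_equal(cls(470), "downstream")      # past the transcript end
  expect_equal(classify_site("chr1", 50, list()), "intergenic")
  # strandness: on a minus-strand copy the 5' flank is at high coordinates
  tx_minus <- suppressWarnings(transcript_model(
    "m", "chr1", "-", tc$tx$exons, 103, 399))
  expect_equal(classify_site("chr1", 50, list(tx_minus)), "downstream")
  expect_equal(classify_site("chr1", 470, list(tx_minus)), "upstream")
  # upstream of one transcript, downstream of another
  tx_b <- suppressWarnings(transcript_model(
    "b", "chr1", "+", data.frame(start = 0, end = 30), 0, 30))
  expect_equal(classify_site("chr1", 50, list(tc$tx, tx_b)),
               "upstream/downstream")
})

test_that("classify_site is invariant under reverse-complementing the genome", {
  tc <- toy_tx_case()
  L <- nchar(tc$seq)
  mirror_tx <- suppressWarnings(transcript_model(
    "mir", "chr1", "-",
    data.frame(start = L - rev(tc$tx$exons$end),
               end = L - rev(tc$tx$exons$start)),
    cds_start = L - tc$tx$cds_end, cds_end = L - tc$tx$cds_start))
  for (pos in c(130, 161, 163, 200, 50, 470, 595)) {
    expect_equal(classify_site("chr1", L - pos + 1, list(mirror_tx)),
                 classify_site("chr1", pos, list(tc$tx)),
                 label = paste("mirrored position", pos))
  }
})

test_that("coding_effect translates the standard genetic code cases", {
  # genome: ATG AAA TAC TGA on a bare single-exon CDS
  g <- toy_genome("ATGAAATACTGA")
  tx <- transcript_model("t", "chr1", "+", data.frame(start = 0, end = 12),
                         0, 12, genome = g)
  site <- function(pos, ref, alt) list(chrom = "chr1", pos = pos,
                                       ref = ref, alt = alt)
  # AAA -> AAG: Lys -> Lys
  expect_equal(coding_effect(site(6, "A", "G"), tx, g), "synonymous")
  # AAA -> GAA: Lys -> Glu
  expect_equal(coding_effect(site(4, "A", "G"), tx, g), "nonsynonymous")
  # TAC -> TAA: Tyr -> stop
  expect_equal(coding_effect(site(9, "C", "A"), tx, g), "stopgain")
  # TGA -> TGG: stop -> Trp
  expect_equal(coding_effect(site(12, "A", "G"), tx, g), "stoploss")
  expect_error(coding_effect(site(13, "A", "G"), tx, g), "not within the CDS")
})

test_that("coding_effect agrees with a whole-CDS translation oracle", {
  set.seed(2024)
  n_cases <- 0L
  mismatches <- 0L
  for (rep in 1:1100) {
    cs <- random_transcript_case()
    tx <- suppressWarnings(transcript_model(
      "t", "chr1", cs$strand, cs$exons, cs$cds_start, cs$cds_end))
    g <- toy_genome(cs$gseq)
    got <- coding_effect(list(chrom = "chr1", pos = cs$pos, ref = cs$ref,
                              alt = cs$alt), tx, g)
    want <- oracle_coding_effect(cs$gseq, cs$exons, cs$cds_start,
                                 cs$cds_end, cs$strand, cs$pos, cs$ref,
                                 cs$alt)
    if (!identical(got, want)) mismatches <- mismatches + 1L
    n_cases <- n_cases + 1L
  }
  expect_equal(mismatches, 0L)
  expect_gte(n_cases, 1000L)
})

test_that("ts/tv counts the canonical substitution classes", {
  s <- pooled_sites("chr1", 1:3, c("A", "C", "A"), c("G", "T", "C"),
                    5, 5, 5, 5)
  expect_equal(ts_tv_ratio(s), 2)
  all_ts <- pooled_sites("chr1", 1:2, c("A", "C"), c("G", "T"), 5, 5, 5, 5)
  expect_warning(r <- ts_tv_ratio(all_ts), "undefined")
  expect_true(is.na(r))
  # exhaustive check over all 12 ordered substitution pairs
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  s_all <- pooled_sites("chr1", seq_len(nrow(pairs)), pairs$ref, pairs$alt,
                        5, 5, 5, 5)
  expect_equal(ts_tv_ratio(s_all), 4 / 8)
})

test_that("het rate counts pool-heterozygous sites per kb", {
  s <- pooled_sites("chr1", 1:3, "A", "G",
                    p1_ref = c(5, 0, 3), p1_alt = c(5, 9, 0),
                    p2_ref = c(5, 5, 5), p2_alt = c(5, 5, 5))
  expect_equal(het_rate_permille(s, 10000, 1), 0.1)     # 1 het site
  expect_equal(het_rate_permille(s, 10000, 2), 0.3)
  # fixed-for-alt sites are not heterozygous
  fixed <- pooled_sites("chr1", 1:2, "A", "G", c(0, 0), c(9, 9),
                        c(0, 0), c(9, 9))
  expect_equal(het_rate_permille(fixed, 1000, 1), 0)
  expect_equal(het_rate_permille(s[0, ], 1000, 1), 0)
})

test_that("tabulate_annotation partitions the sites and matches hand labels", {
  tc <- toy_tx_case()
  pos <- c(130,   # exonic CDS
           420,   # exonic UTR (exon2 past cds_end)
           161,   # splicing
           200,   # intronic
           50,    # upstream
           470,   # downstream
           595)   # intergenic (beyond the 1 kb flank? chromosome is 600 bp;
                  # 595 is 135 bp past the transcript end -> downstream)
  refs <- vapply(pos, function(p) substr(tc$seq, p, p), "")
  alts <- vapply(refs, function(r) setdiff(c("A", "C", "G", "T"), r)[1], "")
  s <- pooled_sites("chr1", pos, refs, alts, 5, 5, 5, 5)
  tab <- tabulate_annotation(s, list(tc$tx), tc$genome)
  expect_equal(sum(tab$counts), nrow(s))
  expect_equal(unname(tab$counts["exonic_noncoding"]), 1L)
  expect_equal(unname(tab$counts["splicing"]), 1L)
  expect_equal(unname(tab$counts["intronic"]), 1L)
  expect_equal(unname(tab$counts["upstream"]), 1L)
  expect_equal(unname(tab$counts["downstream"]), 2L)
  expect_equal(sum(tab$counts[c("exonic_stopgain", "exonic_stoploss",
                                "exonic_synonymous",
                                "exonic_nonsynonymous")]), 1L)
  # empty input -> all-zero table
  tab0 <- tabulate_annotation(s[0, ], list(tc$tx), tc$genome)
  expect_true(all(tab0$counts == 0L))
})

test_that("GFF transcript models round-trip into the classifier", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttoy\tmRNA\t101\t460\t.\t+\t.\tID=tx1",
    "chr1\ttoy\texon\t101\t160\t.\t+\t.\tParent=tx1",
    "chr1\ttoy\texon\t301\t460\t.\t+\t.\tParent=tx1",
    "chr1\ttoy\tCDS\t104\t160\t.\t+\t0\tParent=tx1",
    "chr1\ttoy\tCDS\t301\t399\t.\t+\t0\tParent=tx1"
  ), gff)
  models <- suppressWarnings(read_transcript_models(gff))
  expect_length(models, 1L)
  tx <- models[[1]]
  expect_equal(tx$exons$start, c(100, 300))
  expect_equal(tx$cds_start, 103)
  expect_equal(tx$cds_end, 399)
  expect_equal(classify_site("chr1", 130, models), "exonic")
})
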