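# Fixture builders and independent brute-force oracles used across tests.

random_sites <- function(n, chroms = c(chr1 = 1e6), seed = NULL,
                         max_depth = 30) {
  if (!is.null(seed)) set.seed(seed)
  cn <- sample(names(chroms), n, replace = TRUE)
  pos <- vapply(cn, function(x) sample.int(chroms[[x]], 1L), 0L)
  o <- order(match(cn, names(chroms)), pos)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  pooled_sites(
    chrom = cn[o], pos = pos[o], ref = ref[o], alt = alt[o],
    p1_ref = sample.int(max_depth, n, replace = TRUE),
    p1_alt = sample.int(max_depth, n, replace = TRUE),
    p2_ref = sample.int(max_depth, n, replace = TRUE),
    p2_alt = sample.int(max_depth, n, replace = TRUE),
    qual = round(runif(n, 20, 60))
  )
}

random_read <- function(len = 100, n_frac = 0, lowq = 0, adapter = NULL,
                        adapter_len = 0) {
  bases <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  if (n_frac > 0) {
    k <- round(len * n_frac)
    bases[sample.int(len, k)] <- "N"
  }
  quals <- sample(20:40, len, replace = TRUE)
  lowq <- min(lowq, len)
  if (lowq > 0) quals[sample.int(len, lowq)] <- sample(0:5, lowq, replace = TRUE)
  seq <- paste(bases, collapse = "")
  if (!is.null(adapter) && adapter_len > 0) {
    ins <- substr(adapter, 1, adapter_len)
    at <- sample.int(len - adapter_len, 1L)
    substr(seq, at, at + adapter_len - 1L) <- ins
  }
  list(id = paste0("r", sample.int(1e6, 1)), bases = seq, quals = quals)
}

# independent re-derivation of the read-QC rules (different code path)
oracle_read_fails <- function(read, adapter = NULL) {
  q <- read$quals
  b <- strsplit(read$bases, "")[[1]]
  if (sum(q <= 5) / length(q) > 0.5) return(TRUE)
  if (sum(b == "N") / length(b) >= 0.10) return(TRUE)
  if (!is.null(adapter)) {
    # longest common substring by scanning read substrings against adapter
    lb <- length(b)
    best <- 0L
    for (i in seq_len(lb)) {
      for (j in i:lb) {
        if (j - i + 1L <= best) next
        if (grepl(substr(read$bases, i, j), adapter, fixed = TRUE))
          best <- j - i + 1L
        else break
      }
    }
    if (best > 10L) return(TRUE)
  }
  FALSE
}

# brute-force per-window site counting on 0-based half-open windows,
# 1-based positions
oracle_window_counts <- function(windows, sites) {
  vapply(seq_len(nrow(windows)), function(i) {
    sum(sites$chrom == windows$chrom[i] &
          sites$pos - 1 >= windows$start[i] &
          sites$pos - 1 < windows$end[i])
  }, 0L)
}

# type-7 quantile by explicit order-statistic interpolation
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, n)] - x[lo])
}

# toy single-transcript genome for effect classification
toy_genome <- function(seq) Biostrings::DNAStringSet(c(chr1 = seq))

revcomp_chr <- function(s)
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")

# independent coding-effect oracle: translate the whole reference and
# mutant CDS with Biostrings::translate and diff the proteins
oracle_coding_effect <- function(genome_seq, exons, cds_start, cds_end,
                                 strand, pos, ref, alt) {
  stopifnot(substr(genome_seq, pos, pos) == ref)
  mutant <- genome_seq
  substr(mutant, pos, pos) <- alt
  splice <- function(g) {
    s <- pmax(exons$start, cds_start)
    e <- pmin(exons$end, cds_end)
    keep <- e > s
    cds <- paste(substring(g, s[keep] + 1, e[keep]), collapse = "")
    if (strand == "-") cds <- revcomp_chr(cds)
    cds
  }
  tr <- function(cds) as.character(Biostrings::translate(
    Biostrings::DNAString(cds), if.fuzzy.codon = "X", no.init.codon = TRUE))
  p_ref <- tr(splice(genome_seq))
  p_alt <- tr(splice(mutant))
  if (p_ref == p_alt) return("synonymous")
  d <- which(strsplit(p_ref, "")[[1]] != strsplit(p_alt, "")[[1]])[1]
  a_ref <- substr(p_ref, d, d)
  a_alt <- substr(p_alt, d, d)
  if (a_ref != "*" && a_alt == "*") return("stopgain")
  if (a_ref == "*" && a_alt != "*") return("stoploss")
  "nonsynonymous"
}

# random multi-exon transcript embedded in a random genome
random_transcript_case <- function() {
  n_codons <- sample(4:20, 1)
  cds_len <- 3L * n_codons
  n_exons <- sample(1:4, 1)
  # partition cds_len into exon pieces of >= 1 bp
  cuts <- sort(sample(seq_len(cds_len - 1), n_exons - 1))
  pieces <- diff(c(0, cuts, cds_len))
  introns <- sample(10:60, n_exons)  # last is leading offset
  starts <- integer(n_exons)
  pos <- introns[1]
  exons <- data.frame(start = integer(n_exons), end = integer(n_exons))
  for (i in seq_len(n_exons)) {
    exons$start[i] <- pos
    exons$end[i] <- pos + pieces[i]
    pos <- exons$end[i] + if (i < n_exons) introns[i + 1] else 0L
  }
  glen <- exons$end[n_exons] + 50L
  gseq <- paste(sample(c("A", "C", "G", "T"), glen, replace = TRUE),
                collapse = "")
  strand <- sample(c("+", "-"), 1)
  # pick a CDS base to mutate
  cds_pos0 <- unlist(mapply(seq, exons$start, exons$end - 1L,
                            SIMPLIFY = FALSE))
  hit <- sample(cds_pos0, 1)
  ref <- substr(gseq, hit + 1, hit + 1)
  alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
  list(gseq = gseq, exons = exons, cds_start = exons$start[1],
       cds_end = exons$end[n_exons], strand = strand,
       pos = hit + 1L, ref = ref, alt = alt)
}

small_null_config <- function(seed, lengths = c(chr1 = 3e6)) {
  sweep_sim_config(seed = seed, chrom_lengths = lengths)
}
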