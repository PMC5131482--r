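# builds a minimal stats table for selection tests
fake_stats <- function(zhp1, zfst, zhp2 = zhp1, snp = 50) {
  n <- length(zhp1)
  data.frame(chrom = "chr1", start = (seq_len(n) - 1) * 75000,
             end = (seq_len(n) - 1) * 75000 + 150000, terminal = FALSE,
             snp_count = snp, hp1 = NA_real_, hp2 = NA_real_,
             fst = NA_real_, zhp1 = zhp1, zhp2 = zhp2, zfst = zfst,
             d_zhp = zhp2 - zhp1, eligible = TRUE,
             stringsAsFactors = FALSE)
}

test_that("select_candidates takes the double tail and matches brute force", {
  # 100 windows, zhp = rank/100 ascending, zfst descending: the two extreme
  # tails coincide in the same windows
  zhp <- (1:100) / 100
  zfst <- rev(zhp)
  st <- fake_stats(zhp, zfst)
  sel <- select_candidates(st, 1, 0.05, 0.05)
  zhp_cut <- oracle_quantile7(zhp, 0.05)
  zfst_cut <- oracle_quantile7(zfst, 0.95)
  brute <- which(zhp <= zhp_cut & zfst >= zfst_cut)
  expect_equal(sel$start, st$start[brute])
  expect_equal(unname(attr(sel, "thresholds")),
               unname(c(zhp_cut, zfst_cut)))
  # quantile 0 -> empty set
  expect_equal(nrow(select_candidates(st, 1, 0, 0.05)), 0L)
  expect_equal(nrow(select_candidates(st, 1, 0.05, 0)), 0L)
  # degenerate identical stats -> warning
  expect_warning(select_candidates(fake_stats(rep(1, 30), rep(1, 30)), 1),
                 "degenerate")
  # too few eligible windows -> error
  expect_error(select_candidates(fake_stats(1:10 / 10, 1:10 / 10), 1),
               "fewer than 20")
})

test_that("select_candidates equals a brute-force scan on random stats", {
  set.seed(101)
  n_checked <- 0L
  for (rep in 1:15) {
    n <- sample(30:120, 1)
    st <- fake_stats(rnorm(n), rnorm(n), zhp2 = rnorm(n))
    for (pool in 1:2) {
      q1 <- runif(1, 0.02, 0.3)
      q2 <- runif(1, 0.02, 0.3)
      sel <- select_candidates(st, pool, q1, q2)
      z <- if (pool == 1) st$zhp1 else st$zhp2
      brute <- which(z <= oracle_quantile7(z, q1) &
                       st$zfst >= oracle_quantile7(st$zfst, 1 - q2))
      expect_equal(sel$start, st$start[brute])
      n_checked <- n_checked + n
    }
  }
  expect_gte(n_checked, 1000L)
})

test_that("selection is monotone in the quantiles", {
  set.seed(55)
  st <- fake_stats(rnorm(80), rnorm(80))
  prev <- character()
  for (q in c(0.02, 0.05, 0.1, 0.2, 0.4)) {
    cur <- sprintf("%s:%d", select_candidates(st, 1, q, q)$chrom,
                   select_candidates(st, 1, q, q)$start)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("merge/partition follow the >=1 bp overlap rule", {
  lf <- data.frame(chrom = "chr1", start = 0, end = 150000)
  hf <- data.frame(chrom = "chr1", start = 75000, end = 225000)
  p <- partition_unique_shared(lf, hf, c("LF", "HF"))
  expect_equal(nrow(p$unique1), 0L)
  expect_equal(nrow(p$unique2), 0L)
  expect_equal(nrow(p$shared), 2L)

  hf2 <- data.frame(chrom = "chr1", start = 300000, end = 450000)
  p2 <- partition_unique_shared(lf, hf2, c("LF", "HF"))
  expect_equal(nrow(p2$shared), 0L)
  expect_equal(p2$unique1$start, 0)
  expect_equal(p2$unique2$start, 300000)

  # adjacent sliding windows merge into one maximal interval
  m <- merge_windows(data.frame(chrom = "chr1",
                                start = c(0, 75000, 150000),
                                end = c(150000, 225000, 300000)))
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(0, 300000))
})

test_that("partition agrees with an all-pairs interval oracle", {
  set.seed(77)
  brute_merge <- function(iv) {
    iv <- iv[order(iv$chrom, iv$start), ]
    out <- NULL
    for (i in seq_len(nrow(iv))) {
      if (!is.null(out) && iv$chrom[i] == out$chrom[nrow(out)] &&
          iv$start[i] <= out$end[nrow(out)]) {
        out$end[nrow(out)] <- max(out$end[nrow(out)], iv$end[i])
      } else out <- rbind(out, iv[i, , drop = FALSE])
    }
    rownames(out) <- NULL
    out
  }
  n_cases <- 0L
  for (rep in 1:40) {
    mkset <- function() {
      k <- sample(1:12, 1)
      start <- sample(0:40, k, replace = TRUE) * 25000
      data.frame(chrom = sample(c("c1", "c2"), k, replace = TRUE),
                 start = start, end = start + 150000)
    }
    a <- mkset(); b <- mkset()
    p <- partition_unique_shared(a, b, c("A", "B"))
    ma <- brute_merge(a); mb <- brute_merge(b)
    ov <- function(x, yset) any(x$chrom == yset$chrom &
                                  x$start < yset$end & yset$start < x$end)
    sha <- vapply(seq_len(nrow(ma)), function(i) ov(ma[i, ], mb), TRUE)
    shb <- vapply(seq_len(nrow(mb)), function(i) ov(mb[i, ], ma), TRUE)
    expect_equal(p$unique1[c("chrom", "start", "end")],
                 ma[!sha, ], ignore_attr = TRUE)
    expect_equal(p$unique2[c("chrom", "start", "end")],
                 mb[!shb, ], ignore_attr = TRUE)
    expect_equal(nrow(p$shared), sum(sha) + sum(shb))
    # partition property: unique + shared reconstitute the merged sets
    g1 <- rbind(p$unique1, p$shared[p$shared$group == "A",
                                    c("chrom", "start", "end")])
    expect_equal(g1[order(g1$chrom, g1$start), ], ma, ignore_attr = TRUE)
    n_cases <- n_cases + nrow(ma) * nrow(mb)
  }
  expect_gte(n_cases, 500L)
})

test_that("gene overlap is half-open and matches an all-pairs oracle", {
  win <- data.frame(chrom = "chr1", start = 0, end = 150000)
  genes <- data.frame(chrom = "chr1",
                      start = c(100, 150000, 149999),
                      end = c(200, 150001, 150300),
                      name = c("inA", "pastEnd", "spans"))
  hits <- overlap_genes(win, genes)
  expect_equal(hits[["chr1:0-150000"]], c("inA", "spans"))
  # unknown chromosome warns and is skipped
  genes2 <- rbind(genes, data.frame(chrom = "chrZ", start = 1, end = 2,
                                    name = "lost"))
  expect_warning(h2 <- overlap_genes(win, genes2), "chrZ")
  expect_equal(h2, hits)

  set.seed(91)
  n_cases <- 0L
  for (rep in 1:25) {
    nw <- sample(2:8, 1); ng <- sample(5:40, 1)
    ws <- sample(0:30, nw) * 50000
    win <- data.frame(chrom = sample(c("c1", "c2"), nw, replace = TRUE),
                      start = ws, end = ws + 150000)
    gs <- sample(0:(1.6e6 / 100), ng, replace = TRUE) * 100
    genes <- data.frame(chrom = sample(c("c1", "c2"), ng, replace = TRUE),
                        start = gs, end = gs + sample(100:5000, ng, TRUE),
                        name = paste0("g", seq_len(ng)))
    hits <- suppressWarnings(overlap_genes(win, genes))
    for (i in seq_len(nw)) {
      brute <- genes[genes$chrom == win$chrom[i] &
                       genes$start < win$end[i] &
                       win$start[i] < genes$end, ]
      brute <- brute[order(brute$start, brute$end), ]
      expect_equal(hits[[i]], brute$name)
      n_cases <- n_cases + ng
    }
  }
  expect_gte(n_cases, 1000L)
})

test_that("phenotype summaries give group mean and n-1 SD to 2 decimals", {
  out <- summarize_phenotypes(list(LF = rep(1, 20), HF = c(rep(3, 13), 4)))
  expect_equal(out$n, c(20L, 14L))
  expect_equal(out$mean, c(1.00, 3.07))
  expect_equal(out$sd, c(0.00, 0.27))
  one <- summarize_phenotypes(list(g = 2))
  expect_equal(one$mean, 2.00)
  expect_equal(one$sd, 0.00)
  expect_true(one$sd_degenerate)
  expect_error(summarize_phenotypes(list(a = 1, b = numeric())), "non-empty")
})
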