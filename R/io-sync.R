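#' Read pool-seq allele counts from a sync file
#'
#' The sync format (as popularised by pool-seq pipelines) has one site per
#' line: chromosome, 1-based position, reference base, then one
#' colon-separated count column `A:T:C:G:N:del` per pool. Only biallelic
#' SNP sites are returned: exactly two of A/C/G/T must have a positive count
#' summed across the two pools, one of them being the reference base.
#' Multiallelic lines, lines with deletion counts, monomorphic lines and
#' lines whose observed alleles do not include the stated reference are
#' skipped; the skip tally is attached as attribute `skipped` and reported
#' via [message()].
#'
#' @param path Path to a sync file.
#' @param pool_labels Length-2 character vector naming the two pool columns
#'   (column 4 and 5), in file order.
#' @return A [pooled_sites()] data.frame with `qual = NA` (sync carries no
#'   call quality) and attribute `skipped` (named integer vector).
#' @export
read_sync <- function(path, pool_labels = c("pool1", "pool2")) {
  if (!file.exists(path)) stop("sync file not found: ", path)
  if (length(pool_labels) != 2L)
    stop("pool_labels must name exactly two pools")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  skip <- c(multiallelic = 0L, indel = 0L, monomorphic = 0L,
            ref_mismatch = 0L)
  if (length(lines) == 0L) {
    out <- pooled_sites(pool_labels = pool_labels)
    attr(out, "skipped") <- skip
    return(out)
  }
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf < 5L)
  if (length(bad))
    stop("malformed sync line ", bad[1], ": expected >= 5 fields, got ",
         nf[bad[1]])
  base_order <- c("A", "T", "C", "G")   # sync column order A:T:C:G:N:del

  parse_pool <- function(i, col) {
    cnt <- strsplit(vapply(fields, `[[`, "", col), ":", fixed = TRUE)
    if (any(lengths(cnt) != 6L))
      stop("malformed sync line ", which(lengths(cnt) != 6L)[1],
           ": pool column must have 6 ':'-separated counts")
    m <- matrix(suppressWarnings(as.integer(unlist(cnt))),
                ncol = 6L, byrow = TRUE)
    if (anyNA(m))
      stop("malformed sync line ", which(rowSums(is.na(m)) > 0)[1],
           ": non-integer count")
    m
  }
  m1 <- parse_pool(1, 4L)
  m2 <- parse_pool(2, 5L)

  chrom <- vapply(fields, `[[`, "", 1L)
  pos <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  if (anyNA(pos))
    stop("malformed sync line ", which(is.na(pos))[1], ": bad position")
  refb <- toupper(vapply(fields, `[[`, "", 3L))

  acgt <- cbind(m1[, 1:4, drop = FALSE] + m2[, 1:4, drop = FALSE])
  has_del <- (m1[, 6] + m2[, 6]) > 0L
  n_alleles <- rowSums(acgt > 0L)

  keep <- logical(length(lines))
  alt <- character(length(lines))
  for (r in seq_along(lines)) {
    if (has_del[r]) { skip["indel"] <- skip["indel"] + 1L; next }
    if (n_alleles[r] > 2L) { skip["multiallelic"] <- skip["multiallelic"] + 1L; next }
    if (n_alleles[r] < 2L) { skip["monomorphic"] <- skip["monomorphic"] + 1L; next }
    obs <- base_order[acgt[r, ] > 0L]
    if (!refb[r] %in% obs) { skip["ref_mismatch"] <- skip["ref_mismatch"] + 1L; next }
    keep[r] <- TRUE
    alt[r] <- setdiff(obs, refb[r])
  }
  ri <- match(refb[keep], base_order)
  ai <- match(alt[keep], base_order)
  kidx <- which(keep)
  out <- pooled_sites(
    chrom = chrom[keep], pos = pos[keep], ref = refb[keep], alt = alt[keep],
    p1_ref = m1[cbind(kidx, ri)], p1_alt = m1[cbind(kidx, ai)],
    p2_ref = m2[cbind(kidx, ri)], p2_alt = m2[cbind(kidx, ai)],
    qual = NA_real_, pool_labels = pool_labels
  )
  if (sum(skip) > 0L)
    message("read_sync: skipped ", sum(skip), " line(s) (",
            paste(names(skip), skip, sep = "=", collapse = ", "), ")")
  attr(out, "skipped") <- skip
  out
}

#' Write biallelic sites as a sync file
#'
#' Inverse of [read_sync()] for the count fields; call quality is not
#' representable in sync and is dropped.
#'
#' @param sites A [pooled_sites()] data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sync <- function(sites, path) {
  base_order <- c("A", "T", "C", "G")
  fmt_pool <- function(ref, alt, rc, ac) {
    m <- matrix(0L, nrow = length(rc), ncol = 6L)
    m[cbind(seq_along(rc), match(ref, base_order))] <- rc
    m[cbind(seq_along(ac), match(alt, base_order))] <- ac
    apply(m, 1L, paste, collapse = ":")
  }
  if (nrow(sites) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  lines <- paste(sites$chrom, sites$pos, sites$ref,
                 fmt_pool(sites$ref, sites$alt, sites$p1_ref, sites$p1_alt),
                 fmt_pool(sites$ref, sites$alt, sites$p2_ref, sites$p2_alt),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
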