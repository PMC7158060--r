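# Independent brute-force oracles. These re-derive the quantities the
# package computes, from first principles and simple loops, so that tests
# compare two independent routes.

COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

oracle_revcomp <- function(s) {
  paste(rev(COMP[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
}

# per-read aligned (refpos0, readoff0) pairs from a CIGAR, by simple walk
oracle_aligned_pairs <- function(pos0, cigar) {
  nums <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MN]", cigar))[[1]]
  ref <- pos0; rd <- 0L
  out <- NULL
  for (k in seq_along(ops)) {
    if (ops[k] == "M") {
      out <- rbind(out, cbind(ref + seq_len(nums[k]) - 1L,
                              rd + seq_len(nums[k]) - 1L))
      ref <- ref + nums[k]; rd <- rd + nums[k]
    } else ref <- ref + nums[k]
  }
  out
}

# brute-force retained-C count of one read (transcript-strand logic)
oracle_nonconv_count <- function(rec, seqs) {
  ref <- strsplit(seqs[[rec$rname]], "", fixed = TRUE)[[1]]
  rd <- strsplit(rec$seq, "", fixed = TRUE)[[1]]
  ap <- oracle_aligned_pairs(rec$pos, rec$cigar)
  n <- 0L
  for (k in seq_len(nrow(ap))) {
    rb <- ref[ap[k, 1] + 1L]; qb <- rd[ap[k, 2] + 1L]
    if (rec$strand == "+" && rb == "C" && qb == "C") n <- n + 1L
    if (rec$strand == "-" && rb == "G" && qb == "G") n <- n + 1L
  }
  n
}

# exhaustive per-position pileup recount honouring 3C, terminal mask and
# the base-quality floor; returns a data.frame keyed by (seqname, pos)
oracle_pileup <- function(aln, seqs, strand_of_seq, max_3c = 3L,
                          min_bq = 30L, mask_nt = 6L) {
  counts <- list()
  bump <- function(key, field, by = 1L) {
    if (is.null(counts[[key]]))
      counts[[key]] <<- c(raw = 0L, filt = 0L, c = 0L, t = 0L, o = 0L)
    counts[[key]][field] <<- counts[[key]][field] + by
  }
  n3c <- vapply(seq_len(nrow(aln)), function(i)
    oracle_nonconv_count(aln[i, ], seqs), integer(1))
  for (i in seq_len(nrow(aln))) {
    rec <- aln[i, ]
    ref <- strsplit(seqs[[rec$rname]], "", fixed = TRUE)[[1]]
    rd <- strsplit(rec$seq, "", fixed = TRUE)[[1]]
    bq <- as.integer(charToRaw(rec$qual)) - 33L
    ap <- oracle_aligned_pairs(rec$pos, rec$cigar)
    rlen <- nchar(rec$seq)
    for (k in seq_len(nrow(ap))) {
      rb <- ref[ap[k, 1] + 1L]
      isC <- (rec$strand == "+" && rb == "C") ||
        (rec$strand == "-" && rb == "G")
      if (!isC) next
      key <- paste(rec$rname, ap[k, 1])
      bump(key, "raw")
      if (n3c[i] > max_3c) next
      bump(key, "filt")
      qb <- rd[ap[k, 2] + 1L]
      terminal <- ap[k, 2] < mask_nt || ap[k, 2] >= rlen - mask_nt
      if (bq[ap[k, 2] + 1L] < min_bq || terminal) next
      ret <- (rec$strand == "+" && qb == "C") ||
        (rec$strand == "-" && qb == "G")
      conv <- (rec$strand == "+" && qb == "T") ||
        (rec$strand == "-" && qb == "A")
      if (ret) bump(key, "c") else if (conv) bump(key, "t") else bump(key, "o")
    }
  }
  out <- do.call(rbind, lapply(names(counts), function(k) {
    sp <- strsplit(k, " ")[[1]]
    data.frame(seqname = sp[1], pos = as.integer(sp[2]),
               raw = counts[[k]]["raw"], filt = counts[[k]]["filt"],
               c = counts[[k]]["c"], t = counts[[k]]["t"],
               o = counts[[k]]["o"], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# exhaustive enumeration of non-crossing matchings -> maximum pair count
oracle_max_pairs <- function(seq, min_loop = 3L) {
  ch <- strsplit(chartr("T", "U", toupper(seq)), "", fixed = TRUE)[[1]]
  ok <- c("AU", "UA", "GC", "CG", "GU", "UG")
  n <- length(ch)
  memo <- new.env()
  rec <- function(i, j) {
    if (j - i < min_loop + 1L) return(0L)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- rec(i, j - 1L)
    for (k in i:(j - min_loop - 1L)) {
      if (paste0(ch[k], ch[j]) %in% ok) {
        v <- 1L + (if (k > i) rec(i, k - 1L) else 0L) +
          (if (k + 1L <= j - 1L) rec(k + 1L, j - 1L) else 0L)
        if (v > best) best <- v
      }
    }
    memo[[key]] <- best
    best
  }
  if (n < min_loop + 2L) return(0L)
  rec(1L, n)
}

# two-proportion binomial likelihood-ratio deviance, from log-likelihoods
oracle_lrt <- function(m1, u1, m2, u2) {
  ll <- function(m, u) {
    if (m + u == 0) return(0)
    p <- m / (m + u)
    (if (m > 0) m * log(p) else 0) + (if (u > 0) u * log(1 - p) else 0)
  }
  p0 <- (m1 + m2) / (m1 + u1 + m2 + u2)
  ll0 <- (if (m1 + m2 > 0) (m1 + m2) * log(p0) else 0) +
    (if (u1 + u2 > 0) (u1 + u2) * log(1 - p0) else 0)
  2 * (ll(m1, u1) + ll(m2, u2) - ll0)
}

# adjusted Rand index between two labellings
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab)); si <- sum(ch2(rowSums(tab))); sj <- sum(ch2(colSums(tab)))
  n <- ch2(sum(tab))
  (sij - si * sj / n) / ((si + sj) / 2 - si * sj / n)
}
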