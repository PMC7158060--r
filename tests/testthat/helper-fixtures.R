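# Small fixtures constructed in code.

# two-gene toy reference: one plus-strand, one minus-strand mRNA
toy_refset <- function() {
  seqs <- c(gplus = "ATCGACGTTACGATCCGATACGTAGCTAGCATCGATTTACGCATGCATGC",
            gminus = "TTGGAACCGGTTAACCGGAAGGTTCCAAGGCCTTAAGGCCAATTGGCCAA")
  transcripts <- data.frame(
    transcript_id = c("tp.1", "tm.1"), gene_id = c("gp", "gm"),
    seqname = c("gplus", "gminus"), strand = c("+", "-"),
    biotype = c("protein_coding", "protein_coding"),
    stringsAsFactors = FALSE)
  exons <- data.frame(transcript_id = c("tp.1", "tm.1"),
                      start = c(0L, 0L), end = c(50L, 50L),
                      stringsAsFactors = FALSE)
  cds <- data.frame(transcript_id = c("tp.1", "tm.1"),
                    start = c(9L, 9L), end = c(39L, 39L),
                    stringsAsFactors = FALSE)
  ReferenceSet(seqs, transcripts, exons, cds,
               class_of = c(gp = "mRNA", gm = "mRNA"))
}

# hand-built alignment record
mk_read <- function(rname, pos, seq, strand = "+", qual = NULL,
                    cigar = NULL, qname = "r1", mapq = 42L) {
  n <- nchar(seq)
  d <- data.frame(qname = qname, rname = rname, pos = pos, strand = strand,
                  seq = seq,
                  qual = qual %||% strrep(rawToChar(as.raw(37 + 33)), n),
                  cigar = cigar %||% paste0(n, "M"), mapq = mapq,
                  flag = if (strand == "+") 0L else 16L,
                  stringsAsFactors = FALSE)
  class(d) <- c("bs_alignments", "data.frame")
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

bind_reads <- function(...) {
  d <- do.call(rbind, list(...))
  class(d) <- c("bs_alignments", "data.frame")
  d
}

# a deterministic 50-read toy alignment set over toy_refset(), with a mix
# of strands, qualities, terminal placements and 3C failures
toy_reads_50 <- function() {
  ref <- toy_refset()
  set.seed(99)
  reads <- list()
  for (i in 1:25) {
    pos <- sample(0:30, 1)
    len <- 20L
    tpl <- substr(ref$sequences[["gplus"]], pos + 1, pos + len)
    ch <- strsplit(tpl, "", fixed = TRUE)[[1]]
    # convert transcript-strand Cs with prob 0.7, retain otherwise
    cs <- which(ch == "C")
    conv <- cs[runif(length(cs)) < 0.7]
    ch[conv] <- "T"
    qual <- paste(sample(c("F", "5"), len, TRUE, prob = c(.9, .1)),
                  collapse = "")  # F = Q37, 5 = Q20
    reads[[length(reads) + 1]] <- mk_read("gplus", pos,
                                          paste(ch, collapse = ""),
                                          "+", qual, qname = paste0("p", i))
  }
  for (i in 1:25) {
    pos <- sample(0:30, 1)
    len <- 20L
    tpl <- substr(ref$sequences[["gminus"]], pos + 1, pos + len)
    ch <- strsplit(tpl, "", fixed = TRUE)[[1]]
    gs <- which(ch == "G")             # transcript-strand C on minus gene
    conv <- gs[runif(length(gs)) < 0.7]
    ch[conv] <- "A"
    qual <- paste(sample(c("F", "5"), len, TRUE, prob = c(.9, .1)),
                  collapse = "")
    reads[[length(reads) + 1]] <- mk_read("gminus", pos,
                                          paste(ch, collapse = ""),
                                          "-", qual, qname = paste0("m", i))
  }
  do.call(bind_reads, reads)
}
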