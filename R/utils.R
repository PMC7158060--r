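# Internal helpers shared across modules.
# All coordinates are 0-based half-open internally; GTF/SAM positions are
# converted on read/write.

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(x) {
  vapply(x, function(s) {
    ch <- rev(strsplit(s, "", fixed = TRUE)[[1]])
    paste(DNA_COMPLEMENT[ch], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# transcript-strand character at each plus-strand position of a sequence
ts_chars <- function(seq, strand) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (strand == "-") ch <- unname(DNA_COMPLEMENT[ch])
  ch
}

# Parse a CIGAR restricted to M and N operations into reference/read offsets.
# Returns list(ref = 0-based offsets from POS, read = 0-based read indices).
parse_cigar <- function(cigar) {
  ops <- gregexpr("\\d+[MN]", cigar)[[1]]
  if (ops[1] == -1L) stop("unparseable CIGAR: ", cigar)
  toks <- regmatches(cigar, gregexpr("\\d+[MN]", cigar))[[1]]
  if (sum(nchar(toks)) != nchar(cigar))
    stop("CIGAR contains unsupported operations (only M/N allowed): ", cigar)
  lens <- as.integer(sub("[MN]", "", toks))
  type <- substr(toks, nchar(toks), nchar(toks))
  ref_off <- integer(0); read_off <- integer(0)
  rpos <- 0L; qpos <- 0L
  for (i in seq_along(toks)) {
    if (type[i] == "M") {
      ref_off <- c(ref_off, rpos + seq_len(lens[i]) - 1L)
      read_off <- c(read_off, qpos + seq_len(lens[i]) - 1L)
      rpos <- rpos + lens[i]; qpos <- qpos + lens[i]
    } else {
      rpos <- rpos + lens[i]
    }
  }
  list(ref = ref_off, read = read_off)
}

phred_to_int <- function(qual) as.integer(charToRaw(qual)) - 33L

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# gene spans (0-based half-open) derived from exon extents, one row per gene
gene_spans <- function(refset) {
  ex <- merge(refset$exons, refset$transcripts[, c("transcript_id", "gene_id",
                                                   "seqname", "strand")],
              by = "transcript_id")
  sp <- do.call(rbind, lapply(split(ex, ex$gene_id), function(d) {
    data.frame(gene_id = d$gene_id[1], seqname = d$seqname[1],
               strand = d$strand[1], start = min(d$start), end = max(d$end),
               stringsAsFactors = FALSE)
  }))
  rownames(sp) <- NULL
  sp
}
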