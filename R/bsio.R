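#' Assemble a reference set
#'
#' A `ReferenceSet` bundles everything the pipeline needs as a coordinate
#' frame: nucleotide sequences, transcript models, RNA-class labels and,
#' for tRNA genes, the mature-region interval inside the pre-tRNA span.
#' All intervals are 0-based half-open.
#'
#' @param sequences named character vector of plus-strand DNA sequences.
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `seqname`, `strand` ("+"/"-"), `biotype`.
#' @param exons data.frame with columns `transcript_id`, `start`, `end`
#'   (0-based half-open, non-overlapping per transcript).
#' @param cds optional data.frame with columns `transcript_id`, `start`,
#'   `end`: the genomic span from the first base of the start codon to the
#'   last base of the stop codon.
#' @param class_of named character vector mapping gene ids to RNA classes
#'   (`mRNA`, `tRNA`, `rRNA`, `spikein`, `ncRNA`).
#' @param mature_region_of optional data.frame with columns `gene_id`,
#'   `start`, `end`: mature tRNA interval nested in the pre-tRNA gene span.
#' @return an object of class `ReferenceSet`.
#' @export
ReferenceSet <- function(sequences, transcripts, exons, cds = NULL,
                         class_of, mature_region_of = NULL) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  if (!all(transcripts$seqname %in% names(sequences)))
    stopf("transcript(s) %s reference sequences absent from the FASTA set",
          paste(setdiff(transcripts$seqname, names(sequences)), collapse = ", "))
  ex <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  for (tid in unique(ex$transcript_id)) {
    e <- ex[ex$transcript_id == tid, ]
    if (any(e$start >= e$end)) stopf("empty exon in transcript %s", tid)
    if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)]))
      stopf("overlapping exons in transcript %s", tid)
    sq <- transcripts$seqname[transcripts$transcript_id == tid]
    if (max(e$end) > nchar(sequences[[sq]]))
      stopf("exon of %s exceeds sequence %s bounds", tid, sq)
  }
  obj <- structure(list(sequences = sequences, transcripts = transcripts,
                        exons = ex, cds = cds, class_of = class_of,
                        mature_region_of = mature_region_of),
                   class = "ReferenceSet")
  obj
}

#' @export
print.ReferenceSet <- function(x, ...) {
  cat("ReferenceSet:", length(x$sequences), "sequences,",
      nrow(x$transcripts), "transcripts\n")
  cat("RNA classes:", paste(sprintf("%s=%d", names(table(x$class_of)),
                                    table(x$class_of)), collapse = ", "), "\n")
  invisible(x)
}

spliced_length <- function(refset, transcript_id) {
  e <- refset$exons[refset$exons$transcript_id == transcript_id, ]
  sum(e$end - e$start)
}

#' Write a reference set to FASTA + GTF
#'
#' The GTF dialect carries `gene_id`, `transcript_id` and `rna_class`
#' attributes; tRNA gene features additionally carry `mature_start` and
#' `mature_end` (1-based inclusive, like all GTF coordinates).
#'
#' @param refset a [ReferenceSet].
#' @param fasta_path,gtf_path output paths.
#' @return invisibly, the two paths.
#' @export
write_reference <- function(refset, fasta_path, gtf_path) {
  dna <- Biostrings::DNAStringSet(refset$sequences)
  Biostrings::writeXStringSet(dna, fasta_path)
  lines <- character(0)
  spans <- gene_spans(refset)
  for (i in seq_len(nrow(spans))) {
    g <- spans[i, ]
    attrs <- sprintf('gene_id "%s"; rna_class "%s";', g$gene_id,
                     refset$class_of[[g$gene_id]])
    if (!is.null(refset$mature_region_of) &&
        g$gene_id %in% refset$mature_region_of$gene_id) {
      m <- refset$mature_region_of[refset$mature_region_of$gene_id == g$gene_id, ]
      attrs <- paste0(attrs, sprintf(' mature_start "%d"; mature_end "%d";',
                                     m$start + 1L, m$end))
    }
    lines <- c(lines, paste(g$seqname, "polybs", "gene", g$start + 1L, g$end,
                            ".", g$strand, ".", attrs, sep = "\t"))
    trs <- refset$transcripts[refset$transcripts$gene_id == g$gene_id, ]
    for (j in seq_len(nrow(trs))) {
      tr <- trs[j, ]
      e <- refset$exons[refset$exons$transcript_id == tr$transcript_id, ]
      tattrs <- sprintf('gene_id "%s"; transcript_id "%s"; rna_class "%s"; biotype "%s";',
                        tr$gene_id, tr$transcript_id,
                        refset$class_of[[tr$gene_id]], tr$biotype)
      lines <- c(lines, paste(tr$seqname, "polybs", "transcript",
                              min(e$start) + 1L, max(e$end), ".", tr$strand,
                              ".", tattrs, sep = "\t"))
      for (k in seq_len(nrow(e)))
        lines <- c(lines, paste(tr$seqname, "polybs", "exon", e$start[k] + 1L,
                                e$end[k], ".", tr$strand, ".", tattrs,
                                sep = "\t"))
      if (!is.null(refset$cds) && tr$transcript_id %in% refset$cds$transcript_id) {
        cd <- refset$cds[refset$cds$transcript_id == tr$transcript_id, ]
        lines <- c(lines, paste(tr$seqname, "polybs", "CDS", cd$start + 1L,
                                cd$end, ".", tr$strand, ".", tattrs,
                                sep = "\t"))
      }
    }
  }
  writeLines(lines, gtf_path)
  invisible(c(fasta = fasta_path, gtf = gtf_path))
}

#' Load a reference set from FASTA + GTF
#'
#' Inverse of [write_reference()]: `load_reference(write_reference(x))` is
#' the identity on the data model.
#'
#' @param fasta_path,annotation_path input paths.
#' @return a [ReferenceSet].
#' @export
load_reference <- function(fasta_path, annotation_path) {
  dna <- Biostrings::readDNAStringSet(fasta_path)
  sequences <- as.character(dna)
  names(sequences) <- sub("\\s.*", "", names(sequences))
  g <- rtracklayer::import(annotation_path, format = "gtf")
  gd <- as.data.frame(g)
  need <- setdiff(unique(as.character(gd$seqnames)), names(sequences))
  if (length(need))
    stopf("annotation references sequence(s) absent from FASTA: %s",
          paste(need, collapse = ", "))
  genes <- gd[gd$type == "gene", ]
  trs <- gd[gd$type == "transcript", ]
  exs <- gd[gd$type == "exon", ]
  cdss <- gd[gd$type == "CDS", ]
  transcripts <- data.frame(
    transcript_id = trs$transcript_id, gene_id = trs$gene_id,
    seqname = as.character(trs$seqnames), strand = as.character(trs$strand),
    biotype = if ("biotype" %in% names(trs)) trs$biotype else NA_character_,
    stringsAsFactors = FALSE)
  exons <- data.frame(transcript_id = exs$transcript_id,
                      start = exs$start - 1L, end = exs$end,
                      stringsAsFactors = FALSE)
  cds <- NULL
  if (nrow(cdss))
    cds <- data.frame(transcript_id = cdss$transcript_id,
                      start = cdss$start - 1L, end = cdss$end,
                      stringsAsFactors = FALSE)
  class_of <- stats::setNames(genes$rna_class, genes$gene_id)
  mature <- NULL
  if ("mature_start" %in% names(genes)) {
    hm <- genes[!is.na(genes$mature_start), ]
    if (nrow(hm))
      mature <- data.frame(gene_id = hm$gene_id,
                           start = as.integer(hm$mature_start) - 1L,
                           end = as.integer(hm$mature_end),
                           stringsAsFactors = FALSE)
  }
  ReferenceSet(sequences, transcripts, exons, cds, class_of, mature)
}

#' Bisulfite in-silico conversion of a reference
#'
#' Builds the two converted reference strands a bisulfite-aware aligner
#' indexes: C-to-T conversion of the forward strand and G-to-A conversion
#' of the reverse strand (applied to the stored plus-strand sequence, so
#' reverse-strand conversion replaces G with A in place).
#'
#' @param x a [ReferenceSet] or a named character vector of sequences.
#' @return list with elements `c2t` and `g2a`, both named character vectors
#'   of the same lengths as the input.
#' @export
convert_reference <- function(x) {
  seqs <- if (inherits(x, "ReferenceSet")) x$sequences else x
  stopifnot(is.character(seqs))
  for (nm in names(seqs)) {
    bad <- regmatches(seqs[[nm]], gregexpr("[^ACGTN]", seqs[[nm]]))[[1]]
    if (length(bad)) {
      pos <- gregexpr("[^ACGTN]", seqs[[nm]])[[1]][1]
      stopf("sequence %s contains non-nucleotide character '%s' at position %d",
            nm, bad[1], pos)
    }
  }
  list(c2t = chartr("C", "T", seqs), g2a = chartr("G", "A", seqs))
}

#' Read bisulfite alignments from SAM/BAM
#'
#' Yields only mapped records at or above `min_mapq`. The originating
#' transcript strand is taken from the `YS` tag when present; otherwise the
#' stranded-protocol rule applies: a read aligned forward (FLAG bit 0x10
#' unset) derives from a plus-strand transcript, a reverse-aligned read from
#' a minus-strand transcript.
#'
#' @param path a SAM or BAM file.
#' @param min_mapq minimum mapping quality (default 30; advisory — the
#'   uniqueness contract is normally carried by the aligner's MAPQ itself).
#' @return a data.frame of class `bs_alignments` with columns `qname`,
#'   `rname`, `pos` (0-based leftmost), `strand` (transcript strand), `seq`,
#'   `qual`, `cigar`, `mapq`, `flag`.
#' @export
read_alignments <- function(path, min_mapq = 30) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE))
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"),
    tag = "YS"))[[1]]
  keep <- !bitwAnd(res$flag, 4L) & !is.na(res$pos) & res$mapq >= min_mapq
  ys <- res$tag$YS
  strand <- if (!is.null(ys)) ys else
    ifelse(bitwAnd(res$flag, 16L) > 0L, "-", "+")
  out <- data.frame(
    qname = res$qname[keep],
    rname = as.character(res$rname)[keep],
    pos = res$pos[keep] - 1L,
    strand = strand[keep],
    seq = as.character(res$seq)[keep],
    qual = as.character(res$qual)[keep],
    cigar = res$cigar[keep],
    mapq = res$mapq[keep],
    flag = res$flag[keep],
    stringsAsFactors = FALSE)
  class(out) <- c("bs_alignments", "data.frame")
  out
}

#' Write alignments as SAM
#'
#' Emits a minimal SAM file with `@SQ` headers for every reference
#' sequence, FLAG-encoded alignment orientation and the original transcript
#' strand in a `YS:A` tag.
#'
#' @param aln a `bs_alignments` data.frame (see [read_alignments()]).
#' @param refset the [ReferenceSet] the alignments refer to.
#' @param path output SAM path.
#' @return invisibly, `path`.
#' @export
write_sam <- function(aln, refset, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(refset$sequences),
                   nchar(refset$sequences)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tYS:A:%s",
                  aln$qname, aln$flag, aln$rname, aln$pos + 1L, aln$mapq,
                  aln$cigar, aln$seq, aln$qual, aln$strand)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a pileup or candidate-site table as TSV
#'
#' Site tables emit both the 0-based BED-style `pos0` and a 1-based
#' `coord_1based` column.
#'
#' @param x a `bs_pileup` or `bs_candidates` data.frame.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_site_table <- function(x, path) {
  d <- as.data.frame(x)
  if ("pos" %in% names(d)) {
    d$pos0 <- d$pos
    d$coord_1based <- d$pos + 1L
    d$pos <- NULL
  }
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
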