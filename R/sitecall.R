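#' Filter-cascade configuration
#'
#' Holds every threshold of the candidate-site filter cascade. Defaults
#' are the published cascade: reads retaining more than three cytosines
#' are removed (3C); positions where fewer than 90\% of covering reads
#' survive 3C are flagged (S/N90); base calls below phred 30 are ignored
#' and retained cytosines within the terminal 6 nt of a read are masked;
#' a site needs coverage >= 30 (30RC), >= 5 retained cytosines (5C),
#' >= 80\% C+T base calls (80CT) in each replicate, and >= 10\% mean
#' non-conversion across replicates (10MM).
#'
#' @param max_nonconverted_per_read 3C threshold: reads with strictly more
#'   retained cytosines are removed.
#' @param signal_to_noise_min positions with 3C-surviving/raw coverage
#'   below this are suppressed.
#' @param sn_boundary `"lt"` flags when the ratio is strictly below the
#'   threshold; `"le"` also flags equality.
#' @param min_base_quality phred floor for pileup base calls.
#' @param end_mask_nt base calls within this many nt of either read end
#'   carry no methylation evidence (terminal mask).
#' @param mask_as_converted if `TRUE`, a masked retained cytosine is
#'   counted as converted (T) and terminal converted calls keep counting,
#'   instead of the default in which terminal calls carry no evidence.
#' @param min_coverage per-replicate coverage threshold (30RC).
#' @param coverage_basis whether 30RC/80CT are assessed against the
#'   3C-filtered (`"filtered"`, default) or raw (`"raw"`) depth.
#' @param min_c_count per-replicate retained-C threshold (5C).
#' @param min_ct_fraction fraction of identified base calls (post-mask,
#'   post-quality-floor) that must be C or T (80CT mismatch guard).
#' @param min_avg_nonconversion across-replicate mean non-conversion
#'   threshold (10MM).
#' @param require_all_replicates candidate sites must pass the
#'   per-replicate filters in every replicate.
#' @param apply_sn if `FALSE`, the signal-to-noise suppression is skipped
#'   (sensitivity analyses of structure artefacts).
#' @return a list of class `filter_config`.
#' @export
filter_config <- function(max_nonconverted_per_read = 3L,
                          signal_to_noise_min = 0.9,
                          sn_boundary = c("lt", "le"),
                          min_base_quality = 30L,
                          end_mask_nt = 6L,
                          mask_as_converted = FALSE,
                          min_coverage = 30L,
                          coverage_basis = c("filtered", "raw"),
                          min_c_count = 5L,
                          min_ct_fraction = 0.8,
                          min_avg_nonconversion = 0.10,
                          require_all_replicates = TRUE,
                          apply_sn = TRUE) {
  cfg <- as.list(environment())
  cfg$sn_boundary <- match.arg(sn_boundary)
  cfg$coverage_basis <- match.arg(coverage_basis)
  stopifnot(cfg$max_nonconverted_per_read >= 0, cfg$min_coverage >= 0,
            cfg$min_c_count >= 0, cfg$end_mask_nt >= 0)
  fr <- c(cfg$signal_to_noise_min, cfg$min_ct_fraction,
          cfg$min_avg_nonconversion)
  if (any(fr < 0 | fr > 1)) stopf("fractions must lie in [0,1]")
  class(cfg) <- "filter_config"
  cfg
}

# per-alignment context shared by the counting routines: aligned reference
# positions, read offsets, and transcript-strand retained/converted calls
aln_calls <- function(rec_seq, rec_qual, rec_pos, rec_cigar, rec_strand,
                      refraw, co = NULL) {
  if (is.null(co)) co <- parse_cigar(rec_cigar)
  rp <- rec_pos + co$ref            # 0-based reference positions
  qp <- co$read                     # 0-based read offsets
  readraw <- charToRaw(rec_seq)
  refb <- refraw[rp + 1L]
  readb <- readraw[qp + 1L]
  if (rec_strand == "+") {
    isC <- refb == charToRaw("C")
    ret <- isC & readb == charToRaw("C")
    conv <- isC & readb == charToRaw("T")
  } else {
    isC <- refb == charToRaw("G")
    ret <- isC & readb == charToRaw("G")
    conv <- isC & readb == charToRaw("A")
  }
  list(refpos = rp, readoff = qp, isC = isC, retained = ret, converted = conv,
       qual = as.integer(charToRaw(rec_qual)) - 33L, read_len = nchar(rec_seq))
}

#' Count non-converted cytosines in one read
#'
#' Number of aligned positions where the transcript-strand reference base
#' is C and the read retains C (for minus-strand transcripts: plus-strand
#' reference G with read G). Counted over the full read, before any base
#' quality filtering or terminal masking — read-level filtering precedes
#' the pileup.
#'
#' @param record one-row `bs_alignments` data.frame (or list with the same
#'   fields).
#' @param refset a [ReferenceSet].
#' @return integer count.
#' @export
read_nonconversion_count <- function(record, refset) {
  refraw <- charToRaw(refset$sequences[[record$rname]])
  a <- aln_calls(record$seq, record$qual, record$pos, record$cigar,
                 record$strand, refraw)
  sum(a$retained)
}

# vectorised nonconversion counts for a whole alignment set
nonconversion_counts <- function(aln, refset) {
  n <- nrow(aln)
  counts <- integer(n)
  refcache <- lapply(refset$sequences, charToRaw)
  cmap <- cigar_cache(aln$cigar)
  for (i in seq_len(n)) {
    a <- aln_calls(aln$seq[i], aln$qual[i], aln$pos[i], aln$cigar[i],
                   aln$strand[i], refcache[[aln$rname[i]]],
                   co = cmap[[aln$cigar[i]]])
    counts[i] <- sum(a$retained)
  }
  counts
}

cigar_cache <- function(cigars) {
  u <- unique(cigars)
  stats::setNames(lapply(u, parse_cigar), u)
}

#' Remove reads with excess non-conversion (3C filter)
#'
#' @param aln a `bs_alignments` data.frame.
#' @param refset a [ReferenceSet].
#' @param cfg a [filter_config()].
#' @return list with `pass` and `fail` alignment sets and `stats`
#'   (`n_pass`, `n_fail`, `counts`).
#' @export
apply_read_filter <- function(aln, refset, cfg = filter_config()) {
  counts <- nonconversion_counts(aln, refset)
  keep <- counts <= cfg$max_nonconverted_per_read
  pass <- aln[keep, , drop = FALSE]; fail <- aln[!keep, , drop = FALSE]
  class(pass) <- class(fail) <- c("bs_alignments", "data.frame")
  list(pass = pass, fail = fail,
       stats = list(n_pass = sum(keep), n_fail = sum(!keep), counts = counts))
}

#' Build a masked, quality-aware pileup over reference cytosines
#'
#' Raw coverage counts every mapped read; the C/T/other evidence counts
#' only reads surviving the 3C filter, only base calls at or above
#' `min_base_quality`, and treats base calls within `end_mask_nt` of
#' either read end as carrying no methylation evidence (they still
#' contribute to coverage; `mask_as_converted` restores the variant in
#' which a terminal retained C is counted as converted instead). Only
#' transcript-strand reference-C positions are emitted.
#' The signal-to-noise ratio is 3C-surviving over raw coverage; positions
#' below `signal_to_noise_min` are flagged.
#'
#' @param aln a `bs_alignments` data.frame (pre-3C: the function applies
#'   the read filter itself so raw and filtered depth share one pass).
#' @param refset a [ReferenceSet].
#' @param cfg a [filter_config()].
#' @return data.frame of class `bs_pileup`: `seqname`, `pos` (0-based),
#'   `strand`, `gene_id`, `raw_coverage`, `filtered_coverage`, `c_count`,
#'   `t_count`, `other_count`, `raw_c`, `raw_t`, `signal_to_noise`,
#'   `sn_flag`. `raw_c`/`raw_t` are pre-3C, unmasked counts used for
#'   conversion-rate summaries.
#' @export
build_pileup <- function(aln, refset, cfg = filter_config()) {
  spans <- gene_spans(refset)
  refcache <- lapply(refset$sequences, charToRaw)
  cmap <- cigar_cache(aln$cigar)
  counts3c <- nonconversion_counts(aln, refset)
  pass3c <- counts3c <= cfg$max_nonconverted_per_read

  # reference-C index per (seqname, strand): map genomic pos -> row
  out <- list()
  mismatch_total <- 0L; call_total <- 0L
  for (sq in unique(aln$rname)) {
    gsp <- spans[spans$seqname == sq, ]
    rows <- which(aln$rname == sq)
    for (strand in unique(aln$strand[rows])) {
      ch <- ts_chars(refset$sequences[[sq]], strand)
      cpos <- which(ch == "C") - 1L
      if (!length(cpos)) next
      idx_of <- rep(NA_integer_, nchar(refset$sequences[[sq]]))
      idx_of[cpos + 1L] <- seq_along(cpos)
      np <- length(cpos)
      rawcov <- integer(np); filtcov <- integer(np)
      cc <- integer(np); tc <- integer(np); oc <- integer(np)
      rc <- integer(np); rt <- integer(np)
      srows <- rows[aln$strand[rows] == strand]
      for (i in srows) {
        a <- aln_calls(aln$seq[i], aln$qual[i], aln$pos[i], aln$cigar[i],
                       strand, refcache[[sq]], co = cmap[[aln$cigar[i]]])
        ci <- which(a$isC)
        if (!length(ci)) next
        at <- idx_of[a$refpos[ci] + 1L]
        ok <- !is.na(at)
        ci <- ci[ok]; at <- at[ok]
        rawcov[at] <- rawcov[at] + 1L
        bq_ok <- a$qual[a$readoff[ci] + 1L] >= cfg$min_base_quality
        retained <- a$retained[ci]; converted <- a$converted[ci]
        call_total <- call_total + sum(bq_ok)
        mismatch_total <- mismatch_total + sum(bq_ok & !retained & !converted)
        # pre-3C, unmasked conversion-rate counts
        rc[at[bq_ok & retained]] <- rc[at[bq_ok & retained]] + 1L
        rt[at[bq_ok & converted]] <- rt[at[bq_ok & converted]] + 1L
        if (!pass3c[i]) next
        filtcov[at] <- filtcov[at] + 1L
        masked <- a$readoff[ci] < cfg$end_mask_nt |
          a$readoff[ci] >= a$read_len - cfg$end_mask_nt
        if (cfg$mask_as_converted) {
          # alternative: terminal retained C counted as converted; makes
          # masking strictly monotone (non-conversion can only drop) at
          # the cost of a downward bias at methylated sites
          add_c <- bq_ok & retained & !masked
          add_t <- bq_ok & (converted | (retained & masked))
          add_o <- bq_ok & !retained & !converted
        } else {
          # default: terminal positions carry no evidence at all, so the
          # c/(c+t) estimator stays unbiased under the mask
          add_c <- bq_ok & retained & !masked
          add_t <- bq_ok & converted & !masked
          add_o <- bq_ok & !retained & !converted & !masked
        }
        cc[at[add_c]] <- cc[at[add_c]] + 1L
        tc[at[add_t]] <- tc[at[add_t]] + 1L
        oc[at[add_o]] <- oc[at[add_o]] + 1L
      }
      covered <- rawcov > 0L
      if (!any(covered)) next
      gsp_s <- gsp[gsp$strand == strand, ]
      gene_at <- rep(NA_character_, np)
      for (k in seq_len(nrow(gsp_s)))
        gene_at[cpos >= gsp_s$start[k] & cpos < gsp_s$end[k]] <- gsp_s$gene_id[k]
      sn <- ifelse(rawcov > 0, filtcov / rawcov, 1)
      flag <- if (cfg$sn_boundary == "lt") sn < cfg$signal_to_noise_min else
        sn <= cfg$signal_to_noise_min
      out[[length(out) + 1L]] <- data.frame(
        seqname = sq, pos = cpos[covered], strand = strand,
        gene_id = gene_at[covered],
        raw_coverage = rawcov[covered], filtered_coverage = filtcov[covered],
        c_count = cc[covered], t_count = tc[covered],
        other_count = oc[covered], raw_c = rc[covered], raw_t = rt[covered],
        signal_to_noise = sn[covered], sn_flag = flag[covered],
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame(
    seqname = character(0), pos = integer(0), strand = character(0),
    gene_id = character(0), raw_coverage = integer(0),
    filtered_coverage = integer(0), c_count = integer(0),
    t_count = integer(0), other_count = integer(0), raw_c = integer(0),
    raw_t = integer(0), signal_to_noise = numeric(0), sn_flag = logical(0))
  rownames(res) <- NULL
  if (call_total > 0 && mismatch_total / call_total > 0.05)
    warning(sprintf("reference mismatch rate %.1f%% at cytosine positions",
                    100 * mismatch_total / call_total))
  class(res) <- c("bs_pileup", "data.frame")
  res
}

#' Call candidate positions in one replicate
#'
#' Applies the per-replicate thresholds (30RC, 5C, 80CT) and the
#' signal-to-noise suppression to a pileup; non-conversion is
#' `c / (c + t)`.
#'
#' @param columns a `bs_pileup` from one composite replicate.
#' @param cfg a [filter_config()].
#' @return data.frame of passing positions with a `nonconversion` column.
#' @export
call_replicate_sites <- function(columns, cfg = filter_config()) {
  cov <- if (cfg$coverage_basis == "filtered") columns$filtered_coverage else
    columns$raw_coverage
  ct <- columns$c_count + columns$t_count
  calls <- ct + columns$other_count   # identified base calls (post-mask/BQ)
  pass <- cov >= cfg$min_coverage &
    columns$c_count >= cfg$min_c_count &
    ifelse(calls > 0, ct / calls, 0) >= cfg$min_ct_fraction
  if (cfg$apply_sn) pass <- pass & !columns$sn_flag
  res <- columns[pass, , drop = FALSE]
  res$nonconversion <- ifelse(res$c_count + res$t_count > 0,
                              res$c_count / (res$c_count + res$t_count), 0)
  rownames(res) <- NULL
  class(res) <- c("bs_sites", "data.frame")
  res
}

#' Merge replicate calls into candidate sites
#'
#' A position is a candidate site when it passes the per-replicate filters
#' in every replicate (under `require_all_replicates`) and its mean
#' per-replicate non-conversion is at least `min_avg_nonconversion`
#' (10MM). The mean is the mean of per-replicate proportions, not a
#' pooled-count ratio.
#'
#' @param replicate_calls list of per-replicate call tables from
#'   [call_replicate_sites()].
#' @param cfg a [filter_config()].
#' @return data.frame of class `bs_candidates`: locus columns,
#'   `n_replicates`, per-replicate non-conversion (`nonconv_rep<i>`),
#'   `avg_nonconversion`, `rna_class`.
#' @export
combine_replicates <- function(replicate_calls, cfg = filter_config()) {
  n_rep <- length(replicate_calls)
  if (n_rep < 2) stopf("need at least 2 replicates, got %d", n_rep)
  keyed <- lapply(replicate_calls, function(d) {
    d$key <- paste(d$seqname, d$pos, d$strand, sep = ":")
    d
  })
  all_keys <- unique(unlist(lapply(keyed, `[[`, "key")))
  if (!length(all_keys)) {
    res <- data.frame(seqname = character(0), pos = integer(0),
                      strand = character(0), gene_id = character(0),
                      n_replicates = integer(0),
                      avg_nonconversion = numeric(0))
    class(res) <- c("bs_candidates", "data.frame")
    return(res)
  }
  present <- sapply(keyed, function(d) all_keys %in% d$key)
  nonconv <- sapply(keyed, function(d)
    d$nonconversion[match(all_keys, d$key)])
  if (length(all_keys) == 1) {
    present <- matrix(present, nrow = 1)
    nonconv <- matrix(nonconv, nrow = 1)
  }
  n_present <- rowSums(present)
  avg <- rowMeans(nonconv, na.rm = TRUE)
  keep <- if (cfg$require_all_replicates) n_present == n_rep else n_present >= 2
  keep <- keep & avg >= cfg$min_avg_nonconversion
  keep[is.na(keep)] <- FALSE
  ref <- keyed[[1]][match(all_keys, keyed[[1]]$key), c("seqname", "pos",
                                                       "strand", "gene_id")]
  for (j in seq_len(n_rep)) {
    miss <- is.na(ref$seqname)
    if (!any(miss)) break
    alt <- keyed[[j]][match(all_keys, keyed[[j]]$key),
                      c("seqname", "pos", "strand", "gene_id")]
    ref[miss, ] <- alt[miss, ]
  }
  res <- cbind(ref, n_replicates = n_present,
               stats::setNames(as.data.frame(nonconv),
                               paste0("nonconv_rep", seq_len(n_rep))),
               avg_nonconversion = avg)
  res <- res[keep, , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("bs_candidates", "data.frame")
  res
}

#' Per-class cytosine conversion summary
#'
#' Conversion is the fraction of converted calls, `sum(t) / sum(c + t)`,
#' aggregated over all reference-C positions of each RNA class. Reported
#' both on the initial mapping (pre-3C, unmasked counts) and after the 3C
#' filter and terminal mask.
#'
#' @param columns a `bs_pileup`.
#' @param class_of named character vector mapping gene ids to classes;
#'   unknown genes are grouped as `"other"`.
#' @return data.frame with columns `rna_class`, `conversion_raw`,
#'   `conversion_3c`, `n_positions`.
#' @export
summarize_conversion <- function(columns, class_of) {
  cls <- class_of[columns$gene_id]
  cls[is.na(cls)] <- "other"
  agg <- function(v, by) tapply(v, by, sum)
  rcl <- sort(unique(cls))
  rc <- agg(columns$raw_c, cls)[rcl]; rt <- agg(columns$raw_t, cls)[rcl]
  cc <- agg(columns$c_count, cls)[rcl]; tc <- agg(columns$t_count, cls)[rcl]
  data.frame(rna_class = rcl,
             conversion_raw = as.numeric(rt / (rc + rt)),
             conversion_3c = as.numeric(tc / (cc + tc)),
             n_positions = as.integer(table(cls)[rcl]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call tRNA sites from processed reads
#'
#' Restricts the alignments of tRNA genes to reads fully contained in the
#' predicted mature tRNA region ("processed" reads), then runs the
#' standard per-replicate cascade and replicate merge. Sites are reported
#' in gene coordinates with an additional mature-region offset.
#'
#' @param aln_replicates list of `bs_alignments`, one per replicate.
#' @param refset a [ReferenceSet] with `mature_region_of` entries.
#' @param cfg a [filter_config()].
#' @return a `bs_candidates` data.frame with an extra `mature_offset`
#'   column.
#' @export
call_trna_sites <- function(aln_replicates, refset, cfg = filter_config()) {
  trna_genes <- names(refset$class_of)[refset$class_of == "tRNA"]
  if (!length(trna_genes)) {
    res <- data.frame()
    class(res) <- c("bs_candidates", "data.frame")
    return(res)
  }
  mr <- refset$mature_region_of
  missing <- setdiff(trna_genes, mr$gene_id)
  if (length(missing))
    stopf("tRNA gene(s) without a mature region: %s",
          paste(missing, collapse = ", "))
  spans <- gene_spans(refset)
  calls <- lapply(aln_replicates, function(aln) {
    span_len <- vapply(aln$cigar, function(cg) {
      toks <- regmatches(cg, gregexpr("\\d+[MN]", cg))[[1]]
      sum(as.integer(sub("[MN]", "", toks)))
    }, integer(1), USE.NAMES = FALSE)
    keep <- logical(nrow(aln))
    for (g in trna_genes) {
      sq <- spans$seqname[spans$gene_id == g]
      m <- mr[mr$gene_id == g, ]
      keep <- keep | (aln$rname == sq & aln$pos >= m$start &
                        aln$pos + span_len <= m$end)
    }
    sub <- aln[keep, , drop = FALSE]
    class(sub) <- c("bs_alignments", "data.frame")
    if (!nrow(sub)) return(call_replicate_sites(
      build_pileup(sub, refset, cfg), cfg))
    call_replicate_sites(build_pileup(sub, refset, cfg), cfg)
  })
  if (all(vapply(calls, nrow, 0L) == 0)) {
    res <- data.frame()
    class(res) <- c("bs_candidates", "data.frame")
    return(res)
  }
  res <- combine_replicates(calls, cfg)
  if (nrow(res)) {
    mo <- integer(nrow(res))
    for (i in seq_len(nrow(res))) {
      g <- res$gene_id[i]
      m <- mr[mr$gene_id == g, ]
      mo[i] <- res$pos[i] - m$start
    }
    res$mature_offset <- mo
  }
  res
}
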