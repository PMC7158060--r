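# Site annotation, metagene/enrichment analyses, sequence context, codon
# bias and secondary-structure profiles.

# 0-based spliced offset (distance from transcript 5' end) of a genomic
# position, or NA if the position is intronic
spliced_offset <- function(exons, strand, gpos) {
  ex <- exons[order(exons$start), , drop = FALSE]
  inex <- which(gpos >= ex$start & gpos < ex$end)
  if (!length(inex)) return(NA_integer_)
  widths <- ex$end - ex$start
  if (strand == "+") {
    before <- if (inex > 1) sum(widths[seq_len(inex - 1)]) else 0L
    as.integer(before + gpos - ex$start[inex])
  } else {
    n <- nrow(ex)
    after <- if (inex < n) sum(widths[(inex + 1):n]) else 0L
    as.integer(after + ex$end[inex] - 1L - gpos)
  }
}

# spliced [start, end) interval of a transcript's CDS, or NULL
cds_spliced_interval <- function(refset, transcript_id) {
  if (is.null(refset$cds)) return(NULL)
  cd <- refset$cds[refset$cds$transcript_id == transcript_id, ]
  if (!nrow(cd)) return(NULL)
  ex <- refset$exons[refset$exons$transcript_id == transcript_id, ]
  strand <- refset$transcripts$strand[
    refset$transcripts$transcript_id == transcript_id]
  ends <- c(spliced_offset(ex, strand, cd$start),
            spliced_offset(ex, strand, cd$end - 1L))
  c(min(ends), max(ends) + 1L)
}

# spliced-coordinate transcript sequence (transcript strand, 5'->3')
transcript_sequence <- function(refset, transcript_id) {
  tr <- refset$transcripts[refset$transcripts$transcript_id == transcript_id, ]
  ex <- refset$exons[refset$exons$transcript_id == transcript_id, ]
  ex <- ex[order(ex$start), ]
  parts <- vapply(seq_len(nrow(ex)), function(k)
    substr(refset$sequences[[tr$seqname]], ex$start[k] + 1L, ex$end[k]),
    character(1))
  s <- paste(parts, collapse = "")
  if (tr$strand == "-") s <- revcomp(s)
  s
}

#' Annotate candidate sites to transcript features
#'
#' Each site is assigned to the longest transcript (spliced length; ties
#' broken by lexicographic transcript id) of the overlapping same-strand
#' gene, and classified as one of `5UTR`, `CDS`, `3UTR`, `intronic`,
#' `ncRNA_exonic`, `ncRNA_intronic` or `intergenic`. For CDS sites the
#' 1-based codon index and codon position (1/2/3) are computed from the
#' spliced CDS offset.
#'
#' @param sites data.frame with `seqname`, `pos` (0-based), `strand`.
#' @param refset a [ReferenceSet].
#' @return the input with columns `gene_id`, `transcript_id`, `feature`,
#'   `spliced_offset`, `codon_index`, `codon_pos`, `rna_class` appended.
#' @export
annotate_sites <- function(sites, refset) {
  spans <- gene_spans(refset)
  n <- nrow(sites)
  gene_id <- transcript_id <- feature <- rna_class <- rep(NA_character_, n)
  so <- codon_index <- codon_pos <- rep(NA_integer_, n)
  # spliced lengths once
  sl <- vapply(refset$transcripts$transcript_id,
               function(t) spliced_length(refset, t), numeric(1))
  names(sl) <- refset$transcripts$transcript_id
  for (i in seq_len(n)) {
    hit <- spans[spans$seqname == sites$seqname[i] &
                   spans$strand == sites$strand[i] &
                   spans$start <= sites$pos[i] & spans$end > sites$pos[i], ]
    if (!nrow(hit)) { feature[i] <- "intergenic"; next }
    g <- hit$gene_id[1]
    gene_id[i] <- g
    rna_class[i] <- refset$class_of[[g]]
    cand <- refset$transcripts[refset$transcripts$gene_id == g, ]
    ord <- order(-sl[cand$transcript_id], cand$transcript_id)
    tid <- cand$transcript_id[ord[1]]
    transcript_id[i] <- tid
    ex <- refset$exons[refset$exons$transcript_id == tid, ]
    off <- spliced_offset(ex, hit$strand[1], sites$pos[i])
    coding <- cand$biotype[ord[1]] == "protein_coding"
    if (is.na(off)) {
      feature[i] <- if (coding) "intronic" else "ncRNA_intronic"
      next
    }
    so[i] <- off
    if (!coding) { feature[i] <- "ncRNA_exonic"; next }
    cdsi <- cds_spliced_interval(refset, tid)
    if (is.null(cdsi)) { feature[i] <- "ncRNA_exonic"; next }
    if (off < cdsi[1]) feature[i] <- "5UTR"
    else if (off >= cdsi[2]) feature[i] <- "3UTR"
    else {
      feature[i] <- "CDS"
      rel <- off - cdsi[1]
      codon_index[i] <- rel %/% 3L + 1L
      codon_pos[i] <- rel %% 3L + 1L
    }
  }
  out <- cbind(sites, gene_id = gene_id, transcript_id = transcript_id,
               feature = feature, spliced_offset = so,
               codon_index = codon_index, codon_pos = codon_pos,
               rna_class = rna_class)
  rownames(out) <- NULL
  out
}

# per-transcript feature lengths (5UTR/CDS/3UTR) in spliced coordinates
feature_lengths <- function(refset, transcript_id) {
  cdsi <- cds_spliced_interval(refset, transcript_id)
  tl <- spliced_length(refset, transcript_id)
  if (is.null(cdsi)) return(NULL)
  c(utr5 = cdsi[1], cds = cdsi[2] - cdsi[1], utr3 = tl - cdsi[2])
}

#' Metagene distribution of sites along scaled mRNAs
#'
#' Maps every exonic protein-coding site onto a composite
#' 5'UTR--CDS--3'UTR axis whose segment widths are proportional to the
#' median (default) or mean feature lengths of the represented
#' transcripts; relative position within the feature determines the
#' position within the segment. The background is every transcript-strand
#' C within the same features of the same transcripts. Both densities are
#' normalised to sum to 1.
#'
#' @param annot annotated sites from [annotate_sites()].
#' @param refset a [ReferenceSet].
#' @param n_bins histogram bins over the composite axis.
#' @param scaling `"median"` or `"mean"` feature-length scaling.
#' @return list of class `bs_metagene`: `site_density`,
#'   `background_density`, `mids`, `widths`, `n_sites`, `n_skipped`.
#' @export
metagene_profile <- function(annot, refset, n_bins = 60,
                             scaling = c("median", "mean")) {
  scaling <- match.arg(scaling)
  use <- annot[!is.na(annot$feature) &
                 annot$feature %in% c("5UTR", "CDS", "3UTR"), , drop = FALSE]
  n_skipped <- nrow(annot) - nrow(use)
  if (!nrow(use)) stopf("no exonic mRNA sites to profile")
  tids <- unique(use$transcript_id)
  fl <- do.call(rbind, lapply(tids, function(t) feature_lengths(refset, t)))
  rownames(fl) <- tids
  agg <- if (scaling == "median") apply(fl, 2, stats::median) else colMeans(fl)
  widths <- agg / sum(agg)
  offsets <- c(0, cumsum(widths))[1:3]
  names(offsets) <- c("5UTR", "CDS", "3UTR")

  pos_on_axis <- function(tid, feature, off) {
    l <- fl[tid, ]
    cdsi <- cds_spliced_interval(refset, tid)
    rel <- switch(feature,
                  "5UTR" = off / max(1, l["utr5"]),
                  "CDS" = (off - cdsi[1]) / max(1, l["cds"]),
                  "3UTR" = (off - cdsi[2]) / max(1, l["utr3"]))
    offsets[[feature]] + rel * widths[[which(c("5UTR", "CDS", "3UTR") == feature)]]
  }
  x_sites <- mapply(pos_on_axis, use$transcript_id, use$feature,
                    use$spliced_offset)
  # background: all Cs of the represented transcripts, feature-resolved
  xb <- list()
  for (tid in tids) {
    s <- transcript_sequence(refset, tid)
    cpos <- which(strsplit(s, "", fixed = TRUE)[[1]] == "C") - 1L
    cdsi <- cds_spliced_interval(refset, tid)
    tl <- nchar(s)
    for (p in cpos) {
      f <- if (p < cdsi[1]) "5UTR" else if (p >= cdsi[2]) "3UTR" else "CDS"
      xb[[length(xb) + 1L]] <- pos_on_axis(tid, f, p)
    }
  }
  x_bg <- unlist(xb)
  br <- seq(0, 1, length.out = n_bins + 1)
  clamp <- function(x) pmin(pmax(x, 0), 1 - 1e-12)
  hs <- graphics::hist(clamp(x_sites), breaks = br, plot = FALSE)$counts
  hb <- graphics::hist(clamp(x_bg), breaks = br, plot = FALSE)$counts
  structure(list(site_density = hs / sum(hs),
                 background_density = hb / sum(hb),
                 mids = (br[-1] + br[-length(br)]) / 2, widths = widths,
                 n_sites = nrow(use), n_skipped = n_skipped),
            class = "bs_metagene")
}

#' @export
plot.bs_metagene <- function(x, ...) {
  graphics::plot(x$mids, x$site_density, type = "l", col = "steelblue",
                 xlab = "scaled mRNA position", ylab = "density",
                 ylim = range(0, x$site_density, x$background_density), ...)
  graphics::lines(x$mids, x$background_density, col = "grey50")
  graphics::abline(v = cumsum(x$widths)[1:2], lty = 2)
  graphics::legend("topright", c("sites", "background C"), lty = 1,
                   col = c("steelblue", "grey50"), bty = "n")
  invisible(x)
}

#' Binned spatial enrichment of sites around an anchor
#'
#' Places sites into fixed-width bins relative to an anchor (first
#' position of the start or stop codon, transcript start or end) and
#' compares each bin's occupancy against a randomised-cytosine null drawn
#' uniformly from the unmodified Cs of the same transcripts (aggregated
#' over `n_null` resamples). Each bin yields a Fisher's exact 2x2 test
#' (in-bin vs out-of-bin, observed vs null) with odds ratio, 95\% CI and
#' BH-adjusted p.
#'
#' @param annot annotated sites from [annotate_sites()].
#' @param refset a [ReferenceSet].
#' @param anchor one of `"start_codon"`, `"stop_codon"`,
#'   `"transcript_start"`, `"transcript_end"`.
#' @param window length-2 vector, e.g. `c(-400, 1000)`; must be divisible
#'   into `bin_width` bins.
#' @param bin_width bin width (nt).
#' @param n_null number of null resamples aggregated.
#' @param seed RNG seed for the null.
#' @return data.frame: `bin_start`, `bin_end`, `observed`, `null`,
#'   `odds_ratio`, `ci_lo`, `ci_hi`, `p`, `padj`, `degenerate` (flag for
#'   Haldane--Anscombe-corrected zero cells).
#' @export
binned_enrichment <- function(annot, refset,
                              anchor = c("start_codon", "stop_codon",
                                         "transcript_start", "transcript_end"),
                              window = c(-400, 1000), bin_width = 100,
                              n_null = 100, seed = 1L) {
  anchor <- match.arg(anchor)
  if ((window[2] - window[1]) %% bin_width != 0)
    stopf("window must be divisible by bin_width")
  set.seed(seed)
  use <- annot[!is.na(annot$transcript_id) & !is.na(annot$spliced_offset) &
                 annot$rna_class %in% "mRNA", , drop = FALSE]
  tids <- unique(use$transcript_id)
  anchor_of <- function(tid) {
    cdsi <- cds_spliced_interval(refset, tid)
    switch(anchor,
           start_codon = cdsi[1],
           stop_codon = cdsi[2] - 3L,
           transcript_start = 0L,
           transcript_end = spliced_length(refset, tid))
  }
  anchors <- vapply(tids, anchor_of, numeric(1))
  names(anchors) <- tids
  rel <- use$spliced_offset - anchors[use$transcript_id]
  in_win <- rel >= window[1] & rel < window[2]
  obs_rel <- rel[in_win]
  # null pool: unmodified Cs of the same transcripts, in-window
  site_key <- paste(use$transcript_id, use$spliced_offset)
  pool <- numeric(0)
  for (tid in tids) {
    s <- transcript_sequence(refset, tid)
    cpos <- which(strsplit(s, "", fixed = TRUE)[[1]] == "C") - 1L
    cpos <- cpos[!(paste(tid, cpos) %in% site_key)]
    r <- cpos - anchors[[tid]]
    pool <- c(pool, r[r >= window[1] & r < window[2]])
  }
  if (!length(pool)) stopf("no background cytosines in window")
  null_rel <- sample(pool, length(obs_rel) * n_null, replace = TRUE)
  br <- seq(window[1], window[2], by = bin_width)
  obs_ct <- graphics::hist(obs_rel, breaks = br, right = FALSE,
                           plot = FALSE)$counts
  null_ct <- graphics::hist(null_rel, breaks = br, right = FALSE,
                            plot = FALSE)$counts
  nb <- length(obs_ct)
  res <- data.frame(bin_start = br[-length(br)], bin_end = br[-1],
                    observed = obs_ct, null = null_ct,
                    odds_ratio = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                    p = NA_real_, degenerate = FALSE)
  for (b in seq_len(nb)) {
    m <- matrix(c(obs_ct[b], sum(obs_ct) - obs_ct[b],
                  null_ct[b], sum(null_ct) - null_ct[b]), 2, byrow = TRUE)
    ft <- stats::fisher.test(m)
    res$p[b] <- ft$p.value
    if (any(m == 0)) {
      mh <- m + 0.5  # Haldane-Anscombe
      res$odds_ratio[b] <- (mh[1, 1] * mh[2, 2]) / (mh[1, 2] * mh[2, 1])
      se <- sqrt(sum(1 / mh))
      res$ci_lo[b] <- exp(log(res$odds_ratio[b]) - 1.96 * se)
      res$ci_hi[b] <- exp(log(res$odds_ratio[b]) + 1.96 * se)
      res$degenerate[b] <- TRUE
    } else {
      res$odds_ratio[b] <- unname(ft$estimate)
      res$ci_lo[b] <- ft$conf.int[1]; res$ci_hi[b] <- ft$conf.int[2]
    }
  }
  res$padj <- stats::p.adjust(res$p, method = "BH")
  res
}

#' Sequence-context position frequency matrix
#'
#' Extracts the transcript-strand 21-nt window (for `flank = 10`) centred
#' on each site from the genomic sequence, and tabulates base frequencies
#' per position; a matching background matrix uses every transcript-strand
#' C of the genes carrying sites. T is reported as U (RNA alphabet).
#'
#' @param sites data.frame with `seqname`, `pos`, `strand` (annotated
#'   sites work as-is).
#' @param refset a [ReferenceSet].
#' @param flank half-window (nt).
#' @return list: `pfm` and `background` (4 x (2*flank+1) count matrices
#'   over A/C/G/U), `n_sites`, `n_dropped`.
#' @export
context_matrix <- function(sites, refset, flank = 10) {
  window_of <- function(sq, pos, strand) {
    L <- nchar(refset$sequences[[sq]])
    if (pos - flank < 0 || pos + flank >= L) return(NULL)
    w <- substr(refset$sequences[[sq]], pos - flank + 1L, pos + flank + 1L)
    if (strand == "-") w <- revcomp(w)
    w
  }
  tab <- function(windows) {
    m <- matrix(0L, 4, 2 * flank + 1,
                dimnames = list(c("A", "C", "G", "U"),
                                as.character(-flank:flank)))
    for (w in windows) {
      ch <- chartr("T", "U", strsplit(w, "", fixed = TRUE)[[1]])
      for (j in seq_along(ch))
        if (ch[j] %in% rownames(m)) m[ch[j], j] <- m[ch[j], j] + 1L
    }
    m
  }
  wins <- list(); dropped <- 0L
  for (i in seq_len(nrow(sites))) {
    w <- window_of(sites$seqname[i], sites$pos[i], sites$strand[i])
    if (is.null(w)) dropped <- dropped + 1L else wins[[length(wins) + 1L]] <- w
  }
  pfm <- tab(wins)
  # background: all transcript-strand Cs of genes bearing sites
  genes <- unique(stats::na.omit(
    if ("gene_id" %in% names(sites)) sites$gene_id else NULL))
  if (!length(genes)) {
    spans <- gene_spans(refset)
    genes <- unique(spans$gene_id[spans$seqname %in% sites$seqname])
  }
  spans <- gene_spans(refset)
  bwins <- list()
  for (g in genes) {
    sp <- spans[spans$gene_id == g, ]
    ch <- ts_chars(refset$sequences[[sp$seqname]], sp$strand)
    cpos <- which(ch == "C") - 1L
    cpos <- cpos[cpos >= sp$start & cpos < sp$end]
    for (p in cpos) {
      w <- window_of(sp$seqname, p, sp$strand)
      if (!is.null(w)) bwins[[length(bwins) + 1L]] <- w
    }
  }
  list(pfm = pfm, background = tab(bwins), n_sites = length(wins),
       n_dropped = dropped)
}

#' Codon and codon-position enrichment of CDS sites
#'
#' For every (codon, codon position) combination, tests whether sites at
#' that position fall on the codon more often than expected from overall
#' codon usage in the represented transcripts (Fisher's exact test,
#' BH-adjusted).
#'
#' @param annot annotated sites from [annotate_sites()] (CDS rows used).
#' @param refset a [ReferenceSet].
#' @return data.frame: `codon`, `codon_pos`, `n_sites`, `codon_usage`,
#'   `odds_ratio`, `p`, `padj`; empty when no CDS sites exist.
#' @export
codon_position_enrichment <- function(annot, refset) {
  cds_sites <- annot[!is.na(annot$feature) & annot$feature == "CDS", ,
                     drop = FALSE]
  empty <- data.frame(codon = character(0), codon_pos = integer(0),
                      n_sites = integer(0), codon_usage = integer(0),
                      odds_ratio = numeric(0), p = numeric(0),
                      padj = numeric(0))
  if (!nrow(cds_sites)) return(empty)
  tids <- unique(cds_sites$transcript_id)
  # codon usage across represented transcripts
  usage <- integer(0)
  codon_of_site <- character(nrow(cds_sites))
  for (tid in tids) {
    s <- transcript_sequence(refset, tid)
    cdsi <- cds_spliced_interval(refset, tid)
    cds_seq <- substr(s, cdsi[1] + 1L, cdsi[2])
    cods <- substring(cds_seq, seq(1, nchar(cds_seq) - 2, 3),
                      seq(3, nchar(cds_seq), 3))
    t_us <- table(cods)
    for (cd in names(t_us))
      usage[cd] <- (if (is.na(usage[cd])) 0L else usage[cd]) + t_us[[cd]]
    rows <- which(cds_sites$transcript_id == tid)
    codon_of_site[rows] <- cods[cds_sites$codon_index[rows]]
  }
  total_usage <- sum(usage)
  out <- list()
  for (pos in 1:3) {
    at_pos <- cds_sites$codon_pos == pos
    n_pos <- sum(at_pos)
    if (!n_pos) next
    for (cd in names(usage)) {
      a <- sum(at_pos & codon_of_site == cd)
      if (a == 0) next
      m <- matrix(c(a, n_pos - a,
                    usage[[cd]] - a, total_usage - usage[[cd]] - (n_pos - a)),
                  2, byrow = TRUE)
      ft <- stats::fisher.test(m)
      out[[length(out) + 1L]] <- data.frame(
        codon = cd, codon_pos = pos, n_sites = a, codon_usage = usage[[cd]],
        odds_ratio = unname(ft$estimate), p = ft$p.value)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res$padj <- stats::p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  res
}
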