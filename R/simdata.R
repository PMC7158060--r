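#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: a stranded
#' bisulfite RNA-seq experiment over 4 polysome fractions x 3 biological
#' replicates, with a small per-cytosine conversion-failure rate, planted
#' m5C sites whose stoichiometry varies across fractions, fully
#' unmethylated spike-ins, tRNA-like genes with clustered sites inside a
#' mature region flanked by 100-nt precursor sequence, and rRNA-like genes
#' carrying structure-correlated non-conversion clusters.
#'
#' @param n_mrna_genes,n_trna_genes,n_rrna_genes,n_spikeins gene counts per
#'   RNA class.
#' @param gene_length_range spliced mRNA length range (nt).
#' @param utr_cds_proportions fractions of spliced length assigned to
#'   5'UTR/CDS/3'UTR; must sum to 1.
#' @param conversion_failure_rate probability that an unmethylated cytosine
#'   escapes conversion (default 0.002, i.e. 99.8\% conversion).
#' @param planted_site_count number of m5C sites planted on mRNA genes.
#' @param stoichiometry_by_fraction optional matrix (`planted_site_count` x
#'   `n_fractions`) of per-fraction methylation fractions; when `NULL`,
#'   sites receive a base stoichiometry drawn uniformly from
#'   `stoichiometry_range` and a trend (negative/neutral/positive in equal
#'   proportion) of `trend_step` per fraction step.
#' @param stoichiometry_range range for base stoichiometry when profiles
#'   are auto-generated.
#' @param trend_step per-fraction stoichiometry increment used for planted
#'   positive/negative trends.
#' @param structure_cluster_spec list with `n` (clusters, placed on
#'   rRNA-like genes), `width` (nt window holding 5 clustered Cs) and `p`
#'   (probability that a read covering the cluster co-retains C at all of
#'   its cytosines — the structure-driven conversion-failure artefact).
#' @param read_length read length (nt).
#' @param coverage_mean expected read depth per position.
#' @param base_quality_model list with `high`, `low` phred scores and
#'   `p_low`, the probability of a low-quality call.
#' @param n_fractions,n_replicates experiment layout (4 x 3 by default).
#' @param replicate_concentration Beta concentration of replicate-level
#'   stoichiometry jitter; 200 keeps replicates tightly concordant.
#' @param end_bias_rate probability that a cytosine within 6 nt of a read
#'   end spuriously retains C (the read-end artefact the terminal mask
#'   exists for); set 0 to disable.
#' @param trna_sites_range number of clustered sites planted per tRNA-like
#'   gene, sampled uniformly from this range.
#' @param spliced_transcripts if `TRUE`, mRNA genes may carry multi-exon
#'   transcripts (introns in the genomic sequence).
#' @param spliced_read_rate fraction of mRNA reads emitted with a single
#'   N gap in the CIGAR (default 0: all reads ungapped), to exercise
#'   splice-aware pileups.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_mrna_genes = 20, n_trna_genes = 4, n_rrna_genes = 2,
                       n_spikeins = 2,
                       gene_length_range = c(1200L, 2400L),
                       utr_cds_proportions = c(0.1, 0.5, 0.4),
                       conversion_failure_rate = 0.002,
                       planted_site_count = 30,
                       stoichiometry_by_fraction = NULL,
                       stoichiometry_range = c(0.2, 0.6),
                       trend_step = 0.08,
                       structure_cluster_spec = list(n = 2, width = 12, p = 0.25),
                       read_length = 100L,
                       coverage_mean = 50,
                       base_quality_model = list(high = 37L, low = 20L,
                                                 p_low = 0.02),
                       n_fractions = 4L, n_replicates = 3L,
                       replicate_concentration = 200,
                       end_bias_rate = 0.01,
                       trna_sites_range = c(1L, 4L),
                       spliced_transcripts = TRUE,
                       spliced_read_rate = 0) {
  cfg <- as.list(environment())
  if (abs(sum(cfg$utr_cds_proportions) - 1) > 1e-9)
    stopf("utr_cds_proportions must sum to 1")
  probs <- c(cfg$conversion_failure_rate, cfg$end_bias_rate,
             cfg$structure_cluster_spec$p, cfg$base_quality_model$p_low)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0,1]")
  if (!is.null(cfg$stoichiometry_by_fraction)) {
    m <- cfg$stoichiometry_by_fraction
    if (!is.matrix(m) || ncol(m) != cfg$n_fractions)
      stopf("stoichiometry_by_fraction must be a matrix with n_fractions columns")
    if (any(m < 0 | m > 1)) stopf("stoichiometries must lie in [0,1]")
  }
  class(cfg) <- "sim_config"
  cfg
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# sample() guards: never fall into the scalar-x expansion
sample1 <- function(x) x[sample.int(length(x), 1L)]
sample_range <- function(lo, hi)
  if (lo >= hi) as.integer(lo) else
    as.integer(lo + sample.int(hi - lo + 1L, 1L) - 1L)

# planted stoichiometry profiles: base level plus a monotone trend across
# fractions, clipped to [0.02, 0.98]
make_profiles <- function(n, cfg) {
  base <- stats::runif(n, cfg$stoichiometry_range[1], cfg$stoichiometry_range[2])
  trend <- sample(c("negative", "neutral", "positive"), n, replace = TRUE)
  step <- ifelse(trend == "negative", -cfg$trend_step,
                 ifelse(trend == "positive", cfg$trend_step, 0))
  prof <- sapply(seq_len(cfg$n_fractions), function(f)
    pmin(0.98, pmax(0.02, base + (f - (cfg$n_fractions + 1) / 2) * step)))
  list(profiles = matrix(prof, nrow = n), trend = trend)
}

#' Build a synthetic reference set with planted methylation truth
#'
#' Generates one reference sequence per gene: mRNA-like genes (optionally
#' multi-exon, alternating strand, UTR/CDS/UTR structure), tRNA-like genes
#' whose mature region is flanked by 100 nt of precursor sequence on each
#' side, rRNA-like genes carrying the structure-artefact clusters, and
#' unmethylated spike-ins. Planted m5C sites land on transcript-strand
#' cytosines: `planted_site_count` sites on mRNA exons and 1-4 clustered
#' sites per tRNA mature region.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; output is deterministic given (config, seed).
#' @return list with elements `refset` (a [ReferenceSet]) and `truth`
#'   (a data.frame of class `bs_truth` with one row per planted site:
#'   `gene_id`, `seqname`, `strand`, `pos` (0-based), `class`, `trend`, and
#'   one `stoich_f<i>` column per fraction).
#' @export
build_reference <- function(config, seed = 1L) {
  set.seed(seed)
  cfg <- config
  seqs <- character(0); class_of <- character(0)
  transcripts <- list(); exons <- list(); cds <- list(); mature <- list()
  truth <- list()

  flank <- 100L  # precursor flank on each side of a tRNA mature region

  for (i in seq_len(cfg$n_mrna_genes)) {
    gid <- sprintf("mgene%02d", i)
    strand <- if (i %% 2 == 1) "+" else "-"
    sl <- sample_range(cfg$gene_length_range[1], cfg$gene_length_range[2])
    p <- cfg$utr_cds_proportions
    utr5 <- max(30L, as.integer(sl * p[1]))
    cds_len <- (as.integer(sl * p[2]) %/% 3L) * 3L
    utr3 <- sl - utr5 - cds_len
    sl <- utr5 + cds_len + utr3
    # exon structure in spliced space, then inflate with introns
    n_ex <- if (cfg$spliced_transcripts && i %% 3 == 0) sample(2:3, 1) else 1L
    cuts <- sort(sample(seq(100L, sl - 100L))[seq_len(n_ex - 1L)])
    ex_sp <- cbind(c(0L, cuts), c(cuts, sl))            # spliced intervals
    introns <- if (n_ex > 1) sample(100:300, n_ex - 1L, replace = TRUE) else integer(0)
    gstart <- 0L; ex_g <- matrix(0L, n_ex, 2)
    off <- 0L
    for (k in seq_len(n_ex)) {
      w <- ex_sp[k, 2] - ex_sp[k, 1]
      ex_g[k, ] <- c(off, off + w)
      off <- off + w + if (k < n_ex) introns[k] else 0L
    }
    glen <- off
    # transcript-strand spliced sequence -> genomic plus strand
    gseq_ts <- random_dna(glen)
    seq_plus <- if (strand == "+") gseq_ts else revcomp(gseq_ts)
    seqs[[gid]] <- seq_plus
    class_of[[gid]] <- "mRNA"
    tid <- paste0(gid, ".t1")
    transcripts[[length(transcripts) + 1L]] <- data.frame(
      transcript_id = tid, gene_id = gid, seqname = gid, strand = strand,
      biotype = "protein_coding", stringsAsFactors = FALSE)
    exons[[length(exons) + 1L]] <- data.frame(
      transcript_id = tid, start = ex_g[, 1], end = ex_g[, 2],
      stringsAsFactors = FALSE)
    # CDS spliced interval [utr5, utr5+cds_len) -> genomic span
    cds_g <- spliced_to_genomic(ex_g, strand, glen, c(utr5, utr5 + cds_len))
    cds[[length(cds) + 1L]] <- data.frame(
      transcript_id = tid, start = cds_g[1], end = cds_g[2],
      stringsAsFactors = FALSE)
    # a shorter second transcript on the first gene exercises the
    # longest-transcript annotation rule
    if (i == 1L) {
      tid2 <- paste0(gid, ".t2")
      transcripts[[length(transcripts) + 1L]] <- data.frame(
        transcript_id = tid2, gene_id = gid, seqname = gid, strand = strand,
        biotype = "protein_coding", stringsAsFactors = FALSE)
      exons[[length(exons) + 1L]] <- data.frame(
        transcript_id = tid2, start = ex_g[1, 1],
        end = ex_g[1, 1] + min(300L, ex_g[1, 2] - ex_g[1, 1]),
        stringsAsFactors = FALSE)
    }
  }

  for (i in seq_len(cfg$n_trna_genes)) {
    gid <- sprintf("tgene%02d", i)
    mat_len <- sample_range(70L, 85L)
    glen <- mat_len + 2L * flank
    seqs[[gid]] <- random_dna(glen)
    class_of[[gid]] <- "tRNA"
    tid <- paste0(gid, ".t1")
    transcripts[[length(transcripts) + 1L]] <- data.frame(
      transcript_id = tid, gene_id = gid, seqname = gid, strand = "+",
      biotype = "tRNA", stringsAsFactors = FALSE)
    exons[[length(exons) + 1L]] <- data.frame(
      transcript_id = tid, start = 0L, end = glen, stringsAsFactors = FALSE)
    mature[[length(mature) + 1L]] <- data.frame(
      gene_id = gid, start = flank, end = flank + mat_len,
      stringsAsFactors = FALSE)
  }

  for (i in seq_len(cfg$n_rrna_genes)) {
    gid <- sprintf("rgene%02d", i)
    seqs[[gid]] <- random_dna(800L)
    class_of[[gid]] <- "rRNA"
    tid <- paste0(gid, ".t1")
    transcripts[[length(transcripts) + 1L]] <- data.frame(
      transcript_id = tid, gene_id = gid, seqname = gid, strand = "+",
      biotype = "rRNA", stringsAsFactors = FALSE)
    exons[[length(exons) + 1L]] <- data.frame(
      transcript_id = tid, start = 0L, end = 800L, stringsAsFactors = FALSE)
  }

  for (i in seq_len(cfg$n_spikeins)) {
    gid <- sprintf("spike%02d", i)
    seqs[[gid]] <- random_dna(500L)
    class_of[[gid]] <- "spikein"
    tid <- paste0(gid, ".t1")
    transcripts[[length(transcripts) + 1L]] <- data.frame(
      transcript_id = tid, gene_id = gid, seqname = gid, strand = "+",
      biotype = "spikein", stringsAsFactors = FALSE)
    exons[[length(exons) + 1L]] <- data.frame(
      transcript_id = tid, start = 0L, end = 500L, stringsAsFactors = FALSE)
  }

  refset <- ReferenceSet(seqs, do.call(rbind, transcripts),
                         do.call(rbind, exons), do.call(rbind, cds),
                         class_of,
                         if (length(mature)) do.call(rbind, mature) else NULL)

  # plant mRNA sites on exonic transcript-strand cytosines
  if (cfg$planted_site_count > 0 && cfg$n_mrna_genes > 0) {
    pool <- exonic_c_positions(refset, classes = "mRNA")
    if (nrow(pool) < cfg$planted_site_count)
      stopf("requested %d planted sites but only %d exonic cytosines available",
            cfg$planted_site_count, nrow(pool))
    pick <- pool[sample(nrow(pool), cfg$planted_site_count), ]
    if (is.null(cfg$stoichiometry_by_fraction)) {
      pr <- make_profiles(cfg$planted_site_count, cfg)
      prof <- pr$profiles; trend <- pr$trend
    } else {
      prof <- cfg$stoichiometry_by_fraction
      trend <- rep(NA_character_, nrow(prof))
    }
    truth[[length(truth) + 1L]] <- data.frame(
      gene_id = pick$gene_id, seqname = pick$seqname, strand = pick$strand,
      pos = pick$pos, class = "mRNA", trend = trend,
      stats::setNames(as.data.frame(prof),
                      paste0("stoich_f", seq_len(cfg$n_fractions))),
      stringsAsFactors = FALSE)
  }

  # clustered tRNA sites inside mature regions (constant across fractions)
  for (i in seq_len(cfg$n_trna_genes)) {
    gid <- sprintf("tgene%02d", i)
    m <- refset$mature_region_of[refset$mature_region_of$gene_id == gid, ]
    ch <- ts_chars(seqs[[gid]], "+")
    cpos <- which(ch == "C") - 1L
    cpos <- cpos[cpos >= m$start & cpos < m$end]
    k <- sample_range(cfg$trna_sites_range[1], cfg$trna_sites_range[2])
    k <- min(k, length(cpos))
    if (k == 0) next
    # clustered: k consecutive available cytosines
    first <- sample_range(1L, length(cpos) - k + 1L)
    sel <- cpos[first:(first + k - 1L)]
    st <- stats::runif(1, 0.4, 0.8)
    truth[[length(truth) + 1L]] <- data.frame(
      gene_id = gid, seqname = gid, strand = "+", pos = sel, class = "tRNA",
      trend = NA_character_,
      stats::setNames(as.data.frame(matrix(st, length(sel), cfg$n_fractions)),
                      paste0("stoich_f", seq_len(cfg$n_fractions))),
      stringsAsFactors = FALSE)
  }

  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(gene_id = character(0), seqname = character(0),
               strand = character(0), pos = integer(0), class = character(0),
               trend = character(0),
               stats::setNames(as.data.frame(matrix(numeric(0), 0, cfg$n_fractions)),
                               paste0("stoich_f", seq_len(cfg$n_fractions))))
  rownames(truth) <- NULL
  class(truth) <- c("bs_truth", "data.frame")

  # structure-artefact clusters: 5 adjacent cytosines on rRNA-like genes
  clusters <- list()
  spec <- cfg$structure_cluster_spec
  if (spec$n > 0 && cfg$n_rrna_genes > 0) {
    for (j in seq_len(spec$n)) {
      gid <- sprintf("rgene%02d", ((j - 1L) %% cfg$n_rrna_genes) + 1L)
      ch <- ts_chars(seqs[[gid]], "+")
      cpos <- which(ch == "C") - 1L
      # keep clusters in the gene body so read coverage is uniform there
      margin <- min(cfg$read_length + 20L, 200L)
      cpos <- cpos[cpos >= margin & cpos < 800L - margin - spec$width]
      ok <- FALSE
      for (attempt in 1:50) {
        start <- sample1(cpos)
        members <- cpos[cpos >= start & cpos < start + spec$width]
        if (length(members) >= 5) { members <- members[1:5]; ok <- TRUE; break }
      }
      if (!ok) { # fall back to 5 closest cytosines
        start <- sample_range(1L, length(cpos) - 5L)
        members <- cpos[start:(start + 4L)]
      }
      clusters[[j]] <- data.frame(gene_id = gid, pos = members, cluster = j,
                                  stringsAsFactors = FALSE)
    }
  }
  attr(refset, "structure_clusters") <- if (length(clusters))
    do.call(rbind, clusters) else NULL

  list(refset = refset, truth = truth)
}

# map a spliced interval [a,b) to its genomic span c(start, end) 0-based
spliced_to_genomic <- function(ex_g, strand, glen, interval) {
  # genomic positions in transcript (5'->3') order: ascending for "+",
  # descending for "-"
  gpos <- unlist(lapply(seq_len(nrow(ex_g)), function(k)
    seq(ex_g[k, 1], ex_g[k, 2] - 1L)))
  if (strand == "-") gpos <- rev(gpos)
  sel <- gpos[(interval[1] + 1L):interval[2]]
  c(min(sel), max(sel) + 1L)
}

#' Enumerate exonic transcript-strand cytosines
#'
#' All exonic cytosine positions (transcript-strand) of genes in the
#' given RNA classes — the sampling pool for planted sites and for
#' randomised-cytosine null controls.
#'
#' @param refset a [ReferenceSet].
#' @param classes RNA classes to include (e.g. `"mRNA"`).
#' @return data.frame with `gene_id`, `seqname`, `strand`, `pos`
#'   (0-based), one row per cytosine.
#' @export
exonic_c_positions <- function(refset, classes) {
  out <- list()
  spans <- gene_spans(refset)
  for (i in seq_len(nrow(spans))) {
    g <- spans[i, ]
    if (!(refset$class_of[[g$gene_id]] %in% classes)) next
    ch <- ts_chars(refset$sequences[[g$seqname]], g$strand)
    cpos <- which(ch == "C") - 1L
    trs <- refset$transcripts$transcript_id[refset$transcripts$gene_id == g$gene_id]
    ex <- refset$exons[refset$exons$transcript_id %in% trs, ]
    inex <- rep(FALSE, length(cpos))
    for (k in seq_len(nrow(ex)))
      inex <- inex | (cpos >= ex$start[k] & cpos < ex$end[k])
    cpos <- cpos[inex]
    if (length(cpos))
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g$gene_id, seqname = g$seqname, strand = g$strand,
        pos = cpos, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(gene_id = character(0),
                                      seqname = character(0),
                                      strand = character(0), pos = integer(0)))
  do.call(rbind, out)
}

#' Simulate one bisulfite-converted sample
#'
#' Emits alignments in the post-alignment state the pipeline consumes:
#' uniquely mapped reads whose bases are the original (unconverted) read
#' sequence, i.e. C retained at non-converted positions and T at converted
#' positions in transcript-strand space, stored in plus-strand orientation
#' with the transcript strand in the `strand` column. Per planted site the
#' retention probability is `stoich + (1 - stoich) * failure_rate`, where
#' the replicate-level stoichiometry is Beta-jittered around the fraction
#' value; unmethylated cytosines retain C with probability `failure_rate`.
#' Reads covering a structure cluster co-retain C at all cluster cytosines
#' with the configured probability, and cytosines within 6 nt of either
#' read end spuriously retain C at `end_bias_rate`.
#'
#' @param refset,truth output of [build_reference()].
#' @param fraction_index 1-based polysome fraction (<= `n_fractions`).
#' @param replicate_index 1-based biological replicate (<= `n_replicates`).
#' @param config the [sim_config()] used to build the reference.
#' @param seed integer seed.
#' @return a `bs_alignments` data.frame; attribute `site_tallies` holds the
#'   generator's internal per-site retained/covered counts for
#'   truth-consistency checks.
#' @export
simulate_sample <- function(refset, truth, fraction_index, replicate_index,
                            config, seed = 1L) {
  cfg <- config
  if (fraction_index < 1 || fraction_index > cfg$n_fractions)
    stopf("unknown fraction index %d", fraction_index)
  if (replicate_index < 1 || replicate_index > cfg$n_replicates)
    stopf("unknown replicate index %d", replicate_index)
  set.seed(seed)
  rl <- cfg$read_length
  fail <- cfg$conversion_failure_rate
  clusters <- attr(refset, "structure_clusters")
  spans <- gene_spans(refset)

  # replicate-jittered stoichiometry for this (fraction, replicate)
  stoich <- numeric(0)
  if (nrow(truth)) {
    s <- truth[[paste0("stoich_f", fraction_index)]]
    conc <- cfg$replicate_concentration
    stoich <- ifelse(s <= 0 | s >= 1, s,
                     stats::rbeta(length(s), s * conc, (1 - s) * conc))
  }

  recs <- list()
  tally_ret <- integer(nrow(truth)); tally_cov <- integer(nrow(truth))
  qm <- cfg$base_quality_model
  read_no <- 0L
  reads_per_gene <- stats::setNames(integer(nrow(spans)), spans$gene_id)

  for (gi in seq_len(nrow(spans))) {
    g <- spans[gi, ]
    seq_plus <- refset$sequences[[g$seqname]]
    L <- nchar(seq_plus)
    tsc <- ts_chars(seq_plus, g$strand)          # transcript-strand chars
    plus_ch <- strsplit(seq_plus, "", fixed = TRUE)[[1]]
    is_c <- tsc == "C"
    rl_g <- min(rl, L)
    n_reads <- stats::rpois(1, cfg$coverage_mean * L / rl_g)
    reads_per_gene[[g$gene_id]] <- n_reads
    if (n_reads == 0) next
    is_trna <- identical(refset$class_of[[g$gene_id]], "tRNA") &&
      !is.null(refset$mature_region_of) &&
      g$gene_id %in% refset$mature_region_of$gene_id
    if (is_trna) {
      # bisulfite fragments are short; most tRNA reads are "processed"
      # (fully inside the mature region), the rest span precursor flanks
      m <- refset$mature_region_of[
        refset$mature_region_of$gene_id == g$gene_id, ]
      mat_len <- m$end - m$start
      processed <- stats::runif(n_reads) < 0.8
      lens <- ifelse(processed,
                     pmin(mat_len, 40L + floor(stats::runif(n_reads) *
                                                 (mat_len - 39L))),
                     rl_g)
      starts <- integer(n_reads)
      for (q in seq_len(n_reads)) {
        starts[q] <- if (processed[q])
          m$start + sample.int(mat_len - lens[q] + 1L, 1) - 1L
        else sample.int(L - lens[q] + 1L, 1) - 1L
      }
    } else {
      lens <- rep(rl_g, n_reads)
      starts <- sample.int(L - rl_g + 1L, n_reads, replace = TRUE) - 1L
    }

    gt <- which(truth$seqname == g$seqname)
    site_pos <- truth$pos[gt]
    site_p <- stoich[gt]
    cl <- if (!is.null(clusters)) clusters[clusters$gene_id == g$gene_id, ] else NULL

    spliceable <- identical(refset$class_of[[g$gene_id]], "mRNA") &&
      cfg$spliced_read_rate > 0
    for (ri in seq_len(n_reads)) {
      s0 <- starts[ri]
      len <- lens[ri]
      gap <- 0L
      if (spliceable && s0 + len + 30L <= L &&
          stats::runif(1) < cfg$spliced_read_rate) gap <- 30L
      if (gap > 0L) {
        h <- len %/% 2L
        idx <- c((s0 + 1L):(s0 + h),
                 (s0 + h + gap + 1L):(s0 + len + gap))
        cigar <- sprintf("%dM%dN%dM", h, gap, len - h)
      } else {
        idx <- (s0 + 1L):(s0 + len)              # 1-based into sequence
        cigar <- paste0(len, "M")
      }
      cpos_rel <- which(is_c[idx])               # read-local 1-based offsets
      retained <- logical(length(cpos_rel))
      if (length(cpos_rel)) {
        gpos <- idx[cpos_rel] - 1L               # genomic 0-based
        p_ret <- rep(fail, length(gpos))
        if (length(site_pos)) {
          mi <- match(gpos, site_pos)
          hit <- !is.na(mi)
          p_ret[hit] <- site_p[mi[hit]] + (1 - site_p[mi[hit]]) * fail
        }
        retained <- stats::runif(length(gpos)) < p_ret
        # structure cluster co-retention
        if (!is.null(cl) && nrow(cl)) {
          incl <- gpos %in% cl$pos
          if (any(incl) && stats::runif(1) < cfg$structure_cluster_spec$p)
            retained[incl] <- TRUE
        }
        # read-end artefact: within 6 nt of either end
        if (cfg$end_bias_rate > 0) {
          near_end <- cpos_rel <= 6L | cpos_rel > len - 6L
          flip <- near_end & !retained &
            stats::runif(length(gpos)) < cfg$end_bias_rate
          retained[flip] <- TRUE
        }
        if (length(site_pos)) {
          mi <- match(gpos, site_pos)
          hit <- which(!is.na(mi))
          for (h in hit) {
            tally_cov[gt[mi[h]]] <- tally_cov[gt[mi[h]]] + 1L
            if (retained[h]) tally_ret[gt[mi[h]]] <- tally_ret[gt[mi[h]]] + 1L
          }
        }
      }
      # build plus-strand read bases: converted C -> T (plus strand) or
      # transcript C on minus strand is plus-strand G -> A
      bases <- plus_ch[idx]
      if (length(cpos_rel)) {
        conv <- cpos_rel[!retained]
        if (length(conv))
          bases[conv] <- if (g$strand == "+") "T" else "A"
      }
      qual <- ifelse(stats::runif(len) < qm$p_low, qm$low, qm$high)
      read_no <- read_no + 1L
      recs[[read_no]] <- list(qname = sprintf("%s_f%dr%d_%06d", g$gene_id,
                                              fraction_index, replicate_index,
                                              read_no),
                              rname = g$seqname, pos = s0,
                              strand = g$strand,
                              seq = paste(bases, collapse = ""),
                              qual = rawToChar(as.raw(qual + 33L)),
                              cigar = cigar, mapq = 42L,
                              flag = if (g$strand == "+") 0L else 16L)
    }
  }

  out <- if (read_no) data.frame(
    qname = vapply(recs, `[[`, "", "qname"),
    rname = vapply(recs, `[[`, "", "rname"),
    pos = vapply(recs, `[[`, 0L, "pos"),
    strand = vapply(recs, `[[`, "", "strand"),
    seq = vapply(recs, `[[`, "", "seq"),
    qual = vapply(recs, `[[`, "", "qual"),
    cigar = vapply(recs, `[[`, "", "cigar"),
    mapq = vapply(recs, `[[`, 0L, "mapq"),
    flag = vapply(recs, `[[`, 0L, "flag"),
    stringsAsFactors = FALSE) else
    data.frame(qname = character(0), rname = character(0), pos = integer(0),
               strand = character(0), seq = character(0), qual = character(0),
               cigar = character(0), mapq = integer(0), flag = integer(0))
  class(out) <- c("bs_alignments", "data.frame")
  attr(out, "site_tallies") <- if (nrow(truth)) data.frame(
    seqname = truth$seqname, pos = truth$pos, retained = tally_ret,
    covered = tally_cov, stringsAsFactors = FALSE) else NULL
  # replicate-level realized stoichiometry (after Beta jitter): the truth
  # this sample's counts were actually drawn from
  attr(out, "realized_stoich") <- if (nrow(truth)) data.frame(
    seqname = truth$seqname, pos = truth$pos, stoich = stoich,
    stringsAsFactors = FALSE) else NULL
  attr(out, "sample") <- list(fraction = fraction_index,
                              replicate = replicate_index)
  attr(out, "reads_per_gene") <- reads_per_gene
  out
}

#' Simulate the full 4-fraction x 3-replicate experiment
#'
#' @param refset,truth output of [build_reference()].
#' @param config the [sim_config()].
#' @param seed base seed; sample `(f, r)` uses `seed * 100 + f * 10 + r` so
#'   samples are independent but jointly deterministic.
#' @return nested list `samples[[fraction]][[replicate]]` of
#'   `bs_alignments`.
#' @export
simulate_experiment <- function(refset, truth, config, seed = 1L) {
  lapply(seq_len(config$n_fractions), function(f)
    lapply(seq_len(config$n_replicates), function(r)
      simulate_sample(refset, truth, f, r, config,
                      seed = seed * 100L + f * 10L + r)))
}

#' Pool fraction samples into replicate-level alignment sets
#'
#' Transcriptome-wide site discovery pools the fraction libraries of each
#' biological replicate before filtering and calling.
#'
#' @param samples nested list from [simulate_experiment()].
#' @return list of `bs_alignments`, one per replicate.
#' @export
pool_replicates <- function(samples) {
  n_rep <- length(samples[[1]])
  lapply(seq_len(n_rep), function(r) {
    out <- do.call(rbind, lapply(samples, `[[`, r))
    class(out) <- c("bs_alignments", "data.frame")
    out
  })
}

#' Write the truth table as BED6+
#'
#' BED coordinates are 0-based half-open; extra columns carry the
#' per-fraction stoichiometry.
#'
#' @param truth a `bs_truth` data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_truth_bed <- function(truth, path) {
  sc <- grep("^stoich_f", names(truth), value = TRUE)
  lines <- sprintf("%s\t%d\t%d\t%s\t.\t%s\t%s", truth$seqname, truth$pos,
                   truth$pos + 1L, truth$gene_id, truth$strand,
                   apply(truth[, sc, drop = FALSE], 1, function(v)
                     paste(format(v, digits = 6), collapse = "\t")))
  writeLines(lines, path)
  invisible(path)
}
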