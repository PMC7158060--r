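# gplus starts ATCGACGTT...: C at 0-based 2, 5, ...
test_that("read-level non-conversion counting matches hand counts and oracle", {
  ref <- toy_refset()
  # fully converted read over reference Cs -> 0
  tpl <- substr(ref$sequences[["gplus"]], 1, 20)
  conv <- chartr("C", "T", tpl)
  expect_equal(read_nonconversion_count(mk_read("gplus", 0, conv), ref), 0)
  # retain C at some reference Cs
  ch <- strsplit(tpl, "")[[1]]
  cs <- which(ch == "C")
  half <- cs[seq(1, length(cs), by = 2)]
  ch2 <- ifelse(seq_along(ch) %in% half, ch, chartr("C", "T", ch))
  r <- mk_read("gplus", 0, paste(ch2, collapse = ""))
  expect_equal(read_nonconversion_count(r, ref), length(half))
  # oracle recount over a stochastic batch, both strands
  reads <- toy_reads_50()
  got <- vapply(seq_len(nrow(reads)), function(i)
    read_nonconversion_count(reads[i, ], ref), integer(1))
  want <- vapply(seq_len(nrow(reads)), function(i)
    oracle_nonconv_count(reads[i, ], ref$sequences), integer(1))
  expect_identical(got, want)
})

test_that("3C read filter uses the more-than-three boundary", {
  ref <- toy_refset()
  tpl <- substr(ref$sequences[["gplus"]], 1, 30)
  ch <- strsplit(tpl, "")[[1]]
  cs <- which(ch == "C")
  mk_with_retained <- function(k) {
    keep <- cs[seq_len(k)]
    ch2 <- ifelse(seq_along(ch) %in% keep, ch, chartr("C", "T", ch))
    mk_read("gplus", 0, paste(ch2, collapse = ""), qname = paste0("k", k))
  }
  expect_gte(length(cs), 4)
  aln <- bind_reads(mk_with_retained(3), mk_with_retained(4))
  res <- apply_read_filter(aln, ref)
  expect_equal(res$pass$qname, "k3")
  expect_equal(res$fail$qname, "k4")
  expect_equal(res$stats$n_pass, 1)
  expect_equal(res$stats$n_fail, 1)
  # empty stream
  empty <- aln[0, ]
  res0 <- apply_read_filter(empty, ref)
  expect_equal(nrow(res0$pass) + nrow(res0$fail), 0)
  expect_equal(res0$stats$n_pass, 0)
})

test_that("pileup counts equal an exhaustive independent recount", {
  ref <- toy_refset()
  reads <- toy_reads_50()
  cfg <- filter_config()
  p <- build_pileup(reads, ref, cfg)
  orc <- oracle_pileup(reads, ref$sequences)
  expect_equal(nrow(p), nrow(orc))
  i <- match(paste(p$seqname, p$pos), paste(orc$seqname, orc$pos))
  expect_false(anyNA(i))
  expect_equal(p$raw_coverage, orc$raw[i])
  expect_equal(p$filtered_coverage, orc$filt[i])
  expect_equal(p$c_count, orc$c[i])
  expect_equal(p$t_count, orc$t[i])
  expect_equal(p$other_count, orc$o[i])
})

test_that("terminal mask and signal-to-noise flag behave per definition", {
  ref <- toy_refset()
  # gplus: C at 0-based position 2 -> 3rd base from the 5' end, masked
  tpl <- substr(ref$sequences[["gplus"]], 1, 20)
  ch <- strsplit(tpl, "")[[1]]
  ch2 <- chartr("C", "T", ch); ch2[3] <- "C"
  r <- mk_read("gplus", 0, paste(ch2, collapse = ""))
  p <- build_pileup(r, ref, filter_config())
  at <- p[p$pos == 2, ]
  expect_equal(at$raw_coverage, 1)
  expect_equal(at$c_count, 0)    # masked: no methylation evidence
  # with mask_as_converted the retained C counts as T
  p2 <- build_pileup(r, ref, filter_config(mask_as_converted = TRUE))
  expect_equal(p2[p2$pos == 2, "t_count"], 1)
  # masking never increases c_count, under either mask semantics
  reads <- toy_reads_50()
  pm <- build_pileup(reads, ref, filter_config())
  p0 <- build_pileup(reads, ref, filter_config(end_mask_nt = 0L))
  i <- match(paste(pm$seqname, pm$pos), paste(p0$seqname, p0$pos))
  expect_true(all(pm$c_count <= p0$c_count[i]))
  # under mask-as-converted semantics the mask is monotone on the
  # non-conversion ratio itself
  pmc <- build_pileup(reads, ref, filter_config(mask_as_converted = TRUE))
  nc <- function(d) ifelse(d$c_count + d$t_count > 0,
                           d$c_count / (d$c_count + d$t_count), 0)
  j0 <- match(paste(pmc$seqname, pmc$pos), paste(p0$seqname, p0$pos))
  expect_true(all(nc(pmc) <= nc(p0)[j0] + 1e-12))
  # 3C filtering never increases c_count
  praw <- build_pileup(reads, ref,
                       filter_config(max_nonconverted_per_read = 1000L))
  j <- match(paste(pm$seqname, pm$pos), paste(praw$seqname, praw$pos))
  expect_true(all(pm$c_count <= praw$c_count[j]))
})

test_that("signal-to-noise ratio flags positions losing reads to 3C", {
  ref <- toy_refset()
  tpl <- substr(ref$sequences[["gplus"]], 1, 30)
  ch <- strsplit(tpl, "")[[1]]
  cs <- which(ch == "C")
  all_t <- chartr("C", "T", tpl)
  fail_read <- ifelse(seq_along(ch) %in% cs[1:4], ch, strsplit(all_t, "")[[1]])
  reads <- c(replicate(85, mk_read("gplus", 0, all_t), simplify = FALSE),
             replicate(15, mk_read("gplus", 0,
                                   paste(fail_read, collapse = "")),
                       simplify = FALSE))
  aln <- do.call(bind_reads, reads)
  aln$qname <- paste0("r", seq_len(nrow(aln)))
  p <- build_pileup(aln, ref, filter_config())
  at <- p[p$pos == 2, ]
  expect_equal(at$raw_coverage, 100)
  expect_equal(at$filtered_coverage, 85)
  expect_equal(at$signal_to_noise, 0.85)
  expect_true(at$sn_flag)
  # boundary: ratio exactly 0.9 is not flagged under "lt", flagged under "le"
  reads2 <- c(replicate(90, mk_read("gplus", 0, all_t), simplify = FALSE),
              replicate(10, mk_read("gplus", 0,
                                    paste(fail_read, collapse = "")),
                        simplify = FALSE))
  aln2 <- do.call(bind_reads, reads2)
  aln2$qname <- paste0("r", seq_len(nrow(aln2)))
  p2 <- build_pileup(aln2, ref, filter_config())
  expect_false(p2[p2$pos == 2, "sn_flag"])
  p3 <- build_pileup(aln2, ref, filter_config(sn_boundary = "le"))
  expect_true(p3[p3$pos == 2, "sn_flag"])
})

test_that("per-replicate thresholds follow the 30RC/5C/80CT boundaries", {
  col <- function(cov, c, t, o = 0L, sn = FALSE) {
    d <- data.frame(seqname = "s", pos = 1L, strand = "+", gene_id = "g",
                    raw_coverage = cov, filtered_coverage = cov,
                    c_count = c, t_count = t, other_count = o,
                    raw_c = c, raw_t = t, signal_to_noise = 1,
                    sn_flag = sn)
    class(d) <- c("bs_pileup", "data.frame")
    d
  }
  cfg <- filter_config()
  # boundary pass: cov 30, C 5, T 25
  got <- call_replicate_sites(col(30L, 5L, 25L), cfg)
  expect_equal(nrow(got), 1)
  expect_equal(got$nonconversion, 5 / 30, tolerance = 1e-12)
  # 5C rejection at C = 4
  expect_equal(nrow(call_replicate_sites(col(30L, 4L, 26L), cfg)), 0)
  # 80CT rejection: 10 C + 20 T + 10 other
  expect_equal(nrow(call_replicate_sites(col(40L, 10L, 20L, 10L), cfg)), 0)
  # S/N-flagged positions are suppressed, and re-admitted with apply_sn off
  expect_equal(nrow(call_replicate_sites(col(40L, 10L, 30L, sn = TRUE), cfg)), 0)
  expect_equal(nrow(call_replicate_sites(col(40L, 10L, 30L, sn = TRUE),
                                         filter_config(apply_sn = FALSE))), 1)
})

test_that("replicate merge enforces presence and the 10MM average", {
  rep_call <- function(nonconv, pos = 1L) {
    d <- data.frame(seqname = "s", pos = pos, strand = "+", gene_id = "g",
                    raw_coverage = 50L, filtered_coverage = 50L,
                    c_count = round(nonconv * 50), t_count = 50L - round(nonconv * 50),
                    other_count = 0L, raw_c = 0L, raw_t = 0L,
                    signal_to_noise = 1, sn_flag = FALSE,
                    nonconversion = nonconv)
    class(d) <- c("bs_sites", "data.frame")
    d
  }
  cfg <- filter_config()
  # mean (0.12, 0.10, 0.09) = 0.1033 >= 0.10 -> candidate
  out <- combine_replicates(list(rep_call(0.12), rep_call(0.10),
                                 rep_call(0.09)), cfg)
  expect_equal(nrow(out), 1)
  expect_equal(out$avg_nonconversion, mean(c(0.12, 0.10, 0.09)),
               tolerance = 1e-12)
  # absent in one replicate -> rejected when all replicates are required
  out2 <- combine_replicates(list(rep_call(0.30), rep_call(0.30),
                                  rep_call(0.30)[0, ]), cfg)
  expect_equal(nrow(out2), 0)
  out3 <- combine_replicates(list(rep_call(0.30), rep_call(0.30),
                                  rep_call(0.30)[0, ]),
                             filter_config(require_all_replicates = FALSE))
  expect_equal(nrow(out3), 1)
  # below 10MM -> rejected
  out4 <- combine_replicates(list(rep_call(0.09), rep_call(0.09),
                                  rep_call(0.09)), cfg)
  expect_equal(nrow(out4), 0)
})

test_that("conversion summaries aggregate per RNA class", {
  cols <- data.frame(seqname = c("a", "a", "b"), pos = 1:3, strand = "+",
                     gene_id = c("g1", "g1", "g2"),
                     raw_coverage = 100L, filtered_coverage = 100L,
                     c_count = c(2L, 0L, 1L), t_count = c(98L, 100L, 99L),
                     other_count = 0L, raw_c = c(2L, 0L, 1L),
                     raw_t = c(98L, 100L, 99L),
                     signal_to_noise = 1, sn_flag = FALSE)
  class(cols) <- c("bs_pileup", "data.frame")
  sm <- summarize_conversion(cols, c(g1 = "spikein"))
  expect_equal(sm$conversion_raw[sm$rna_class == "spikein"], 198 / 200)
  expect_equal(sm$rna_class, c("other", "spikein"))
  expect_equal(sm$conversion_raw[sm$rna_class == "other"], 0.99)
})

test_that("tRNA calling restricts to processed reads inside mature regions", {
  cfg <- sim_config(n_mrna_genes = 0, n_trna_genes = 2, n_rrna_genes = 0,
                    n_spikeins = 0, planted_site_count = 0,
                    coverage_mean = 60, trna_sites_range = c(2L, 2L))
  br <- build_reference(cfg, seed = 51)
  reps <- lapply(1:3, function(r)
    simulate_sample(br$refset, br$truth, 1, r, cfg, seed = 510 + r))
  fc <- filter_config()
  out <- call_trna_sites(reps, br$refset, fc)
  # recovered sites are a subset of truth (3C can eat clustered sites)
  tk <- paste(br$truth$seqname, br$truth$pos)
  expect_true(all(paste(out$seqname, out$pos) %in% tk))
  m <- br$refset$mature_region_of
  for (i in seq_len(nrow(out))) {
    mm <- m[m$gene_id == out$gene_id[i], ]
    expect_gte(out$pos[i], mm$start)
    expect_lt(out$pos[i], mm$end)
    expect_equal(out$mature_offset[i], out$pos[i] - mm$start)
  }
  # no tRNA reads -> empty result
  none <- lapply(reps, function(a) a[0, ])
  expect_equal(nrow(call_trna_sites(none, br$refset, fc)), 0)
  # a tRNA gene without a mature region is an error
  broken <- br$refset
  broken$mature_region_of <- broken$mature_region_of[-1, ]
  expect_error(call_trna_sites(reps, broken, fc), "mature")
})

test_that("precursor-spanning reads never contribute to tRNA pileups", {
  cfg <- sim_config(n_mrna_genes = 0, n_trna_genes = 1, n_rrna_genes = 0,
                    n_spikeins = 0, planted_site_count = 0,
                    coverage_mean = 40, trna_sites_range = c(1L, 1L))
  br <- build_reference(cfg, seed = 61)
  aln <- simulate_sample(br$refset, br$truth, 1, 1, cfg, seed = 62)
  m <- br$refset$mature_region_of
  # flank-only coverage must vanish after the processed-read restriction
  span <- vapply(aln$cigar, function(cg)
    sum(as.integer(sub("[MN]", "", regmatches(cg, gregexpr("\\d+[MN]", cg))[[1]]))),
    integer(1), USE.NAMES = FALSE)
  processed <- aln$pos >= m$start & aln$pos + span <= m$end
  expect_gt(sum(!processed), 0)   # precursor reads exist in the sample
  sub <- aln[processed, ]
  class(sub) <- c("bs_alignments", "data.frame")
  p <- build_pileup(sub, br$refset, filter_config())
  expect_true(all(p$pos >= m$start & p$pos < m$end))
})
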