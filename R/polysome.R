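# Polysome-fraction methylation-trend analysis: fraction matrix, fuzzy
# c-means clustering, trend labels, pairwise differential methylation,
# bulk tests, amplicon grids and expression association.

#' Build the sites x fractions methylation matrix
#'
#' Aggregates per-sample counts at candidate loci into per-fraction means
#' and applies the coverage-based row selection: `F1234` rows have any
#' coverage in at least `min_samples` of the 12 fraction samples and mean
#' coverage >= `min_cov` in all 4 fractions; `F234` rows satisfy both
#' rules over fractions 2-4 but fail the fraction-1 coverage rule; all
#' other rows are excluded.
#'
#' @param samples long data.frame with columns `fraction`, `replicate`,
#'   `seqname`, `pos`, `strand`, `coverage`, `meth`, `unmeth` — one row per
#'   (sample, site) observation. Typically derived from per-sample pileups
#'   restricted to the candidate loci (see [fraction_observations()]).
#' @param n_fractions,n_replicates experiment layout.
#' @param min_cov per-fraction mean coverage threshold (default 10).
#' @param min_samples observations required across all samples (default 9
#'   of 12).
#' @return data.frame of class `bs_fraction_matrix` with locus columns,
#'   `n_obs`, per-fraction `nonconv_f<i>` (mean of per-replicate
#'   proportions), `cov_f<i>`, `meth_f<i>`, `unmeth_f<i>` (averaged
#'   counts), and `selection` (`F1234`/`F234`/`excluded`).
#' @export
build_fraction_matrix <- function(samples, n_fractions = 4L,
                                  n_replicates = 3L, min_cov = 10,
                                  min_samples = 9L) {
  nf <- n_fractions
  if (!all(samples$fraction %in% seq_len(nf)) ||
      !all(samples$replicate %in% seq_len(n_replicates)))
    stopf("sample table does not match the %d x %d layout", nf, n_replicates)
  samples$key <- paste(samples$seqname, samples$pos, samples$strand, sep = ":")
  keys <- unique(samples$key)
  res <- list()
  for (k in keys) {
    d <- samples[samples$key == k & samples$coverage > 0, ]
    n_obs <- nrow(d)
    nonconv <- cov <- meth <- unmeth <- rep(NA_real_, nf)
    for (f in seq_len(nf)) {
      df <- d[d$fraction == f, ]
      if (!nrow(df)) { cov[f] <- 0; next }
      cov[f] <- mean(df$coverage)
      meth[f] <- mean(df$meth); unmeth[f] <- mean(df$unmeth)
      pr <- df$meth / pmax(df$meth + df$unmeth, 1)
      nonconv[f] <- mean(pr)
    }
    sel <- "excluded"
    if (n_obs >= min_samples) {
      if (all(cov >= min_cov)) sel <- "F1234"
      else if (all(cov[2:nf] >= min_cov) && cov[1] < min_cov) sel <- "F234"
    }
    res[[length(res) + 1L]] <- data.frame(
      seqname = d$seqname[1], pos = d$pos[1], strand = d$strand[1],
      n_obs = n_obs,
      stats::setNames(as.data.frame(t(nonconv)), paste0("nonconv_f", 1:nf)),
      stats::setNames(as.data.frame(t(cov)), paste0("cov_f", 1:nf)),
      stats::setNames(as.data.frame(t(meth)), paste0("meth_f", 1:nf)),
      stats::setNames(as.data.frame(t(unmeth)), paste0("unmeth_f", 1:nf)),
      selection = sel, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("bs_fraction_matrix", "data.frame")
  out
}

#' Extract per-sample observations at candidate loci
#'
#' Convenience bridge from per-sample pileups to the long table
#' [build_fraction_matrix()] consumes. `meth`/`unmeth` are the pileup's
#' C/T evidence counts; `coverage` is the 3C-filtered depth.
#'
#' @param pileups nested list `pileups[[fraction]][[replicate]]` of
#'   `bs_pileup` tables.
#' @param candidates a `bs_candidates` table defining the loci.
#' @return long data.frame for [build_fraction_matrix()].
#' @export
fraction_observations <- function(pileups, candidates) {
  key <- paste(candidates$seqname, candidates$pos, candidates$strand,
               sep = ":")
  out <- list()
  for (f in seq_along(pileups)) for (r in seq_along(pileups[[f]])) {
    p <- pileups[[f]][[r]]
    pk <- paste(p$seqname, p$pos, p$strand, sep = ":")
    hit <- pk %in% key
    if (!any(hit)) next
    d <- p[hit, ]
    out[[length(out) + 1L]] <- data.frame(
      fraction = f, replicate = r, seqname = d$seqname, pos = d$pos,
      strand = d$strand, coverage = d$filtered_coverage, meth = d$c_count,
      unmeth = d$t_count, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# ---- fuzzy c-means ---------------------------------------------------------

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  if (k > 1) for (j in 2:k) {
    d2 <- apply(x, 1, function(r)
      min(colSums((t(centers[seq_len(j - 1), , drop = FALSE]) - r)^2)))
    p <- d2 / sum(d2)
    centers[j, ] <- x[sample.int(n, 1, prob = p), ]
  }
  centers
}

fcm_fit <- function(x, k, m, tol, max_iter) {
  n <- nrow(x)
  centers <- kmeanspp_init(x, k)
  J_hist <- numeric(0)
  u <- matrix(0, n, k)
  for (iter in seq_len(max_iter)) {
    d2 <- sapply(seq_len(k), function(j)
      rowSums(sweep(x, 2, centers[j, ])^2))
    d2 <- pmax(matrix(d2, n, k), 1e-12)
    w <- d2^(-1 / (m - 1))
    u <- w / rowSums(w)
    um <- u^m
    centers <- (t(um) %*% x) / colSums(um)
    J <- sum(um * d2)
    J_hist <- c(J_hist, J)
    if (iter > 1 && abs(J_hist[iter - 1] - J) < tol * max(J, 1e-12)) break
  }
  list(centers = centers, membership = u, objective = J_hist[length(J_hist)],
       J_history = J_hist)
}

#' Fuzzy c-means clustering of fraction profiles
#'
#' Standardises each site's profile (mean 0, SD 1 across fractions) and
#' partitions the profiles into `c` soft clusters with fuzzifier `m`
#' (defaults c = 9, m = 2, the published clustering settings).
#' Initialisation is k-means++ with `n_start` restarts; the best final
#' objective is kept and the whole procedure is deterministic given
#' `seed`. Constant profiles (SD 0) cannot be standardised and are
#' excluded with a message.
#'
#' @param x numeric matrix, sites x fractions (e.g. the `nonconv_f*`
#'   columns of a [build_fraction_matrix()] result).
#' @param c number of clusters.
#' @param m fuzzifier (> 1).
#' @param seed RNG seed.
#' @param tol relative objective-change convergence tolerance.
#' @param max_iter iteration cap per restart.
#' @param n_start number of k-means++ restarts.
#' @return object of class `bs_fcm`: `centers` (c x fractions, standardised
#'   scale), `membership` (kept sites x c, rows sum to 1), `cluster`
#'   (argmax membership), `objective`, `J_history` (best restart),
#'   `scaled` (standardised input), `kept` (row indices used).
#' @export
cluster_profiles <- function(x, c = 9L, m = 2, seed = 1L, tol = 1e-8,
                             max_iter = 200L, n_start = 10L) {
  x <- as.matrix(x)
  if (m <= 1) stopf("fuzzifier m must exceed 1")
  sds <- apply(x, 1, stats::sd)
  kept <- which(!is.na(sds) & sds > 0 & !apply(x, 1, anyNA))
  if (length(kept) < nrow(x))
    message(sprintf("excluding %d constant or incomplete profile(s)",
                    nrow(x) - length(kept)))
  xs <- t(scale(t(x[kept, , drop = FALSE])))
  if (nrow(xs) < c)
    stopf("need at least c = %d profiles, have %d", c, nrow(xs))
  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_start)) {
    fit <- fcm_fit(xs, c, m, tol, max_iter)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  structure(list(centers = best$centers, membership = best$membership,
                 cluster = max.col(best$membership), m = m,
                 objective = best$objective, J_history = best$J_history,
                 scaled = xs, kept = kept),
            class = "bs_fcm")
}

#' @export
print.bs_fcm <- function(x, ...) {
  cat("Fuzzy c-means: ", nrow(x$membership), " profiles, ",
      nrow(x$centers), " clusters, m = ", x$m,
      ", objective = ", format(x$objective, digits = 6), "\n", sep = "")
  cat("cluster sizes (argmax):",
      paste(tabulate(x$cluster, nrow(x$centers)), collapse = " "), "\n")
  invisible(x)
}

#' @export
plot.bs_fcm <- function(x, ...) {
  k <- nrow(x$centers)
  graphics::matplot(t(x$centers), type = "l", lty = 1, col = seq_len(k),
                    xlab = "fraction", ylab = "standardised non-conversion",
                    ...)
  graphics::legend("topright", legend = paste0("C", seq_len(k)), lty = 1,
                   col = seq_len(k), bty = "n", cex = 0.7)
  invisible(x)
}

#' Assign translation-state trend labels
#'
#' Automates the visual grouping of cluster profiles into negative,
#' neutral and positive translation-state trends: the least-squares slope
#' of each centroid across fraction index (standardised scale, unit
#' steps) is compared against `epsilon`. Sites inherit the label of their
#' argmax-membership cluster.
#'
#' @param model a [cluster_profiles()] fit.
#' @param epsilon slope threshold in SD units per fraction step (default
#'   0.1).
#' @return list: `cluster_trend` (per cluster), `site_trend` (per kept
#'   site), `slopes`.
#' @export
assign_trend <- function(model, epsilon = 0.1) {
  k <- nrow(model$centers)
  idx <- seq_len(ncol(model$centers))
  slopes <- apply(model$centers, 1, function(y)
    stats::cov(idx, y) / stats::var(idx))
  lab <- ifelse(slopes < -epsilon, "negative",
                ifelse(slopes > epsilon, "positive", "neutral"))
  list(cluster_trend = lab, site_trend = lab[model$cluster], slopes = slopes)
}

# two-proportion binomial likelihood-ratio deviance (shared with tests'
# oracle only in formula, computed here via glm)
#' Pairwise differential methylation between adjacent fractions
#'
#' For each site with mean coverage >= `min_cov` in both fractions of the
#' pair, the replicate-averaged methylated/unmethylated counts (rounded
#' to integers) enter a binomial logistic regression of methylation
#' state on fraction; the likelihood-ratio test against the
#' intercept-only model gives the p value. q values are BH-adjusted
#' across tested sites, and a site is significant when `q < alpha` and
#' the absolute methylation difference is at least `min_diff` percentage
#' points (or, with `relative = TRUE`, when the difference relative to
#' the first fraction's level exceeds `min_diff`/100).
#'
#' @param fm a [build_fraction_matrix()] result.
#' @param pair length-2 integer vector of adjacent fractions, e.g.
#'   `c(1, 2)`.
#' @param alpha q-value threshold.
#' @param min_diff methylation-difference threshold in percentage points.
#' @param relative interpret `min_diff` relative to the first fraction.
#' @param min_cov per-fraction mean coverage required (default 10).
#' @param round_counts round averaged counts before testing.
#' @return data.frame of class `bs_diffmeth`: locus, per-fraction levels,
#'   `diff_pp`, `statistic` (LR deviance), `p`, `q`, `significant`,
#'   `direction`.
#' @export
pairwise_diffmeth <- function(fm, pair = c(1, 2), alpha = 0.05,
                              min_diff = 10, relative = FALSE, min_cov = 10,
                              round_counts = TRUE) {
  if (!all(diff(pair) == 1))
    stopf("pair must be adjacent fractions")
  f1 <- pair[1]; f2 <- pair[2]
  cov1 <- fm[[paste0("cov_f", f1)]]; cov2 <- fm[[paste0("cov_f", f2)]]
  use <- which(!is.na(cov1) & !is.na(cov2) & cov1 >= min_cov & cov2 >= min_cov)
  if (!length(use)) {
    res <- data.frame()
    class(res) <- c("bs_diffmeth", "data.frame")
    return(res)
  }
  m1 <- fm[[paste0("meth_f", f1)]][use]; u1 <- fm[[paste0("unmeth_f", f1)]][use]
  m2 <- fm[[paste0("meth_f", f2)]][use]; u2 <- fm[[paste0("unmeth_f", f2)]][use]
  if (round_counts) {
    m1 <- round(m1); u1 <- round(u1); m2 <- round(m2); u2 <- round(u2)
  }
  n <- length(use)
  stat <- p <- diff_pp <- numeric(n)
  for (i in seq_len(n)) {
    counts <- cbind(meth = c(m1[i], m2[i]), unmeth = c(u1[i], u2[i]))
    grp <- factor(c(1, 2))
    fit <- stats::glm(counts ~ grp, family = stats::binomial())
    stat[i] <- fit$null.deviance - fit$deviance
    p[i] <- stats::pchisq(stat[i], df = 1, lower.tail = FALSE)
    p1 <- m1[i] / max(m1[i] + u1[i], 1); p2 <- m2[i] / max(m2[i] + u2[i], 1)
    diff_pp[i] <- (p2 - p1) * 100
  }
  q <- stats::p.adjust(p, method = "BH")
  eff <- if (relative) {
    p1v <- m1 / pmax(m1 + u1, 1)
    abs(diff_pp / 100) / pmax(p1v, 1e-12) >= min_diff / 100
  } else abs(diff_pp) >= min_diff
  res <- data.frame(fm[use, c("seqname", "pos", "strand")],
                    fraction_a = f1, fraction_b = f2,
                    level_a = m1 / pmax(m1 + u1, 1),
                    level_b = m2 / pmax(m2 + u2, 1),
                    diff_pp = diff_pp, statistic = stat, p = p, q = q,
                    significant = q < alpha & eff,
                    direction = ifelse(diff_pp > 0, "up",
                                       ifelse(diff_pp < 0, "down", "none")))
  rownames(res) <- NULL
  class(res) <- c("bs_diffmeth", "data.frame")
  res
}

#' Bulk t-tests of non-conversion between adjacent fractions
#'
#' Unpaired two-tailed t tests (Student by default, per the bulk
#' comparison convention; Welch available) comparing the per-site
#' non-conversion distributions of each adjacent fraction pair, overall
#' and optionally per mRNA region.
#'
#' @param fm a [build_fraction_matrix()] result.
#' @param annotations optional annotated sites (matched by locus) whose
#'   `feature` column defines regions.
#' @param var_equal `TRUE` for Student's t (default), `FALSE` for Welch.
#' @return data.frame: `region`, `fraction_a`, `fraction_b`, `n_a`, `n_b`,
#'   `statistic`, `p`.
#' @export
bulk_adjacent_tests <- function(fm, annotations = NULL, var_equal = TRUE) {
  nf <- sum(grepl("^nonconv_f", names(fm)))
  region_of <- rep("all", nrow(fm))
  regions <- "all"
  if (!is.null(annotations)) {
    key <- paste(fm$seqname, fm$pos, fm$strand, sep = ":")
    akey <- paste(annotations$seqname, annotations$pos, annotations$strand,
                  sep = ":")
    feat <- annotations$feature[match(key, akey)]
    region_of <- ifelse(is.na(feat), "all", feat)
    regions <- c("all", unique(stats::na.omit(feat)))
  }
  out <- list()
  for (reg in regions) {
    rows <- if (reg == "all") seq_len(nrow(fm)) else which(region_of == reg)
    for (f in seq_len(nf - 1)) {
      a <- fm[[paste0("nonconv_f", f)]][rows]
      b <- fm[[paste0("nonconv_f", f + 1)]][rows]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (length(a) < 2 || length(b) < 2) {
        message(sprintf("skipping %s F%d-F%d: fewer than 2 sites", reg, f,
                        f + 1))
        next
      }
      tt <- stats::t.test(a, b, var.equal = var_equal)
      out[[length(out) + 1L]] <- data.frame(
        region = reg, fraction_a = f, fraction_b = f + 1,
        n_a = length(a), n_b = length(b),
        statistic = unname(tt$statistic), p = tt$p.value)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Binomial tests of region composition per trend category
#'
#' Tests, for each trend category and mRNA region, whether the category's
#' share of sites in that region departs from the expected proportion
#' computed from all labelled sites (exact binomial test).
#'
#' @param site_trend character vector of per-site trend labels.
#' @param features character vector (same length) of per-site region
#'   labels.
#' @return data.frame: `trend`, `region`, `count`, `n`, `expected_prop`,
#'   `p`.
#' @export
region_trend_test <- function(site_trend, features) {
  stopifnot(length(site_trend) == length(features))
  keep <- !is.na(site_trend) & !is.na(features)
  site_trend <- site_trend[keep]; features <- features[keep]
  overall <- table(features) / length(features)
  out <- list()
  for (tr in unique(site_trend)) {
    rows <- site_trend == tr
    n <- sum(rows)
    if (!n) next
    for (reg in names(overall)) {
      x <- sum(features[rows] == reg)
      bt <- stats::binom.test(x, n, p = overall[[reg]])
      out[[length(out) + 1L]] <- data.frame(
        trend = tr, region = reg, count = x, n = n,
        expected_prop = overall[[reg]], p = bt$p.value)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Amplicon non-conversion grid with knockdown comparison
#'
#' Computes per-cytosine non-conversion at full depth (no coverage
#' thresholds, no 3C filter — amplicon depth is assumed saturating) for
#' every sample/replicate, and, for replicated designs, an unpaired
#' two-tailed t test of each sample against the designated knockdown
#' reference at each position.
#'
#' @param aln_by_sample nested named list: sample -> list of replicate
#'   `bs_alignments`.
#' @param refset the amplicon [ReferenceSet].
#' @param kd_sample name of the knockdown reference sample.
#' @param min_base_quality phred floor for pileup calls.
#' @return list: `grid` (long data.frame sample/replicate/position/
#'   nonconversion), `means` (sample x position matrix), `tests`
#'   (data.frame with t statistics and p values vs the knockdown, `NULL`
#'   for single-replicate designs).
#' @export
amplicon_nonconversion <- function(aln_by_sample, refset, kd_sample,
                                   min_base_quality = 30L) {
  if (!kd_sample %in% names(aln_by_sample))
    stopf("knockdown sample '%s' not found", kd_sample)
  cfg <- filter_config(max_nonconverted_per_read = .Machine$integer.max,
                       end_mask_nt = 0L, min_base_quality = min_base_quality,
                       apply_sn = FALSE)
  grid <- list()
  for (smp in names(aln_by_sample)) {
    reps <- aln_by_sample[[smp]]
    for (r in seq_along(reps)) {
      p <- build_pileup(reps[[r]], refset, cfg)
      if (!nrow(p)) next
      grid[[length(grid) + 1L]] <- data.frame(
        sample = smp, replicate = r, seqname = p$seqname, pos = p$pos,
        coverage = p$c_count + p$t_count,
        nonconversion = ifelse(p$c_count + p$t_count > 0,
                               p$c_count / (p$c_count + p$t_count), NA_real_),
        stringsAsFactors = FALSE)
    }
  }
  grid <- do.call(rbind, grid)
  key <- paste(grid$seqname, grid$pos)
  positions <- unique(key)
  samples <- names(aln_by_sample)
  means <- matrix(NA_real_, length(samples), length(positions),
                  dimnames = list(samples, positions))
  for (s in samples) for (k in positions) {
    v <- grid$nonconversion[grid$sample == s & key == k]
    if (length(v)) means[s, k] <- mean(v, na.rm = TRUE)
  }
  n_rep <- vapply(aln_by_sample, length, 0L)
  tests <- NULL
  if (all(n_rep >= 2)) {
    out <- list()
    for (s in setdiff(samples, kd_sample)) for (k in positions) {
      a <- grid$nonconversion[grid$sample == s & key == k]
      b <- grid$nonconversion[grid$sample == kd_sample & key == k]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (length(a) < 2 || length(b) < 2) next
      tt <- stats::t.test(a, b, var.equal = TRUE)
      out[[length(out) + 1L]] <- data.frame(
        sample = s, locus = k, mean_sample = mean(a), mean_kd = mean(b),
        statistic = unname(tt$statistic), p = tt$p.value,
        stringsAsFactors = FALSE)
    }
    tests <- do.call(rbind, out)
  }
  list(grid = grid, means = means, tests = tests)
}

#' Association of sites with translation efficiency or stability
#'
#' Compares a per-gene measure (translation efficiency computed as
#' normalised RPF / RNA, or any precomputed value) between site-bearing
#' genes and the remaining genes via empirical CDFs and a two-sample
#' Kolmogorov--Smirnov test. When raw RNA/RPF counts are given, only
#' genes with more than `min_reads` reads in both assays are retained.
#'
#' @param site_genes character vector of gene ids carrying candidate
#'   sites.
#' @param measures data.frame with `gene_id` and either `value` (a
#'   precomputed measure) or `rna` + `rpf` (normalised counts from which
#'   TE = rpf/rna is computed).
#' @param min_reads inclusion threshold (strictly more than this many
#'   reads; default 60).
#' @return list: `table` (gene_id, value, has_site), `ecdf_site`,
#'   `ecdf_other`, `statistic`, `p`.
#' @export
expression_association <- function(site_genes, measures, min_reads = 60) {
  d <- measures
  if (!"value" %in% names(d)) {
    if (!all(c("rna", "rpf") %in% names(d)))
      stopf("measures needs either a 'value' column or 'rna' + 'rpf'")
    d <- d[d$rna > min_reads & d$rpf > min_reads, , drop = FALSE]
    d$value <- d$rpf / d$rna
  }
  d$has_site <- d$gene_id %in% site_genes
  if (!any(d$has_site) || all(d$has_site))
    stopf("no overlap (or no complement) between site genes and the measure table")
  a <- d$value[d$has_site]; b <- d$value[!d$has_site]
  ks <- stats::ks.test(a, b)
  list(table = d[, c("gene_id", "value", "has_site")],
       ecdf_site = stats::ecdf(a), ecdf_other = stats::ecdf(b),
       statistic = unname(ks$statistic), p = ks$p.value)
}
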