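# Maximum-base-pairing secondary-structure stand-in and the base-pairing
# meta-profile around candidate sites.

PAIRABLE <- list(A = "U", U = c("A", "G"), G = c("C", "U"), C = "G")

can_pair <- function(a, b) b %in% PAIRABLE[[a]]

#' Fold a short RNA window by maximum base pairing
#'
#' Nussinov-style dynamic programme maximising the number of AU/GC/GU
#' pairs with a minimum hairpin loop of 3 unpaired bases; the pairing is a
#' valid non-crossing matching. This is a structural stand-in for
#' thermodynamic MFE folding: it captures whether flanks are structured,
#' not the precise MFE structure. A thermodynamic folder can be plugged in
#' via `fold_fun`, which must return a logical paired-indicator vector.
#'
#' @param sequence RNA string (ACGU; T accepted and read as U), length
#'   <= 200.
#' @param min_loop minimum unpaired bases inside a hairpin loop.
#' @param fold_fun optional replacement folding engine,
#'   `function(sequence) -> logical`.
#' @return list of class `bs_fold`: `paired` (logical per base), `pairs`
#'   (2-column index matrix, 1-based), `n_pairs`.
#' @export
fold_window <- function(sequence, min_loop = 3L, fold_fun = NULL) {
  s <- chartr("Tt", "Uu", toupper(sequence))
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  if (any(!ch %in% c("A", "C", "G", "U")))
    stopf("invalid alphabet in sequence (expected ACGU): '%s'",
          ch[which(!ch %in% c("A", "C", "G", "U"))[1]])
  n <- length(ch)
  if (n > 200) stopf("sequence longer than 200 nt")
  if (!is.null(fold_fun)) {
    paired <- fold_fun(sequence)
    return(structure(list(paired = paired, pairs = NULL,
                          n_pairs = sum(paired) / 2), class = "bs_fold"))
  }
  if (n == 0)
    return(structure(list(paired = logical(0),
                          pairs = matrix(0L, 0, 2), n_pairs = 0L),
                     class = "bs_fold"))
  M <- matrix(0L, n, n)
  ok_pairs <- c("AU", "UA", "GC", "CG", "GU", "UG")
  pairmat <- matrix(paste0(rep(ch, times = n), rep(ch, each = n)) %in% ok_pairs,
                    n, n)
  spans_seq <- if (n - 1L >= min_loop + 1L) (min_loop + 1L):(n - 1L) else integer(0)
  for (span in spans_seq) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- M[i, j - 1L]
      ks <- i:(j - min_loop - 1L)
      ks <- ks[pairmat[ks, j]]
      if (length(ks)) {
        left <- ifelse(ks > i, M[cbind(pmax(i, 1L), pmax(ks - 1L, 1L))], 0L)
        left[ks == i] <- 0L
        inner <- M[cbind(pmin(ks + 1L, n), j - 1L)]
        inner[ks + 1L > j - 1L] <- 0L
        best <- max(best, max(left + inner + 1L))
      }
      M[i, j] <- best
    }
  }
  # traceback
  pairs <- matrix(0L, 0, 2)
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    if (j - i < min_loop + 1L) next
    if (M[i, j] == M[i, j - 1L]) { stack[[length(stack) + 1L]] <- c(i, j - 1L); next }
    ks <- i:(j - min_loop - 1L)
    ks <- ks[pairmat[ks, j]]
    for (k in ks) {
      left <- if (k > i) M[i, k - 1L] else 0L
      inner <- if (k + 1L <= j - 1L) M[k + 1L, j - 1L] else 0L
      if (left + inner + 1L == M[i, j]) {
        pairs <- rbind(pairs, c(k, j))
        if (k > i) stack[[length(stack) + 1L]] <- c(i, k - 1L)
        if (k + 1L <= j - 1L) stack[[length(stack) + 1L]] <- c(k + 1L, j - 1L)
        break
      }
    }
  }
  paired <- logical(n)
  if (nrow(pairs)) paired[as.vector(pairs)] <- TRUE
  structure(list(paired = paired, pairs = pairs, n_pairs = nrow(pairs)),
            class = "bs_fold")
}

#' Base-pairing profile around candidate sites
#'
#' Extracts the transcript-strand window `flank` nt either side of each
#' site, folds it with [fold_window()], and reports the fraction of
#' windows in which each relative position is paired; a matched control
#' uses randomly selected transcript-strand Cs from the same genes.
#'
#' @param sites data.frame with `seqname`, `pos`, `strand` (plus `gene_id`
#'   if available, used to restrict the control pool).
#' @param refset a [ReferenceSet].
#' @param flank half-window (nt, default 25 for a 51-nt window).
#' @param n_control number of control windows (default: number of site
#'   windows).
#' @param seed RNG seed for control sampling.
#' @param fold_fun optional folding engine passed to [fold_window()].
#' @return data.frame: `position` (-flank..flank), `site_paired`,
#'   `control_paired` (fractions).
#' @export
pairing_profile <- function(sites, refset, flank = 25, n_control = NULL,
                            seed = 1L, fold_fun = NULL) {
  set.seed(seed)
  spans <- gene_spans(refset)
  get_window <- function(sq, pos, strand) {
    L <- nchar(refset$sequences[[sq]])
    if (pos - flank < 0 || pos + flank >= L) return(NULL)
    w <- substr(refset$sequences[[sq]], pos - flank + 1L, pos + flank + 1L)
    if (strand == "-") w <- revcomp(w)
    w
  }
  fold_frac <- function(windows) {
    acc <- numeric(2 * flank + 1); n <- 0L
    for (w in windows) {
      f <- fold_window(w, fold_fun = fold_fun)
      acc <- acc + as.numeric(f$paired); n <- n + 1L
    }
    if (n == 0) acc else acc / n
  }
  site_w <- list()
  for (i in seq_len(nrow(sites))) {
    w <- get_window(sites$seqname[i], sites$pos[i], sites$strand[i])
    if (!is.null(w)) site_w[[length(site_w) + 1L]] <- w
  }
  genes <- if ("gene_id" %in% names(sites))
    unique(stats::na.omit(sites$gene_id)) else
      unique(spans$gene_id[spans$seqname %in% sites$seqname])
  pool <- list()
  for (g in genes) {
    sp <- spans[spans$gene_id == g, ]
    ch <- ts_chars(refset$sequences[[sp$seqname]], sp$strand)
    cpos <- which(ch == "C") - 1L
    cpos <- cpos[cpos - flank >= 0 &
                   cpos + flank < nchar(refset$sequences[[sp$seqname]])]
    for (p in cpos)
      pool[[length(pool) + 1L]] <- list(sq = sp$seqname, pos = p,
                                        strand = sp$strand)
  }
  n_control <- n_control %||% length(site_w)
  ctrl_w <- list()
  if (length(pool)) {
    pick <- sample(length(pool), min(n_control, length(pool)))
    for (k in pick) {
      e <- pool[[k]]
      w <- get_window(e$sq, e$pos, e$strand)
      if (!is.null(w)) ctrl_w[[length(ctrl_w) + 1L]] <- w
    }
  }
  data.frame(position = -flank:flank,
             site_paired = fold_frac(site_w),
             control_paired = fold_frac(ctrl_w))
}
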