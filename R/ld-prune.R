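# Windowed pairwise-r2 LD pruning (the "indep-pairwise" procedure): slide a
# window of `window` SNPs forward by `step`, and within each placement remove
# one SNP of every pair whose squared correlation exceeds the threshold.

#' Pruning parameters
#'
#' Defaults reproduce the 50-SNP window, 5-SNP step, r2 > 0.1 setting used
#' for the correlation analyses; the odds-ratio analyses use the laxer 0.8
#' threshold.
#'
#' @param window window size in SNPs (>= 2).
#' @param step window shift in SNPs (1..window).
#' @param r2_max removal threshold in [0, 1].
#' @return list of class `prune_spec`.
#' @export
prune_spec <- function(window = 50, step = 5, r2_max = 0.1) {
  if (window < 2) stop("configuration error: window must be >= 2")
  if (step < 1 || step > window)
    stop("configuration error: step must be in 1..window")
  if (r2_max < 0 || r2_max > 1)
    stop("configuration error: r2_max must be in [0, 1]")
  structure(list(window = as.integer(window), step = as.integer(step),
                 r2_max = r2_max), class = "prune_spec")
}

#' Pairwise genotype r-squared
#'
#' Squared Pearson correlation between two dosage columns over individuals
#' with both values non-missing. Zero-variance input yields 0 with attribute
#' `undefined = TRUE`.
#'
#' @param a,b dosage vectors.
#' @return r^2 in [0, 1].
#' @export
genotype_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) stop("data error: fewer than 2 complete pairs")
  va <- stats::var(a[ok]); vb <- stats::var(b[ok])
  if (va == 0 || vb == 0) return(structure(0, undefined = TRUE))
  stats::cor(a[ok], b[ok])^2
}

#' Windowed LD pruning
#'
#' Greedy removal within sliding windows: for each window placement (start
#' advancing by `step`), every pair of still-kept SNPs with r^2 above
#' `r2_max` loses one member — the SNP with the lower sample MAF; on ties,
#' the later-positioned SNP. The rule makes the output deterministic. SNPs
#' must already be ordered by chromosome and position; output preserves
#' input order.
#'
#' @param genotypes n x m dosage matrix, columns position-ordered.
#' @param spec a [prune_spec()].
#' @return list: `kept` (SNP ids, input order), `kept_idx`, and `removals`
#'   (data.frame snp_id, window_start, partner, r2).
#' @export
prune_windowed <- function(genotypes, spec = prune_spec()) {
  m <- ncol(genotypes)
  ids <- colnames(genotypes)
  if (is.null(ids)) ids <- as.character(seq_len(m))
  keep <- rep(TRUE, m)
  cm <- colMeans(genotypes, na.rm = TRUE) / 2
  maf <- pmin(cm, 1 - cm)
  rem_snp <- character(0); rem_win <- integer(0)
  rem_partner <- character(0); rem_r2 <- numeric(0)
  starts <- if (m <= spec$window) 1L else seq(1L, m, by = spec$step)
  for (st in starts) {
    en <- min(st + spec$window - 1L, m)
    idx <- which(keep[st:en]) + st - 1L
    if (length(idx) < 2) next
    repeat {
      cc <- suppressWarnings(stats::cor(genotypes[, idx, drop = FALSE],
                                        use = "pairwise.complete.obs"))
      cc[is.na(cc)] <- 0
      r2 <- cc^2
      diag(r2) <- 0
      hit <- which(r2 > spec$r2_max, arr.ind = TRUE)
      if (!nrow(hit)) break
      hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
      # process the worst pair first, then rescan (removals may clear others)
      w <- which.max(r2[hit])
      i <- idx[hit[w, 1]]; j <- idx[hit[w, 2]]
      drop <- if (maf[i] < maf[j]) i else if (maf[j] < maf[i]) j else max(i, j)
      partner <- if (drop == i) j else i
      keep[drop] <- FALSE
      rem_snp <- c(rem_snp, ids[drop]); rem_win <- c(rem_win, st)
      rem_partner <- c(rem_partner, ids[partner])
      rem_r2 <- c(rem_r2, r2[hit[w, 1], hit[w, 2]])
      idx <- setdiff(idx, drop)
      if (length(idx) < 2) break
    }
  }
  list(kept = ids[keep], kept_idx = which(keep),
       removals = data.frame(snp_id = rem_snp, window_start = rem_win,
                             partner = rem_partner, r2 = rem_r2,
                             stringsAsFactors = FALSE))
}

#' Audit a pruned set
#'
#' Exhaustively re-scans every window placement over the kept SNPs and
#' returns the maximum within-window pairwise r^2 — which must not exceed
#' `spec$r2_max` if pruning met its post-condition.
#'
#' @param genotypes the dosage matrix pruning ran on.
#' @param kept_idx column indices retained by [prune_windowed()].
#' @param spec the same [prune_spec()].
#' @return the maximum kept within-window r^2.
#' @export
prune_audit <- function(genotypes, kept_idx, spec = prune_spec()) {
  m <- ncol(genotypes)
  worst <- 0
  starts <- if (m <= spec$window) 1L else seq(1L, m, by = spec$step)
  for (st in starts) {
    en <- min(st + spec$window - 1L, m)
    idx <- intersect(st:en, kept_idx)
    if (length(idx) < 2) next
    cc <- suppressWarnings(stats::cor(genotypes[, idx, drop = FALSE],
                                      use = "pairwise.complete.obs"))
    cc[is.na(cc)] <- 0
    diag(cc) <- 0
    worst <- max(worst, max(cc^2))
  }
  worst
}
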