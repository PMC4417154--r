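# Evaluation protocol for predicted binding: peak/random window selection,
# correlation statistics, ROC/AUROC, and motif-vs-track correlation
# matrices with per-target ranks of the matched motif.

#' Select evaluation windows: top peaks plus random eligible windows
#'
#' Eligible windows are accessible under `mask` and do not overlap any
#' coding interval by one or more bp.  Positives are the `n_pos` eligible
#' windows with the largest `peak_track` value (ties by genomic order);
#' randoms are a seeded uniform sample, without replacement, from the
#' remaining eligible windows.
#'
#' @param peak_track `window_track` of e.g. ChIP signal.
#' @param mask accessibility mask on the same grid.
#' @param coding tibble of coding intervals (`chrom`, `start`, `end`).
#' @param n_pos,n_rand set sizes.
#' @param seed integer seed for the random draw.
#' @return An `eval_window_set` tibble (`chrom`, `start`, `end`, `window`
#'   grid row, `set` = "peak"/"random") with `seed` and `filters`
#'   attributes.
#' @export
select_eval_windows <- function(peak_track, mask, coding, n_pos, n_rand,
                                seed) {
  if (!same_grid(peak_track, mask)) abort("track and mask grids differ")
  eligible <- mask$accessible & !is.na(peak_track$value)
  if (!is.null(coding) && nrow(coding) > 0) {
    ov <- interval_overlaps(
      tibble(chrom = peak_track$chrom, start = peak_track$start,
             end = peak_track$end), coding)
    eligible[unique(ov$query)] <- FALSE
  }
  idx <- which(eligible)
  if (length(idx) < n_pos + n_rand) {
    abort(sprintf(
      "insufficient eligible windows: need %d, have %d (deficit %d)",
      n_pos + n_rand, length(idx), n_pos + n_rand - length(idx)))
  }
  ord <- idx[order(-peak_track$value[idx], peak_track$chrom[idx],
                   peak_track$start[idx])]
  pos <- ord[seq_len(n_pos)]
  pool <- setdiff(idx, pos)
  rnd <- with_seed(seed, sort(sample(pool, n_rand)))
  out <- tibble(
    chrom = peak_track$chrom[c(pos, rnd)],
    start = peak_track$start[c(pos, rnd)],
    end = peak_track$end[c(pos, rnd)],
    window = c(pos, rnd),
    set = rep(c("peak", "random"), c(n_pos, n_rand)))
  attr(out, "seed") <- seed
  attr(out, "filters") <- c("accessible", "non-coding")
  class(out) <- c("eval_window_set", class(tibble()))
  out
}

#' Correlation with a two-sided t-transform p-value
#'
#' Pearson r or Spearman rho (midrank ties); the two-sided p-value comes
#' from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom
#' (for Spearman this is the usual large-n approximation).  `|r| = 1`
#' reports p = 0.
#'
#' @param x,y numeric vectors (n >= 3, finite).
#' @param method "pearson" or "spearman".
#' @return one-row tibble: `method`, `r`, `n`, `p_value`, `df`.
#' @export
correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  if (length(x) < 3) abort("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("values must be finite")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("zero variance in x or y")
  }
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
  }
  r <- stats::cor(x, y)
  n <- length(x)
  df <- n - 2
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df)
  }
  tibble(method = method, r = r, n = n, p_value = p, df = df)
}

#' ROC curve and AUROC with Mann-Whitney tie handling
#'
#' The AUROC equals `P(score_pos > score_neg) + 0.5 * P(tie)`; the curve is
#' a descending-score threshold sweep (tied scores move together).
#'
#' @param scores numeric predictions.
#' @param labels logical (or 0/1) truth labels; both classes must occur.
#' @return A `roc_result` list: `auroc` and a `curve` tibble with
#'   `threshold`, `fpr`, `tpr`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !any(is.na(scores)))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) abort("both classes must be present")
  rk <- rank(scores)                     # midranks handle ties
  auroc <- (sum(rk[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(-scores)
  s <- scores[ord]; l <- labels[ord]
  grp_last <- cumsum(rle(s)$lengths)
  tp <- cumsum(l)[grp_last]
  fp <- cumsum(!l)[grp_last]
  curve <- tibble(threshold = c(Inf, s[grp_last]),
                  fpr = c(0, fp / n_neg),
                  tpr = c(0, tp / n_pos))
  structure(list(auroc = auroc, curve = curve), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUROC = %.4f (%d thresholds)\n",
              x$auroc, nrow(x$curve) - 1))
  invisible(x)
}

#' Correlation matrix between motif tracks and target tracks on an
#' evaluation window set
#'
#' Correlations are computed over the windows of `eval_set` only.  For each
#' target with a declared matched motif, the rank of that motif among all
#' motifs by descending correlation is reported (rank 1 best, ties by
#' average rank).
#'
#' @param motif_tracks named list of `window_track`s.
#' @param target_tracks named list of `window_track`s (e.g. ChIP or
#'   accessibility).
#' @param eval_set a [select_eval_windows()] result.
#' @param method correlation method, "pearson" or "spearman".
#' @param pairs tibble with `motif` and `target` declaring matched pairs.
#' @return list: `matrix` (motifs x targets correlations) and `ranks`
#'   tibble (`target`, `motif`, `rank`).
#' @export
cross_correlation_matrix <- function(motif_tracks, target_tracks, eval_set,
                                     method = c("pearson", "spearman"),
                                     pairs = NULL) {
  method <- match.arg(method)
  idx <- eval_set$window
  for (tr in c(motif_tracks, target_tracks)) {
    if (!identical(nrow(tr), nrow(motif_tracks[[1]]))) {
      abort("all tracks must share one grid")
    }
  }
  mvals <- vapply(motif_tracks, function(tr) tr$value[idx],
                  numeric(length(idx)))
  tvals <- vapply(target_tracks, function(tr) tr$value[idx],
                  numeric(length(idx)))
  if (method == "spearman") {
    mvals <- apply(mvals, 2, rank)
    tvals <- apply(tvals, 2, rank)
  }
  cmat <- stats::cor(mvals, tvals)
  rownames(cmat) <- names(motif_tracks)
  colnames(cmat) <- names(target_tracks)
  ranks <- NULL
  if (!is.null(pairs)) {
    ranks <- pairs %>%
      mutate(rank = map2_dbl(.data$motif, .data$target, function(m, tg) {
        rk <- rank(-cmat[, tg])
        unname(rk[m])
      }))
  }
  list(matrix = cmat, ranks = ranks)
}
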