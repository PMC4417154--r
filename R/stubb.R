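# Stubb-style window motif scoring: an HMM whose free parameter, the
# site-entry probability p, is fitted per window by EM, and whose score is
# the log-likelihood ratio logL(p_hat) - logL(0) in nats (clamped at 0).
# Multi-species scores average per-species window scores with phylogenetic
# weights renormalised over species that have an orthologous segment.

site_ratios <- function(codes, pwm, bg) {
  e <- motif_emission_cpp(codes, pwm$mat)
  bgp <- background_probs(codes, bg)
  site_ratio_cpp(e, bgp, pwm$width)
}

#' Score one window with the motif + background HMM
#'
#' Fits the per-position site-entry probability `p` by EM (capped at
#' `p_max = 1/w`) and reports `logL(p_hat) - logL(0)` in nats, clamped at 0.
#' Windows shorter than the motif width get score 0 with `p_hat = 0`.
#' Non-ACGT bases emit as background with probability 0.25 and can never
#' sit inside a site.
#'
#' @param window_seq DNA string of the window.
#' @param pwm a [build_pwm()] object.
#' @param bg a [train_background()] model.
#' @param p_init EM initialisation; default `1/(4w)`.
#' @param p_max cap on the fitted site probability; default `1/w`.
#' @param tol EM convergence tolerance on the log-likelihood (nats).
#' @param max_iter EM iteration cap.
#' @return list with `score` (nats, >= 0) and `fit`, a `stubb_fit` with
#'   `p_hat`, `loglik` and `loglik0` (nats), `iters`, the per-iteration
#'   log-likelihood `trace`, and `n_flagged` non-ACGT bases.
#' @export
stubb_score <- function(window_seq, pwm, bg, p_init = NULL, p_max = NULL,
                        tol = 1e-9, max_iter = 200L) {
  w <- pwm$width
  if (is.null(p_init)) p_init <- 1 / (4 * w)
  if (is.null(p_max)) p_max <- 1 / w
  codes <- encode_dna(window_seq)
  if (length(codes) < 1) abort("window sequence must be non-empty")
  r <- site_ratios(codes, pwm, bg)
  em <- stubb_em_cpp(r, w, p_init, p_max, tol, as.integer(max_iter), TRUE)
  loglik0 <- sum(log(background_probs(codes, bg)))
  fit <- structure(
    list(p_hat = em$p_hat, loglik = loglik0 + em$gain, loglik0 = loglik0,
         iters = em$iters, trace = em$trace + loglik0,
         n_flagged = sum(codes >= 4L)),
    class = "stubb_fit")
  list(score = em$score, fit = fit)
}

#' @export
print.stubb_fit <- function(x, ...) {
  cat(sprintf("<stubb_fit> p_hat = %.5g, logL = %.4f (logL0 = %.4f), %d EM iterations\n",
              x$p_hat, x$loglik, x$loglik0, x$iters))
  invisible(x)
}

#' Window log-likelihood ratio at a fixed site probability
#'
#' Evaluates `logL(p) - logL(0)` (nats) of the window HMM without fitting,
#' via the forward recursion.
#'
#' @inheritParams stubb_score
#' @param p fixed site-entry probability.
#' @return scalar log-likelihood ratio.
#' @export
stubb_likelihood <- function(window_seq, pwm, bg, p) {
  codes <- encode_dna(window_seq)
  r <- site_ratios(codes, pwm, bg)
  stubb_loglik_ratio_cpp(r, pwm$width, p)
}

#' Score every window of a grid against one motif
#'
#' Each window is scored in isolation with [stubb_score()] semantics;
#' only `windows` (row indices of the grid) are scored when given, other
#' windows receiving `NA`.
#'
#' @param genome named character vector or [Biostrings::DNAStringSet] of
#'   chromosome sequences.
#' @param pwm a `pwm`.
#' @param grid a [tile_genome()] grid whose chromosomes exist in `genome`.
#' @param bg a `background_model`.
#' @param windows optional integer vector of grid row indices to score.
#' @return A `window_track` of motif scores (NA where unscored).
#' @export
score_genome <- function(genome, pwm, grid, bg, windows = NULL) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  missing_chr <- setdiff(unique(grid$chrom), names(genome))
  if (length(missing_chr) > 0) {
    abort(paste0("sequence missing for chromosome(s): ",
                 paste(missing_chr, collapse = ", ")))
  }
  win_len <- attr(grid, "window_length")
  values <- rep(NA_real_, nrow(grid))
  idx_all <- if (is.null(windows)) seq_len(nrow(grid)) else sort(unique(windows))
  for (ch in unique(grid$chrom[idx_all])) {
    idx <- idx_all[grid$chrom[idx_all] == ch]
    codes <- encode_dna(genome[[ch]])
    r <- site_ratios(codes, pwm, bg)
    res <- stubb_windows_cpp(r, grid$start[idx], win_len, pwm$width,
                             1 / (4 * pwm$width), 1 / pwm$width, 1e-9, 200L)
    values[idx] <- res$score
  }
  new_window_track(grid, values)
}

#' Score a set of equal-length window segments (e.g. orthologous segments)
#'
#' @param segments named character vector of window-id -> sequence.
#' @param pwm a `pwm`.
#' @param bg a `background_model`.
#' @return named numeric vector of scores.
#' @export
score_segments <- function(segments, pwm, bg) {
  if (length(segments) == 0) return(setNames(numeric(0), character(0)))
  lens <- nchar(segments)
  codes <- encode_dna(paste0(segments, collapse = ""))
  r <- site_ratios(codes, pwm, bg)
  starts <- cumsum(c(0L, unname(lens[-length(lens)])))
  # segments are isolated sequences: zero ratios that straddle a boundary
  if (length(segments) > 1) {
    w <- pwm$width
    for (i in 2:length(segments)) {
      s <- starts[i]
      if (w > 1) r[(s + 1):min(s + w - 1, length(r))] <- 0
    }
  }
  out <- numeric(length(segments))
  for (i in seq_along(segments)) {
    res <- stubb_em_cpp(r[(starts[i] + 1):(starts[i] + lens[i])], pwm$width,
                        1 / (4 * pwm$width), 1 / pwm$width, 1e-9, 200L, FALSE)
    out[i] <- res$score
  }
  setNames(out, names(segments))
}

#' Construct an orthology map
#'
#' @param segments named list: species -> named character vector mapping
#'   reference window keys (`"chrom:start"`) to orthologous segment
#'   sequences.  The reference species must map every window that appears
#'   anywhere in the map.
#' @param weights tibble with `species` and `weight` (non-negative, summing
#'   to 1 across all species).
#' @param reference name of the reference species.
#' @return An `orthology_map` list.
#' @export
orthology_map <- function(segments, weights, reference) {
  assert_that(reference %in% names(segments),
              "reference species missing from segments")
  assert_that(all(weights$species %in% names(segments)) &&
                all(names(segments) %in% weights$species),
              "weights and segments name different species")
  assert_that(all(weights$weight >= 0), "weights must be non-negative")
  assert_that(abs(sum(weights$weight) - 1) < 1e-9, "weights must sum to 1")
  all_keys <- unique(unlist(lapply(segments, names)))
  assert_that(all(all_keys %in% names(segments[[reference]])),
              "reference species must cover every mapped window")
  structure(list(segments = segments, weights = weights,
                 reference = reference),
            class = "orthology_map")
}

#' Phylogenetically weighted average of per-species window scores
#'
#' Weights are renormalised over the species actually present (non-NA);
#' absence of an orthologous segment is treated as missing data, not as a
#' zero score.
#'
#' @param scores numeric vector (one window) or matrix (windows x species)
#'   of per-species scores, NA where the species has no segment.
#' @param weights numeric vector of per-species weights, aligned with the
#'   columns (or elements) of `scores`.
#' @return numeric vector of weighted averages.
#' @export
multispecies_average <- function(scores, weights) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  stopifnot(ncol(scores) == length(weights))
  present <- !is.na(scores)
  if (any(rowSums(present) == 0)) {
    abort("no species present for at least one window")
  }
  wmat <- matrix(weights, nrow = nrow(scores), ncol = length(weights),
                 byrow = TRUE)
  wmat[!present] <- 0
  num <- rowSums(scores * wmat, na.rm = TRUE)
  num / rowSums(wmat)
}

#' Multi-species motif score track over a grid
#'
#' Scores the reference genome plus each species' orthologous segments and
#' combines them with [multispecies_average()].
#'
#' @param genome reference genome (named character or DNAStringSet).
#' @param orth an [orthology_map()]; per-species backgrounds are trained on
#'   each species' own segments unless supplied.
#' @param pwm a `pwm`.
#' @param grid window grid.
#' @param bg reference background model.
#' @param species_bg optional named list of per-species background models.
#' @param windows optional grid row indices to score.
#' @return A `window_track` of multi-species scores.
#' @export
score_genome_multispecies <- function(genome, orth, pwm, grid, bg,
                                      species_bg = NULL, windows = NULL) {
  ref_track <- score_genome(genome, pwm, grid, bg, windows = windows)
  keys <- window_key(grid$chrom, grid$start)
  idx <- if (is.null(windows)) seq_len(nrow(grid)) else sort(unique(windows))
  others <- setdiff(names(orth$segments), orth$reference)
  smat <- matrix(NA_real_, nrow = length(idx), ncol = 1 + length(others),
                 dimnames = list(NULL, c(orth$reference, others)))
  smat[, 1] <- ref_track$value[idx]
  for (sp in others) {
    segs <- orth$segments[[sp]]
    hit <- intersect(keys[idx], names(segs))
    if (length(hit) == 0) next
    bg_sp <- if (!is.null(species_bg)) species_bg[[sp]] else
      train_background(unname(segs), order = bg$order,
                       pseudocount = bg$pseudocount, label = sp)
    sc <- score_segments(segs[hit], pwm, bg_sp)
    smat[match(hit, keys[idx]), sp] <- sc
  }
  wts <- orth$weights$weight[match(colnames(smat), orth$weights$species)]
  avg <- multispecies_average(smat, wts)
  values <- rep(NA_real_, nrow(grid))
  values[idx] <- avg
  new_window_track(grid, values)
}
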