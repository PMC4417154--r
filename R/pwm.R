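# Position weight matrices and Markov background models.

#' Build a position weight matrix from nucleotide counts
#'
#' Column probabilities are `(count + pseudocount) / (total + 4 * pseudocount)`.
#'
#' @param count_matrix 4 x w matrix of non-negative counts, rows A, C, G, T.
#' @param pseudocount added to every cell; default 0.5.
#' @param id motif identifier.
#' @return A `pwm` object: list with `id`, `width`, 4 x w probability matrix
#'   `mat`, and the `pseudocount` used.
#' @examples
#' build_pwm(matrix(c(10, 0, 0, 0), nrow = 4), pseudocount = 1)
#' @export
build_pwm <- function(count_matrix, pseudocount = 0.5, id = "motif") {
  m <- as.matrix(count_matrix)
  if (nrow(m) != 4) abort("count matrix must have 4 rows (A, C, G, T)")
  if (ncol(m) < 1) abort("motif width must be at least 1")
  if (any(m < 0)) abort("counts must be non-negative")
  if (any(colSums(m) <= 0)) abort("every column needs at least one count")
  probs <- sweep(m + pseudocount, 2, colSums(m) + 4 * pseudocount, "/")
  if (any(probs <= 0)) {
    abort("zero probabilities in PWM; use a positive pseudocount")
  }
  stopifnot(all(abs(colSums(probs) - 1) < 1e-9))
  rownames(probs) <- DNA_BASES
  structure(list(id = id, width = ncol(probs), mat = probs,
                 pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s (width %d)\n", x$id, x$width))
  print(round(x$mat, 3))
  invisible(x)
}

#' Train an order-k Markov background model on nucleotide sequences
#'
#' Maximum-likelihood conditional nucleotide frequencies with add-pseudocount
#' smoothing.  Positions involving non-ACGT bases are excluded from counts;
#' sequences with more than `max_n_frac` such bases raise an error.
#'
#' @param sequences character vector of DNA strings (or a
#'   [Biostrings::DNAStringSet]).
#' @param order Markov order k >= 0; default 1.
#' @param pseudocount smoothing constant; default 0.5.
#' @param max_n_frac maximum tolerated fraction of non-ACGT characters.
#' @param label free-text label of the training sequences.
#' @return A `background_model`: list with `order`, `trans` (4^k x 4
#'   conditional probabilities), `marginal` (length 4, used where the
#'   context is unavailable), `pseudocount` and `label`.
#' @export
train_background <- function(sequences, order = 1L, pseudocount = 0.5,
                             max_n_frac = 0.2, label = "genome") {
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- as.character(sequences)
  }
  order <- as.integer(order)
  if (order < 0) abort("order must be >= 0")
  codes <- lapply(sequences, encode_dna)
  total <- sum(lengths(codes))
  if (total == 0) abort("total sequence length must be positive")
  n_bad <- sum(vapply(codes, function(z) sum(z >= 4L), numeric(1)))
  if (n_bad / total > max_n_frac) {
    abort(sprintf("non-ACGT fraction %.3f exceeds allowed %.3f",
                  n_bad / total, max_n_frac))
  }
  base_counts <- numeric(4)
  k <- order
  trans_counts <- matrix(0, nrow = 4^k, ncol = 4)
  for (z in codes) {
    ok <- z < 4L
    base_counts <- base_counts + tabulate(z[ok] + 1L, nbins = 4)
    if (k > 0 && length(z) > k) {
      idx <- seq_len(length(z) - k)
      ctx <- rep(0L, length(idx))
      valid <- rep(TRUE, length(idx))
      for (j in seq_len(k)) {
        b <- z[idx + j - 1L]
        valid <- valid & (b < 4L)
        ctx <- ctx * 4L + b
      }
      nxt <- z[idx + k]
      valid <- valid & (nxt < 4L)
      if (any(valid)) {
        cell <- ctx[valid] * 4L + nxt[valid]  # 0-based cell index
        tab <- tabulate(cell + 1L, nbins = 4^(k + 1))
        trans_counts <- trans_counts +
          matrix(tab, nrow = 4^k, ncol = 4, byrow = TRUE)
      }
    }
  }
  marginal <- (base_counts + pseudocount) /
    (sum(base_counts) + 4 * pseudocount)
  if (k > 0) {
    denom <- rowSums(trans_counts) + 4 * pseudocount
    trans <- (trans_counts + pseudocount) / denom
    # contexts never observed (possible with pseudocount 0) fall back to
    # the marginal distribution
    unseen <- denom == 0
    if (any(unseen)) {
      trans[unseen, ] <- matrix(marginal, sum(unseen), 4, byrow = TRUE)
    }
  } else {
    trans <- matrix(marginal, nrow = 1)
  }
  stopifnot(all(abs(rowSums(trans) - 1) < 1e-9))
  structure(list(order = k, trans = trans, marginal = marginal,
                 pseudocount = pseudocount, label = label),
            class = "background_model")
}

#' Per-position background emission probabilities for a coded sequence
#' @keywords internal
#' @noRd
background_probs <- function(codes, bg) {
  bg_probs_cpp(codes, bg$trans, bg$marginal, bg$order)
}
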