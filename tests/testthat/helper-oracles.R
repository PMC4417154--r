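# Independent oracles: brute-force or enumeration implementations used to
# verify the package's algorithms.  Deliberately written without reusing
# any package internals.

# Per-position background probability of a DNA string under a Markov
# background model (marginal fallback where the context is unavailable,
# 0.25 for non-ACGT bases).
oracle_bgp <- function(seq, bg) {
  idx <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T"))
  n <- length(idx)
  out <- numeric(n)
  k <- bg$order
  for (i in seq_len(n)) {
    if (is.na(idx[i])) { out[i] <- 0.25; next }
    if (k == 0 || i <= k || any(is.na(idx[(i - k):(i - 1)]))) {
      out[i] <- bg$marginal[idx[i]]
    } else {
      ctx <- 0
      for (j in (i - k):(i - 1)) ctx <- ctx * 4 + (idx[j] - 1)
      out[i] <- bg$trans[ctx + 1, idx[i]]
    }
  }
  out
}

# log L(p) - log L(0) of the window site/background model by explicit
# enumeration of every set of non-overlapping site placements.
oracle_stubb_loglik <- function(seq, pwm_mat, bgp, p) {
  idx <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T"))
  n <- length(idx)
  w <- ncol(pwm_mat)
  emis <- rep(0, n)
  if (n >= w) {
    for (j in w:n) {
      span <- idx[(j - w + 1):j]
      if (any(is.na(span))) next
      fwd <- prod(pwm_mat[cbind(span, 1:w)])
      rev <- prod(pwm_mat[cbind(5 - rev(span), 1:w)])
      emis[j] <- 0.5 * (fwd + rev)
    }
  }
  ends <- which(emis > 0)
  subsets <- list(integer(0))
  for (e in ends) {
    grown <- lapply(Filter(function(s) {
      length(s) == 0 || min(abs(s - e)) >= w
    }, subsets), function(s) c(s, e))
    subsets <- c(subsets, grown)
  }
  total <- 0
  for (s in subsets) {
    covered <- unlist(lapply(s, function(e) (e - w + 1):e))
    kk <- length(s)
    term <- p^kk * (1 - p)^(n - w * kk) *
      prod(bgp[setdiff(seq_len(n), covered)]) * prod(emis[s])
    total <- total + term
  }
  log(total) - sum(log(bgp))
}

# P(X >= x) for the hypergeometric by enumerating every draw of n from N
# with the first K elements as successes.
oracle_hypergeom_tail <- function(N, K, n) {
  draws <- utils::combn(N, n)
  cnt <- colSums(draws <= K)
  function(x) mean(cnt >= x)
}

# AUROC by brute force over all positive/negative pairs (ties half credit).
oracle_auroc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

random_dna_str <- function(n, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

random_pwm <- function(w, id = "m") {
  cnt <- matrix(rpois(4 * w, 3) + 1, nrow = 4)
  build_pwm(cnt, pseudocount = 0.5, id = id)
}
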