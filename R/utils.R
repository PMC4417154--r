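# Internal helpers shared across modules.

# DNA alphabet used throughout; code 4 marks any non-ACGT character.
DNA_BASES <- c("A", "C", "G", "T")

#' Encode a DNA string as integer codes
#'
#' A, C, G, T map to 0..3; every other character (N, gaps, lower-case is
#' uppercased first) maps to 4.
#' @param seq single character string.
#' @return integer vector of per-base codes.
#' @keywords internal
#' @noRd
encode_dna <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  code <- utf8ToInt(toupper(seq))
  lut <- rep(4L, 128L)
  lut[utf8ToInt("A") + 1L] <- 0L
  lut[utf8ToInt("C") + 1L] <- 1L
  lut[utf8ToInt("G") + 1L] <- 2L
  lut[utf8ToInt("T") + 1L] <- 3L
  code[code > 127L] <- 127L
  lut[code + 1L]
}

#' Reverse complement of a DNA string
#' @keywords internal
#' @noRd
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Seeded evaluation that leaves the caller's RNG state untouched.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
}

window_key <- function(chrom, start) paste0(chrom, ":", start)

# GRanges <-> tibble conversion at module surfaces (0-based half-open in
# tibbles, 1-based closed inside GRanges).
tbl_to_granges <- function(x, seqlevels = NULL) {
  if (is.null(seqlevels)) seqlevels <- unique(x$chrom)
  GenomicRanges::GRanges(
    seqnames = factor(x$chrom, levels = seqlevels),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

granges_to_tbl <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

# Overlap of two interval tibbles (chrom/start/end, 0-based half-open);
# returns a tibble of (queryHits, subjectHits) row indices.
interval_overlaps <- function(query, subject) {
  lv <- unique(c(query$chrom, subject$chrom))
  hits <- GenomicRanges::findOverlaps(tbl_to_granges(query, lv),
                                      tbl_to_granges(subject, lv))
  tibble(query = S4Vectors::queryHits(hits),
         subject = S4Vectors::subjectHits(hits))
}
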