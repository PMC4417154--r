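# Readers and writers for the flat formats used at module boundaries.
# bedGraph and BED go through rtracklayer; tibbles use 0-based half-open
# coordinates throughout.

#' Read a two-column chromosome-sizes TSV
#' @param path file with columns (name, length), no header.
#' @return tibble with `chrom` and `length`.
#' @export
read_chrom_sizes <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "length"),
                  col_types = "ci", progress = FALSE)
}

#' Read a bedGraph signal file into a base-level track tibble
#' @param path bedGraph file.
#' @return tibble with `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  out <- granges_to_tbl(gr)
  out$value <- as.numeric(gr$score)
  out
}

#' Write a track tibble as bedGraph
#' @param x tibble with `chrom`, `start`, `end`, `value`.
#' @param path output file.
#' @export
write_bedgraph <- function(x, path) {
  gr <- tbl_to_granges(x)
  gr$score <- x$value
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a BED file of intervals
#' @param path BED file.
#' @return tibble with `chrom`, `start`, `end` (and `name` when present).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- granges_to_tbl(gr)
  if (!is.null(gr$name) && !all(is.na(gr$name))) out$name <- gr$name
  out
}

#' Write intervals as BED
#' @param x tibble with `chrom`, `start`, `end` and optional `name`.
#' @param path output file.
#' @export
write_bed <- function(x, path) {
  gr <- tbl_to_granges(x)
  if ("name" %in% names(x)) gr$name <- x$name
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write a window track as a flat TSV
#' @param x a `window_track`.
#' @param path output file.
#' @export
write_track_tsv <- function(x, path) {
  readr::write_tsv(tibble(chrom = x$chrom, start = x$start, end = x$end,
                          value = x$value), path, progress = FALSE)
  invisible(path)
}

#' Write the accessible windows of a mask as BED
#' @param mask an accessibility mask.
#' @param path output file.
#' @export
write_mask_bed <- function(mask, path) {
  write_bed(filter(mask, .data$accessible), path)
}

#' Read motifs from a MEME minimal-format file
#'
#' Parses the background letter frequencies (if present) and every
#' `MOTIF` block's letter-probability matrix.
#'
#' @param path MEME minimal format file.
#' @return named list of `pwm` objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  motif_at <- grep("^MOTIF\\s+", lines)
  if (length(motif_at) == 0) abort("no MOTIF blocks found")
  pwms <- list()
  for (i in seq_along(motif_at)) {
    id <- strsplit(trimws(lines[motif_at[i]]), "\\s+")[[1]][2]
    from <- motif_at[i]
    to <- if (i < length(motif_at)) motif_at[i + 1] - 1 else length(lines)
    block <- lines[from:to]
    hdr <- grep("^letter-probability matrix", block)
    if (length(hdr) != 1) abort(paste0("malformed MOTIF block: ", id))
    rows <- character()
    j <- hdr + 1
    while (j <= length(block) &&
           grepl("^\\s*[0-9.eE+-]+(\\s+[0-9.eE+-]+){3}\\s*$", block[j])) {
      rows <- c(rows, block[j])
      j <- j + 1
    }
    mat <- t(vapply(strsplit(trimws(rows), "\\s+"),
                    function(z) as.numeric(z), numeric(4)))
    m <- t(mat)  # 4 x w, rows A C G T
    rownames(m) <- DNA_BASES
    pwms[[id]] <- structure(list(id = id, width = ncol(m), mat = m,
                                 pseudocount = NA_real_),
                            class = "pwm")
  }
  pwms
}

#' Write motifs as a MEME minimal-format file
#' @param pwms list of `pwm` objects.
#' @param path output file.
#' @param bg_freqs optional length-4 background frequencies (A, C, G, T).
#' @export
write_meme <- function(pwms, path, bg_freqs = rep(0.25, 4)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", DNA_BASES, bg_freqs),
                     collapse = " "), ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$id), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0", p$width),
      con)
    for (j in seq_len(p$width)) {
      writeLines(paste(sprintf("%.6f", p$mat[, j]), collapse = "  "), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
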