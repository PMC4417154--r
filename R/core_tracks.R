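# Genome tiling, per-window signal aggregation and accessibility masks.
#
# Coordinates are 0-based, half-open (BED convention) everywhere.  A window
# grid is a tibble of (chrom, start, end) rows sorted by (chrom, start);
# tracks and masks add a `value` / `accessible` column on the same rows.

#' Tile a genome into overlapping fixed-length windows
#'
#' Windows of `window_length` bp are placed every `stride` bp along each
#' chromosome, starting at 0, as long as they fit entirely within the
#' chromosome.  Trailing segments shorter than `window_length` produce no
#' window.
#'
#' @param chrom_sizes named numeric vector (or two-column data frame with
#'   `chrom` and `length`) of chromosome lengths in bp.
#' @param window_length window length in bp (must be a multiple of `stride`).
#' @param stride shift between consecutive window starts in bp.
#' @return A `window_grid` tibble with columns `chrom`, `start`, `end`,
#'   ordered by (chrom, start).
#' @examples
#' tile_genome(c(chr1 = 1000), window_length = 500, stride = 50)
#' @export
tile_genome <- function(chrom_sizes, window_length = 500L, stride = 50L) {
  if (is.data.frame(chrom_sizes)) {
    chrom_sizes <- setNames(chrom_sizes[[2]], chrom_sizes[[1]])
  }
  window_length <- as.integer(window_length)
  stride <- as.integer(stride)
  if (window_length <= 0L || stride <= 0L) {
    abort("window_length and stride must be positive")
  }
  if (any(chrom_sizes <= 0)) abort("chromosome lengths must be positive")
  if (window_length %% stride != 0L) {
    abort("window_length must be a multiple of stride")
  }
  chroms <- sort(names(chrom_sizes))
  rows <- lapply(chroms, function(ch) {
    L <- as.integer(chrom_sizes[[ch]])
    if (L < window_length) {
      return(tibble(chrom = character(), start = integer(), end = integer()))
    }
    starts <- seq.int(0L, L - window_length, by = stride)
    tibble(chrom = ch, start = starts, end = starts + window_length)
  })
  grid <- bind_rows(rows)
  structure(grid,
            window_length = window_length,
            stride = stride,
            chrom_sizes = chrom_sizes[chroms],
            class = c("window_grid", class(tibble())))
}

grid_meta <- function(grid) {
  list(window_length = attr(grid, "window_length"),
       stride = attr(grid, "stride"),
       chrom_sizes = attr(grid, "chrom_sizes"))
}

#' Test whether two window-level tibbles share a grid
#' @keywords internal
#' @noRd
same_grid <- function(a, b) {
  identical(a$chrom, b$chrom) && identical(a$start, b$start) &&
    identical(a$end, b$end)
}

#' Construct a window track from a grid and per-window values
#' @param grid a [tile_genome()] grid.
#' @param value numeric vector, one value per window (NA = missing).
#' @return A `window_track` tibble.
#' @export
window_track <- function(grid, value) {
  new_window_track(grid, value)
}

new_window_track <- function(grid, value) {
  stopifnot(length(value) == nrow(grid))
  out <- tibble(chrom = grid$chrom, start = grid$start, end = grid$end,
                value = as.numeric(value))
  attributes(out)[c("window_length", "stride", "chrom_sizes")] <-
    grid_meta(grid)
  class(out) <- c("window_track", class(tibble()))
  out
}

#' Aggregate a per-base signal track into window values
#'
#' Each window value is the arithmetic mean, over its `stride`-bp
#' subsegments, of the maximum per-base signal within the subsegment.
#' Bases not covered by any interval count as 0.
#'
#' @param track tibble with `chrom`, `start`, `end`, `value` columns
#'   (bedGraph semantics: non-overlapping intervals per chromosome).
#' @param grid a [tile_genome()] window grid.
#' @return A `window_track` tibble (`chrom`, `start`, `end`, `value`).
#' @export
aggregate_base_track <- function(track, grid) {
  meta <- grid_meta(grid)
  stride <- meta$stride
  nseg <- meta$window_length %/% stride
  extra <- setdiff(unique(track$chrom), names(meta$chrom_sizes))
  if (length(extra) > 0) {
    warn(paste0("signal chromosomes absent from grid skipped: ",
                paste(extra, collapse = ", ")))
    track <- filter(track, !.data$chrom %in% extra)
  }
  values <- numeric(nrow(grid))
  for (ch in unique(grid$chrom)) {
    L <- meta$chrom_sizes[[ch]]
    ntile <- ceiling(L / stride)
    tile_max <- numeric(ntile)       # max over covered bases, 0 baseline
    tile_cov <- numeric(ntile)       # covered width per tile
    tr <- track[track$chrom == ch & track$end > track$start, , drop = FALSE]
    if (nrow(tr) > 0) {
      if (any(!is.finite(tr$value))) abort("base track values must be finite")
      t0 <- tr$start %/% stride
      t1 <- (tr$end - 1L) %/% stride
      reps <- t1 - t0 + 1L
      tile <- unlist(mapply(seq.int, t0, t1, SIMPLIFY = FALSE)) + 1L
      val <- rep(tr$value, reps)
      lo <- pmax(rep(tr$start, reps), (tile - 1L) * stride)
      hi <- pmin(rep(tr$end, reps), tile * stride)
      keep <- tile <= ntile
      tile <- tile[keep]; val <- val[keep]; covw <- (hi - lo)[keep]
      mx <- tapply(val, tile, max)
      tile_max[as.integer(names(mx))] <- as.numeric(mx)
      cv <- tapply(covw, tile, sum)
      tile_cov[as.integer(names(cv))] <- as.numeric(cv)
    }
    # a tile with any uncovered base includes value-0 bases in its max
    full <- pmin(stride, pmax(0, L - (seq_len(ntile) - 1L) * stride))
    partial <- tile_cov < full
    tile_max[partial] <- pmax(tile_max[partial], 0)
    csum <- c(0, cumsum(tile_max))
    idx <- which(grid$chrom == ch)
    first_tile <- grid$start[idx] %/% stride
    values[idx] <- (csum[first_tile + nseg + 1L] - csum[first_tile + 1L]) / nseg
  }
  new_window_track(grid, values)
}

#' Mark the top fraction of windows of a track as accessible
#'
#' Exactly `floor(fraction * N)` windows (N = total windows) are marked,
#' chosen by descending value; ties at the cut are broken by ascending
#' (chrom, start).  Missing values are never selected.
#'
#' @param track a `window_track`.
#' @param fraction fraction of windows to mark, in (0, 1); default 0.10.
#' @param stage stage label stored on the mask.
#' @return An `accessibility_mask` tibble (`chrom`, `start`, `end`,
#'   `accessible`) with attributes `stage` and `fraction`.
#' @export
top_fraction_mask <- function(track, fraction = 0.1, stage = NA_character_) {
  if (!(fraction > 0 && fraction < 1)) abort("fraction must be in (0, 1)")
  v <- track$value
  if (all(is.na(v))) abort("all track values are missing")
  N <- length(v)
  m <- floor(fraction * N)
  ord <- order(-v, track$chrom, track$start, na.last = TRUE)
  if (m > sum(!is.na(v))) {
    abort("not enough non-missing windows for the requested fraction")
  }
  accessible <- logical(N)
  if (m > 0) accessible[ord[seq_len(m)]] <- TRUE
  out <- tibble(chrom = track$chrom, start = track$start, end = track$end,
                accessible = accessible)
  attributes(out)[c("window_length", "stride", "chrom_sizes")] <-
    grid_meta(track)
  attr(out, "stage") <- stage
  attr(out, "fraction") <- fraction
  class(out) <- c("accessibility_mask", class(tibble()))
  out
}

#' Mask a window track, filling masked-out windows
#'
#' Values are unchanged where the mask is accessible and set to `fill`
#' (default 0) elsewhere, so that downstream max/mean aggregation stays
#' defined.
#'
#' @param track a `window_track`.
#' @param mask an [top_fraction_mask()] result on the same grid.
#' @param fill value assigned to masked-out windows.
#' @return A `window_track` on the same grid.
#' @export
apply_mask <- function(track, mask, fill = 0) {
  if (!same_grid(track, mask)) abort("track and mask are on different grids")
  v <- ifelse(mask$accessible, track$value, fill)
  out <- track
  out$value <- v
  out
}
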