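# Shared synthetic worlds and pipeline runs, cached across test files
# (files run in one process; heavy runs are reused).

world_cache <- new.env(parent = emptyenv())

small_config <- function(seed, ...) {
  defaults <- list(seed = seed, chrom_lengths = c(chrA = 150000L),
                   n_tfs = 8L, n_genes = 30L, n_domains = 6L,
                   enhancers_per_domain = 4L, n_species = 2L)
  do.call(world_config, utils::modifyList(defaults, list(...)))
}

get_small_world <- function(seed = 11L) {
  key <- paste0("small", seed)
  if (is.null(world_cache[[key]])) {
    world_cache[[key]] <- simulate_world(small_config(seed))
  }
  world_cache[[key]]
}

# full default-world pipeline run (the study conditions), cached by seed
get_default_run <- function(seed) {
  key <- paste0("run", seed)
  if (is.null(world_cache[[key]])) {
    w <- simulate_world(world_config(seed = seed))
    res <- run_pipeline(w$bundle, seed = seed)
    world_cache[[key]] <- list(world = w, result = res)
  }
  world_cache[[key]]
}

make_grid <- function(len = 1000, window = 500, stride = 50,
                      chrom = "chr1") {
  tile_genome(setNames(len, chrom), window, stride)
}

make_track <- function(grid, values) window_track(grid, values)

# a synthetic open-regions frame with the columns the enhancer-model
# stage expects (one stage label "5")
make_regions <- function(n, stage = "5", chrom = "chrA") {
  out <- tibble::tibble(
    region = sprintf("or%05d", seq_len(n)),
    window = seq_len(n),
    chrom = chrom,
    start = seq(0L, by = 1000L, length.out = n),
    end = seq(0L, by = 1000L, length.out = n) + 500L)
  out[[paste0("acc_", stage)]] <- runif(n, 1, 5)
  out[[paste0("open_", stage)]] <- TRUE
  out$max_motif <- runif(n)
  out$ref_overlap <- FALSE
  out$ref_domains <- rep(list(character(0)), n)
  out$gene1 <- NA_character_; out$dist1 <- NA_real_
  out$gene2 <- NA_character_; out$dist2 <- NA_real_
  out$domains <- rep(list(character(0)), n)
  attr(out, "stages") <- stage
  class(out) <- c("open_regions", class(tibble::tibble()))
  out
}
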