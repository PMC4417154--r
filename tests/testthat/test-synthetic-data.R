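# The synthetic-world generator, bundle round trips and recovery
# reporting.

test_that("world simulation is deterministic and honours the planting density", {
  cfg <- small_config(7L)
  w1 <- simulate_world(cfg)
  w2 <- simulate_world(cfg)
  expect_identical(w1$bundle$genome, w2$bundle$genome)
  expect_identical(w1$bundle$fpkm, w2$bundle$fpkm)
  expect_identical(w1$truth, w2$truth)
  w3 <- simulate_world(small_config(8L))
  expect_false(identical(w1$bundle$genome, w3$bundle$genome))
  # zero planting density -> no planted pairs, no sites
  w0 <- simulate_world(small_config(7L, planted_density = 0))
  expect_equal(nrow(w0$truth$planted_pairs), 0)
  expect_equal(nrow(w0$truth$sites), 0)
  expect_error(world_config(n_genes = 0), "positive")
  expect_error(world_config(mu = 1.5), "rates")
})

test_that("generated worlds satisfy their structural invariants", {
  w <- get_small_world(11L)
  b <- w$bundle
  # accessibility tracks strictly positive
  for (tr in b$acc_tracks) expect_true(all(tr$value > 0))
  # planted sites lie inside their enhancer
  s <- w$truth$sites
  e <- w$truth$enhancers[match(s$enhancer, w$truth$enhancers$enhancer), ]
  expect_true(all(s$start >= e$start & s$end <= e$end))
  # every planted enhancer's domain is annotated on its target gene
  gd <- b$atlas$gene_domain
  key <- paste(w$truth$enhancers$gene, w$truth$enhancers$domain)
  expect_true(all(key %in% paste(gd$gene, gd$domain)))
  # insulators never separate an enhancer from its target gene
  env <- tibble::tibble(
    chrom = w$truth$enhancers$chrom,
    start = pmin(w$truth$enhancers$start,
                 b$genes$start[match(w$truth$enhancers$gene, b$genes$gene)]),
    end = pmax(w$truth$enhancers$end,
               b$genes$end[match(w$truth$enhancers$gene, b$genes$gene)]))
  ov <- regmapr:::interval_overlaps(b$insulators, env)
  expect_equal(nrow(ov), 0)
  # species weights sum to one and include the reference
  expect_equal(sum(b$species_weights$weight), 1)
  expect_true("ref" %in% b$species_weights$species)
})

test_that("with perfect conservation multi-species scores equal single-species scores", {
  cfg <- small_config(9L, mu = 0, rho = 1, missing_rate = 0)
  w <- simulate_world(cfg)
  b <- w$bundle
  grid <- tile_genome(b$chrom_sizes, cfg$window_length, cfg$stride)
  bg <- train_background(b$genome, order = 1)
  pwm <- b$pwms[[1]]
  enh_ov <- regmapr:::interval_overlaps(w$truth$enhancers, grid)
  idx <- sort(unique(enh_ov$subject))[1:10]
  omap <- bundle_orthology_map(b, grid, windows = idx)
  multi <- score_genome_multispecies(b$genome, omap, pwm, grid, bg,
                                     windows = idx)
  single <- score_genome(b$genome, pwm, grid, bg, windows = idx)
  expect_equal(multi$value[idx], single$value[idx], tolerance = 1e-9)
})

test_that("bundles survive a disk round trip through their standard formats", {
  w <- get_small_world(11L)
  dir <- withr::local_tempdir()
  expect_no_warning(write_bundle(w, dir))
  expect_no_warning(rt <- read_bundle(dir))
  b <- w$bundle
  expect_equal(rt$genome, b$genome)
  expect_equal(rt$chrom_sizes, b$chrom_sizes)
  expect_equal(names(rt$pwms), names(b$pwms))
  for (m in names(b$pwms)) {
    expect_equal(rt$pwms[[m]]$mat, b$pwms[[m]]$mat, tolerance = 1e-5)
  }
  expect_equal(as.data.frame(rt$genes), as.data.frame(b$genes))
  expect_equal(dplyr::arrange(rt$atlas$gene_domain, gene, domain),
               dplyr::arrange(b$atlas$gene_domain, gene, domain))
  expect_equal(rt$fpkm, b$fpkm, tolerance = 1e-9)
  expect_equal(names(rt$acc_tracks), names(b$acc_tracks))
  expect_equal(rt$acc_tracks[["5"]]$value, b$acc_tracks[["5"]]$value,
               tolerance = 1e-6)
  expect_equal(names(rt$chip_tracks), names(b$chip_tracks))
  expect_equal(as.data.frame(rt$insulators), as.data.frame(b$insulators))
  expect_equal(rt$species_weights, b$species_weights, tolerance = 1e-9)
  expect_setequal(names(rt$ortholog_segments),
                  setdiff(b$species_weights$species, "ref"))
  # ground truth and manifest round-trip
  gt <- read_ground_truth(dir)
  expect_equal(as.data.frame(gt$planted_pairs),
               as.data.frame(w$truth$planted_pairs))
  expect_equal(as.data.frame(gt$enhancers),
               as.data.frame(w$truth$enhancers))
  expect_equal(rt$config$seed, b$config$seed)
  expect_equal(rt$config$chrom_lengths, b$config$chrom_lengths)
  expect_equal(rt$config$stage_map, b$config$stage_map)
  # the re-read bundle drives the pipeline end to end
  res <- run_pipeline(rt, seed = 3, train_models = FALSE)
  expect_s3_class(res$associations, "association_results")
})

test_that("recovery reporting scores perfect and shuffled predictions correctly", {
  truth <- list(
    planted_pairs = tibble::tibble(tf = c("t1", "t2"),
                                   domain = c("d1", "d2")),
    enhancers = tibble::tibble(enhancer = c("e1", "e2"),
                               chrom = "chrA",
                               start = c(0L, 1000L), end = c(500L, 1500L),
                               domain = c("d1", "d2"),
                               gene = c("g1", "g2")))
  regions <- make_regions(2, chrom = "chrA")
  result <- list(
    associations = tibble::tibble(
      tf = rep(c("t1", "t2"), each = 2),
      domain = rep(c("d1", "d2"), 2),
      S = c(9, 0, 0, 9)),
    open_regions = regions,
    assignments = tibble::tibble(region = regions$region,
                                 domain = c("d1", "d2"),
                                 score = c(1, 1),
                                 percentile = c(0.99, 0.99)),
    rank_stats = list(stats = tibble::tibble(
      region = regions$region, k = c(3, 3), rank_true = c(1, 1),
      statistic = c(1, 1)), n_excluded = 0L))
  rep <- recovery_report(result, truth)
  expect_equal(rep$association_auroc, 1)
  expect_equal(rep$enhancer_domain_recovery, 1)
  expect_equal(rep$mean_rank_statistic, 1)
  expect_equal(rep$frac_rank_one, 1)
  # anti-correlated association scores score 0
  result$associations$S <- c(0, 9, 9, 0)
  expect_equal(recovery_report(result, truth)$association_auroc, 0)
})

test_that("planted enhancers are accessible in their active stage in the default worlds", {
  hits <- unlist(lapply(c(101L, 102L), function(s) {
    run <- get_default_run(s)
    b <- run$world$bundle
    truth <- run$world$truth
    masks <- run$result$masks
    stage_of <- setNames(b$config$stage_map[
      b$atlas$domain_stage$stage], b$atlas$domain_stage$domain)
    vapply(seq_len(nrow(truth$enhancers)), function(i) {
      e <- truth$enhancers[i, ]
      m <- masks[[stage_of[[e$domain]]]]
      idx <- which(m$chrom == e$chrom & m$start < e$end & m$end > e$start)
      any(m$accessible[idx])
    }, logical(1))
  }))
  expect_gte(mean(hits), 0.95)
})
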