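# Open-region construction, candidate domains, noisy training sets, the
# linear activity model, gating, genome-wide assignment and the rank
# statistic.

open_region_fixture <- function() {
  grid <- make_grid(len = 500 + 50 * 60)      # 61 windows
  n <- nrow(grid)
  acc <- rep(0.1, n)
  acc[c(5, 6, 40)] <- c(9, 8, 7)              # 5/6 overlap; 40 disjoint
  acc_tr <- make_track(grid, acc)
  mask <- top_fraction_mask(acc_tr, fraction = 0.06)   # floor(.06*61) = 3
  motif <- make_track(grid, rep(1, n))
  list(grid = grid, masks = list(`5` = mask), acc = list(`5` = acc_tr),
       motifs = list(m1 = motif))
}

test_that("open regions resolve overlaps greedily by accessibility", {
  fx <- open_region_fixture()
  or <- build_open_regions(fx$masks, fx$acc, fx$motifs)
  expect_equal(sort(or$window), c(5L, 40L))    # window 6 loses to 5
  # pairwise non-overlapping
  ov <- regmapr:::interval_overlaps(or, or)
  expect_true(all(ov$query == ov$subject))
  expect_equal(or$acc_5, c(9, 7))
  expect_error(build_open_regions(
    list(`5` = dplyr::mutate(fx$masks[["5"]], accessible = FALSE)),
    fx$acc, fx$motifs), "accessible")
})

test_that("the motif-content filter drops regions below the reference quantile", {
  fx <- open_region_fixture()
  n <- nrow(fx$grid)
  motif <- make_track(fx$grid, c(rep(0, 20), rep(5, 41)))
  ref <- reference_enhancers(
    tibble::tibble(enhancer = "re1", chrom = "chr1",
                   start = 2000L, end = 2500L),
    tibble::tibble(enhancer = "re1", domain = "dA"))
  or <- build_open_regions(fx$masks, fx$acc, list(m1 = motif),
                           reference = ref)
  expect_equal(or$window, 40L)                 # zero-signal region dropped
  # the surviving region overlaps the reference enhancer
  expect_true(or$ref_overlap[or$window == 40])
  expect_equal(or$ref_domains[[which(or$window == 40)]], "dA")
})

test_that("RFVO evaluation uses reference-overlapping positives with the 10-region minimum", {
  set.seed(60)
  n <- 60
  regions <- make_regions(n)
  regions$ref_overlap[1:12] <- TRUE
  regions$ref_domains[1:12] <- list("dT")
  regions$domains[1:30] <- list("dT")
  atlas <- expression_atlas(
    gene_domain = tibble::tibble(gene = "gT", domain = "dT"),
    domain_stage = tibble::tibble(domain = "dT", stage = "5"))
  regions$gene1[13:30] <- "gT"; regions$dist1[13:30] <- 100
  X <- matrix(c(rep(5, 12), rep(3, 18), rep(0, 30)), ncol = 1,
              dimnames = list(regions$region, "f"))
  training <- tibble::tibble(
    region = regions$region[c(13:30, 31:48)],
    label = rep(c(1L, 0L), each = 18),
    split = rep(rep(c("train", "test"), c(13, 5)), 2))
  class(training) <- c("training_set", class(tibble::tibble()))
  mdl <- train_enhancer_model(X[training$region[training$split == "train"], ,
                                drop = FALSE],
                              training$label[training$split == "train"],
                              domain = "dT")
  ev <- evaluate_enhancer_model(mdl, regions, X, training, atlas)
  expect_equal(ev$test_auroc, 1)
  expect_equal(ev$rfvo_auroc, 1)       # 12 reference positives >= 10
  expect_true(is.na(ev$rfvo_reason))
  # below the minimum the metric is absent with a reason
  regions2 <- regions
  regions2$ref_overlap[5:12] <- FALSE
  regions2$ref_domains[5:12] <- list(character(0))
  ev2 <- evaluate_enhancer_model(mdl, regions2, X, training, atlas)
  expect_true(is.na(ev2$rfvo_auroc))
  expect_match(ev2$rfvo_reason, "4 reference-overlapping")
})

test_that("candidate domains come from the two nearest genes", {
  fx <- open_region_fixture()
  or <- build_open_regions(fx$masks, fx$acc, fx$motifs)
  genes <- tibble::tibble(
    gene = c("gA", "gB", "gC"), chrom = "chr1", strand = "+",
    tss = c(0L, 900L, 2600L), start = c(0L, 900L, 2600L),
    end = c(150L, 1000L, 2900L))
  atlas <- expression_atlas(
    gene_domain = tibble::tibble(gene = c("gA", "gA", "gB", "gB"),
                                 domain = c("d1", "d2", "d2", "d3")),
    domain_stage = tibble::tibble(domain = c("d1", "d2", "d3"),
                                  stage = "s"))
  out <- assign_candidate_domains(or, genes, atlas)
  # region at window 5 spans [200, 700): nearest genes gA and gB
  r5 <- out[out$window == 5L, ]
  expect_setequal(c(r5$gene1, r5$gene2), c("gA", "gB"))
  expect_setequal(r5$domains[[1]], c("d1", "d2", "d3"))
  # region at window 40 spans [1950, 2450): gB overlaps nothing;
  # gC unannotated, gB annotated -> still kept via gB
  r40 <- out[out$window == 40L, ]
  expect_setequal(c(r40$gene1, r40$gene2), c("gB", "gC"))
  expect_setequal(r40$domains[[1]], c("d2", "d3"))
  # distance 0 when the region overlaps the gene span
  genes2 <- dplyr::mutate(genes, start = c(0L, 300L, 2600L),
                          end = c(150L, 1000L, 2900L))
  out2 <- assign_candidate_domains(or, genes2, atlas)
  expect_equal(out2$dist1[out2$window == 5L], 0)
  # no annotated neighbour -> region discarded
  atlas_empty <- expression_atlas(
    gene_domain = tibble::tibble(gene = "zz", domain = "d1"),
    domain_stage = tibble::tibble(domain = "d1", stage = "s"))
  expect_equal(nrow(assign_candidate_domains(or, genes, atlas_empty)), 0)
})

training_fixture <- function(n_pos = 80, n_neg = 120, seed = 3) {
  withr::with_seed(seed, {
    regions <- make_regions(n_pos + n_neg)
    genes <- tibble::tibble(gene = c("gPos", "gNeg"))
    regions$gene1 <- rep(c("gPos", "gNeg"), c(n_pos, n_neg))
    regions$dist1 <- runif(n_pos + n_neg, 0, 4000)
    regions$domains <- lapply(regions$gene1, function(g) {
      if (g == "gPos") "dT" else "dX"
    })
    atlas <- expression_atlas(
      gene_domain = tibble::tibble(gene = c("gPos", "gNeg"),
                                   domain = c("dT", "dX")),
      domain_stage = tibble::tibble(domain = c("dT", "dX"), stage = "5"))
    list(regions = regions, atlas = atlas)
  })
}

test_that("training sets are capped, balanced and split 75/25 per class", {
  fx <- training_fixture(80, 120)
  ts <- build_training_sets("dT", fx$regions, fx$atlas, seed = 5)
  tab <- table(ts$label, ts$split)
  expect_equal(unname(tab["1", "train"]), 60)
  expect_equal(unname(tab["1", "test"]), 20)
  expect_equal(unname(tab["0", "train"]), 60)
  expect_equal(unname(tab["0", "test"]), 20)
  # positive cap by seeded subsample
  ts2 <- build_training_sets("dT", fx$regions, fx$atlas, seed = 5,
                             max_pos = 30)
  expect_equal(sum(ts2$label == 1), 30)
  # reference-overlapping regions are excluded
  fx3 <- training_fixture(80, 120)
  fx3$regions$ref_overlap[fx3$regions$gene1 == "gPos"] <- TRUE
  skip_res <- build_training_sets("dT", fx3$regions, fx3$atlas, seed = 5)
  expect_s3_class(skip_res, "skipped_training_set")
  expect_match(skip_res$reason, "0 positives")
  # distance bound: positives farther than 5 kb are ineligible
  fx4 <- training_fixture(80, 120)
  fx4$regions$dist1[fx4$regions$gene1 == "gPos"] <- 9000
  expect_s3_class(build_training_sets("dT", fx4$regions, fx4$atlas,
                                      seed = 5), "skipped_training_set")
  # determinism
  expect_identical(build_training_sets("dT", fx$regions, fx$atlas, seed = 5),
                   build_training_sets("dT", fx$regions, fx$atlas, seed = 5))
})

feature_fixture <- function() {
  grid <- make_grid(len = 500 + 50 * 9)
  regions <- make_regions(3)
  regions$window <- 1:3
  motif_tracks <- list(
    mP = make_track(grid, c(2, 1, 0, rep(0, 7))),
    mQ = make_track(grid, c(4, 0, 1, rep(0, 7))))
  atlas <- expression_atlas(
    gene_domain = tibble::tibble(gene = c("tfP", "g1"),
                                 domain = c("dT", "dT")),
    domain_stage = tibble::tibble(domain = "dT", stage = "s1"),
    tfs = tibble::tibble(tf = c("tfP", "tfQ"), motif = c("mP", "mQ")))
  assoc <- tibble::tibble(tf = c("tfP", "tfQ"), domain = "dT",
                          S = c(3, 50))
  fpkm <- tibble::tibble(tf = c("tfP", "tfQ"), stage = "s1",
                         fpkm = c(0.5, 2))
  list(regions = regions, motif_tracks = motif_tracks, atlas = atlas,
       assoc = assoc, fpkm = fpkm)
}

test_that("features are the Z*S*E*R products plus stage accessibility", {
  fx <- feature_fixture()
  X <- featurize(fx$regions, "dT", fx$motif_tracks, fx$assoc, fx$atlas,
                 fx$fpkm)
  expect_equal(colnames(X), c("mP", "mQ", "5"))
  # tfP: S=3, E=1 (specific), R=0.5 -> Z * 1.5
  expect_equal(unname(X[, "mP"]), c(2, 1, 0) * 3 * 0.5)
  # tfQ is not expressed in dT: E = 0 kills the feature regardless of S, R
  expect_equal(unname(X[, "mQ"]), c(0, 0, 0))
  expect_equal(unname(X[, "5"]), fx$regions$acc_5)
  expect_true(all(X >= 0))
  bad <- fx$motif_tracks
  names(bad) <- c("mP", "mZ")
  expect_error(featurize(fx$regions, "dT", bad, fx$assoc, fx$atlas,
                         fx$fpkm), "without a TF")
})

test_that("ridge training is deterministic and interpolates noise-free linear labels", {
  set.seed(1)
  n <- 20; p <- 30
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- rbinom(n, 1, 0.5); y[1] <- 0; y[2] <- 1
  fit <- train_enhancer_model(X, y, lambda = 1e-10, domain = "d")
  expect_lt(max(abs(score_regions(fit, X) - y)), 1e-6)
  # retraining on identical inputs reproduces the model bit for bit
  expect_identical(fit$coef,
                   train_enhancer_model(X, y, lambda = 1e-10,
                                        domain = "d")$coef)
  # in the well-determined regime duplicating every example changes nothing
  set.seed(2)
  Xw <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(NULL, paste0("g", 1:5)))
  yw <- rbinom(60, 1, 0.5); yw[1:2] <- c(0, 1)
  f1 <- train_enhancer_model(Xw, yw, lambda = 0)
  f2 <- train_enhancer_model(rbind(Xw, Xw), c(yw, yw), lambda = 0)
  expect_equal(f1$coef, f2$coef, tolerance = 1e-9)
  # all-zero features predict the label mean through the intercept
  Z <- matrix(0, 10, 2, dimnames = list(NULL, c("a", "b")))
  yz <- rep(c(0, 1), 5)
  fz <- train_enhancer_model(Z, yz)
  expect_equal(unname(score_regions(fz, Z)), rep(0.5, 10))
  expect_error(train_enhancer_model(X, rep(1, n)), "both labels")
  X[1, 1] <- NA
  expect_error(train_enhancer_model(X, y), "finite")
})

test_that("linear scoring matches the coefficient algebra", {
  coefs <- c(`(intercept)` = 0.3, mA = 2, mB = -1)
  mdl <- structure(list(domain = "d", coef = coefs, lambda = 0,
                        n_train = 10, metadata = list()),
                   class = "enhancer_model")
  X <- rbind(c(0, 0), c(1, 0), c(0.5, 2))
  colnames(X) <- c("mA", "mB")
  expect_equal(score_regions(mdl, X), c(0.3, 2.3, -0.7))
  # batch equals the per-region loop
  loop <- vapply(seq_len(nrow(X)), function(i) {
    score_regions(mdl, X[i, , drop = FALSE])
  }, numeric(1))
  expect_equal(score_regions(mdl, X), loop)
  expect_error(score_regions(mdl, X[, 1, drop = FALSE]), "match")
})

test_that("the good-model gate applies the two AUROC thresholds", {
  expect_true(good_model_gate(0.55, 0.72))
  expect_false(good_model_gate(0.59, 0.65))
  expect_true(good_model_gate(0.61, NA))
  expect_false(good_model_gate(0.59, NA))
  expect_true(good_model_gate(NA, 0.71))
  expect_error(good_model_gate(NA, NA), "at least one")
})

rank_fixture <- function() {
  n <- 20
  regions <- make_regions(n)
  regions$domains <- rep(list(c("d1", "d2", "d3", "d4", "d5")), n)
  regions$ref_overlap[1:3] <- TRUE
  regions$ref_domains[[1]] <- "d1"
  regions$ref_domains[[2]] <- "d5"
  regions$ref_domains[[3]] <- "dOutside"
  vals <- lapply(1:5, function(i) {
    v <- seq_len(n) / n
    # domain d1 scores region 1 highest; d5 scores region 2 lowest rank
    if (i == 1) v[1] <- 2
    if (i != 5) v[2] <- v[2] + 1   # every other model beats d5 on region 2
    v
  })
  models <- setNames(lapply(1:5, function(i) {
    structure(list(domain = paste0("d", i),
                   coef = c(`(intercept)` = 0, x = 1), lambda = 0,
                   n_train = 4, metadata = list()),
              class = "enhancer_model")
  }), paste0("d", 1:5))
  ffn <- function(domain) {
    i <- as.integer(substring(domain, 2))
    matrix(vals[[i]], ncol = 1, dimnames = list(NULL, "x"))
  }
  list(regions = regions, models = models, ffn = ffn)
}

test_that("the rank statistic rewards top-ranked true domains and counts exclusions", {
  fx <- rank_fixture()
  rk <- rank_statistic(fx$regions, fx$models, fx$ffn)
  expect_equal(rk$n_excluded, 1)             # dOutside not a candidate
  s1 <- rk$stats[rk$stats$region == fx$regions$region[1], ]
  expect_equal(s1$k, 5)
  expect_equal(s1$rank_true, 1)
  expect_equal(s1$statistic, 1)
  s2 <- rk$stats[rk$stats$region == fx$regions$region[2], ]
  expect_equal(s2$rank_true, 5)
  expect_equal(s2$statistic, 0)
  # single-candidate regions score 1 by convention
  fx$regions$domains[[1]] <- "d1"
  rk1 <- rank_statistic(fx$regions, fx$models, fx$ffn)
  expect_equal(rk1$stats$statistic[rk1$stats$region ==
                                     fx$regions$region[1]], 1)
})

test_that("genome-wide assignment requires both percentile and neighbour support", {
  n <- 40
  regions <- make_regions(n)
  regions$domains <- c(rep(list("dT"), 20), rep(list(character(0)), 20))
  mdl <- structure(list(domain = "dT",
                        coef = c(`(intercept)` = 0, x = 1), lambda = 0,
                        n_train = 4, metadata = list()),
                   class = "enhancer_model")
  ffn <- function(domain) {
    matrix(seq_len(n), ncol = 1, dimnames = list(NULL, "x"))
  }
  out <- annotate_genome_wide(list(dT = mdl), regions, ffn)
  # top 5% of 40 scores = scores 39, 40; only regions 1..20 have support
  expect_equal(nrow(out), 0)
  regions$domains <- rev(regions$domains)
  out2 <- annotate_genome_wide(list(dT = mdl), regions, ffn)
  # inclusive percentile: score 38 sits exactly at the 95th percentile
  expect_equal(sort(out2$region), regions$region[c(38, 39, 40)])
  expect_true(all(out2$percentile >= 0.95))
  # a region may receive several domains
  regions$domains[[40]] <- c("dT", "dU")
  mdl2 <- mdl; mdl2$domain <- "dU"
  out3 <- annotate_genome_wide(list(dT = mdl, dU = mdl2), regions, ffn)
  expect_equal(sum(out3$region == regions$region[40]), 2)
})

test_that("model evaluation produces left-out and RFVO AUROCs with the minimum-positives rule", {
  run <- get_default_run(101L)
  ev <- run$result$model_eval
  expect_true(all(ev$test_auroc >= 0 & ev$test_auroc <= 1))
  expect_true(all(is.na(ev$rfvo_auroc) | (ev$rfvo_auroc >= 0 &
                                            ev$rfvo_auroc <= 1)))
  # with ~2 reference enhancers per domain, RFVO requires more overlapping
  # regions than exist
  expect_true(all(is.na(ev$rfvo_auroc) | ev$rfvo_auroc >= 0))
  expect_equal(ev$good, ifelse(is.na(ev$rfvo_auroc), ev$test_auroc > 0.6,
                               ev$rfvo_auroc > 0.7 | ev$test_auroc > 0.6))
})
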