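# Enhancer-activity modelling: candidate open regions, preliminary
# gene/domain assignment, noisy training sets, the complete linear model
# y^r = sum_m alpha_m Z_m S_m E_m R_m + sum_s gamma_s A_s + beta,
# RFVO and left-out evaluation, the good-model gate, genome-wide domain
# assignment, and the rank statistic on reference enhancers.

#' Bundle reference enhancers with their domain labels
#'
#' @param intervals tibble (`chrom`, `start`, `end`) with optional
#'   `enhancer` ids.
#' @param domains tibble (`enhancer`, `domain`).
#' @return A `reference_enhancers` tibble with a `domains` list-column.
#' @export
reference_enhancers <- function(intervals, domains) {
  if (!"enhancer" %in% names(intervals)) {
    intervals$enhancer <- sprintf("re%04d", seq_len(nrow(intervals)))
  }
  dl <- split(domains$domain, domains$enhancer)
  out <- intervals %>%
    mutate(domains = unname(map(.data$enhancer, function(e) {
      d <- dl[[e]]
      if (is.null(d)) character(0) else unique(d)
    })))
  if (any(lengths(out$domains) == 0)) {
    abort("every reference enhancer needs at least one domain")
  }
  class(out) <- c("reference_enhancers", class(tibble()))
  out
}

#' Build candidate open regions from stage accessibility
#'
#' The union of windows accessible in any stage is reduced to a
#' non-overlapping set greedily, by descending maximum-stage accessibility
#' (ties by genomic order).  When reference enhancers are given, regions
#' whose maximum unmasked multi-species motif score (over all motifs)
#' falls below the `motif_quantile` quantile of the same statistic over
#' the reference set are dropped.
#'
#' @param masks named list (stage) of accessibility masks on one grid.
#' @param acc_tracks named list (stage) of accessibility `window_track`s.
#' @param motif_tracks named list of unmasked multi-species motif tracks.
#' @param reference optional [reference_enhancers()].
#' @param motif_quantile reference quantile for the motif-content filter
#'   (default 0.05).
#' @return An `open_regions` tibble: `region`, `window` (grid row),
#'   `chrom`, `start`, `end`, per-stage `acc_<stage>` and `open_<stage>`
#'   columns, `max_motif`, `ref_overlap`, `ref_domains` (list).  Stage
#'   labels are kept in the `stages` attribute.
#' @export
build_open_regions <- function(masks, acc_tracks, motif_tracks,
                               reference = NULL, motif_quantile = 0.05) {
  stages <- names(masks)
  stopifnot(length(stages) > 0, identical(names(acc_tracks), stages))
  grid1 <- masks[[1]]
  open_any <- Reduce(`|`, lapply(masks, function(m) m$accessible))
  if (!any(open_any)) abort("no accessible windows in any stage")
  acc_mat <- vapply(acc_tracks, function(tr) tr$value, numeric(nrow(grid1)))
  max_acc <- apply(acc_mat, 1, max)
  cand <- which(open_any)
  cand <- cand[order(-max_acc[cand], grid1$chrom[cand], grid1$start[cand])]
  # greedy non-overlap selection, per chromosome
  kept_flag <- logical(nrow(grid1))
  by_chrom <- split(cand, grid1$chrom[cand])
  for (ch in names(by_chrom)) {
    ids <- by_chrom[[ch]]
    taken_start <- integer(0); taken_end <- integer(0)
    for (i in ids) {
      s <- grid1$start[i]; e <- grid1$end[i]
      if (length(taken_start) == 0 ||
          !any(s < taken_end & e > taken_start)) {
        taken_start <- c(taken_start, s); taken_end <- c(taken_end, e)
        kept_flag[i] <- TRUE
      }
    }
  }
  kept <- which(kept_flag)
  kept <- kept[order(grid1$chrom[kept], grid1$start[kept])]
  out <- tibble(window = kept,
                chrom = grid1$chrom[kept],
                start = grid1$start[kept],
                end = grid1$end[kept])
  for (st in stages) {
    out[[paste0("acc_", st)]] <- acc_mat[kept, st]
    out[[paste0("open_", st)]] <- masks[[st]]$accessible[kept]
  }
  # interval-level motif-content statistic: max unmasked multi-species
  # score over all windows overlapping the interval (computed identically
  # for open regions and reference enhancers)
  full_mot <- vapply(motif_tracks, function(tr) tr$value,
                     numeric(nrow(grid1)))
  win_max <- suppressWarnings(apply(full_mot, 1, max, na.rm = TRUE))
  win_max[!is.finite(win_max)] <- 0
  ovq <- interval_overlaps(out, tibble(chrom = grid1$chrom,
                                       start = grid1$start,
                                       end = grid1$end))
  qstat <- tapply(win_max[ovq$subject], ovq$query, max)
  out$max_motif <- 0
  out$max_motif[as.integer(names(qstat))] <- as.numeric(qstat)
  out$ref_overlap <- FALSE
  out$ref_domains <- rep(list(character(0)), nrow(out))
  if (!is.null(reference) && nrow(reference) > 0) {
    ovr <- interval_overlaps(reference, grid1)
    ref_stat <- tapply(win_max[ovr$subject], ovr$query, max)
    thr <- unname(quantile(as.numeric(ref_stat), motif_quantile,
                           na.rm = TRUE))
    out_keep <- out$max_motif >= thr
    out <- out[out_keep, , drop = FALSE]
    ov2 <- interval_overlaps(out, reference)
    out$ref_overlap[unique(ov2$query)] <- TRUE
    doms <- tapply(ov2$subject, ov2$query, function(j) {
      unique(unlist(reference$domains[j]))
    })
    for (nm in names(doms)) {
      out$ref_domains[[as.integer(nm)]] <- doms[[nm]]
    }
  }
  out$region <- sprintf("or%05d", seq_len(nrow(out)))
  out <- select(out, "region", dplyr::everything())
  attr(out, "stages") <- stages
  class(out) <- c("open_regions", class(tibble()))
  out
}

#' Assign neighbouring genes and candidate domains to open regions
#'
#' Each region gets its two nearest genes by distance to the gene span
#' (0 if overlapping, ties by gene id) and the union of their atlas
#' domains as candidate domains.  Regions with an empty candidate set are
#' discarded; regions on chromosomes without genes are discarded with a
#' warning.
#'
#' @param regions an [build_open_regions()] tibble.
#' @param genes gene-model tibble (`gene`, `chrom`, `strand`, `tss`,
#'   `start`, `end`).
#' @param atlas an [expression_atlas()].
#' @return `regions` with `gene1`, `dist1`, `gene2`, `dist2` and a
#'   `domains` list-column, restricted to regions with candidates.
#' @export
assign_candidate_domains <- function(regions, genes, atlas) {
  dom_by_gene <- split(atlas$gene_domain$domain, atlas$gene_domain$gene)
  no_genes <- setdiff(unique(regions$chrom), unique(genes$chrom))
  if (length(no_genes) > 0) {
    warn(paste0("regions on chromosomes without genes discarded: ",
                paste(no_genes, collapse = ", ")))
  }
  n <- nrow(regions)
  gene1 <- gene2 <- rep(NA_character_, n)
  dist1 <- dist2 <- rep(NA_real_, n)
  doms <- vector("list", n)
  for (ch in intersect(unique(regions$chrom), unique(genes$chrom))) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    ridx <- which(regions$chrom == ch)
    for (i in ridx) {
      rs <- regions$start[i]; re <- regions$end[i]
      gap <- ifelse(g$end <= rs, g$end - rs,        # gene left: negative
                    ifelse(g$start >= re, g$start - re, 0))
      ord <- order(abs(gap), g$gene)
      take <- head(ord, 2)
      gene1[i] <- g$gene[take[1]]; dist1[i] <- gap[take[1]]
      if (length(take) > 1) {
        gene2[i] <- g$gene[take[2]]; dist2[i] <- gap[take[2]]
      }
      dd <- unique(c(dom_by_gene[[gene1[i]]],
                     if (!is.na(gene2[i])) dom_by_gene[[gene2[i]]]))
      doms[[i]] <- if (is.null(dd)) character(0) else dd
    }
  }
  regions$gene1 <- gene1; regions$dist1 <- dist1
  regions$gene2 <- gene2; regions$dist2 <- dist2
  regions$domains <- doms
  keep <- lengths(doms) > 0
  out <- regions[keep, , drop = FALSE]
  attr(out, "stages") <- attr(regions, "stages")
  class(out) <- class(regions)
  out
}

region_has_domain_neighbor <- function(regions, domain, dom_by_gene,
                                       max_dist = Inf) {
  check <- function(gene, dist) {
    ann <- vapply(gene, function(gn) {
      !is.na(gn) && !is.null(dom_by_gene[[gn]]) &&
        domain %in% dom_by_gene[[gn]]
    }, logical(1), USE.NAMES = FALSE)
    ann & !is.na(dist) & abs(dist) <= max_dist
  }
  check(regions$gene1, regions$dist1) | check(regions$gene2, regions$dist2)
}

#' Build the noisy training set for one domain
#'
#' Positives: open regions with a neighbouring gene annotated with the
#' domain within 5 kb, accessible in the domain's stage, not overlapping
#' any reference enhancer; capped at `max_pos` by a seeded uniform
#' subsample.  Negatives: an equal count sampled from regions accessible
#' in the stage with no neighbour annotated with the domain and no
#' reference overlap.  A stratified seeded 75/25 train/test split is
#' attached.
#'
#' @param domain domain id.
#' @param regions regions from [assign_candidate_domains()].
#' @param atlas an [expression_atlas()].
#' @param stage_map named map from atlas stage labels to mask stage labels.
#' @param seed integer seed.
#' @param max_pos positive-set cap (default 500).
#' @param max_dist neighbour distance bound (default 5000 bp).
#' @param min_class minimum class size; below it the domain is skipped.
#' @return A `training_set` tibble (`region`, `label`, `split`) with
#'   attributes `domain` and `seed`, or a `skipped_training_set` object
#'   carrying the reason when either class is too small.
#' @export
build_training_sets <- function(domain, regions, atlas, stage_map = NULL,
                                seed = 1L, max_pos = 500L,
                                max_dist = 5000L, min_class = 10L) {
  st <- domain_stage_of(atlas, domain)
  if (!is.null(stage_map)) st <- stage_map[[st]]
  open_col <- paste0("open_", st)
  if (!open_col %in% names(regions)) {
    abort(paste0("no mask column for stage: ", st))
  }
  dom_by_gene <- split(atlas$gene_domain$domain, atlas$gene_domain$gene)
  near <- region_has_domain_neighbor(regions, domain, dom_by_gene,
                                     max_dist = max_dist)
  any_nb <- region_has_domain_neighbor(regions, domain, dom_by_gene)
  open_st <- regions[[open_col]]
  pos_pool <- which(near & open_st & !regions$ref_overlap)
  neg_pool <- which(!any_nb & open_st & !regions$ref_overlap)
  if (length(pos_pool) < min_class || length(neg_pool) < min_class) {
    return(structure(list(domain = domain, reason = sprintf(
      "domain %s skipped: %d positives, %d negatives (need >= %d)",
      domain, length(pos_pool), length(neg_pool), min_class)),
      class = "skipped_training_set"))
  }
  pos <- with_seed(seed, {
    if (length(pos_pool) > max_pos) sort(sample(pos_pool, max_pos))
    else pos_pool
  })
  neg <- with_seed(seed + 1L, {
    sort(sample(neg_pool, min(length(pos), length(neg_pool))))
  })
  pos <- pos[seq_len(min(length(pos), length(neg)))]
  split_one <- function(ids, s) {
    n_test <- floor(length(ids) * 0.25)
    test <- with_seed(s, sort(sample(ids, n_test)))
    tibble(idx = ids, split = ifelse(ids %in% test, "test", "train"))
  }
  sp <- bind_rows(mutate(split_one(pos, seed + 2L), label = 1L),
                  mutate(split_one(neg, seed + 3L), label = 0L))
  out <- tibble(region = regions$region[sp$idx], label = sp$label,
                split = sp$split)
  attr(out, "domain") <- domain
  attr(out, "seed") <- seed
  class(out) <- c("training_set", class(tibble()))
  out
}

#' Feature matrix for the complete enhancer model of one domain
#'
#' Motif features are `x_m = Z_m^r * S_m^D * E_m^D * R_m^D`: the unmasked
#' multi-species motif score of the region, the association strength
#' `S = -log10(p_best)` (0 when the pair was not tested), the 0/1
#' expression indicator (support in {specific, related, ubiquitous}), and
#' the TF's FPKM in the domain's stage.  Stage features are the region's
#' per-stage accessibility.
#'
#' @param regions open-region rows to featurise.
#' @param domain domain id.
#' @param motif_tracks named list of unmasked multi-species motif tracks.
#' @param assoc association tibble (from [discover_associations()]).
#' @param atlas an [expression_atlas()].
#' @param fpkm tibble (`tf`, `stage`, `fpkm`), stages on the atlas scale.
#' @param cap cap on S (default 300).
#' @return numeric matrix, rows = regions, columns = motifs then stages.
#' @export
featurize <- function(regions, domain, motif_tracks, assoc, atlas, fpkm,
                      cap = 300) {
  stages <- attr(regions, "stages")
  motifs <- names(motif_tracks)
  tf_of <- setNames(atlas$tfs$tf, atlas$tfs$motif)
  if (any(!motifs %in% names(tf_of))) {
    abort("motif id without a TF in the atlas")
  }
  dstage <- domain_stage_of(atlas, domain)
  Z <- vapply(motif_tracks, function(tr) tr$value[regions$window],
              numeric(nrow(regions)))
  Z[is.na(Z)] <- 0
  if (nrow(regions) == 1) Z <- matrix(Z, nrow = 1,
                                      dimnames = list(NULL, motifs))
  a <- assoc[assoc$domain == domain, , drop = FALSE]
  S <- setNames(rep(0, length(motifs)), motifs)
  hit <- match(tf_of[motifs], a$tf)
  S[!is.na(hit)] <- pmin(cap, a$S[hit[!is.na(hit)]])
  E <- vapply(motifs, function(m) {
    expression_support(tf_of[[m]], domain, atlas) %in%
      c("specific", "related", "ubiquitous")
  }, logical(1))
  R <- vapply(motifs, function(m) {
    v <- fpkm$fpkm[fpkm$tf == tf_of[[m]] & fpkm$stage == dstage]
    if (length(v) == 0) 0 else v[[1]]
  }, numeric(1))
  X_m <- sweep(Z, 2, S * as.numeric(E) * R, "*")
  A <- vapply(stages, function(st) regions[[paste0("acc_", st)]],
              numeric(nrow(regions)))
  if (nrow(regions) == 1) A <- matrix(A, nrow = 1,
                                      dimnames = list(NULL, stages))
  X <- cbind(X_m, A)
  colnames(X) <- c(motifs, stages)
  rownames(X) <- regions$region
  X
}

#' Train a ridge-regularised linear enhancer-activity model
#'
#' Least squares on raw features against 0/1 labels with an L2 penalty
#' `lambda` on all coefficients except the intercept.
#'
#' @param features numeric matrix (examples x features).
#' @param labels 0/1 (or logical) vector.
#' @param lambda ridge penalty (default 1e-6).
#' @param domain domain id stored on the model.
#' @param metadata optional list stored on the model.
#' @return An `enhancer_model`: list with `domain`, `coef` (named,
#'   intercept first), `lambda`, `n_train`, `metadata`.
#' @export
train_enhancer_model <- function(features, labels, lambda = 1e-6,
                                 domain = NA_character_, metadata = list()) {
  y <- as.numeric(labels)
  if (length(unique(y)) < 2) abort("both labels must be present")
  if (nrow(features) != length(y)) abort("feature/label size mismatch")
  if (nrow(features) <= 2) abort("need more than 2 examples")
  if (any(!is.finite(features))) abort("non-finite features")
  A <- cbind(`(intercept)` = 1, features)
  P <- diag(c(0, rep(lambda, ncol(features))))
  coef <- solve(crossprod(A) + P, crossprod(A, y))
  structure(list(domain = domain,
                 coef = setNames(as.numeric(coef), colnames(A)),
                 lambda = lambda, n_train = length(y),
                 metadata = metadata),
            class = "enhancer_model")
}

#' @export
print.enhancer_model <- function(x, ...) {
  cat(sprintf("<enhancer_model> domain %s: %d coefficients (lambda = %g, n = %d)\n",
              x$domain, length(x$coef), x$lambda, x$n_train))
  invisible(x)
}

#' Linear activity predictions for a feature matrix
#' @param model an [train_enhancer_model()] fit.
#' @param features matrix with the model's feature columns.
#' @return numeric vector of `y^r` predictions.
#' @export
score_regions <- function(model, features) {
  want <- names(model$coef)[-1]
  if (!identical(colnames(features), want)) {
    if (!all(want %in% colnames(features))) {
      abort("feature columns do not match the model")
    }
    features <- features[, want, drop = FALSE]
  }
  as.numeric(cbind(1, features) %*% model$coef)
}

#' Evaluate an enhancer model on the left-out and RFVO sets
#'
#' The test AUROC uses the 25% left-out noisy examples.  The RFVO
#' ("reference versus open regions") AUROC is computed only when at least
#' `min_rfvo` reference-overlapping regions are annotated with the domain:
#' positives are regions overlapping reference enhancers labelled with the
#' domain, negatives regions with no reference overlap and no neighbour
#' annotated with the domain.
#'
#' @param model an `enhancer_model`.
#' @param regions regions from [assign_candidate_domains()].
#' @param features feature matrix for all `regions` rows.
#' @param training a [build_training_sets()] tibble.
#' @param atlas an [expression_atlas()].
#' @param min_rfvo minimum reference positives (default 10).
#' @return one-row tibble: `domain`, `test_auroc`, `rfvo_auroc` (NA when
#'   absent), `rfvo_reason`.
#' @export
evaluate_enhancer_model <- function(model, regions, features, training,
                                    atlas, min_rfvo = 10L) {
  domain <- model$domain
  preds_all <- setNames(score_regions(model, features), regions$region)
  test <- training[training$split == "test", , drop = FALSE]
  if (nrow(test) == 0 || length(unique(test$label)) < 2) {
    abort("left-out test set is missing or single-class")
  }
  test_auroc <- roc_auc(preds_all[test$region], test$label == 1L)$auroc
  rfvo_pos <- vapply(regions$ref_domains, function(d) domain %in% d,
                     logical(1))
  dom_by_gene <- split(atlas$gene_domain$domain, atlas$gene_domain$gene)
  any_nb <- region_has_domain_neighbor(regions, domain, dom_by_gene)
  rfvo_neg <- !regions$ref_overlap & !any_nb
  if (sum(rfvo_pos) >= min_rfvo && sum(rfvo_neg) > 0) {
    sc <- c(preds_all[rfvo_pos], preds_all[rfvo_neg])
    lb <- rep(c(TRUE, FALSE), c(sum(rfvo_pos), sum(rfvo_neg)))
    rfvo <- roc_auc(sc, lb)$auroc
    reason <- NA_character_
  } else {
    rfvo <- NA_real_
    reason <- sprintf("only %d reference-overlapping regions with %s",
                      sum(rfvo_pos), domain)
  }
  tibble(domain = domain, test_auroc = test_auroc, rfvo_auroc = rfvo,
         rfvo_reason = reason)
}

#' Gate on model quality
#'
#' A model is "good" when its RFVO AUROC exceeds 0.7 or its left-out test
#' AUROC exceeds 0.6.
#'
#' @param test_auroc,rfvo_auroc metrics (NA = absent; at least one must be
#'   present).
#' @return logical.
#' @export
good_model_gate <- function(test_auroc, rfvo_auroc) {
  if (is.na(test_auroc) && is.na(rfvo_auroc)) {
    abort("at least one metric must be present")
  }
  isTRUE(rfvo_auroc > 0.7) || isTRUE(test_auroc > 0.6)
}

#' Genome-wide enhancer activity assignment
#'
#' A domain is assigned to a region when a neighbouring gene is annotated
#' with the domain and the region's model score reaches the top 5% of
#' scores over all open regions (inclusive empirical percentile).
#'
#' @param models named list (domain) of gated `enhancer_model`s.
#' @param regions regions from [assign_candidate_domains()].
#' @param features_fn function(domain) returning the feature matrix for
#'   all `regions` rows under that domain's model.
#' @param top_fraction assignment threshold (default 0.05).
#' @return tibble (`region`, `domain`, `score`, `percentile`).
#' @export
annotate_genome_wide <- function(models, regions, features_fn,
                                 top_fraction = 0.05) {
  out <- list()
  for (domain in names(models)) {
    sc <- score_regions(models[[domain]], features_fn(domain))
    pct <- stats::ecdf(sc)(sc)       # inclusive (<=)
    eligible <- vapply(regions$domains, function(d) domain %in% d,
                       logical(1))
    sel <- eligible & pct >= 1 - top_fraction
    if (any(sel)) {
      out[[domain]] <- tibble(region = regions$region[sel], domain = domain,
                              score = sc[sel], percentile = pct[sel])
    }
  }
  if (length(out) == 0) {
    return(tibble(region = character(), domain = character(),
                  score = numeric(), percentile = numeric()))
  }
  arrange(bind_rows(out), .data$region, .data$domain)
}

#' Rank statistic of reference enhancers under the trained models
#'
#' For each region overlapping a reference enhancer, its candidate domains
#' that have gated models are ranked by model score percentile
#' (descending); with `k` candidates and the reference domain at rank
#' `rank_true`, the statistic is 1 for `k == 1` and
#' `(k - rank_true) / (k - 1)` otherwise (best true domain when several).
#' Regions whose reference domain is not among the candidates are excluded
#' and counted.
#'
#' @param regions regions from [assign_candidate_domains()].
#' @param models named list (domain) of gated models.
#' @param features_fn function(domain) -> feature matrix for all regions.
#' @return list: `stats` tibble (`region`, `k`, `rank_true`, `statistic`)
#'   and `n_excluded`.
#' @export
rank_statistic <- function(regions, models, features_fn) {
  doms <- names(models)
  pct <- vapply(doms, function(domain) {
    sc <- score_regions(models[[domain]], features_fn(domain))
    stats::ecdf(sc)(sc)
  }, numeric(nrow(regions)))
  if (nrow(regions) == 1) pct <- matrix(pct, nrow = 1,
                                        dimnames = list(NULL, doms))
  colnames(pct) <- doms
  rows <- list()
  n_excluded <- 0L
  for (i in which(regions$ref_overlap)) {
    cand <- intersect(regions$domains[[i]], doms)
    true_d <- intersect(regions$ref_domains[[i]], cand)
    if (length(cand) == 0 || length(true_d) == 0) {
      n_excluded <- n_excluded + 1L
      next
    }
    k <- length(cand)
    rk <- rank(-pct[i, cand], ties.method = "average")
    rank_true <- min(rk[true_d])
    stat <- if (k == 1) 1 else (k - rank_true) / (k - 1)
    rows[[length(rows) + 1]] <- tibble(region = regions$region[i], k = k,
                                       rank_true = rank_true,
                                       statistic = stat)
  }
  stats_tbl <- if (length(rows) > 0) bind_rows(rows) else
    tibble(region = character(), k = integer(), rank_true = numeric(),
           statistic = numeric())
  list(stats = stats_tbl, n_excluded = n_excluded)
}
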