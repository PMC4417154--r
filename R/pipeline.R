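# End-to-end orchestration over a world bundle: window grid, accessibility
# masks, multi-species motif tracks, TF-domain associations, enhancer
# models and genome-wide domain assignments, plus recovery metrics against
# a known ground truth.

#' All TF x domain pairs of an association run
#' @param tfs character vector of TF ids.
#' @param domains character vector of domain ids.
#' @return tibble with one row per (tf, domain) pair.
#' @export
association_grid <- function(tfs, domains) {
  tidyr::expand_grid(tf = tfs, domain = domains)
}

# Multi-species motif score values for a window subset of the grid.
# Reference scores come from the reference genome; per-species scores from
# ortholog genomes (fast path) or per-window segments, with missing
# segments treated as absent species.
multispecies_scores <- function(bundle, pwm, grid, bg_ref, species_bg,
                                windows) {
  idx <- sort(unique(windows))
  ref <- score_genome(bundle$genome, pwm, grid, bg_ref, windows = idx)
  if (!is.null(bundle$ortholog_genomes)) {
    species <- names(bundle$ortholog_genomes)
    smat <- matrix(NA_real_, length(idx), 1 + length(species),
                   dimnames = list(NULL, c("ref", species)))
    smat[, "ref"] <- ref$value[idx]
    for (sp in species) {
      tr <- score_genome(bundle$ortholog_genomes[[sp]], pwm, grid,
                         species_bg[[sp]], windows = idx)
      v <- tr$value[idx]
      v[!bundle$ortholog_presence[[sp]][idx]] <- NA
      smat[, sp] <- v
    }
  } else {
    keys <- window_key(grid$chrom, grid$start)[idx]
    species <- names(bundle$ortholog_segments)
    smat <- matrix(NA_real_, length(idx), 1 + length(species),
                   dimnames = list(NULL, c("ref", species)))
    smat[, "ref"] <- ref$value[idx]
    for (sp in species) {
      segs <- bundle$ortholog_segments[[sp]]
      hit <- intersect(keys, names(segs))
      if (length(hit) == 0) next
      sc <- score_segments(segs[hit], pwm, species_bg[[sp]])
      smat[match(hit, keys), sp] <- sc
    }
  }
  wts <- bundle$species_weights$weight[
    match(colnames(smat), bundle$species_weights$species)]
  avg <- multispecies_average(smat, wts)
  values <- rep(NA_real_, nrow(grid))
  values[idx] <- avg
  new_window_track(grid, values)
}

#' Run the full regulatory-map pipeline on a world bundle
#'
#' Tiles the genome, aggregates accessibility into top-10% stage masks,
#' computes multi-species motif score tracks (restricted to the windows the
#' downstream stages can use: accessible in any stage or overlapping a
#' reference enhancer), discovers TF-domain associations, trains and gates
#' per-domain enhancer-activity models, and annotates open regions with
#' expression domains genome-wide.
#'
#' @param bundle a `world_bundle` (from [simulate_world()] or
#'   [read_bundle()]).
#' @param seed seed for training-set construction.
#' @param fraction accessibility mask fraction (default 0.10).
#' @param k association target-set size (NULL = `min(1000, 20%` of the
#'   universe)).
#' @param alpha significance threshold for reporting (default 1e-7).
#' @param lambda ridge penalty of the enhancer models.
#' @param bg_order background Markov order (default 1).
#' @param train_models train enhancer models (set FALSE to stop after the
#'   association stage).
#' @return A `regmap_result` list: `grid`, `masks`, `acc_windows`,
#'   `motif_tracks`, `associations`, `significant`, `open_regions`,
#'   `models`, `model_eval`, `assignments`, `rank_stats`, `params`.
#' @export
run_pipeline <- function(bundle, seed = 1L, fraction = 0.1, k = NULL,
                         alpha = 1e-7, lambda = 1e-6, bg_order = 1L,
                         train_models = TRUE) {
  cfg <- bundle$config
  grid <- tile_genome(bundle$chrom_sizes, cfg$window_length, cfg$stride)
  stage_map <- cfg$stage_map

  acc_windows <- lapply(bundle$acc_tracks, aggregate_base_track, grid = grid)
  masks <- imap(acc_windows, function(tr, st) {
    top_fraction_mask(tr, fraction = fraction, stage = st)
  })

  open_any <- Reduce(`|`, lapply(masks, function(m) m$accessible))
  ref_ov <- interval_overlaps(bundle$ref_enhancers, grid)
  windows <- sort(union(which(open_any), unique(ref_ov$subject)))

  bg_ref <- train_background(bundle$genome, order = bg_order)
  species_bg <- NULL
  if (!is.null(bundle$ortholog_genomes)) {
    species_bg <- lapply(bundle$ortholog_genomes, train_background,
                         order = bg_order)
  } else if (!is.null(bundle$ortholog_segments)) {
    species_bg <- lapply(bundle$ortholog_segments, function(s) {
      train_background(unname(s), order = bg_order)
    })
  }
  motif_tracks <- setNames(lapply(bundle$pwms, function(pwm) {
    multispecies_scores(bundle, pwm, grid, bg_ref, species_bg, windows)
  }), names(bundle$pwms))

  region_sets <- setNames(lapply(c("p1K", "p5K", "IG"), function(md) {
    build_regulatory_regions(bundle$genes, md, bundle$insulators,
                             bundle$chrom_sizes)
  }), c("p1K", "p5K", "IG"))

  assoc <- discover_associations(motif_tracks, masks, region_sets,
                                 bundle$atlas, stage_map = stage_map, k = k)
  assoc <- support_labels(assoc, bundle$atlas)
  signif <- filter_significant(assoc, alpha = alpha)

  out <- list(grid = grid, masks = masks, acc_windows = acc_windows,
              motif_tracks = motif_tracks, region_sets = region_sets,
              associations = assoc, significant = signif,
              params = list(seed = seed, fraction = fraction,
                            k = attr(assoc, "k"), alpha = alpha,
                            lambda = lambda, bg_order = bg_order,
                            stage_map = stage_map))
  class(out) <- "regmap_result"
  if (!train_models) return(out)

  regions <- build_open_regions(masks, acc_windows, motif_tracks,
                                reference = bundle$ref_enhancers)
  regions <- assign_candidate_domains(regions, bundle$genes, bundle$atlas)

  feat_cache <- new.env(parent = emptyenv())
  features_fn <- function(domain) {
    if (is.null(feat_cache[[domain]])) {
      feat_cache[[domain]] <- featurize(regions, domain, motif_tracks,
                                        assoc, bundle$atlas, bundle$fpkm)
    }
    feat_cache[[domain]]
  }

  domains <- bundle$atlas$domain_stage$domain
  models <- list(); evals <- list(); skipped <- list()
  for (i in seq_along(domains)) {
    d <- domains[i]
    tr_set <- build_training_sets(d, regions, bundle$atlas,
                                  stage_map = stage_map,
                                  seed = seed + i)
    if (inherits(tr_set, "skipped_training_set")) {
      skipped[[d]] <- tr_set$reason
      next
    }
    X <- features_fn(d)
    ridx <- match(tr_set$region, regions$region)
    train <- tr_set$split == "train"
    mdl <- train_enhancer_model(X[ridx[train], , drop = FALSE],
                                tr_set$label[train], lambda = lambda,
                                domain = d,
                                metadata = list(seed = seed + i,
                                                stages = names(masks)))
    ev <- evaluate_enhancer_model(mdl, regions, X, tr_set, bundle$atlas)
    ev$good <- good_model_gate(ev$test_auroc, ev$rfvo_auroc)
    models[[d]] <- mdl
    evals[[d]] <- ev
  }
  model_eval <- bind_rows(evals)
  gated <- models[model_eval$domain[model_eval$good]]
  assignments <- annotate_genome_wide(gated, regions, features_fn)
  rk <- rank_statistic(regions, gated, features_fn)

  out$open_regions <- regions
  out$models <- models
  out$model_eval <- model_eval
  out$gated_models <- gated
  out$assignments <- assignments
  out$rank_stats <- rk
  out$skipped_domains <- skipped
  out
}

#' @export
print.regmap_result <- function(x, ...) {
  cat(sprintf("<regmap_result> %d windows, %d motifs, %d associations",
              nrow(x$grid), length(x$motif_tracks), nrow(x$associations)))
  if (!is.null(x$model_eval)) {
    cat(sprintf("; %d/%d good enhancer models", sum(x$model_eval$good),
                nrow(x$model_eval)))
  }
  cat("\n")
  invisible(x)
}

#' Recovery metrics of a pipeline run against the planted ground truth
#'
#' @param result a [run_pipeline()] result.
#' @param truth the matching `ground_truth`.
#' @return tibble with `association_auroc` (S vs the planted TF-domain
#'   map), `enhancer_domain_recovery` (fraction of planted enhancers whose
#'   true domain is assigned to an overlapping open region),
#'   `mean_rank_statistic` and `frac_rank_one` over reference-overlapping
#'   regions.
#' @export
recovery_report <- function(result, truth) {
  assoc_auroc <- evaluate_vs_expression(result$associations,
                                        truth$planted_pairs)$auroc
  enh_rec <- NA_real_
  mean_rk <- NA_real_
  frac_one <- NA_real_
  if (!is.null(result$assignments)) {
    ov <- interval_overlaps(truth$enhancers, result$open_regions)
    hit <- logical(nrow(truth$enhancers))
    if (nrow(ov) > 0) {
      key <- paste(result$open_regions$region[ov$subject],
                   truth$enhancers$domain[ov$query])
      akey <- paste(result$assignments$region, result$assignments$domain)
      hit_idx <- unique(ov$query[key %in% akey])
      hit[hit_idx] <- TRUE
    }
    enh_rec <- mean(hit)
    if (nrow(result$rank_stats$stats) > 0) {
      mean_rk <- mean(result$rank_stats$stats$statistic)
      frac_one <- mean(result$rank_stats$stats$statistic == 1)
    }
  }
  tibble(association_auroc = assoc_auroc,
         enhancer_domain_recovery = enh_rec,
         mean_rank_statistic = mean_rk,
         frac_rank_one = frac_one)
}
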