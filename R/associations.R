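# TF-domain association discovery: regulatory-region construction
# (p1K / p5K / IG), motif-based TF target sets, hypergeometric overlap
# tests merged over the three region definitions, significance filtering,
# expression-support classification and proximal/distal bias analysis.

#' Build gene regulatory regions under one definition
#'
#' `p1K`/`p5K`: the 1 kb / 5 kb interval immediately upstream of the TSS
#' (strand-aware), clipped at chromosome bounds.  `IG`: the gene span
#' extended by up to 50 kb on each side, each extension truncated at the
#' nearest insulator-mark boundary between the gene and the extension
#' limit.
#'
#' @param genes tibble (`gene`, `chrom`, `strand`, `tss`, `start`, `end`).
#' @param mode one of "p1K", "p5K", "IG".
#' @param insulators tibble of insulator intervals (`chrom`, `start`,
#'   `end`); only used for IG.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param ig_extension maximum IG extension per side (bp).
#' @return A `regulatory_region_set` tibble (`gene`, `chrom`, `start`,
#'   `end`) with a `mode` attribute.  Clipped intervals may be empty
#'   (start == end).
#' @export
build_regulatory_regions <- function(genes, mode = c("p1K", "p5K", "IG"),
                                     insulators = NULL, chrom_sizes,
                                     ig_extension = 50000L) {
  mode <- match.arg(mode)
  if (is.data.frame(chrom_sizes)) {
    chrom_sizes <- setNames(chrom_sizes[[2]], chrom_sizes[[1]])
  }
  unknown <- setdiff(unique(genes$chrom), names(chrom_sizes))
  if (length(unknown) > 0) {
    abort(paste0("genes on unknown chromosome(s): ",
                 paste(unknown, collapse = ", ")))
  }
  L <- unname(chrom_sizes[genes$chrom])
  if (mode %in% c("p1K", "p5K")) {
    len <- if (mode == "p1K") 1000L else 5000L
    start <- ifelse(genes$strand == "+", genes$tss - len, genes$tss)
    end <- ifelse(genes$strand == "+", genes$tss, genes$tss + len)
    start <- pmax(0L, pmin(start, L))
    end <- pmax(start, pmin(end, L))
    out <- tibble(gene = genes$gene, chrom = genes$chrom,
                  start = as.integer(start), end = as.integer(end))
  } else {
    start <- pmax(0L, genes$start - ig_extension)
    end <- pmin(L, genes$end + ig_extension)
    if (!is.null(insulators) && nrow(insulators) > 0) {
      for (i in seq_len(nrow(genes))) {
        ins <- insulators[insulators$chrom == genes$chrom[i], , drop = FALSE]
        if (nrow(ins) == 0) next
        lb <- ins$end[ins$end <= genes$start[i] & ins$end > start[i]]
        if (length(lb) > 0) start[i] <- max(lb)
        rb <- ins$start[ins$start >= genes$end[i] & ins$start < end[i]]
        if (length(rb) > 0) end[i] <- min(rb)
      }
    }
    out <- tibble(gene = genes$gene, chrom = genes$chrom,
                  start = as.integer(start), end = as.integer(end))
  }
  attr(out, "mode") <- mode
  class(out) <- c("regulatory_region_set", class(tibble()))
  out
}

#' Per-gene motif evidence: max masked window score over a region set
#'
#' @param masked_track accessibility-masked multi-species motif
#'   `window_track`.
#' @param region_set a [build_regulatory_regions()] result.
#' @return tibble (`gene`, `score`); genes whose regions overlap no window
#'   score 0.
#' @export
gene_region_scores <- function(masked_track, region_set) {
  nonempty <- region_set[region_set$end > region_set$start, , drop = FALSE]
  scores <- setNames(rep(0, length(unique(region_set$gene))),
                     unique(region_set$gene))
  if (nrow(nonempty) > 0) {
    ov <- interval_overlaps(nonempty, masked_track)
    if (nrow(ov) > 0) {
      vals <- masked_track$value[ov$subject]
      ok <- !is.na(vals)
      agg <- tapply(vals[ok], nonempty$gene[ov$query][ok], max)
      scores[names(agg)] <- as.numeric(agg)
    }
  }
  tibble(gene = names(scores), score = unname(scores))
}

#' Motif evidence score of one gene
#' @inheritParams gene_region_scores
#' @param gene gene id present in the region set.
#' @return scalar score (max overlapping masked window score, 0 if none).
#' @export
gene_motif_score <- function(masked_track, region_set, gene) {
  if (!gene %in% region_set$gene) abort(paste0("unknown gene: ", gene))
  sc <- gene_region_scores(masked_track,
                           region_set[region_set$gene == gene, ,
                                      drop = FALSE])
  sc$score[[1]]
}

#' TF target set: top-k genes by motif evidence
#'
#' Genes with score 0 are excluded even if fewer than `k` remain; ties at
#' the cut are broken by ascending gene id.
#'
#' @param scores named numeric vector (gene -> score) or a tibble with
#'   `gene` and `score`.
#' @param k target-set size.
#' @return character vector of gene ids (possibly empty).
#' @export
tf_target_set <- function(scores, k) {
  if (is.data.frame(scores)) scores <- setNames(scores$score, scores$gene)
  if (k < 1) abort("k must be >= 1")
  pos <- scores[!is.na(scores) & scores > 0]
  if (length(pos) == 0) return(character(0))
  ord <- order(-pos, names(pos))
  names(pos)[ord][seq_len(min(k, length(pos)))]
}

#' Hypergeometric upper-tail probability P(X >= x)
#'
#' Drawing `n` genes from a universe of `N` containing `K` domain genes.
#'
#' @param x observed overlap.
#' @param N universe size.
#' @param K domain gene-set size.
#' @param n target-set size.
#' @return the p-value P(X >= x).
#' @export
hypergeom_sf <- function(x, N, K, n) {
  if (any(c(x, N, K, n) < 0) || K > N || n > N || x > min(K, n)) {
    abort("inconsistent hypergeometric counts")
  }
  if (x == 0) return(1)
  stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
}

#' Test one TF against one domain across the three region definitions
#'
#' For each mode the TF target set is built from that mode's gene scores
#' (already masked by the accessibility of the domain's stage) and tested
#' for overlap with the domain's gene set; the lowest p-value wins, ties
#' resolved by the fixed precedence p1K > p5K > IG.
#'
#' @param tf TF gene id.
#' @param domain expression-domain id.
#' @param mode_scores named list (p1K/p5K/IG) of per-gene score tibbles for
#'   this TF's motif under the domain's stage mask (see
#'   [gene_region_scores()]).
#' @param atlas an [expression_atlas()].
#' @param k target-set size.
#' @param cap cap applied to `S = -log10(p_best)`; default 300.
#' @return one-row tibble: `tf`, `domain`, `mode`, `n`, `K`, `x`, `N`,
#'   `p_p1K`, `p_p5K`, `p_IG`, `p_best`, `S`.
#' @export
associate <- function(tf, domain, mode_scores, atlas, k, cap = 300) {
  modes <- c("p1K", "p5K", "IG")
  stopifnot(all(modes %in% names(mode_scores)))
  domain_genes <- atlas$gene_domain$gene[atlas$gene_domain$domain == domain]
  atlas_genes <- unique(atlas$gene_domain$gene)
  per_mode <- lapply(modes, function(md) {
    sc <- mode_scores[[md]]
    universe <- intersect(sc$gene, atlas_genes)
    # the draw is n genes from the universe: rank within it
    tgt <- tf_target_set(sc[sc$gene %in% universe, , drop = FALSE], k)
    Kd <- length(intersect(domain_genes, universe))
    x <- length(intersect(tgt, domain_genes))
    list(p = if (length(tgt) == 0) 1 else
           hypergeom_sf(x, length(universe), Kd, length(tgt)),
         n = length(tgt), K = Kd, x = x, N = length(universe))
  })
  names(per_mode) <- modes
  ps <- vapply(per_mode, function(z) z$p, numeric(1))
  best <- modes[which(ps == min(ps))][1]   # precedence p1K > p5K > IG
  b <- per_mode[[best]]
  tibble(tf = tf, domain = domain, mode = best,
         n = b$n, K = b$K, x = b$x, N = b$N,
         p_p1K = ps[["p1K"]], p_p5K = ps[["p5K"]], p_IG = ps[["IG"]],
         p_best = min(ps), S = min(cap, -log10(max(min(ps), 1e-320))))
}

#' Discover TF-domain associations over a whole grid of pairs
#'
#' Computes, for every TF with a motif and every domain of the atlas, the
#' best-of-three-regions hypergeometric association using the
#' accessibility mask of the domain's stage.
#'
#' @param motif_tracks named list (motif id) of unmasked multi-species
#'   `window_track`s.
#' @param masks named list (stage label) of accessibility masks.
#' @param region_sets named list (p1K/p5K/IG) of
#'   [build_regulatory_regions()] results.
#' @param atlas an [expression_atlas()] whose `tfs` table maps TF -> motif.
#' @param stage_map named character vector mapping atlas stage labels to
#'   mask stage labels (e.g. `c("4-6" = "5")`); identity when NULL.
#' @param k target-set size; default `min(1000, 0.2 * universe)`.
#' @param cap cap on S.
#' @return An `association_results` tibble, one row per TF x domain.
#' @export
discover_associations <- function(motif_tracks, masks, region_sets, atlas,
                                  stage_map = NULL, k = NULL, cap = 300) {
  tfs <- atlas$tfs
  domains <- atlas$domain_stage
  if (is.null(stage_map)) {
    stage_map <- setNames(unique(domains$stage), unique(domains$stage))
  }
  atlas_genes <- unique(atlas$gene_domain$gene)
  if (is.null(k)) {
    k <- min(1000L, max(1L, floor(0.2 * length(atlas_genes))))
  }
  # per (motif, stage, mode): gene score table, shared across domains
  score_cache <- new.env(parent = emptyenv())
  get_scores <- function(motif, stage_label) {
    key <- paste(motif, stage_label, sep = "\r")
    if (!is.null(score_cache[[key]])) return(score_cache[[key]])
    mask <- masks[[stage_label]]
    if (is.null(mask)) abort(paste0("missing stage mask: ", stage_label))
    masked <- apply_mask(motif_tracks[[motif]], mask, fill = 0)
    out <- lapply(region_sets, function(rs) gene_region_scores(masked, rs))
    score_cache[[key]] <- out
    out
  }
  rows <- vector("list", nrow(tfs) * nrow(domains))
  i <- 0L
  for (ti in seq_len(nrow(tfs))) {
    for (di in seq_len(nrow(domains))) {
      i <- i + 1L
      stage_label <- stage_map[[domains$stage[di]]]
      ms <- get_scores(tfs$motif[ti], stage_label)
      rows[[i]] <- associate(tfs$tf[ti], domains$domain[di], ms, atlas,
                             k = k, cap = cap)
    }
  }
  out <- bind_rows(rows)
  attr(out, "k") <- k
  class(out) <- c("association_results", class(tibble()))
  out
}

#' Bonferroni-corrected significance level for a TF x domain grid
#' @param alpha per-test p-value threshold.
#' @param n_tf,n_domain grid dimensions.
#' @return `min(1, alpha * n_tf * n_domain)`.
#' @export
bonferroni_level <- function(alpha, n_tf, n_domain) {
  min(1, alpha * n_tf * n_domain)
}

#' Keep associations below a p-value threshold
#'
#' @param results an association tibble with `p_best`.
#' @param alpha per-test threshold (default 1e-7).
#' @return the filtered tibble; the Bonferroni-corrected level
#'   `alpha * n_tf * n_domain` (capped at 1) is attached as attribute
#'   `"bonferroni_level"`.
#' @export
filter_significant <- function(results, alpha = 1e-7) {
  if (!(alpha > 0 && alpha <= 1)) abort("alpha must be in (0, 1]")
  lvl <- bonferroni_level(alpha, dplyr::n_distinct(results$tf),
                          dplyr::n_distinct(results$domain))
  out <- filter(results, .data$p_best < alpha)
  attr(out, "bonferroni_level") <- lvl
  out
}

#' Expression support of a TF in a domain
#'
#' `specific` if the TF gene is annotated with the domain; else `related`
#' if annotated with an ontology ancestor or descendant of the domain from
#' the same stage; else `ubiquitous` if flagged ubiquitously expressed in
#' the domain's stage; else `none`.
#'
#' @param tf TF gene id (must be in the atlas TF table).
#' @param domain domain id.
#' @param atlas an [expression_atlas()].
#' @return one of "specific", "related", "ubiquitous", "none".
#' @export
expression_support <- function(tf, domain, atlas) {
  if (!tf %in% atlas$tfs$tf) abort(paste0("unknown TF: ", tf))
  stage <- domain_stage_of(atlas, domain)
  annotated <- atlas$gene_domain$domain[atlas$gene_domain$gene == tf]
  if (domain %in% annotated) return("specific")
  rel <- ontology_relatives(atlas$ontology, domain)
  rel <- rel[rel %in% atlas$domain_stage$domain[
    atlas$domain_stage$stage == stage]]
  if (length(intersect(annotated, rel)) > 0) return("related")
  ubi <- atlas$ubiquitous
  if (nrow(ubi) > 0 && any(ubi$tf == tf & ubi$stage == stage)) {
    return("ubiquitous")
  }
  "none"
}

#' Add expression-support labels to an association table
#' @param results association tibble with `tf` and `domain`.
#' @param atlas an [expression_atlas()].
#' @return `results` with a `support` column.
#' @export
support_labels <- function(results, atlas) {
  results %>%
    mutate(support = map2_chr(.data$tf, .data$domain,
                              function(tf, d) expression_support(tf, d,
                                                                 atlas)))
}

#' Evaluate association scores against TF-expression ground truth
#'
#' All TF x domain pairs are ranked by S (descending) and compared to the
#' truth set with [roc_auc()].
#'
#' @param results association tibble with `tf`, `domain`, `S`.
#' @param truth tibble (`tf`, `domain`) of true pairs.
#' @return A `roc_result`.
#' @export
evaluate_vs_expression <- function(results, truth) {
  if (is.null(truth) || nrow(truth) == 0) abort("truth set is empty")
  key <- paste(results$tf, results$domain)
  tkey <- paste(truth$tf, truth$domain)
  outside <- setdiff(tkey, key)
  if (length(outside) > 0) {
    abort(paste0(length(outside), " truth pair(s) outside the tested grid"))
  }
  roc_auc(results$S, key %in% tkey)
}

#' Write an association table as TSV
#'
#' Columns: tf, domain, mode, n, K, x, N, p_p1K, p_p5K, p_IG, p_best, S
#' and (when present) support; the target-set size k is recorded in a
#' comment header line.
#'
#' @param results an association tibble.
#' @param path output file.
#' @export
write_associations <- function(results, path) {
  k <- attr(results, "k")
  con <- file(path, "w")
  if (!is.null(k)) writeLines(sprintf("# target_set_k=%d", k), con)
  close(con)
  readr::write_tsv(as_tibble(results), path, append = !is.null(k),
                   col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Proximal/distal regulatory-region bias of TFs and domains
#'
#' An association is p1K-specific when significant under p1K
#' (`p_p1K < alpha_sig`) and clearly not under IG (`p_IG > alpha_null`);
#' IG-specific symmetrically.  Per TF and per domain, the split between
#' the two specific counts is tested against 0.5 with a two-sided exact
#' binomial test.
#'
#' @param results association tibble.
#' @param alpha_sig significance threshold (default 1e-7).
#' @param alpha_null "clearly not significant" threshold (default 1e-3).
#' @return list with `associations` (flagged rows), `by_tf` and
#'   `by_domain` count tables with `p_bias`.
#' @export
region_class_bias <- function(results, alpha_sig = 1e-7,
                              alpha_null = 1e-3) {
  if (!(alpha_sig < alpha_null)) abort("alpha_sig must be < alpha_null")
  flagged <- results %>%
    mutate(p1K_specific = .data$p_p1K < alpha_sig & .data$p_IG > alpha_null,
           IG_specific = .data$p_IG < alpha_sig & .data$p_p1K > alpha_null)
  count_bias <- function(df, by) {
    df %>%
      group_by(.data[[by]]) %>%
      summarise(n_p1K = sum(.data$p1K_specific),
                n_IG = sum(.data$IG_specific), .groups = "drop") %>%
      mutate(p_bias = map2_dbl(.data$n_p1K, .data$n_IG, function(a, b) {
        if (a + b == 0) return(1)
        stats::binom.test(a, a + b, 0.5,
                          alternative = "two.sided")$p.value
      }))
  }
  list(associations = flagged,
       by_tf = count_bias(flagged, "tf"),
       by_domain = count_bias(flagged, "domain"))
}
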