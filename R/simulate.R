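# Synthetic-world generator: a small genome with planted enhancers, motif
# sites, stage-specific accessibility, ChIP-like occupancy, orthologous
# genomes, a gene expression atlas and TF metadata, with full ground truth
# for recovery experiments.

#' Configuration of the synthetic world
#'
#' Defaults describe the standard study conditions: a 2 x 300 kb genome,
#' 20 TFs with 6-10 bp motifs, 120 genes, 12 expression domains over four
#' developmental stages, 8 planted enhancers per domain carrying 4 motif
#' sites each, 3 ortholog species at background mutation rate 0.15/bp with
#' planted sites preserved with probability 0.8, and 30% of planted
#' enhancers exported as the labelled reference set.
#'
#' @param seed integer seed governing every random draw.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param n_tfs number of TFs/motifs.
#' @param motif_width inclusive motif width range.
#' @param n_genes number of genes (split across chromosomes).
#' @param n_domains number of expression domains.
#' @param planted_density probability that a (TF, domain) pair is planted
#'   as a true regulatory relationship; when positive, every domain is
#'   guaranteed at least one regulator.
#' @param enhancers_per_domain planted enhancers per domain.
#' @param sites_per_enhancer motif sites planted per enhancer.
#' @param acc_peak_height,acc_peak_sd,acc_noise accessibility bump height,
#'   Gaussian sd (bp) and truncated-normal background noise sd.
#' @param chip_height,chip_sd,chip_noise ChIP-like site-density kernel and
#'   noise parameters.
#' @param n_species ortholog species count.
#' @param mu per-base background mutation rate of ortholog genomes.
#' @param rho per-site, per-species probability that a planted site is
#'   preserved intact.
#' @param missing_rate per-window, per-species probability that the
#'   orthologous segment is missing (no alignment).
#' @param gc genome GC content.
#' @param reference_fraction fraction of planted enhancers exported as the
#'   labelled reference-enhancer set.
#' @param extra_annotation_rate probability of a random extra gene-domain
#'   annotation.
#' @param n_insulators,insulator_width insulator-mark count and width.
#' @param window_length,stride window grid geometry (bp).
#' @param gene_span gene span length range (bp).
#' @param fpkm_active_mult FPKM multiplier in stages where the TF regulates
#'   some domain.
#' @param ubiquitous_rate probability of a (TF, stage) ubiquitous flag.
#' @return A `world_config` list.
#' @export
world_config <- function(seed = 1L,
                         chrom_lengths = c(chrA = 300000L, chrB = 300000L),
                         n_tfs = 20L,
                         motif_width = c(6L, 10L),
                         n_genes = 120L,
                         n_domains = 12L,
                         planted_density = 0.15,
                         enhancers_per_domain = 8L,
                         sites_per_enhancer = 4L,
                         acc_peak_height = 8,
                         acc_peak_sd = 300,
                         acc_noise = 1,
                         chip_height = 5,
                         chip_sd = 200,
                         chip_noise = 0.5,
                         n_species = 3L,
                         mu = 0.15,
                         rho = 0.8,
                         missing_rate = 0.05,
                         gc = 0.4,
                         reference_fraction = 0.3,
                         extra_annotation_rate = 0.02,
                         n_insulators = 80L,
                         insulator_width = 200L,
                         window_length = 500L,
                         stride = 50L,
                         gene_span = c(500L, 2000L),
                         fpkm_active_mult = 8,
                         ubiquitous_rate = 0.1) {
  cfg <- as.list(environment())
  counts <- c(cfg$chrom_lengths, cfg$n_tfs, cfg$n_genes, cfg$n_domains,
              cfg$enhancers_per_domain, cfg$n_species, cfg$window_length,
              cfg$stride)
  if (any(counts <= 0)) abort("all counts must be positive")
  rates <- c(cfg$planted_density, cfg$mu, cfg$rho, cfg$missing_rate,
             cfg$gc, cfg$reference_fraction, cfg$extra_annotation_rate,
             cfg$ubiquitous_rate)
  if (any(rates < 0 | rates > 1)) abort("rates must lie in [0, 1]")
  cfg$atlas_stages <- c("4-6", "9-10", "11-12", "13-16")
  cfg$mask_stages <- c("5", "9", "11", "14")
  cfg$stage_map <- setNames(cfg$mask_stages, cfg$atlas_stages)
  class(cfg) <- "world_config"
  cfg
}

random_dna <- function(n, gc) {
  sample(DNA_BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

sample_site <- function(pwm) {
  vapply(seq_len(pwm$width), function(j) {
    sample(DNA_BASES, 1, prob = pwm$mat[, j])
  }, character(1))
}

# Gaussian bump values over 1-based bin centres
bump <- function(centers, mid, height, sd) {
  height * exp(-(centers - mid)^2 / (2 * sd^2))
}

#' Simulate a complete synthetic regulatory world
#'
#' Generates an i.i.d. background genome, random informative PWMs, genes
#' with TSSs spaced along the chromosomes, planted enhancers near their
#' target genes containing sites of the planted regulator TFs,
#' stage-specific accessibility peaks over active enhancers, ChIP-like
#' tracks per TF, partially conserved ortholog genomes, an expression
#' atlas driven by the planted TF-domain map, TF FPKM values, insulator
#' marks and a labelled reference-enhancer subset.  Deterministic given
#' the config seed.
#'
#' @param config a [world_config()].
#' @return list with `bundle` (all pipeline inputs) and `truth`
#'   (planted TF-domain pairs, enhancers, sites, gene annotations).
#' @export
simulate_world <- function(config = world_config()) {
  cfg <- config
  with_seed(cfg$seed, simulate_world_impl(cfg))
}

simulate_world_impl <- function(cfg) {
  chroms <- names(cfg$chrom_lengths)
  genome_chars <- lapply(cfg$chrom_lengths, function(L) random_dna(L, cfg$gc))

  # --- motifs ------------------------------------------------------------
  tf_ids <- sprintf("tf%02d", seq_len(cfg$n_tfs))
  motif_ids <- sprintf("m%02d", seq_len(cfg$n_tfs))
  pwms <- setNames(lapply(seq_len(cfg$n_tfs), function(i) {
    w <- sample(seq(cfg$motif_width[1], cfg$motif_width[2]), 1)
    counts <- sapply(seq_len(w), function(j) {
      dom <- sample(1:4, 1)
      # high-information columns: a w-bp site must carry clearly more than
      # log(window length) ~ 6.2 nats of log-odds to be detectable by the
      # window HMM, as for the in vitro motif collections being emulated
      p_dom <- runif(1, 0.85, 0.99)
      cnt <- rep((1 - p_dom) / 3 * 100, 4)
      cnt[dom] <- p_dom * 100
      cnt
    })
    build_pwm(round(counts), pseudocount = 0.5, id = motif_ids[i])
  }), motif_ids)

  # --- domains and the planted TF -> domain map --------------------------
  domain_ids <- sprintf("d%02d", seq_len(cfg$n_domains))
  domain_stage <- tibble(domain = domain_ids,
                         stage = rep(cfg$atlas_stages,
                                     length.out = cfg$n_domains))
  planted <- which(matrix(runif(cfg$n_tfs * cfg$n_domains),
                          cfg$n_tfs) < cfg$planted_density,
                   arr.ind = TRUE)
  planted_pairs <- tibble(tf = tf_ids[planted[, 1]],
                          domain = domain_ids[planted[, 2]])
  if (cfg$planted_density > 0) {
    missing_dom <- setdiff(domain_ids, planted_pairs$domain)
    if (length(missing_dom) > 0) {
      planted_pairs <- bind_rows(planted_pairs,
                                 tibble(tf = sample(tf_ids,
                                                    length(missing_dom),
                                                    replace = TRUE),
                                        domain = missing_dom))
    }
  }
  planted_pairs <- distinct(arrange(planted_pairs, .data$tf, .data$domain))
  regulators <- split(planted_pairs$tf, planted_pairs$domain)

  # --- genes -------------------------------------------------------------
  per_chrom <- rep(floor(cfg$n_genes / length(chroms)), length(chroms))
  per_chrom[1] <- per_chrom[1] + cfg$n_genes - sum(per_chrom)
  gene_rows <- list()
  gi <- 0L
  for (ci in seq_along(chroms)) {
    L <- cfg$chrom_lengths[[ci]]
    ng <- per_chrom[ci]
    slot <- L / ng
    for (j in seq_len(ng)) {
      gi <- gi + 1L
      center <- round((j - 0.5) * slot + runif(1, -500, 500))
      len <- round(runif(1, cfg$gene_span[1], cfg$gene_span[2]))
      gstart <- max(0L, as.integer(center - len %/% 2))
      gend <- min(L, gstart + len)
      strand <- sample(c("+", "-"), 1)
      gene_rows[[gi]] <- tibble(
        gene = sprintf("g%03d", gi), chrom = chroms[ci], strand = strand,
        tss = if (strand == "+") gstart else gend,
        start = gstart, end = gend)
    }
  }
  genes <- bind_rows(gene_rows)

  # --- planted enhancers and sites --------------------------------------
  win <- cfg$window_length
  enh_rows <- list(); site_rows <- list()
  enh_iv <- tibble(chrom = character(), start = integer(), end = integer())
  ei <- 0L
  for (d in domain_ids) {
    targets <- sample(genes$gene, min(cfg$enhancers_per_domain,
                                      nrow(genes)))
    for (tg in targets) {
      g <- genes[genes$gene == tg, ]
      L <- cfg$chrom_lengths[[g$chrom]]
      placed <- FALSE
      for (try in 1:60) {
        if (try %% 20 == 0) {  # give up on this gene, pick another
          tg2 <- sample(genes$gene, 1)
          g <- genes[genes$gene == tg2, ]
          L <- cfg$chrom_lengths[[g$chrom]]
        }
        # strand-aware placement within the 5 kb upstream regulatory
        # neighbourhood of the target TSS
        off <- round(runif(1, 0, 5000 - win))
        s <- if (g$strand == "+") as.integer(g$tss - 5000 + off)
             else as.integer(g$tss + off)
        if (s < 0 || s + win > L) next
        gch <- genes$chrom == g$chrom
        gene_hit <- any(s < genes$end[gch] & s + win > genes$start[gch])
        ech <- enh_iv$chrom == g$chrom
        enh_hit <- any(s < enh_iv$end[ech] & s + win > enh_iv$start[ech])
        if (!gene_hit && !enh_hit) {
          cand <- tibble(chrom = g$chrom, start = s, end = s + win)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort("infeasible enhancer placement: genome too crowded")
      }
      ei <- ei + 1L
      enh_id <- sprintf("e%03d", ei)
      enh_iv <- bind_rows(enh_iv, cand)
      enh_rows[[ei]] <- mutate(cand, enhancer = enh_id, domain = d,
                               gene = g$gene)
      regs <- regulators[[d]]
      if (!is.null(regs) && cfg$sites_per_enhancer > 0) {
        site_taken <- integer(0)
        # round-robin over a shuffled regulator order: every planted
        # regulator of the domain is represented in each enhancer when
        # sites_per_enhancer >= #regulators (cooperative-binding structure)
        reg_cycle <- rep(sample(regs, length(regs)),
                         length.out = cfg$sites_per_enhancer)
        for (si in seq_len(cfg$sites_per_enhancer)) {
          tf <- reg_cycle[si]
          pwm <- pwms[[motif_ids[match(tf, tf_ids)]]]
          w <- pwm$width
          for (stry in 1:30) {
            off <- sample(0:(win - w), 1)
            if (!any(abs(off - site_taken) < w + 2)) break
            off <- NA
          }
          if (is.na(off)) next
          site_taken <- c(site_taken, off)
          site_seq <- sample_site(pwm)
          if (runif(1) < 0.5) {
            site_seq <- rev(chartr("ACGT", "TGCA", site_seq))
          }
          pos <- cand$start + off
          genome_chars[[g$chrom]][(pos + 1):(pos + w)] <- site_seq
          site_rows[[length(site_rows) + 1]] <-
            tibble(chrom = g$chrom, start = pos, end = pos + w, tf = tf,
                   enhancer = enh_id, domain = d)
        }
      }
    }
  }
  enhancers <- bind_rows(enh_rows) %>%
    select("enhancer", "chrom", "start", "end", "domain", "gene")
  sites <- if (length(site_rows) > 0) bind_rows(site_rows) else
    tibble(chrom = character(), start = integer(), end = integer(),
           tf = character(), enhancer = character(), domain = character())

  # --- atlas annotations -------------------------------------------------
  planted_ann <- distinct(tibble(gene = enhancers$gene,
                                 domain = enhancers$domain))
  extra <- which(matrix(runif(nrow(genes) * cfg$n_domains),
                        nrow(genes)) < cfg$extra_annotation_rate,
                 arr.ind = TRUE)
  extra_ann <- tibble(gene = genes$gene[extra[, 1]],
                      domain = domain_ids[extra[, 2]])
  tf_ann <- tibble(gene = planted_pairs$tf, domain = planted_pairs$domain)
  gene_domain <- distinct(bind_rows(planted_ann, extra_ann, tf_ann))
  # small within-stage ontology: each domain may have one earlier
  # same-stage domain as parent
  ont_rows <- list()
  for (st in unique(domain_stage$stage)) {
    ds <- domain_stage$domain[domain_stage$stage == st]
    if (length(ds) > 1) {
      for (j in 2:length(ds)) {
        if (runif(1) < 0.5) {
          ont_rows[[length(ont_rows) + 1]] <-
            tibble(parent = ds[sample(j - 1, 1)], child = ds[j])
        }
      }
    }
  }
  ontology <- if (length(ont_rows) > 0) bind_rows(ont_rows) else
    tibble(parent = character(), child = character())
  ubi <- which(matrix(runif(cfg$n_tfs * length(cfg$atlas_stages)),
                      cfg$n_tfs) < cfg$ubiquitous_rate, arr.ind = TRUE)
  ubiquitous <- tibble(tf = tf_ids[ubi[, 1]],
                       stage = cfg$atlas_stages[ubi[, 2]])
  atlas <- expression_atlas(
    gene_domain = gene_domain, domain_stage = domain_stage,
    ontology = ontology, tfs = tibble(tf = tf_ids, motif = motif_ids),
    ubiquitous = ubiquitous)

  # --- accessibility and ChIP base tracks (50 bp bins) -------------------
  bin <- cfg$stride
  make_bins <- function(ch) {
    L <- cfg$chrom_lengths[[ch]]
    starts <- seq.int(0L, L - 1L, by = bin)
    tibble(chrom = ch, start = starts, end = pmin(starts + bin, L))
  }
  bins <- lapply(chroms, make_bins)
  names(bins) <- chroms
  stage_of_domain <- setNames(cfg$stage_map[domain_stage$stage],
                              domain_stage$domain)
  acc_tracks <- list()
  for (st in cfg$mask_stages) {
    rows <- lapply(chroms, function(ch) {
      b <- bins[[ch]]
      centers <- (b$start + b$end) / 2
      v <- abs(rnorm(nrow(b), 0, cfg$acc_noise))
      act <- enhancers[stage_of_domain[enhancers$domain] == st &
                         enhancers$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(act))) {
        mid <- (act$start[i] + act$end[i]) / 2
        near <- which(abs(centers - mid) < 4 * cfg$acc_peak_sd)
        v[near] <- v[near] + bump(centers[near], mid, cfg$acc_peak_height,
                                  cfg$acc_peak_sd)
      }
      mutate(b, value = v)
    })
    acc_tracks[[st]] <- bind_rows(rows)
  }
  chip_tracks <- list()
  for (ti in seq_len(cfg$n_tfs)) {
    tf <- tf_ids[ti]
    rows <- lapply(chroms, function(ch) {
      b <- bins[[ch]]
      centers <- (b$start + b$end) / 2
      v <- abs(rnorm(nrow(b), 0, cfg$chip_noise))
      ss <- sites[sites$tf == tf & sites$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(ss))) {
        mid <- (ss$start[i] + ss$end[i]) / 2
        near <- which(abs(centers - mid) < 4 * cfg$chip_sd)
        v[near] <- v[near] + bump(centers[near], mid, cfg$chip_height,
                                  cfg$chip_sd)
      }
      mutate(b, value = v)
    })
    chip_tracks[[tf]] <- bind_rows(rows)
  }

  # --- ortholog genomes --------------------------------------------------
  species <- sprintf("sp%d", seq_len(cfg$n_species))
  ortholog_genomes <- list()
  for (sp in species) {
    mutated <- lapply(chroms, function(ch) {
      x <- genome_chars[[ch]]
      hit <- which(runif(length(x)) < cfg$mu)
      if (length(hit) > 0) {
        x[hit] <- sample(DNA_BASES, length(hit), replace = TRUE)
      }
      x
    })
    names(mutated) <- chroms
    if (nrow(sites) > 0) {
      preserved <- runif(nrow(sites)) < cfg$rho
      for (i in which(preserved)) {
        ch <- sites$chrom[i]
        idx <- (sites$start[i] + 1):sites$end[i]
        mutated[[ch]][idx] <- genome_chars[[ch]][idx]
      }
    }
    ortholog_genomes[[sp]] <- vapply(mutated, paste0, character(1),
                                     collapse = "")
  }
  grid <- tile_genome(cfg$chrom_lengths, cfg$window_length, cfg$stride)
  presence <- setNames(lapply(species, function(sp) {
    runif(nrow(grid)) >= cfg$missing_rate
  }), species)
  # branch-length-derived weights on a fixed toy tree
  dists <- c(0.1, seq(0.25, by = 0.35, length.out = cfg$n_species))
  wts <- exp(-dists) / sum(exp(-dists))
  species_weights <- tibble(species = c("ref", species), weight = wts)

  # --- TF expression -----------------------------------------------------
  active <- distinct(tibble(
    tf = planted_pairs$tf,
    stage = domain_stage$stage[match(planted_pairs$domain,
                                     domain_stage$domain)]))
  fpkm <- tidyr::expand_grid(tf = tf_ids, stage = cfg$atlas_stages) %>%
    mutate(fpkm = rlnorm(dplyr::n(), 0, 0.5)) %>%
    left_join(mutate(active, is_active = TRUE), by = c("tf", "stage")) %>%
    mutate(fpkm = ifelse(!is.na(.data$is_active),
                         .data$fpkm * cfg$fpkm_active_mult, .data$fpkm)) %>%
    select("tf", "stage", "fpkm")

  # --- insulators, coding, reference enhancers ---------------------------
  ins_per_chrom <- round(cfg$n_insulators * cfg$chrom_lengths /
                           sum(cfg$chrom_lengths))
  # insulator marks delimit regulatory domains: a planted enhancer and its
  # target gene lie in one domain by construction, so marks never fall
  # between them
  env_g <- genes[match(enhancers$gene, genes$gene), ]
  envelopes <- tibble(chrom = enhancers$chrom,
                      start = pmin(enhancers$start, env_g$start),
                      end = pmax(enhancers$end, env_g$end))
  insulators <- bind_rows(lapply(seq_along(chroms), function(ci) {
    L <- cfg$chrom_lengths[[ci]]
    s <- sort(sample(0:(L - cfg$insulator_width), ins_per_chrom[ci]))
    iv <- tibble(chrom = chroms[ci], start = as.integer(s),
                 end = as.integer(s + cfg$insulator_width))
    ech <- envelopes[envelopes$chrom == chroms[ci], , drop = FALSE]
    bad <- vapply(seq_len(nrow(iv)), function(j) {
      any(iv$start[j] < ech$end & iv$end[j] > ech$start)
    }, logical(1))
    iv[!bad, , drop = FALSE]
  }))
  coding <- select(genes, "chrom", "start", "end")
  n_ref <- max(1L, round(cfg$reference_fraction * nrow(enhancers)))
  ref_idx <- sort(sample(nrow(enhancers), n_ref))
  ref <- reference_enhancers(
    tibble(enhancer = enhancers$enhancer[ref_idx],
           chrom = enhancers$chrom[ref_idx],
           start = enhancers$start[ref_idx],
           end = enhancers$end[ref_idx]),
    tibble(enhancer = enhancers$enhancer[ref_idx],
           domain = enhancers$domain[ref_idx]))

  genome <- vapply(genome_chars, paste0, character(1), collapse = "")
  names(genome) <- chroms
  bundle <- structure(list(
    config = cfg,
    chrom_sizes = cfg$chrom_lengths,
    genome = genome,
    pwms = pwms,
    genes = genes,
    atlas = atlas,
    fpkm = fpkm,
    acc_tracks = acc_tracks,
    chip_tracks = chip_tracks,
    ortholog_genomes = ortholog_genomes,
    ortholog_presence = presence,
    species_weights = species_weights,
    insulators = insulators,
    coding = coding,
    ref_enhancers = ref), class = "world_bundle")
  truth <- structure(list(
    planted_pairs = planted_pairs,
    enhancers = enhancers,
    sites = sites,
    gene_domains = planted_ann), class = "ground_truth")
  stopifnot(all(sites$start >= enhancers$start[match(sites$enhancer,
                                                     enhancers$enhancer)]),
            all(sites$end <= enhancers$end[match(sites$enhancer,
                                                 enhancers$enhancer)]))
  list(bundle = bundle, truth = truth)
}

#' Extract the orthology map (segments per window) from a bundle
#'
#' @param bundle a [simulate_world()] bundle (or one read back with
#'   [read_bundle()]).
#' @param grid window grid of the reference genome.
#' @param windows optional grid row indices to extract.
#' @return An [orthology_map()].
#' @export
bundle_orthology_map <- function(bundle, grid, windows = NULL) {
  idx <- if (is.null(windows)) seq_len(nrow(grid)) else sort(unique(windows))
  keys <- window_key(grid$chrom, grid$start)[idx]
  segs <- list()
  segs[["ref"]] <- setNames(substring(
    bundle$genome[grid$chrom[idx]], grid$start[idx] + 1, grid$end[idx]),
    keys)
  if (!is.null(bundle$ortholog_genomes)) {
    for (sp in names(bundle$ortholog_genomes)) {
      pres <- bundle$ortholog_presence[[sp]][idx]
      segs[[sp]] <- setNames(substring(
        bundle$ortholog_genomes[[sp]][grid$chrom[idx]],
        grid$start[idx] + 1, grid$end[idx]), keys)[pres]
    }
  } else if (!is.null(bundle$ortholog_segments)) {
    for (sp in names(bundle$ortholog_segments)) {
      s <- bundle$ortholog_segments[[sp]]
      segs[[sp]] <- s[names(s) %in% keys]
    }
  }
  orthology_map(segs, bundle$species_weights, reference = "ref")
}
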