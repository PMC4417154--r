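# On-disk representation of a world bundle: FASTA genome and per-species
# ortholog segments, MEME motifs, bedGraph signal, BED intervals, TSV
# tables and a JSON ground truth + manifest.

#' Write a simulated world bundle (and its ground truth) to a directory
#'
#' @param world a [simulate_world()] result (list with `bundle`, `truth`).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(world, dir) {
  bundle <- world$bundle
  truth <- world$truth
  cfg <- bundle$config
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(...) file.path(dir, ...)

  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(bundle$genome), p("genome.fa"))
  readr::write_tsv(tibble(chrom = names(bundle$chrom_sizes),
                          length = unname(bundle$chrom_sizes)),
                   p("chrom.sizes"), col_names = FALSE, progress = FALSE)
  write_meme(bundle$pwms, p("motifs.meme"))

  grid <- tile_genome(bundle$chrom_sizes, cfg$window_length, cfg$stride)
  orth_dir <- p("orthologs")
  dir.create(orth_dir, showWarnings = FALSE)
  omap <- bundle_orthology_map(bundle, grid)
  for (sp in setdiff(names(omap$segments), "ref")) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(omap$segments[[sp]]),
      file.path(orth_dir, paste0(sp, ".fa")))
  }
  readr::write_tsv(bundle$species_weights, p("species_weights.tsv"),
                   progress = FALSE)

  for (st in names(bundle$acc_tracks)) {
    write_bedgraph(bundle$acc_tracks[[st]],
                   p(sprintf("accessibility_stage%s.bedGraph", st)))
  }
  chip_dir <- p("chip")
  dir.create(chip_dir, showWarnings = FALSE)
  for (tf in names(bundle$chip_tracks)) {
    write_bedgraph(bundle$chip_tracks[[tf]],
                   file.path(chip_dir, paste0(tf, ".bedGraph")))
  }

  readr::write_tsv(bundle$genes, p("genes.tsv"), progress = FALSE)
  readr::write_tsv(bundle$atlas$gene_domain, p("atlas_gene_domain.tsv"),
                   progress = FALSE)
  readr::write_tsv(bundle$atlas$domain_stage, p("atlas_domain_stage.tsv"),
                   progress = FALSE)
  readr::write_tsv(bundle$atlas$ontology, p("atlas_ontology.tsv"),
                   progress = FALSE)
  readr::write_tsv(bundle$atlas$tfs, p("tf_motifs.tsv"), progress = FALSE)
  readr::write_tsv(bundle$atlas$ubiquitous, p("tf_ubiquitous.tsv"),
                   progress = FALSE)
  readr::write_tsv(bundle$fpkm, p("tf_fpkm.tsv"), progress = FALSE)
  write_bed(bundle$insulators, p("insulators.bed"))
  write_bed(bundle$coding, p("coding.bed"))
  write_bed(tibble(chrom = bundle$ref_enhancers$chrom,
                   start = bundle$ref_enhancers$start,
                   end = bundle$ref_enhancers$end,
                   name = bundle$ref_enhancers$enhancer),
            p("reference_enhancers.bed"))
  ref_dom <- bundle$ref_enhancers %>%
    select("enhancer", "domains") %>%
    tidyr::unnest("domains") %>%
    rename(domain = "domains")
  readr::write_tsv(ref_dom, p("reference_enhancer_domains.tsv"),
                   progress = FALSE)

  truth_json <- list(
    planted_pairs = truth$planted_pairs,
    enhancers = truth$enhancers,
    sites = truth$sites,
    gene_domains = truth$gene_domains)
  jsonlite::write_json(truth_json, p("ground_truth.json"),
                       dataframe = "rows", digits = NA)
  manifest <- cfg
  class(manifest) <- NULL
  manifest$chrom_lengths <- as.list(manifest$chrom_lengths)
  manifest$stage_map <- as.list(manifest$stage_map)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a world bundle back from a directory
#'
#' Reconstructs every pipeline input written by [write_bundle()]; ortholog
#' sequences come back as per-window segments (`ortholog_segments`).
#'
#' @param dir bundle directory.
#' @return A `world_bundle` list (without ground truth; see
#'   [read_ground_truth()]).
#' @export
read_bundle <- function(dir) {
  p <- function(...) file.path(dir, ...)
  manifest <- jsonlite::read_json(p("manifest.json"), simplifyVector = TRUE)
  cs <- read_chrom_sizes(p("chrom.sizes"))
  chrom_sizes <- setNames(cs$length, cs$chrom)
  genome <- as.character(Biostrings::readDNAStringSet(p("genome.fa")))
  names(genome) <- sub("\\s.*$", "", names(genome))
  pwms <- read_meme(p("motifs.meme"))
  seg_files <- list.files(p("orthologs"), pattern = "\\.fa$",
                          full.names = TRUE)
  ortholog_segments <- setNames(lapply(seg_files, function(f) {
    s <- Biostrings::readDNAStringSet(f)
    setNames(as.character(s), sub("\\s.*$", "", names(s)))
  }), sub("\\.fa$", "", basename(seg_files)))
  species_weights <- readr::read_tsv(p("species_weights.tsv"),
                                     col_types = "cd", progress = FALSE)
  acc_files <- list.files(dir, pattern = "^accessibility_stage.*bedGraph$")
  acc_tracks <- setNames(lapply(acc_files, function(f) read_bedgraph(p(f))),
                         sub("^accessibility_stage(.*)\\.bedGraph$", "\\1",
                             acc_files))
  stage_order <- intersect(unlist(manifest$mask_stages),
                           names(acc_tracks))
  acc_tracks <- acc_tracks[c(stage_order,
                             setdiff(names(acc_tracks), stage_order))]
  chip_files <- list.files(p("chip"), pattern = "bedGraph$",
                           full.names = TRUE)
  chip_tracks <- setNames(lapply(chip_files, read_bedgraph),
                          sub("\\.bedGraph$", "", basename(chip_files)))
  genes <- readr::read_tsv(p("genes.tsv"), col_types = "cccinn",
                           progress = FALSE) %>%
    mutate(tss = as.integer(.data$tss), start = as.integer(.data$start),
           end = as.integer(.data$end))
  atlas <- read_atlas(p("atlas_gene_domain.tsv"),
                      p("atlas_domain_stage.tsv"),
                      p("atlas_ontology.tsv"),
                      p("tf_motifs.tsv"),
                      p("tf_ubiquitous.tsv"))
  fpkm <- readr::read_tsv(p("tf_fpkm.tsv"), col_types = "ccd",
                          progress = FALSE)
  ref_bed <- read_bed(p("reference_enhancers.bed"))
  ref_dom <- readr::read_tsv(p("reference_enhancer_domains.tsv"),
                             col_types = "cc", progress = FALSE)
  ref <- reference_enhancers(rename(ref_bed, enhancer = "name"), ref_dom)
  cfg <- manifest
  cfg$chrom_lengths <- unlist(cfg$chrom_lengths)
  cfg$stage_map <- unlist(cfg$stage_map)
  class(cfg) <- "world_config"
  structure(list(
    config = cfg,
    chrom_sizes = chrom_sizes,
    genome = genome,
    pwms = pwms,
    genes = genes,
    atlas = atlas,
    fpkm = fpkm,
    acc_tracks = acc_tracks,
    chip_tracks = chip_tracks,
    ortholog_segments = ortholog_segments,
    species_weights = species_weights,
    insulators = read_bed(p("insulators.bed"))[, c("chrom", "start", "end")],
    coding = read_bed(p("coding.bed"))[, c("chrom", "start", "end")],
    ref_enhancers = ref), class = "world_bundle")
}

#' Read the ground truth written by [write_bundle()]
#' @param dir bundle directory.
#' @return A `ground_truth` list of tibbles.
#' @export
read_ground_truth <- function(dir) {
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  structure(list(planted_pairs = as_tibble(gt$planted_pairs),
                 enhancers = as_tibble(gt$enhancers),
                 sites = as_tibble(gt$sites),
                 gene_domains = as_tibble(gt$gene_domains)),
            class = "ground_truth")
}
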