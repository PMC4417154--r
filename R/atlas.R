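# The expression atlas: gene <-> expression-domain annotations, the
# domain -> developmental-stage map, the domain ontology, and TF metadata
# (motif assignment, per-stage ubiquitous-expression flags).

#' Construct an expression atlas
#'
#' @param gene_domain tibble (`gene`, `domain`): non-exclusive membership of
#'   genes in expression domains.
#' @param domain_stage tibble (`domain`, `stage`): one stage label per
#'   domain.
#' @param ontology tibble (`parent`, `child`) of domain ontology edges;
#'   must be acyclic.
#' @param tfs tibble (`tf`, `motif`): TF gene ids and their motif ids.
#' @param ubiquitous tibble (`tf`, `stage`) rows flagging ubiquitous TF
#'   expression in a stage.
#' @return An `expression_atlas` list.
#' @export
expression_atlas <- function(gene_domain, domain_stage, ontology = NULL,
                             tfs = NULL, ubiquitous = NULL) {
  if (is.null(ontology)) ontology <- tibble(parent = character(),
                                            child = character())
  if (is.null(tfs)) tfs <- tibble(tf = character(), motif = character())
  if (is.null(ubiquitous)) ubiquitous <- tibble(tf = character(),
                                                stage = character())
  missing_stage <- setdiff(unique(gene_domain$domain), domain_stage$domain)
  if (length(missing_stage) > 0) {
    abort(paste0("domains without a stage: ",
                 paste(head(missing_stage, 5), collapse = ", ")))
  }
  if (nrow(ontology) > 0 && ontology_has_cycle(ontology)) {
    abort("domain ontology must be acyclic")
  }
  structure(list(gene_domain = distinct(gene_domain),
                 domain_stage = distinct(domain_stage),
                 ontology = distinct(ontology),
                 tfs = distinct(tfs),
                 ubiquitous = distinct(ubiquitous)),
            class = "expression_atlas")
}

#' @export
print.expression_atlas <- function(x, ...) {
  cat(sprintf(
    "<expression_atlas> %d genes, %d domains (%d stages), %d TFs\n",
    dplyr::n_distinct(x$gene_domain$gene),
    nrow(x$domain_stage),
    dplyr::n_distinct(x$domain_stage$stage),
    nrow(x$tfs)))
  invisible(x)
}

ontology_has_cycle <- function(edges) {
  nodes <- unique(c(edges$parent, edges$child))
  indeg <- table(factor(edges$child, levels = nodes))
  active <- setNames(as.integer(indeg), nodes)
  queue <- nodes[active == 0]
  seen <- 0L
  edges_left <- edges
  while (length(queue) > 0) {
    v <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    kids <- edges_left$child[edges_left$parent == v]
    for (kid in kids) {
      active[kid] <- active[kid] - 1L
      if (active[kid] == 0L) queue <- c(queue, kid)
    }
    edges_left <- edges_left[edges_left$parent != v, , drop = FALSE]
  }
  seen < length(nodes)
}

# Ancestors and descendants of a domain in the ontology (transitive).
ontology_relatives <- function(ontology, domain) {
  reach <- function(start, from_col, to_col) {
    seen <- character()
    frontier <- start
    while (length(frontier) > 0) {
      nxt <- ontology[[to_col]][ontology[[from_col]] %in% frontier]
      nxt <- setdiff(unique(nxt), seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    seen
  }
  unique(c(reach(domain, "child", "parent"),    # ancestors
           reach(domain, "parent", "child")))   # descendants
}

domain_stage_of <- function(atlas, domain) {
  st <- atlas$domain_stage$stage[atlas$domain_stage$domain == domain]
  if (length(st) == 0) abort(paste0("unknown domain: ", domain))
  st[[1]]
}

#' Read an expression atlas from its three TSV files plus TF metadata
#'
#' @param gene_domain_path TSV with columns `gene`, `domain`.
#' @param domain_stage_path TSV with columns `domain`, `stage`.
#' @param ontology_path TSV with columns `parent`, `child` (optional).
#' @param tf_path TSV with columns `tf`, `motif` (optional).
#' @param ubiquitous_path TSV with columns `tf`, `stage` (optional).
#' @return An [expression_atlas()].
#' @export
read_atlas <- function(gene_domain_path, domain_stage_path,
                       ontology_path = NULL, tf_path = NULL,
                       ubiquitous_path = NULL) {
  rd <- function(p) readr::read_tsv(p, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  expression_atlas(
    gene_domain = rd(gene_domain_path),
    domain_stage = rd(domain_stage_path),
    ontology = if (!is.null(ontology_path)) rd(ontology_path),
    tfs = if (!is.null(tf_path)) rd(tf_path),
    ubiquitous = if (!is.null(ubiquitous_path)) rd(ubiquitous_path))
}
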