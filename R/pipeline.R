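#' Toy gene graphs
#'
#' Three two-genome fixtures, each with one bubble between `>A` and `>C`:
#' `"TOY1"` a deletion (`>A >B >C` vs `>A >C`), `"TOY2"` an inversion
#' (`>A >B >C` vs `>A <B >C`), `"TOY3"` a tandem copy gain
#' (`>A >B >C` vs `>A >B >B >C`), and `"PARALLEL"` a substitution-like pair
#' of alternatives (`>A >B >C` vs `>A >D >C`).
#'
#' @param name fixture name.
#' @return a `pangraph`.
#' @examples
#' toy_graph("TOY1")
#' @export
toy_graph <- function(name = c("TOY1", "TOY2", "TOY3", "PARALLEL")) {
  name <- match.arg(name)
  w2 <- switch(name,
    TOY1 = c(">A", ">C"),
    TOY2 = c(">A", "<B", ">C"),
    TOY3 = c(">A", ">B", ">B", ">C"),
    PARALLEL = c(">A", ">D", ">C"))
  pangraph_from_walks(list(
    list(genome = "g1", contig = "c1", steps = c(">A", ">B", ">C"),
         score = c(500, 500, 500), n_introns = c(1L, 1L, 1L)),
    list(genome = "g2", contig = "c2", steps = w2,
         score = rep(500, length(w2)), n_introns = rep(1L, length(w2)))))
}

#' Build a pangenome gene graph from PAF alignments
#'
#' The full construction pipeline: read one PAF per genome, suppress
#' putative pseudogene alignments, keep one protein per gene, take best
#' hits, select non-orthologous genes via the greedy b(v) loop, place
#' non-overlapping hits per contig, build walks and skew-symmetric scored
#' edges, then (optionally) apply the false-edge filter, the low-priority
#' re-annotation and the topology-based gene/edge filters.
#'
#' @param paf character vector of PAF paths (names override genome ids) or
#'   a pre-read hit table from [read_paf_set()].
#' @param config a [pangraph_config()].
#' @param apply_filters run [apply_gene_filters()] at the end.
#' @return a `pangraph`; `meta$counts` records the sizes at each stage.
#' @export
pangraph <- function(paf, config = pangraph_config(), apply_filters = TRUE) {
  cfg <- config
  hits <- if (is.character(paf)) {
    read_paf_set(paf, cfg = paf_options(cfg$score_tags, cfg$intron_ops))
  } else paf
  counts <- list(hits_in = nrow(hits), genes_in = length(unique(hits$gene)))
  genomes <- sort(unique(hits$genome))
  hits <- filter_pseudogene_hits(hits, cfg$pseudogene_mode)
  hits <- choose_protein_per_gene(hits)
  bh <- best_hits(hits)
  sel <- select_genes(bh, overlap_min = cfg$overlap_min)
  counts$genes_selected <- length(sel)
  hits <- hits[gene %in% sel]
  placed <- place_hits(hits, overlap_min = cfg$overlap_min)
  g <- build_graph(placed, genomes = genomes)
  counts$edges_initial <- nrow(g$edges)
  if (cfg$adjust) {
    g <- filter_false_edges(g, cfg)   # rebuilds internally after deletions
    if (length(g$meta$removed_hits))
      hits <- hits[!hit_id %in% g$meta$removed_hits]
    lp <- mark_low_priority(g, cfg)
    if (length(lp$low_marks)) {
      # one re-annotation pass preferring unmarked genes at each locus
      placed <- place_hits(hits, overlap_min = cfg$overlap_min,
                           low_marks = lp$low_marks)
      g <- build_graph(placed, genomes = genomes)
    } else {
      g <- lp$graph
    }
  }
  if (apply_filters) g <- apply_gene_filters(g, cfg)
  counts$genes_final <- length(g$genes)
  counts$edges_final <- nrow(g$edges)
  g$meta$counts <- counts
  g$meta$config <- cfg
  g
}
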