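## Building walks and the skew-symmetric edge set from placed annotations,
## edge scoring, score-ratio edge adjustments and topology-based gene
## filters.

#' Graph construction and filtering parameters
#'
#' @param r1 false-edge score ratio: x->y is a false edge when a competing
#'   x->z on always-different contigs out-scores it by more than this factor
#'   (default 0.95).
#' @param r2 low-priority score ratio: x->y is low priority when a competing
#'   x->z whose endpoint shares a contig with y's gene somewhere out-scores
#'   it by more than this factor (default 0.98).
#' @param min_edge_support edges supported by fewer contigs are pruned.
#' @param max_gene_edges genes with a larger bidirected degree are removed.
#' @param max_distant_loci genes hit at more distinct loci (per genome,
#'   after merging hits closer than `locus_merge_distance`) are removed.
#' @param min_gene_freq genes present in a smaller fraction of genomes are
#'   removed; use 0.001 to keep effectively everything.
#' @param drop_single_exon remove genes all of whose hits are intronless.
#' @param locus_merge_distance gap (bp) under which same-contig hits of a
#'   gene count as one locus.
#' @param overlap_min hit-overlap fraction used by selection and placement.
#' @param pseudogene_mode see [filter_pseudogene_hits()].
#' @param adjust apply the false-edge filter and the low-priority
#'   re-annotation during [pangraph()].
#' @param score_tags,intron_ops see [paf_options()].
#' @return a configuration list for [pangraph()] and the filter operations.
#' @export
pangraph_config <- function(r1 = 0.95, r2 = 0.98,
                            min_edge_support = 1L,
                            max_gene_edges = 10L,
                            max_distant_loci = 3L,
                            min_gene_freq = 0.05,
                            drop_single_exon = FALSE,
                            locus_merge_distance = 1e5,
                            overlap_min = 0.5,
                            pseudogene_mode = c("default", "strict", "off"),
                            adjust = TRUE,
                            score_tags = c("AS:i", "ms:i"),
                            intron_ops = c("N", "U", "V")) {
  stopifnot(r1 > 0, r1 <= 1, r2 > 0, r2 <= 1,
            min_edge_support >= 0, max_gene_edges >= 0,
            max_distant_loci >= 0, min_gene_freq >= 0)
  list(r1 = r1, r2 = r2, min_edge_support = as.integer(min_edge_support),
       max_gene_edges = max_gene_edges, max_distant_loci = max_distant_loci,
       min_gene_freq = min_gene_freq, drop_single_exon = drop_single_exon,
       locus_merge_distance = locus_merge_distance, overlap_min = overlap_min,
       pseudogene_mode = match.arg(pseudogene_mode), adjust = adjust,
       score_tags = score_tags, intron_ops = intron_ops)
}

#' Build the gene graph from placed hits
#'
#' One walk per contig carrying at least one placed hit; each consecutive
#' pair of placed hits becomes a directed edge (with its skew twin)
#' accumulating `(genome, contig)` support, with edge scores averaged per
#' supporting contig.
#'
#' @param placed placed hit table from [place_hits()] (non-overlapping,
#'   sorted).
#' @param genomes optional character vector of all genome ids.
#' @return a `pangraph`.
#' @export
build_graph <- function(placed, genomes = NULL) {
  if (nrow(placed)) {
    ovl <- overlap_pairs(placed, overlap_min = 1e-9)
    if (nrow(ovl)) stop("placed hits overlap; placement contract violated")
  }
  genes <- sort(unique(placed$gene))
  steps <- data.table(
    genome = placed$genome, contig = placed$contig,
    og = if (nrow(placed)) {
      k <- match(placed$gene, genes)
      ifelse(placed$strand == "+", og_fwd(k), og_rev(k))
    } else integer(0),
    start = placed$tstart, end = placed$tend,
    score = placed$score, n_introns = placed$n_introns,
    hit_id = placed$hit_id)
  graph_from_steps(genes, steps, genomes = genomes)
}

#' Score of a directed edge
#'
#' S(x|y): the mean, over contigs supporting x -> y, of the alignment score
#' of x's placed hit on that contig. The twin view S(flip(y)|flip(x)) is
#' generally different because it averages the other endpoint's scores.
#'
#' @param g a `pangraph`.
#' @param x,y oriented gene strings forming the directed edge `x -> y`.
#' @return numeric score.
#' @export
edge_score <- function(g, x, y) {
  stopifnot(inherits(g, "pangraph"))
  xi <- og_from_str(g$genes, x)
  yi <- og_from_str(g$genes, y)
  cp <- canonical_pair(xi, yi)
  row <- g$edges[src == cp$src & dst == cp$dst]
  if (nrow(row) == 0L) stop("no such edge: ", x, " -> ", y)
  if (length(row$support[[1]]) == 0L) stop("edge has empty support")
  if (cp$swapped) row$score_rv else row$score_fd
}

# directed edge views with scores: one row per direction of each canonical
# edge (palindromic self-twin edges contribute a single view)
directed_edge_views <- function(g) {
  e <- g$edges
  if (nrow(e) == 0L)
    return(data.table(x = integer(), y = integer(), score = numeric(),
                      eid = integer(), support = list()))
  v1 <- data.table(x = e$src, y = e$dst, score = e$score_fd,
                   eid = seq_len(nrow(e)), support = e$support)
  v2 <- data.table(x = og_flip_id(e$dst), y = og_flip_id(e$src), score = e$score_rv,
                   eid = seq_len(nrow(e)), support = e$support)
  out <- rbind(v1, v2)
  out[!duplicated(paste(x, y))]
}

# per-gene contig presence: named list gene -> character vector of
# "genome\tcontig" strings where the gene has a placed step
gene_contigs <- function(g) {
  if (nrow(g$walks) == 0L) return(setNames(vector("list", length(g$genes)), g$genes))
  dd <- unique(data.table(gene = g$genes[og_gene_id(g$walks$og)],
                          gc = paste(g$walks$genome, g$walks$contig, sep = "\t")))
  out <- setNames(vector("list", length(g$genes)), g$genes)
  sp <- split(dd$gc, dd$gene)
  out[names(sp)] <- sp
  out
}

# step row indices of gene(x) occurrences adjacent via directed edge x -> y
# (both the stored direction and the twin direction of the physical walks)
x_side_steps <- function(g, x, y) {
  w <- g$walks
  if (nrow(w) < 2L) return(integer(0))
  idx <- w[, .(i = .I[-.N], j = .I[-1L]), by = .(genome, contig)]
  if (nrow(idx) == 0L) return(integer(0))
  a <- w$og[idx$i]; bkn <- w$og[idx$j]
  hit1 <- idx$i[a == x & bkn == y]                                 # x then y
  hit2 <- idx$j[a == og_flip_id(y) & bkn == og_flip_id(x)]         # twin form
  unique(c(hit1, hit2))
}

#' Mark and remove false edges
#'
#' x -> y is a false edge when some competing edge x -> z exists such that
#' the genes of y and z never share a contig in any input genome and
#' S(x|y) < S(x|z) * r1. Such an edge is evidence that x's gene was aligned
#' to a paralogous locus because its true locus is missing from some
#' assemblies; every placed hit of x's gene incident to a false edge is
#' deleted and the affected walks and edges are rebuilt (adjacency re-joined
#' across the deletions).
#'
#' @param g a `pangraph`.
#' @param cfg a [pangraph_config()].
#' @return the adjusted `pangraph`; deleted `hit_id`s (when known) are
#'   recorded in `meta$removed_hits`.
#' @export
filter_false_edges <- function(g, cfg = pangraph_config()) {
  stopifnot(inherits(g, "pangraph"))
  views <- directed_edge_views(g)
  if (nrow(views) < 2L) return(g)
  gc <- gene_contigs(g)
  drop_steps <- integer(0)
  marked_eid <- integer(0)
  grp <- split(seq_len(nrow(views)), views$x)
  grp <- grp[lengths(grp) >= 2L]
  for (rows in grp) {
    xv <- views$x[rows[1]]
    for (a in rows) {
      ya <- views$y[a]
      for (bkn in rows) {
        if (a == bkn) next
        yb <- views$y[bkn]
        if (og_gene_id(ya) == og_gene_id(yb)) next
        shared <- intersect(gc[[og_gene_id(ya)]], gc[[og_gene_id(yb)]])
        if (length(shared)) next
        if (!is.na(views$score[a]) && !is.na(views$score[bkn]) &&
            views$score[a] < views$score[bkn] * cfg$r1) {
          marked_eid <- c(marked_eid, views$eid[a])
          drop_steps <- c(drop_steps, x_side_steps(g, xv, ya))
          break
        }
      }
    }
  }
  if (!length(drop_steps)) {
    g$edges[marked_eid, false_edge := TRUE]
    return(g)
  }
  removed <- unique(g$walks$hit_id[drop_steps])
  removed <- removed[!is.na(removed)]
  steps <- g$walks[-unique(drop_steps)]
  keep_genes <- sort(unique(g$genes[og_gene_id(steps$og)]))
  steps[, og := remap_og(og, g$genes, keep_genes)]
  g2 <- graph_from_steps(keep_genes, steps, genomes = g$meta$genomes, meta = g$meta)
  g2$meta$removed_hits <- unique(c(g$meta$removed_hits, removed))
  g2
}

# re-index oriented ids from one gene universe to another
remap_og <- function(og, from_genes, to_genes) {
  if (!length(og)) return(integer(0))
  k <- match(from_genes[og_gene_id(og)], to_genes)
  as.integer(ifelse(og_is_fwd(og), og_fwd(k), og_rev(k)))
}

#' Mark low-priority edges and re-annotate
#'
#' x -> y is low priority when a competing x -> z exists with the genes of y
#' and z sharing a contig in some genome and S(x|y) < S(x|z) * r2 - the
#' signature of a gene whose missing true locus drags it onto a paralog's
#' locus. Placed hits of x's gene incident to a low-priority edge inherit
#' the mark; the caller re-runs placement preferring unmarked genes (see
#' [place_hits()]) and rebuilds.
#'
#' @param g a `pangraph`.
#' @param cfg a [pangraph_config()].
#' @return list with the flagged graph (`graph`) and the `hit_id`s to mark
#'   (`low_marks`).
#' @export
mark_low_priority <- function(g, cfg = pangraph_config()) {
  stopifnot(inherits(g, "pangraph"))
  views <- directed_edge_views(g)
  low_hits <- integer(0)
  if (nrow(views) >= 2L) {
    gc <- gene_contigs(g)
    grp <- split(seq_len(nrow(views)), views$x)
    grp <- grp[lengths(grp) >= 2L]
    for (rows in grp) {
      xv <- views$x[rows[1]]
      for (a in rows) {
        ya <- views$y[a]
        for (bkn in rows) {
          if (a == bkn) next
          yb <- views$y[bkn]
          if (og_gene_id(ya) == og_gene_id(yb)) next
          shared <- intersect(gc[[og_gene_id(ya)]], gc[[og_gene_id(yb)]])
          if (!length(shared)) next
          if (!is.na(views$score[a]) && !is.na(views$score[bkn]) &&
              views$score[a] < views$score[bkn] * cfg$r2) {
            g$edges[views$eid[a], low_priority := TRUE]
            st <- x_side_steps(g, xv, ya)
            low_hits <- c(low_hits, g$walks$hit_id[st])
            break
          }
        }
      }
    }
  }
  low_hits <- unique(low_hits[!is.na(low_hits)])
  list(graph = g, low_marks = low_hits)
}

#' Topology-based gene and edge filters
#'
#' Applied in order: (1) remove genes whose bidirected degree exceeds
#' `max_gene_edges`; (2) remove genes placed at more than
#' `max_distant_loci` distinct loci in some genome (same-contig placements
#' closer than `locus_merge_distance` merge into one locus); (3) remove
#' genes present in fewer than `min_gene_freq` of the genomes; (4)
#' optionally remove genes with intronless hits only; (5) prune edges
#' supported by fewer than `min_edge_support` contigs. Walks keep their
#' order with removed genes elided, and adjacency is re-joined across the
#' elisions so pruning cannot fragment chromosomes.
#'
#' @param g a `pangraph`.
#' @param cfg a [pangraph_config()].
#' @return the filtered `pangraph`.
#' @export
apply_gene_filters <- function(g, cfg = pangraph_config()) {
  stopifnot(inherits(g, "pangraph"))
  n_genomes <- max(length(g$meta$genomes), 1L)
  # (1) degree
  deg <- gene_degree(g)
  drop <- names(deg)[deg > cfg$max_gene_edges]
  g <- drop_genes(g, drop)
  # (2) distant loci
  if (nrow(g$walks)) {
    w <- copy(g$walks)[, gene := g$genes[og_gene_id(og)]]
    setorder(w, gene, genome, contig, start)
    w[, newloc := start - shift(end, fill = -Inf) > cfg$locus_merge_distance,
      by = .(gene, genome, contig)]
    loci <- w[, .(nl = sum(newloc)), by = .(gene, genome)][, .(mx = max(nl)), by = gene]
    g <- drop_genes(g, loci$gene[loci$mx > cfg$max_distant_loci])
  }
  # (3) frequency
  if (nrow(g$walks)) {
    pres <- unique(data.table(gene = g$genes[og_gene_id(g$walks$og)],
                              genome = g$walks$genome))[, .N, by = gene]
    g <- drop_genes(g, pres$gene[pres$N / n_genomes < cfg$min_gene_freq])
  }
  # (4) single-coding-exon genes
  if (cfg$drop_single_exon && nrow(g$walks)) {
    intr <- g$walks[, .(any_spliced = any(n_introns >= 1L, na.rm = TRUE),
                        known = any(!is.na(n_introns))),
                    by = .(gene = g$genes[og_gene_id(og)])]
    g <- drop_genes(g, intr$gene[intr$known & !intr$any_spliced])
  }
  # (5) weakly supported edges (walks retain their order)
  if (nrow(g$edges)) {
    keep <- lengths(g$edges$support) >= cfg$min_edge_support
    g <- new_pangraph(g$genes, g$edges[keep], g$walks, g$meta)
  }
  g
}

# remove genes entirely: steps elided, walks re-joined, edges rebuilt
drop_genes <- function(g, genes_out) {
  if (!length(genes_out)) return(g)
  keep_genes <- setdiff(g$genes, genes_out)
  steps <- g$walks[!(g$genes[og_gene_id(og)] %in% genes_out)]
  steps[, og := remap_og(og, g$genes, keep_genes)]
  graph_from_steps(keep_genes, steps, genomes = g$meta$genomes, meta = g$meta)
}
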