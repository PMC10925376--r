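## Presence/absence and copy-number summaries derived from walks.

#' Gene-by-genome copy-number matrix
#'
#' Counts, for every gene and genome, the number of walk steps of the gene
#' across the genome's contigs (post-filter annotation, not raw hits).
#'
#' @param g a `pangraph`.
#' @return integer matrix, genes in rows (graph gene order), genomes in
#'   columns (`meta$genomes` order).
#' @examples
#' presence_matrix(toy_graph("TOY3"))
#' @export
presence_matrix <- function(g) {
  stopifnot(inherits(g, "pangraph"))
  genomes <- g$meta$genomes
  m <- matrix(0L, nrow = length(g$genes), ncol = length(genomes),
              dimnames = list(g$genes, genomes))
  if (nrow(g$walks)) {
    tab <- g$walks[, .N, by = .(k = og_gene_id(og), genome)]
    m[cbind(tab$k, match(tab$genome, genomes))] <- tab$N
  }
  m
}

#' Classify genes as core or accessory
#'
#' A gene is core when it is present (at least one copy) in at least
#' `core_threshold` of the genomes; it must be present somewhere to qualify.
#'
#' @param m copy matrix from [presence_matrix()].
#' @param core_threshold presence fraction in `[0, 1]`; the boundary is
#'   inclusive.
#' @return named character vector (`"core"`/`"accessory"`) over genes.
#' @export
classify_core <- function(m, core_threshold = 0.99) {
  if (!is.numeric(core_threshold) || length(core_threshold) != 1L ||
      is.na(core_threshold) || core_threshold < 0 || core_threshold > 1)
    stop("core_threshold must be a fraction in [0, 1]")
  npres <- rowSums(m >= 1L)
  frac <- if (ncol(m)) npres / ncol(m) else rep(0, nrow(m))
  setNames(ifelse(npres >= 1L & frac >= core_threshold, "core", "accessory"),
           rownames(m))
}

#' Report presence/absence variable genes
#'
#' Lists genes present in at most `min_freq` of the genomes, optionally
#' restricted to genes with evidence of splicing (single-coding-exon genes
#' are frequent pseudogene artefacts). Intron evidence is taken from the
#' walk steps; genes whose intron status is unknown (e.g. graphs read from
#' GFA) are kept.
#'
#' @param m copy matrix from [presence_matrix()].
#' @param g the `pangraph` the matrix came from (for intron evidence); may
#'   be `NULL`, in which case `multi_exon_only` keeps everything.
#' @param min_freq maximum presence fraction for a gene to be reported.
#' @param multi_exon_only restrict to genes with at least one spliced hit.
#' @return `data.frame` with columns `gene`, `n_present`, `fraction`,
#'   `copy_min`, `copy_max`, sorted by fraction then gene.
#' @export
pav_report <- function(m, g = NULL, min_freq = 0.5, multi_exon_only = TRUE) {
  npres <- rowSums(m >= 1L)
  frac <- if (ncol(m)) npres / ncol(m) else rep(0, nrow(m))
  keep <- frac <= min_freq
  if (multi_exon_only && !is.null(g) && nrow(g$walks)) {
    intr <- g$walks[, .(any_spliced = any(n_introns >= 1L, na.rm = TRUE),
                        known = any(!is.na(n_introns))),
                    by = .(gene = g$genes[og_gene_id(og)])]
    single <- intr$gene[intr$known & !intr$any_spliced]
    keep <- keep & !(rownames(m) %in% single)
  }
  out <- data.frame(gene = rownames(m)[keep],
                    n_present = unname(npres[keep]),
                    fraction = unname(frac[keep]),
                    copy_min = if (any(keep)) apply(m[keep, , drop = FALSE], 1, min) else integer(0),
                    copy_max = if (any(keep)) apply(m[keep, , drop = FALSE], 1, max) else integer(0),
                    row.names = NULL)
  out[order(out$fraction, out$gene), , drop = FALSE]
}

#' Write the presence/copy table as TSV
#'
#' One row per gene: copy count per genome and the core/accessory class.
#'
#' @param g a `pangraph`.
#' @param path output path.
#' @param core_threshold see [classify_core()].
#' @return invisibly, the path.
#' @export
write_presence_tsv <- function(g, path, core_threshold = 0.99) {
  m <- presence_matrix(g)
  cls <- classify_core(m, core_threshold)
  out <- data.table(gene = rownames(m))
  for (j in colnames(m)) out[[j]] <- m[, j]
  out[["class"]] <- unname(cls)
  fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
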