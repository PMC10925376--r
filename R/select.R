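## Turning raw protein-to-genome hits into a consistent per-genome gene
## annotation: pseudogene suppression, one protein per gene, best hits,
## the b(v) count and the greedy non-orthologous gene selection, and the
## per-contig placement of non-overlapping hits.

# interval overlap pairs within (genome, contig): rows i, j of `dt`
# (1-row-per-hit) whose intervals intersect by at least `overlap_min` of the
# shorter interval. Returns a data.table with columns i, j (i != j, both
# directions present).
overlap_pairs <- function(dt, overlap_min = 0.5) {
  if (nrow(dt) < 2L) return(data.table(i = integer(), j = integer()))
  a <- data.table(row = seq_len(nrow(dt)), genome = dt$genome, contig = dt$contig,
                  s = dt$tstart, e = dt$tend)
  setkey(a, genome, contig, s, e)
  ov <- foverlaps(a, a, type = "any", which = TRUE)
  ov <- ov[xid != yid]
  if (nrow(ov) == 0L) return(data.table(i = integer(), j = integer()))
  i <- a$row[ov$xid]; j <- a$row[ov$yid]
  inter <- pmin(dt$tend[i], dt$tend[j]) - pmax(dt$tstart[i], dt$tstart[j])
  shorter <- pmin(dt$tend[i] - dt$tstart[i], dt$tend[j] - dt$tstart[j])
  keep <- inter > 0 & inter >= overlap_min * shorter
  data.table(i = i[keep], j = j[keep])
}

# TRUE where hit a beats hit b: higher score, ties by FNV-1a of the gene name
beats <- function(score_a, gene_a, score_b, gene_b) {
  score_a > score_b | (score_a == score_b & fnv1a64(gene_a) < fnv1a64(gene_b))
}

#' Suppress putative processed-pseudogene alignments
#'
#' An alignment without splicing is suspect when the same gene aligns with
#' splicing elsewhere: in `"default"` mode such intronless hits are dropped
#' for genes that have at least one spliced hit in any genome; `"strict"`
#' additionally removes every gene lacking a spliced hit anywhere (intended
#' for spliced genomes only); `"off"` keeps everything (the right setting
#' for bacteria, where no hit is spliced).
#'
#' @param hits hit table from [read_paf()]/[read_paf_set()].
#' @param mode one of `"default"`, `"strict"`, `"off"`.
#' @return filtered hit table.
#' @export
filter_pseudogene_hits <- function(hits, mode = c("default", "strict", "off")) {
  mode <- match.arg(mode)
  if (mode == "off" || nrow(hits) == 0L) return(hits)
  spliced_genes <- unique(hits$gene[hits$n_introns >= 1L])
  if (mode == "strict") hits <- hits[gene %in% spliced_genes]
  hits[!(n_introns == 0L & gene %in% spliced_genes)]
}

#' Retain one protein per gene
#'
#' When several proteins share a gene id, the protein maximising the sum
#' over genomes of its best-hit score is kept and all hits of the others are
#' dropped. Ties go to the protein with the smaller FNV-1a digest.
#'
#' @param hits hit table.
#' @return hit table restricted to the chosen protein of each gene.
#' @export
choose_protein_per_gene <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  per <- hits[, .(best = max(score)), by = .(gene, protein, genome)]
  tot <- per[, .(total = sum(best)), by = .(gene, protein)]
  tot[, h := fnv1a64(protein)]
  setorder(tot, gene, -total, h)
  chosen <- tot[tot[, .I[1L], by = gene]$V1]
  hits[protein %in% chosen$protein]
}

#' Best hit of each gene in each genome
#'
#' @param hits hit table (one protein per gene).
#' @return hit table with one row per (gene, genome): the highest-scoring
#'   hit, ties broken by the FNV-1a digest of (gene, contig, tstart).
#' @export
best_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  h <- copy(hits)
  h[, tiekey := fnv1a64(paste(gene, contig, tstart, sep = "\t"))]
  setorder(h, gene, genome, -score, tiekey)
  out <- h[h[, .I[1L], by = .(gene, genome)]$V1]
  out[, tiekey := NULL]
  setcolorder(out, names(hits))
  out[]
}

#' Count genomes where a gene out-scores all overlapping competitors
#'
#' For each gene v, b(v) is the number of genomes in which v's best hit is
#' aligned better than the best hit of every other gene overlapping it
#' (interval intersection of at least `overlap_min` of the shorter
#' interval; score ties resolved by gene-name hash).
#'
#' @param best best-hit table from [best_hits()].
#' @param overlap_min minimum intersection fraction of the shorter interval.
#' @return named integer vector over genes.
#' @export
compute_b <- function(best, overlap_min = 0.5) {
  genes <- sort(unique(best$gene))
  b <- setNames(integer(length(genes)), genes)
  if (nrow(best) == 0L) return(b)
  pres <- best[, .N, by = gene]
  b[pres$gene] <- pres$N
  ov <- overlap_pairs(best, overlap_min)
  if (nrow(ov)) {
    lost <- beats(best$score[ov$j], best$gene[ov$j], best$score[ov$i], best$gene[ov$i])
    beaten <- unique(data.table(gene = best$gene[ov$i][lost],
                                genome = best$genome[ov$i][lost]))
    if (nrow(beaten)) {
      dec <- beaten[, .N, by = gene]
      b[dec$gene] <- b[dec$gene] - dec$N
    }
  }
  b
}

#' Greedy selection of non-orthologous genes
#'
#' Processes genes in descending order of the current b(v) (ties by gene
#' hash). A popped gene with b(v) > 0 is selected, and every gene w whose
#' best mapping overlaps v's best mapping in some genome while out-scoring
#' it loses one count of b(w) per such genome (floored at zero). Genes
#' popped at b(v) = 0 are rejected. Orthologs, which share loci, collapse to
#' one representative; paralogs at distinct loci are all selected.
#'
#' @param best best-hit table from [best_hits()].
#' @param overlap_min minimum intersection fraction of the shorter interval.
#' @param b optional precomputed [compute_b()] result.
#' @return character vector of selected genes, in selection order.
#' @export
select_genes <- function(best, overlap_min = 0.5, b = NULL) {
  if (nrow(best) == 0L) return(character(0))
  if (is.null(b)) b <- compute_b(best, overlap_min)
  genes <- names(b)
  n <- length(genes)
  hrank <- fnv_rank(genes)
  ov <- overlap_pairs(best, overlap_min)
  # decrement triggers: selecting gene(i-side) decrements gene(j-side) once
  # per genome where j overlaps i and beats it
  trig <- NULL
  if (nrow(ov)) {
    wb <- beats(best$score[ov$j], best$gene[ov$j], best$score[ov$i], best$gene[ov$i])
    trig <- unique(data.table(sel = best$gene[ov$i][wb],
                              loser = best$gene[ov$j][wb],
                              genome = best$genome[ov$i][wb]))
  }
  trig_by_sel <- if (!is.null(trig) && nrow(trig)) split(trig$loser, trig$sel) else list()
  bv <- unname(b[genes])
  # selection priority: larger current b first, then smaller hash; processed
  # genes drop out of the queue by taking a negative key
  keybase <- (n + 1L) - hrank
  key <- as.numeric(bv) * (n + 1L) + keybase
  selected <- character(0)
  for (iter in seq_len(n)) {
    v <- which.max(key)
    if (key[v] < 0) break
    if (bv[v] > 0L) {
      selected <- c(selected, genes[v])
      losers <- trig_by_sel[[genes[v]]]
      if (!is.null(losers)) {
        wi <- match(losers, genes)
        for (w in wi) {
          if (bv[w] > 0L) {
            bv[w] <- bv[w] - 1L
            if (key[w] >= 0) key[w] <- as.numeric(bv[w]) * (n + 1L) + keybase[w]
          }
        }
      }
    }
    key[v] <- -1
  }
  selected
}

#' Place non-overlapping hits of the selected genes on each contig
#'
#' Greedy per-contig annotation: hits are taken in priority order (unmarked
#' before low-priority-marked, then score, then hash) and accepted when they
#' do not overlap an already-accepted hit. A gene may be placed several
#' times on a contig (tandem copies) and on several contigs.
#'
#' @param hits hit table restricted to selected genes.
#' @param overlap_min minimum intersection fraction of the shorter interval
#'   for two hits to conflict.
#' @param low_marks integer vector of `hit_id`s carrying the low-priority
#'   mark.
#' @return the accepted subset of `hits`, ordered by genome, contig, tstart.
#' @export
place_hits <- function(hits, overlap_min = 0.5, low_marks = integer(0)) {
  if (nrow(hits) == 0L) return(hits)
  h <- copy(hits)
  h[, marked := hit_id %in% low_marks]
  h[, h64 := fnv1a64(paste(gene, contig, tstart, sep = "\t"))]
  ov <- overlap_pairs(h, overlap_min)
  accepted <- logical(nrow(h))
  if (nrow(ov) == 0L) {
    accepted[] <- TRUE
  } else {
    conflict <- vector("list", nrow(h))
    sp <- split(ov$j, ov$i)
    conflict[as.integer(names(sp))] <- sp
    has_cf <- lengths(conflict) > 0L
    accepted[!has_cf] <- TRUE        # unconflicted hits always place
    ord <- order(h$marked, -h$score, h$h64)
    for (i in ord[has_cf[ord]]) {
      if (!any(accepted[conflict[[i]]])) accepted[i] <- TRUE
    }
  }
  out <- h[accepted]
  out[, c("marked", "h64") := NULL]
  setorder(out, genome, contig, tstart, tend)
  out[]
}
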