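## Targeted alignment-level fixtures for selection and edge-adjustment
## behaviour: an ortholog pair competing for one locus, and the
## chromosome-loss scenario where a gene without its true locus is dragged
## onto a paralogous locus on another chromosome.

mk_hit <- function(protein, genome, contig, tstart, tend, strand = "+",
                   score = 500, n_introns = 1L) {
  sp <- split_protein_name(protein)
  data.table(hit_id = NA_integer_, protein = sp$protein, gene = sp$gene,
             genome = genome, contig = contig,
             tstart = as.numeric(tstart), tend = as.numeric(tend),
             strand = strand, score = as.numeric(score),
             n_introns = as.integer(n_introns),
             identity = 0.97, qcov = 1.0)
}

#' Simulate an ortholog pair competing for one locus
#'
#' Two input genes (`ORTA`, `ORTB`) representing alleles of the same gene
#' align to the same locus in every genome, `ORTA` scoring higher in the
#' odd-numbered genomes and `ORTB` in the even-numbered ones, between two
#' anchor genes. A consistent annotation selects exactly one of them.
#'
#' @param n_genomes number of genomes.
#' @return list with the hit table (`hits`) and the competing gene ids
#'   (`pair`).
#' @export
simulate_ortholog_pair <- function(n_genomes = 4L) {
  rows <- list()
  for (i in seq_len(n_genomes)) {
    gm <- sprintf("genome%02d", i)
    sa <- if (i %% 2L == 1L) 500 else 490
    sb <- if (i %% 2L == 1L) 490 else 500
    rows[[length(rows) + 1L]] <- rbind(
      mk_hit("ANC1", gm, "c1", 0, 1000),
      mk_hit("ORTA", gm, "c1", 11000, 12000, score = sa),
      mk_hit("ORTB", gm, "c1", 11000, 12000, score = sb),
      mk_hit("ANC2", gm, "c1", 22000, 23000))
  }
  hits <- rbindlist(rows)
  hits[, hit_id := seq_len(.N)]
  list(hits = hits, pair = c("ORTA", "ORTB"))
}

#' Simulate a chromosome-loss scenario
#'
#' Gene `MX` lives between `X1` and `X2` on chromosome X, which only some
#' genomes carry. In every genome `MX` also has a weaker hit (93% of the
#' true score) at an empty locus between `A2` and `A3` on an autosome
#' present everywhere. Genomes without chromosome X place `MX` on the
#' autosome, creating spurious cross-chromosome edges that the false-edge
#' filter at its default ratio removes; the cleaned graph equals the truth
#' graph in which `MX` exists only on chromosome X.
#'
#' @param n_genomes number of genomes.
#' @param n_with_x how many genomes carry chromosome X.
#' @return list with the hit table (`hits`), the truth graph (`truth`) and
#'   the focal gene id (`gene`).
#' @export
simulate_chrx_loss <- function(n_genomes = 6L, n_with_x = 3L) {
  stopifnot(n_with_x >= 1L, n_with_x <= n_genomes)
  rows <- list()
  tw <- list()
  for (i in seq_len(n_genomes)) {
    gm <- sprintf("genome%02d", i)
    auto <- rbind(
      mk_hit("A1", gm, "chrA", 0, 1000),
      mk_hit("A2", gm, "chrA", 11000, 12000),
      mk_hit("MX", gm, "chrA", 22000, 23000, score = 465),
      mk_hit("A3", gm, "chrA", 33000, 34000),
      mk_hit("A4", gm, "chrA", 44000, 45000))
    rows[[length(rows) + 1L]] <- auto
    tw[[length(tw) + 1L]] <- list(genome = gm, contig = "chrA",
                                  steps = c(">A1", ">A2", ">A3", ">A4"))
    if (i <= n_with_x) {
      rows[[length(rows) + 1L]] <- rbind(
        mk_hit("X1", gm, "chrX", 0, 1000),
        mk_hit("MX", gm, "chrX", 11000, 12000, score = 500),
        mk_hit("X2", gm, "chrX", 22000, 23000))
      tw[[length(tw) + 1L]] <- list(genome = gm, contig = "chrX",
                                    steps = c(">X1", ">MX", ">X2"))
    }
  }
  hits <- rbindlist(rows)
  hits[, hit_id := seq_len(.N)]
  list(hits = hits, truth = pangraph_from_walks(tw), gene = "MX")
}
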