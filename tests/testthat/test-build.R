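library(data.table)

toy_placed <- function(walks) {
  # walks: list of list(genome, contig, genes, strands, scores)
  rows <- lapply(walks, function(w) {
    n <- length(w$genes)
    data.table(hit_id = NA_integer_, protein = w$genes, gene = w$genes,
               genome = w$genome, contig = w$contig,
               tstart = (seq_len(n) - 1) * 1000, tend = (seq_len(n) - 1) * 1000 + 500,
               strand = if (is.null(w$strands)) rep("+", n) else w$strands,
               score = if (is.null(w$scores)) rep(500, n) else w$scores,
               n_introns = 1L, identity = 0.97, qcov = 1)
  })
  out <- rbindlist(rows)
  out[, hit_id := seq_len(.N)]
  out
}

test_that("build_graph derives walks, edges and supports from placed hits", {
  placed <- toy_placed(list(
    list(genome = "g1", contig = "c1", genes = c("A", "B", "C")),
    list(genome = "g2", contig = "c2", genes = c("A", "C"))))
  g <- build_graph(placed)
  expect_identical(edge_strings(g), c(">A >B", ">A >C", ">B >C"))
  sup <- g$edges$support[[which(edge_strings(g) == ">A >C")]]
  expect_identical(sup, "g2\tc2")
  # single-gene contig: walk but no edges
  g1 <- build_graph(toy_placed(list(list(genome = "g", contig = "c", genes = "A"))))
  expect_identical(nrow(g1$edges), 0L)
  expect_identical(nrow(g1$walks), 1L)
  # tandem pair gives a self-edge
  g3 <- build_graph(toy_placed(list(
    list(genome = "g1", contig = "c1", genes = c("A", "B", "C")),
    list(genome = "g2", contig = "c2", genes = c("A", "B", "B", "C")))))
  expect_true(">B >B" %in% edge_strings(g3))
  # overlapping placed hits violate the contract
  bad <- toy_placed(list(list(genome = "g", contig = "c", genes = c("A", "B"))))
  bad$tstart <- c(0, 100); bad$tend <- c(500, 600)
  expect_error(build_graph(bad), "overlap")
})

test_that("edge_score averages the source gene's score over supporting contigs", {
  placed <- toy_placed(list(
    list(genome = "g1", contig = "c1", genes = c("X", "Y"), scores = c(100, 700)),
    list(genome = "g2", contig = "c2", genes = c("X", "Y"), scores = c(90, 500))))
  g <- build_graph(placed)
  expect_equal(edge_score(g, ">X", ">Y"), 95)        # (100+90)/2
  expect_equal(edge_score(g, "<Y", "<X"), 600)       # twin averages Y's scores
  one <- build_graph(toy_placed(list(
    list(genome = "g1", contig = "c1", genes = c("X", "Y"), scores = c(480, 300)))))
  expect_equal(edge_score(one, ">X", ">Y"), 480)
  expect_error(edge_score(g, ">Y", ">X"), "no such edge")
})

test_that("filter_false_edges applies the score-ratio and contig conditions", {
  cx <- simulate_chrx_loss(6, 3)
  sel <- select_genes(best_hits(cx$hits))
  g0 <- build_graph(place_hits(cx$hits[gene %in% sel]))
  g1 <- filter_false_edges(g0, pangraph_config(r1 = 0.95))
  expect_identical(edge_strings(g1), edge_strings(cx$truth))
  expect_identical(walk_strings(g1), walk_strings(cx$truth))
  # idempotence: a second pass changes nothing
  g2 <- filter_false_edges(g1, pangraph_config(r1 = 0.95))
  expect_identical(edge_strings(g2), edge_strings(g1))
  expect_identical(walk_strings(g2), walk_strings(g1))
  # score ratio 0.96/1.0 survives at r1 = 0.95 (96 >= 95)
  cx2 <- simulate_chrx_loss(6, 3)
  cx2$hits[gene == "MX" & contig == "chrA", score := 480]  # 0.96 of 500
  g3 <- filter_false_edges(build_graph(place_hits(cx2$hits)), pangraph_config())
  expect_true(">A2 >MX" %in% edge_strings(g3))
  # genes co-occurring on a contig are never false regardless of scores
  gco <- build_graph(toy_placed(list(
    list(genome = "g1", contig = "c1", genes = c("X", "Y"), scores = c(50, 500)),
    list(genome = "g1", contig = "c2", genes = c("X", "Z"), scores = c(500, 500)),
    list(genome = "g1", contig = "c3", genes = c("Y", "Z"), scores = c(500, 500)))))
  g4 <- filter_false_edges(gco, pangraph_config())
  expect_identical(edge_strings(g4), edge_strings(gco))
})

test_that("mark_low_priority marks weaker same-locus-competing edges", {
  # >X -> >Y (S = 480) vs >X -> >Z (S = 500): Y and Z share contig c3, and
  # 480 < 500 * 0.98, so X's hit on c1 inherits the low-priority mark
  placed <- toy_placed(list(
    list(genome = "g1", contig = "c1", genes = c("X", "Y"), scores = c(480, 500)),
    list(genome = "g1", contig = "c2", genes = c("X", "Z"), scores = c(500, 500)),
    list(genome = "g1", contig = "c3", genes = c("Y", "Z"), scores = c(500, 500))))
  g <- build_graph(placed)
  lp <- mark_low_priority(g, pangraph_config(r2 = 0.98))
  expect_true(any(lp$graph$edges$low_priority))
  marked <- g$walks$hit_id[pangraph:::x_side_steps(
    g, pangraph:::og_from_str(g$genes, ">X"), pangraph:::og_from_str(g$genes, ">Y"))]
  expect_true(all(marked %in% lp$low_marks))
  # at 490/500 the ratio clears r2 and nothing is marked
  placed2 <- copy(placed)[contig == "c1" & gene == "X", score := 491]
  lp2 <- mark_low_priority(build_graph(placed2), pangraph_config(r2 = 0.98))
  expect_identical(length(lp2$low_marks), 0L)
  # no competing out-edge: no mark
  lone <- build_graph(toy_placed(list(
    list(genome = "g1", contig = "c1", genes = c("X", "Y"), scores = c(100, 500)))))
  expect_identical(length(mark_low_priority(lone, pangraph_config())$low_marks), 0L)
})

test_that("gene filters remove by degree, support and frequency, re-joining walks", {
  g3 <- build_graph(toy_placed(list(
    list(genome = "g1", contig = "c1", genes = c("A", "B", "C")),
    list(genome = "g2", contig = "c2", genes = c("A", "C")))))
  # min_edge_support = 2 prunes all single-contig edges but keeps walks
  gf <- apply_gene_filters(g3, pangraph_config(min_edge_support = 2L, min_gene_freq = 0))
  expect_identical(nrow(gf$edges), 0L)
  expect_identical(length(gf$genes), 3L)
  # frequency filter: B present in 1/2 genomes < 0.6 is removed and the walk
  # re-joined, creating A -> C with the elided contig's support
  gfr <- apply_gene_filters(g3, pangraph_config(min_gene_freq = 0.6))
  expect_identical(gfr$genes, c("A", "C"))
  expect_identical(edge_strings(gfr), ">A >C")
  expect_identical(walk_strings(gfr), c(">A >C", ">A >C"))
  # a hub gene exceeding the degree cap is dropped
  hub <- build_graph(toy_placed(lapply(1:12, function(i)
    list(genome = paste0("g", i), contig = paste0("c", i),
         genes = c(paste0("L", i), "HUB", paste0("R", i))))))
  gh <- apply_gene_filters(hub, pangraph_config(max_gene_edges = 10, min_gene_freq = 0))
  expect_false("HUB" %in% gh$genes)
  # threshold mirroring "-p.001": no frequency removals
  gp <- apply_gene_filters(g3, pangraph_config(min_gene_freq = 0.001))
  expect_identical(length(gp$genes), 3L)
})

test_that("distant-loci and single-exon filters act on placements", {
  # one gene placed at two far loci in one genome, max_distant_loci = 1
  placed <- toy_placed(list(
    list(genome = "g1", contig = "c1", genes = c("A", "M", "B")),
    list(genome = "g1", contig = "c2", genes = c("D", "M", "E"))))
  g <- build_graph(placed)
  gl <- apply_gene_filters(g, pangraph_config(max_distant_loci = 1, min_gene_freq = 0))
  expect_false("M" %in% gl$genes)
  gl2 <- apply_gene_filters(g, pangraph_config(max_distant_loci = 3, min_gene_freq = 0))
  expect_true("M" %in% gl2$genes)
  # drop_single_exon removes intronless genes
  p2 <- toy_placed(list(list(genome = "g1", contig = "c1", genes = c("A", "S", "B"))))
  p2[gene == "S", n_introns := 0L]
  gs <- apply_gene_filters(build_graph(p2),
                           pangraph_config(drop_single_exon = TRUE, min_gene_freq = 0))
  expect_false("S" %in% gs$genes)
})

test_that("skew symmetry and walk consistency survive every filter", {
  for (s in c(2, 5, 8)) {
    g <- random_truth_graph(s)
    for (cfg in list(pangraph_config(min_edge_support = 2L, min_gene_freq = 0),
                     pangraph_config(max_gene_edges = 4, min_gene_freq = 0),
                     pangraph_config(min_gene_freq = 0.4))) {
      gf <- apply_gene_filters(g, cfg)
      expect_true(pangraph:::check_pangraph(gf))
    }
  }
})
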