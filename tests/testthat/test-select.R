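library(data.table)

test_that("choose_protein_per_gene keeps the best-total protein", {
  # p1 best scores 100,100; p2 90,120: 210 > 200 so p2 wins
  h <- rbindlist(list(
    hit_row("G:p1", "g1", "c", 0, 100, score = 100),
    hit_row("G:p1", "g2", "c", 0, 100, score = 100),
    hit_row("G:p2", "g1", "c", 0, 100, score = 90),
    hit_row("G:p2", "g2", "c", 0, 100, score = 120)))
  h[, hit_id := seq_len(.N)]
  out <- choose_protein_per_gene(h)
  expect_identical(unique(out$protein), "G:p2")
  # single protein: identity
  h1 <- h[protein == "G:p1"]
  expect_identical(choose_protein_per_gene(h1), h1)
  # equal sums: smaller protein hash wins, deterministically
  he <- rbindlist(list(
    hit_row("G:pa", "g1", "c", 0, 100, score = 100),
    hit_row("G:pb", "g1", "c", 0, 100, score = 100)))
  he[, hit_id := seq_len(.N)]
  want <- if (fnv1a64("G:pa") < fnv1a64("G:pb")) "G:pa" else "G:pb"
  expect_identical(unique(choose_protein_per_gene(he)$protein), want)
})

test_that("best_hits takes the top-scoring hit per gene and genome", {
  h <- rbindlist(list(
    hit_row("v", "g1", "c", 0, 100, score = 300),
    hit_row("v", "g1", "c", 5000, 5100, score = 280),
    hit_row("v", "g2", "c", 0, 100, score = 250)))
  h[, hit_id := seq_len(.N)]
  b <- best_hits(h)
  expect_identical(nrow(b), 2L)
  expect_identical(b[b$genome == "g1"]$score, 300)
  # absent gene/genome pairs simply have no entry
  expect_false(any(b$genome == "g3"))
  # tie: stable deterministic pick
  ht <- rbindlist(list(
    hit_row("v", "g1", "c", 0, 100, score = 300),
    hit_row("v", "g1", "c", 9000, 9100, score = 300)))
  ht[, hit_id := seq_len(.N)]
  expect_identical(best_hits(ht)$tstart, best_hits(ht)$tstart)
})

test_that("compute_b counts genomes where a gene wins its locus", {
  # v alone in all 3 genomes
  h <- rbindlist(lapply(1:3, function(i) hit_row("v", paste0("g", i), "c", 0, 100)))
  h[, hit_id := seq_len(.N)]
  expect_identical(compute_b(best_hits(h)), c(v = 3L))
  # orthologs v, w overlapping in 3 genomes, v better in 1
  h2 <- rbindlist(lapply(1:3, function(i) rbind(
    hit_row("v", paste0("g", i), "c", 0, 100, score = if (i == 1) 500 else 400),
    hit_row("w", paste0("g", i), "c", 0, 100, score = if (i == 1) 450 else 480))))
  h2[, hit_id := seq_len(.N)]
  b <- compute_b(best_hits(h2))
  expect_identical(b[["v"]], 1L)
  expect_identical(b[["w"]], 2L)
  # different contigs everywhere: no competition
  h3 <- rbindlist(lapply(1:3, function(i) rbind(
    hit_row("v", paste0("g", i), "c1", 0, 100),
    hit_row("w", paste0("g", i), "c2", 0, 100))))
  h3[, hit_id := seq_len(.N)]
  expect_identical(unname(compute_b(best_hits(h3))), c(3L, 3L))
})

test_that("select_genes collapses orthologs and keeps paralogs", {
  h2 <- rbindlist(lapply(1:3, function(i) rbind(
    hit_row("v", paste0("g", i), "c", 0, 100, score = if (i == 1) 500 else 400),
    hit_row("w", paste0("g", i), "c", 0, 100, score = if (i == 1) 450 else 480))))
  h2[, hit_id := seq_len(.N)]
  expect_identical(select_genes(best_hits(h2)), "w")
  # paralogs at distinct loci: both
  h3 <- rbindlist(lapply(1:2, function(i) rbind(
    hit_row("v", paste0("g", i), "c", 0, 100),
    hit_row("w", paste0("g", i), "c", 50000, 50100))))
  h3[, hit_id := seq_len(.N)]
  expect_setequal(select_genes(best_hits(h3)), c("v", "w"))
  # a gene always outscored everywhere is rejected
  h4 <- rbindlist(list(
    hit_row("v", "g1", "c", 0, 100, score = 500),
    hit_row("u", "g1", "c", 0, 100, score = 400)))
  h4[, hit_id := seq_len(.N)]
  expect_identical(select_genes(best_hits(h4)), "v")
})

test_that("selection is deterministic and unaffected by isolated additions", {
  op <- simulate_ortholog_pair(6)
  b1 <- select_genes(best_hits(op$hits))
  b2 <- select_genes(best_hits(op$hits))
  expect_identical(b1, b2)
  # adding a gene overlapping nothing cannot change existing statuses
  extra <- hit_row("LONER", "genome01", "c9", 0, 100)
  extra[, hit_id := max(op$hits$hit_id) + 1L]
  b3 <- select_genes(best_hits(rbind(op$hits, extra)))
  expect_setequal(setdiff(b3, "LONER"), b1)
})

test_that("filter_pseudogene_hits implements default, strict and off modes", {
  h <- rbindlist(list(
    hit_row("v", "g1", "c", 0, 100, n_introns = 2L),
    hit_row("v", "g2", "c", 0, 100, n_introns = 0L),   # unspliced copy of a spliced gene
    hit_row("solo", "g1", "c", 5000, 5100, n_introns = 0L)))
  h[, hit_id := seq_len(.N)]
  def <- filter_pseudogene_hits(h, "default")
  expect_identical(nrow(def), 2L)
  expect_false(any(def$gene == "v" & def$n_introns == 0L))
  expect_true(any(def$gene == "solo"))                 # no spliced hit exists: kept
  strict <- filter_pseudogene_hits(h, "strict")
  expect_false(any(strict$gene == "solo"))
  expect_identical(filter_pseudogene_hits(h, "off"), h)
  # bacterial run: everything intronless, default keeps all
  hb <- rbindlist(list(hit_row("a", "g1", "c", 0, 100, n_introns = 0L),
                       hit_row("b", "g1", "c", 500, 600, n_introns = 0L)))
  hb[, hit_id := seq_len(.N)]
  expect_identical(filter_pseudogene_hits(hb, "default"), hb)
})

test_that("place_hits keeps non-overlapping hits and honours marks", {
  h <- rbindlist(list(
    hit_row("a", "g1", "c", 0, 100, score = 500),
    hit_row("b", "g1", "c", 50, 150, score = 400),    # overlaps a: displaced
    hit_row("c", "g1", "c", 500, 600, score = 300)))
  h[, hit_id := seq_len(.N)]
  p <- place_hits(h)
  expect_setequal(p$gene, c("a", "c"))
  # low-priority mark flips the preference at the contested locus
  p2 <- place_hits(h, low_marks = 1L)
  expect_setequal(p2$gene, c("b", "c"))
})
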