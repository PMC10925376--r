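library(data.table)

test_that("zero event rates give identical genomes and no expected bubbles", {
  tr <- simulate_pangenome(sim_config(p_del = 0, p_inv = 0, p_dup = 0,
                                      n_genomes = 4L, seed = 9L))
  expect_identical(nrow(tr$events), 0L)
  expect_identical(nrow(tr$expected_bubbles), 0L)
  g <- truth_graph(tr)
  ws <- walk_strings(g)
  expect_identical(length(unique(sub("^.*? ", "", ws))), length(unique(ws)))
  expect_identical(nrow(find_bibubbles(g)), 0L)
  expect_true(all(tr$copies == 1L))
})

test_that("an isolated deletion expects its flanking forward pair", {
  events <- data.table(genome = "genome02", type = "del",
                       s = 5L, e = 5L, k = 0L, chrom = 1L)
  eb <- pangraph:::derive_expected_bubbles(
    events, c("genome01", "genome02"), sprintf("g%05d", 1:10), rep(1L, 10))
  expect_identical(nrow(eb), 1L)
  expect_identical(eb$entrance, ">g00004")
  expect_identical(eb$exit, ">g00006")
  expect_identical(eb$interior[[1]], "g00005")
  # identical local haplotypes in every genome are no variation
  ev2 <- rbind(events, data.table(genome = "genome01", type = "del",
                                  s = 5L, e = 5L, k = 0L, chrom = 1L))
  eb2 <- pangraph:::derive_expected_bubbles(
    ev2, c("genome01", "genome02"), sprintf("g%05d", 1:10), rep(1L, 10))
  expect_identical(nrow(eb2), 0L)
})

test_that("the same seed reproduces the simulation and its PAF byte for byte", {
  cfg <- sim_config(n_genes = 60L, n_genomes = 4L, paralog_families = 2L, seed = 13L)
  t1 <- simulate_pangenome(cfg)
  t2 <- simulate_pangenome(cfg)
  expect_identical(t1$walks, t2$walks)
  expect_identical(t1$events, t2$events)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- emit_paf(t1, d1); p2 <- emit_paf(t2, d2)
  for (i in seq_along(p1)) expect_identical(readLines(p1[i]), readLines(p2[i]))
})

test_that("PAF emission encodes orientation, splicing and paralog ratios", {
  cfg <- sim_config(n_genes = 40L, n_genomes = 3L, p_del = 0, p_dup = 0,
                    p_inv = 0.15, paralog_families = 1L, seed = 21L)
  tr <- simulate_pangenome(cfg)
  d <- withr::local_tempdir()
  h <- read_paf_set(emit_paf(tr, d))
  # inverted occurrences come back on the minus strand
  inv <- tr$walks[orient == "-"]
  expect_gt(nrow(inv), 0L)
  hh <- h[h$strand == "-" & h$gene %in% inv$gene]
  expect_gt(nrow(hh), 0L)
  # cross-hits score at the family ratio of the local (noisy) score
  fam <- tr$families[[1]]
  u <- fam[1]; v <- fam[2]
  atv <- tr$walks[gene == v]
  cross <- h[h$gene == u & h$genome == atv$genome[1] & h$tstart == atv$start[1]]
  expect_identical(nrow(cross), 1L)
  expect_identical(cross$score, round(0.93 * atv$score[1]))
  # a hit is spliced exactly when its query gene is spliced
  expect_identical(h$n_introns >= 1L, unname(tr$spliced[h$gene]))
})

test_that("events respect spacing and chromosome margins when enforced", {
  tr <- simulate_pangenome(sim_config(n_genes = 150L, n_genomes = 8L,
                                      p_del = 0.05, p_inv = 0.03, p_dup = 0.03,
                                      n_chromosomes = 3L, seed = 31L))
  ev <- unique(tr$events[, .(chrom, s, e)])
  setorder(ev, chrom, s)
  if (nrow(ev) >= 2L) {
    same <- ev$chrom[-1L] == ev$chrom[-nrow(ev)]
    gaps <- (ev$s[-1L] - ev$e[-nrow(ev)] - 1L)[same]
    expect_true(all(gaps >= 3L))
  }
  # flanks inside chromosomes
  for (i in seq_len(nrow(ev))) {
    pos <- which(rep(1:3, each = 50) == ev$chrom[i])
    expect_gte(ev$s[i] - 1L, min(pos))
    expect_lte(ev$e[i] + 1L, max(pos))
  }
})
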