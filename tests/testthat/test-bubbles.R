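test_that("compute_U follows the passage rules", {
  g <- toy_graph("TOY1")
  expect_identical(compute_U(g, ">A", ">C"), "B")
  # the flipped exit may be entered and contributes the exit's gene
  expect_identical(compute_U(g, ">A", "<C"), c("B", "C"))
  expect_identical(compute_U(g, ">C", "<A"), character(0))
  expect_error(compute_U(g, ">A", ">A"), "differ")
})

test_that("is_bibubble accepts the toys and rejects the documented pairs", {
  for (t in c("TOY1", "TOY2", "TOY3")) {
    g <- toy_graph(t)
    expect_true(is_bibubble(g, ">A", ">C"))
    expect_true(is_bibubble(g, "<C", "<A"))   # twin symmetry
  }
  g <- toy_graph("TOY1")
  expect_false(is_bibubble(g, ">A", "<C"))    # two sides disagree
  expect_false(is_bibubble(g, ">A", "<A"))    # same gene
  expect_false(is_bibubble(g, ">A", ">B"))    # empty interior
  # a pure one-genome chain has no variation and no bubbles
  chain <- pangraph_from_walks(list(
    list(genome = "g1", contig = "c1", steps = c(">A", ">B", ">C"))))
  expect_false(is_bibubble(chain, ">A", ">C"))
})

test_that("find_bibubbles reports each toy's single bubble in canonical form", {
  for (t in c("TOY1", "TOY2", "TOY3")) {
    bb <- find_bibubbles(toy_graph(t))
    expect_identical(nrow(bb), 1L)
    expect_identical(bb$entrance, ">A")
    expect_identical(bb$exit, ">C")
    expect_identical(bb$interior[[1]], "B")
    expect_identical(bb$n_distinct_walk_paths, 2L)
  }
  expect_true(find_bibubbles(toy_graph("TOY2"))$has_inversion)
  expect_false(find_bibubbles(toy_graph("TOY1"))$has_inversion)
  # chain and edgeless graphs yield nothing
  chain <- pangraph_from_walks(list(
    list(genome = "g1", contig = "c1", steps = c(">A", ">B", ">C"))))
  expect_identical(nrow(find_bibubbles(chain)), 0L)
  lone <- pangraph_from_walks(list(list(genome = "g", contig = "c", steps = ">A")))
  expect_identical(nrow(find_bibubbles_bruteforce(lone)), 0L)
})

test_that("the branching-entrance heuristic misses degree-one entrances only", {
  # TOY3's entrance >A has a single out-edge, so the heuristic skips it
  expect_identical(nrow(find_bibubbles(toy_graph("TOY3"), entrances = "branching")), 0L)
  expect_identical(nrow(find_bibubbles(toy_graph("TOY1"), entrances = "branching")), 1L)
})

test_that("fast enumeration equals the brute-force oracle on random graphs", {
  for (s in 1:40) {
    g <- random_truth_graph(s, max_genes = 20L)
    expect_identical(bubkey(find_bibubbles(g)),
                     bubkey(find_bibubbles_bruteforce(g)))
  }
})

test_that("the brute-force oracle refuses oversized graphs", {
  tr <- simulate_pangenome(sim_config(n_genes = 80L, n_genomes = 2L, seed = 1L))
  expect_error(find_bibubbles_bruteforce(truth_graph(tr)), "limited")
})

test_that("reported bubbles satisfy the separator property", {
  check_separator <- function(g, bb) {
    for (i in seq_len(nrow(bb))) {
      avoid <- c(bb$entrance[i], flip(bb$entrance[i]), bb$exit[i], flip(bb$exit[i]))
      interior <- bb$interior[[i]]
      outside <- setdiff(g$genes,
                         c(interior, substring(avoid, 2)))
      for (v in interior) for (o in c(">", "<")) {
        r <- reachable(g, paste0(o, v), avoid = avoid)
        expect_identical(intersect(substring(r, 2), outside), character(0))
      }
    }
  }
  for (t in c("TOY1", "TOY2", "TOY3")) {
    g <- toy_graph(t)
    check_separator(g, find_bibubbles(g))
  }
  for (s in 1:10) {
    g <- random_truth_graph(s, max_genes = 15L)
    check_separator(g, find_bibubbles(g))
  }
})

test_that("nesting and per-entrance uniqueness hold on random graphs", {
  for (s in 1:25) {
    g <- random_truth_graph(s)
    bb <- find_bibubbles_bruteforce(g)
    expect_identical(anyDuplicated(bb$entrance), 0L)
    if (nrow(bb) >= 2L) {
      for (i in 1:(nrow(bb) - 1L)) for (j in (i + 1L):nrow(bb)) {
        a <- bb$interior[[i]]; b <- bb$interior[[j]]
        if (length(intersect(a, b)))
          expect_true(all(a %in% b) || all(b %in% a))
      }
    }
  }
})
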