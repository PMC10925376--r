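test_that("to_net_graph contracts TOY1 into the expected port partition", {
  net <- to_net_graph(toy_graph("TOY1"))
  # ports: {A.s} | {A.e, B.s, B.e, C.s} | {C.e}
  expect_identical(net$n_vertices, 3L)
  comp <- net$port_comp
  ps <- function(k) comp[2L * k - 1L]; pe <- function(k) comp[2L * k]
  # genes are sorted A, B, C
  expect_identical(length(unique(c(pe(1), ps(2), pe(2), ps(3)))), 1L)
  expect_false(ps(1) %in% c(pe(1), pe(3)))
  ed <- net$gene_edges
  expect_identical(nrow(ed), 3L)                    # one edge per gene
  expect_true(ed$u[ed$gene == "B"] == ed$v[ed$gene == "B"])   # B self-loop
  expect_false(ed$u[ed$gene == "A"] == ed$v[ed$gene == "A"])  # A, C bridges
})

test_that("parallel alternatives contract to parallel net edges", {
  net <- to_net_graph(toy_graph("PARALLEL"))
  expect_identical(net$n_vertices, 4L)
  ed <- net$gene_edges
  bd <- ed[ed$gene %in% c("B", "D"), ]
  expect_setequal(paste(pmin(bd$u, bd$v), pmax(bd$u, bd$v))[1],
                  paste(pmin(bd$u, bd$v), pmax(bd$u, bd$v))[2])
})

test_that("cycle classes: triangle, toys, disjoint triangles, bridges", {
  tri <- structure(list(n_vertices = 3L,
    gene_edges = data.table::data.table(gene = c("a", "b", "c"),
                                        u = c(1L, 2L, 3L), v = c(2L, 3L, 1L)),
    port_comp = integer(0)), class = "pg_net")
  cls <- cycle_equiv_classes(tri)
  expect_identical(length(unique(cls)), 1L)          # one class of size 3
  expect_true(is.na(attr(cls, "acyclic_class")))
  # TOY1: A, C share the acyclic class; self-loop B is alone
  c1 <- cycle_equiv_classes(to_net_graph(toy_graph("TOY1")))
  expect_identical(c1[["A"]], c1[["C"]])
  expect_false(c1[["B"]] == c1[["A"]])
  expect_identical(attr(c1, "acyclic_class"), unname(c1[["A"]]))
  # PARALLEL: {B, D} one class, {A, C} acyclic
  cp <- cycle_equiv_classes(to_net_graph(toy_graph("PARALLEL")))
  expect_identical(cp[["B"]], cp[["D"]])
  expect_identical(cp[["A"]], cp[["C"]])
  expect_false(cp[["A"]] == cp[["B"]])
  # two disjoint triangles: two distinct classes
  two <- structure(list(n_vertices = 6L,
    gene_edges = data.table::data.table(gene = sprintf("e%d", 1:6),
      u = c(1L, 2L, 3L, 4L, 5L, 6L), v = c(2L, 3L, 1L, 5L, 6L, 4L)),
    port_comp = integer(0)), class = "pg_net")
  ct <- cycle_equiv_classes(two)
  expect_identical(length(unique(ct)), 2L)
  expect_identical(ct[["e1"]], ct[["e2"]])
  expect_false(ct[["e1"]] == ct[["e4"]])
  # a single bridge: one acyclic class
  br <- structure(list(n_vertices = 2L,
    gene_edges = data.table::data.table(gene = "a", u = 1L, v = 2L),
    port_comp = integer(0)), class = "pg_net")
  cb <- cycle_equiv_classes(br)
  expect_identical(as.integer(cb), attr(cb, "acyclic_class"))
})

test_that("oracle and fast cycle classes agree, including on toys", {
  for (t in c("TOY1", "TOY2", "TOY3", "PARALLEL")) {
    net <- to_net_graph(toy_graph(t))
    expect_true(pangraph:::same_partition(cycle_equiv_classes(net),
                                          cycle_equiv_oracle(net)))
  }
  for (s in 1:40) {
    net <- random_net(s)
    expect_true(pangraph:::same_partition(cycle_equiv_classes(net),
                                          cycle_equiv_oracle(net)))
  }
})

test_that("the oracle refuses oversized graphs", {
  big <- structure(list(n_vertices = 2L,
    gene_edges = data.table::data.table(gene = sprintf("e%d", 1:30),
      u = rep(1L, 30), v = rep(2L, 30)),
    port_comp = integer(0)), class = "pg_net")
  expect_error(cycle_equiv_oracle(big), "limited")
})
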