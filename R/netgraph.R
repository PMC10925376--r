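## Biedged and net graphs, and cycle equivalence of net-graph edges.
##
## Each gene v contributes two ports (v,s) and (v,e) joined by a gene edge;
## every adjacency x -> y contributes an undirected link edge between
## head(x) and tail(y). Contracting all link edges yields the net graph: an
## undirected multigraph whose vertices are port components and whose edges
## are genes (self-loops and parallel edges allowed).

# port ids: s-port of gene k is 2k-1, e-port is 2k
port_s <- function(k) 2L * k - 1L
port_e <- function(k) 2L * k
# head of an oriented gene (the port you leave from), tail (the port you enter)
og_head_port <- function(i) ifelse(og_is_fwd(i), port_e(og_gene_id(i)), port_s(og_gene_id(i)))
og_tail_port <- function(i) ifelse(og_is_fwd(i), port_s(og_gene_id(i)), port_e(og_gene_id(i)))

#' Contract a gene graph to its net graph
#'
#' Splits every gene into a start and an end port, converts every adjacency
#' into an undirected link edge between the ports it joins (skew-symmetric
#' twins give the same unordered link), contracts all link edges and returns
#' the resulting undirected multigraph in which every gene is one edge
#' between the components of its two ports.
#'
#' @param g a `pangraph`.
#' @return an object of class `pg_net`: a list with `n_vertices`, an edge
#'   table `gene_edges` (columns `gene`, `u`, `v`), and `port_comp`, the
#'   component id of every port (ports of gene k are entries 2k-1 and 2k).
#' @examples
#' net <- to_net_graph(toy_graph("TOY1"))
#' net$gene_edges
#' @export
to_net_graph <- function(g) {
  stopifnot(inherits(g, "pangraph"))
  n <- length(g$genes)
  parent <- seq_len(2L * n)
  # union-find with path halving, inline so updates stay in place
  if (nrow(g$edges)) {
    a <- og_head_port(g$edges$src)
    b <- og_tail_port(g$edges$dst)
    for (idx in seq_along(a)) {
      ra <- a[idx]
      while (parent[ra] != ra) { parent[ra] <- parent[parent[ra]]; ra <- parent[ra] }
      rb <- b[idx]
      while (parent[rb] != rb) { parent[rb] <- parent[parent[rb]]; rb <- parent[rb] }
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- integer(2L * n)
  for (i in seq_len(2L * n)) {
    r <- i
    while (parent[r] != r) { parent[r] <- parent[parent[r]]; r <- parent[r] }
    roots[i] <- r
  }
  comp <- match(roots, unique(roots))
  edges <- data.table(gene = g$genes,
                      u = comp[port_s(seq_len(n))],
                      v = comp[port_e(seq_len(n))])
  structure(list(n_vertices = length(unique(comp)), gene_edges = edges,
                 port_comp = comp),
            class = "pg_net")
}

#' @export
print.pg_net <- function(x, ...) {
  nloop <- sum(x$gene_edges$u == x$gene_edges$v)
  cat(sprintf("net graph: %d vertices, %d gene edges (%d self-loops)\n",
              x$n_vertices, nrow(x$gene_edges), nloop))
  invisible(x)
}

# deterministic 31-bit label pairs from two Lehmer generators (exact in
# doubles: products stay below 2^53); independent of the user's RNG state
label_stream <- function(n) {
  out1 <- numeric(n); out2 <- numeric(n)
  s1 <- 424242; s2 <- 271828
  for (i in seq_len(n)) {
    s1 <- (s1 * 48271) %% 2147483647
    s2 <- (s2 * 69621) %% 2147483647
    out1[i] <- s1; out2[i] <- s2
  }
  list(a = as.integer(out1), b = as.integer(out2))
}

#' Cycle-equivalence classes of net-graph edges
#'
#' Two edges of the net graph are cycle equivalent when every cycle (closed
#' walk without edge repetition) through one passes through the other. All
#' bridge edges - edges lying on no cycle at all, for which the definition
#' holds vacuously - are grouped into one designated acyclic class; this is
#' what co-classes the entrance and exit of a bubble embedded in a linear
#' chromosome.
#'
#' The implementation assigns every non-tree edge of a spanning forest a
#' deterministic 62-bit label and gives each edge the XOR of the labels of
#' the fundamental cycles covering it (an edge is cycle equivalent to another
#' exactly when the two are covered by the same set of fundamental cycles,
#' which for non-bridge pairs is the two-edge cut-set characterisation).
#' Runs in near-linear time and is checked against [cycle_equiv_oracle()] on
#' small graphs.
#'
#' @param net a `pg_net` object from [to_net_graph()].
#' @return named integer vector mapping gene to class id, with attribute
#'   `acyclic_class` giving the id of the bridge class (`NA` if no bridges).
#' @examples
#' cycle_equiv_classes(to_net_graph(toy_graph("TOY1")))
#' @export
cycle_equiv_classes <- function(net) {
  stopifnot(inherits(net, "pg_net"))
  ne <- nrow(net$gene_edges)
  nv <- net$n_vertices
  if (ne == 0L) return(structure(setNames(integer(0), character(0)), acyclic_class = NA_integer_))
  u <- net$gene_edges$u; v <- net$gene_edges$v
  # BFS spanning forest over the multigraph
  inc_from <- split(seq_len(ne), u)
  inc_to <- split(seq_len(ne), v)
  inc <- vector("list", nv)
  for (nm in names(inc_from)) inc[[as.integer(nm)]] <- inc_from[[nm]]
  for (nm in names(inc_to)) {
    i <- as.integer(nm)
    inc[[i]] <- c(inc[[i]], inc_to[[nm]])
  }
  visited <- logical(nv)
  parent_edge <- integer(nv)   # 0 = forest root
  parent_vtx <- integer(nv)
  order_bfs <- integer(nv)
  tree_edge <- logical(ne)
  nord <- 0L
  for (root in seq_len(nv)) {
    if (visited[root]) next
    visited[root] <- TRUE
    queue <- integer(nv)
    queue[1L] <- root
    head <- 1L; tail <- 1L
    while (head <= tail) {
      w <- queue[head]; head <- head + 1L
      nord <- nord + 1L; order_bfs[nord] <- w
      for (e in inc[[w]]) {
        o <- if (u[e] == w) v[e] else u[e]
        if (!visited[o]) {
          visited[o] <- TRUE
          tree_edge[e] <- TRUE
          parent_edge[o] <- e
          parent_vtx[o] <- w
          tail <- tail + 1L
          queue[tail] <- o
        }
      }
    }
  }
  nontree <- which(!tree_edge)
  lab <- label_stream(length(nontree))
  acc1 <- integer(nv); acc2 <- integer(nv)
  sig1 <- integer(ne); sig2 <- integer(ne)
  for (j in seq_along(nontree)) {
    e <- nontree[j]
    sig1[e] <- lab$a[j]; sig2[e] <- lab$b[j]
    # XOR the label onto both endpoints; a self-loop cancels itself out,
    # matching the fact that its fundamental cycle covers no tree edge
    acc1[u[e]] <- bitwXor(acc1[u[e]], lab$a[j])
    acc2[u[e]] <- bitwXor(acc2[u[e]], lab$b[j])
    acc1[v[e]] <- bitwXor(acc1[v[e]], lab$a[j])
    acc2[v[e]] <- bitwXor(acc2[v[e]], lab$b[j])
  }
  # accumulate subtree XOR bottom-up: the signature of the tree edge above w
  for (idx in rev(seq_len(nord))) {
    w <- order_bfs[idx]
    pe <- parent_edge[w]
    if (pe > 0L) {
      sig1[pe] <- acc1[w]; sig2[pe] <- acc2[w]
      p <- parent_vtx[w]
      acc1[p] <- bitwXor(acc1[p], acc1[w])
      acc2[p] <- bitwXor(acc2[p], acc2[w])
    }
  }
  key <- paste(sig1, sig2, sep = ",")
  bridge <- sig1 == 0L & sig2 == 0L
  key[bridge] <- "acyclic"
  ids <- match(key, unique(key))
  res <- setNames(ids, net$gene_edges$gene)
  attr(res, "acyclic_class") <- if (any(bridge)) ids[which(bridge)[1]] else NA_integer_
  res
}

#' Brute-force cycle-equivalence oracle
#'
#' Computes cycle-equivalence classes directly from the definition by
#' enumerating every simple cycle of the net graph (self-loops, parallel
#' pairs and vertex-simple cycles of length three or more) and comparing
#' per-edge cycle-membership sets. Edges on no cycle share the acyclic
#' class. Intended as a test oracle only; guarded to small graphs.
#'
#' @param net a `pg_net` object.
#' @param max_genes size guard; an error is raised above it.
#' @return same format as [cycle_equiv_classes()].
#' @export
cycle_equiv_oracle <- function(net, max_genes = 14L) {
  stopifnot(inherits(net, "pg_net"))
  ne <- nrow(net$gene_edges)
  if (ne > max_genes) stop("cycle_equiv_oracle() is limited to ", max_genes, " genes")
  if (ne == 0L) return(structure(setNames(integer(0), character(0)), acyclic_class = NA_integer_))
  u <- net$gene_edges$u; v <- net$gene_edges$v
  nv <- net$n_vertices
  cycles <- list()          # each a sorted integer vector of edge ids
  seen_keys <- new.env(parent = emptyenv())
  add_cycle <- function(es) {
    k <- paste(sort(es), collapse = ",")
    if (is.null(seen_keys[[k]])) {
      seen_keys[[k]] <- TRUE
      cycles[[length(cycles) + 1L]] <<- sort(es)
    }
  }
  for (e in seq_len(ne)) if (u[e] == v[e]) add_cycle(e)
  # parallel pairs
  for (e1 in seq_len(ne)) for (e2 in seq_len(ne)) {
    if (e1 < e2 && u[e1] != v[e1] &&
        ((u[e1] == u[e2] && v[e1] == v[e2]) || (u[e1] == v[e2] && v[e1] == u[e2])))
      add_cycle(c(e1, e2))
  }
  # vertex-simple cycles of length >= 3 by DFS from each smallest vertex
  inc <- lapply(seq_len(nv), function(w) which(u == w | v == w))
  path_v <- integer(0); path_e <- integer(0)
  dfs <- function(w, start) {
    for (e in inc[[w]]) {
      if (u[e] == v[e]) next
      o <- if (u[e] == w) v[e] else u[e]
      if (e %in% path_e) next
      if (o == start && length(path_e) >= 2L) {
        add_cycle(c(path_e, e))
      } else if (o > start && !(o %in% path_v)) {
        path_v <<- c(path_v, o); path_e <<- c(path_e, e)
        dfs(o, start)
        path_v <<- path_v[-length(path_v)]; path_e <<- path_e[-length(path_e)]
      }
    }
  }
  for (start in seq_len(nv)) {
    path_v <- start; path_e <- integer(0)
    dfs(start, start)
  }
  membership <- vapply(seq_len(ne), function(e) {
    inn <- vapply(cycles, function(cy) e %in% cy, logical(1))
    if (!any(inn)) "acyclic" else paste(which(inn), collapse = ",")
  }, character(1))
  ids <- match(membership, unique(membership))
  res <- setNames(ids, net$gene_edges$gene)
  attr(res, "acyclic_class") <-
    if (any(membership == "acyclic")) ids[which(membership == "acyclic")[1]] else NA_integer_
  res
}

# partition equality of two gene -> class maps (ids may differ)
same_partition <- function(c1, c2) {
  if (length(c1) != length(c2)) return(FALSE)
  a1 <- attr(c1, "acyclic_class"); a2 <- attr(c2, "acyclic_class")
  c2 <- c2[names(c1)]
  # relabel both by first occurrence
  r1 <- match(c1, unique(c1)); r2 <- match(c2, unique(c2))
  if (!identical(r1, r2)) return(FALSE)
  # the designated acyclic class must be the same block (or absent in both)
  if (is.na(a1) != is.na(a2)) return(FALSE)
  if (!is.na(a1)) {
    b1 <- names(c1)[c1 == a1]; b2 <- names(c2)[c2 == a2]
    return(setequal(b1, b2))
  }
  TRUE
}
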