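# shared helpers: canonical keys for comparing bubble sets, graph
# fingerprints, and seeded random fixtures built in code

bubkey <- function(bb) {
  sort(paste(bb$entrance, bb$exit,
             vapply(bb$interior, paste, character(1), collapse = ",")))
}

edge_strings <- function(g) {
  if (nrow(g$edges) == 0L) return(character(0))
  sort(paste(pangraph:::og_to_str(g$genes, g$edges$src),
             pangraph:::og_to_str(g$genes, g$edges$dst)))
}

walk_strings <- function(g) {
  if (nrow(g$walks) == 0L) return(character(0))
  w <- data.table::copy(g$walks)
  data.table::setorder(w, genome, contig, start)
  sp <- split(pangraph:::og_to_str(g$genes, w$og), paste(w$genome, w$contig))
  unname(sort(vapply(sp, paste, character(1), collapse = " ")))
}

# a messy random pangenome graph (dense events, no isolation constraints)
random_truth_graph <- function(seed, max_genes = 25L) {
  set.seed(seed)
  ng <- sample(6:max_genes, 1L)
  cfg <- sim_config(n_genes = ng, n_genomes = 3L, n_chromosomes = 1L,
                    p_del = 0.12, p_inv = 0.08, p_dup = 0.08,
                    enforce_spacing = FALSE, seed = seed)
  truth_graph(simulate_pangenome(cfg))
}

# a random undirected multigraph in net-graph form (self-loops and parallel
# edges allowed)
random_net <- function(seed, max_genes = 12L) {
  set.seed(seed)
  ne <- sample(2:max_genes, 1L)
  nv <- sample(2:max(2L, ne), 1L)
  u <- sample(nv, ne, replace = TRUE)
  v <- ifelse(stats::runif(ne) < 0.15, u, sample(nv, ne, replace = TRUE))
  structure(list(n_vertices = nv,
                 gene_edges = data.table::data.table(
                   gene = sprintf("e%02d", seq_len(ne)), u = u, v = v),
                 port_comp = integer(0)),
            class = "pg_net")
}

# simple hit-table row builder (same columns as read_paf output)
hit_row <- pangraph:::mk_hit

# boolean-matrix transitive closure over the directed oriented-gene graph;
# independent oracle for reachable()
closure_oracle <- function(g) {
  genes <- g$genes
  nn <- 2L * length(genes)
  M <- matrix(FALSE, nn, nn)
  e <- g$edges
  if (nrow(e)) {
    src <- c(e$src, pangraph:::og_flip_id(e$dst))
    dst <- c(e$dst, pangraph:::og_flip_id(e$src))
    M[cbind(src, dst)] <- TRUE
  }
  R <- M
  for (k in seq_len(nn)) {
    R2 <- R | (R %*% M > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  R
}
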