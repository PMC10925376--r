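#' @import data.table
NULL

## ---- oriented genes ---------------------------------------------------------
##
## An oriented gene is written ">v" (forward) or "<v" (reverse). Internally an
## oriented gene is an integer id: gene k (1-based position in g$genes) has
## forward id 2k-1 and reverse id 2k, so the reverse complement is a cheap
## parity flip and gene recovery is integer division.

og_fwd <- function(k) 2L * k - 1L
og_rev <- function(k) 2L * k
og_flip_id <- function(i) i + ifelse(i %% 2L == 1L, 1L, -1L)
og_gene_id <- function(i) (i + 1L) %/% 2L
og_is_fwd <- function(i) i %% 2L == 1L

og_to_str <- function(genes, i) {
  paste0(ifelse(og_is_fwd(i), ">", "<"), genes[og_gene_id(i)])
}

og_from_str <- function(genes, s) {
  ori <- substr(s, 1L, 1L)
  if (any(!ori %in% c(">", "<")))
    stop("oriented genes must start with '>' or '<': ", s[which(!ori %in% c(">", "<"))[1]])
  nm <- substr(s, 2L, nchar(s))
  k <- match(nm, genes)
  if (anyNA(k)) stop("unknown gene: ", nm[which(is.na(k))[1]])
  ifelse(ori == ">", og_fwd(k), og_rev(k))
}

#' Reverse-complement an oriented gene
#'
#' `flip(">A")` is `"<A"` and vice versa; flipping twice is the identity and
#' the underlying gene never changes.
#'
#' @param x character vector of oriented genes (`">gene"` or `"<gene"`).
#' @return character vector of the same length with orientations toggled.
#' @examples
#' flip(c(">A", "<B"))
#' @export
flip <- function(x) {
  ori <- substr(x, 1L, 1L)
  if (any(!ori %in% c(">", "<")))
    stop("oriented genes must start with '>' or '<'")
  paste0(ifelse(ori == ">", "<", ">"), substr(x, 2L, nchar(x)))
}

## ---- the pangraph container -------------------------------------------------

# Canonicalize directed oriented-id pairs: the stored representative of the
# skew-symmetric twin pair {(x,y), (flip(y),flip(x))} is the smaller ordered
# integer pair. Returns a list with $src, $dst, $swapped.
canonical_pair <- function(x, y) {
  tx <- og_flip_id(y)
  ty <- og_flip_id(x)
  swap <- (tx < x) | (tx == x & ty < y)
  list(src = ifelse(swap, tx, x), dst = ifelse(swap, ty, y), swapped = swap)
}

empty_edges <- function() {
  data.table(src = integer(), dst = integer(), support = list(),
             score_fd = numeric(), score_rv = numeric(),
             false_edge = logical(), low_priority = logical())
}

empty_steps <- function() {
  data.table(genome = character(), contig = character(), og = integer(),
             start = numeric(), end = numeric(), score = numeric(),
             n_introns = integer(), hit_id = integer())
}

new_pangraph <- function(genes, edges, walks, meta = list()) {
  stopifnot(is.character(genes), !anyDuplicated(genes))
  if (is.null(meta$genomes)) meta$genomes <- sort(unique(walks$genome))
  g <- structure(
    list(genes = genes, edges = edges, walks = walks, meta = meta,
         cache = new.env(parent = emptyenv())),
    class = "pangraph")
  g
}

#' Build a gene graph from explicit walks
#'
#' Constructs a bidirected gene graph directly from per-contig walks of
#' oriented genes. Each consecutive pair of steps on a contig becomes a
#' directed edge together with its skew-symmetric twin; edges are stored once
#' in canonical orientation so skew symmetry holds by construction. This is
#' the constructor used by the simulator's truth walks, the toy fixtures and
#' the GFA reader; the alignment pipeline reaches it through [build_graph()].
#'
#' @param walks a list of walks; each walk is a list with elements `genome`,
#'   `contig` and `steps` (character vector of oriented genes such as
#'   `c(">A", ">B")`), and optionally numeric vectors `start`, `end`, `score`
#'   and integer `n_introns` parallel to `steps`. When coordinates are absent,
#'   deterministic placeholder coordinates are assigned in step order.
#' @param genomes optional character vector of all genome ids (a genome can
#'   contribute zero walks after filtering but still count towards
#'   frequencies).
#' @return a `pangraph` object.
#' @examples
#' g <- pangraph_from_walks(list(
#'   list(genome = "g1", contig = "c1", steps = c(">A", ">B", ">C")),
#'   list(genome = "g2", contig = "c2", steps = c(">A", ">C"))))
#' summary(g)
#' @export
pangraph_from_walks <- function(walks, genomes = NULL) {
  all_steps <- unlist(lapply(walks, `[[`, "steps"), use.names = FALSE)
  genes <- if (length(all_steps)) sort(unique(substring(all_steps, 2L))) else character(0)
  steps <- rbindlist(lapply(walks, function(w) {
    ns <- length(w$steps)
    if (ns == 0L) return(NULL)
    start <- if (!is.null(w$start)) as.numeric(w$start) else (seq_len(ns) - 1) * 2000
    end <- if (!is.null(w$end)) as.numeric(w$end) else start + 1000
    data.table(genome = w$genome, contig = w$contig,
               og = og_from_str(genes, w$steps),
               start = start, end = end,
               score = if (!is.null(w$score)) as.numeric(w$score) else NA_real_,
               n_introns = if (!is.null(w$n_introns)) as.integer(w$n_introns) else NA_integer_,
               hit_id = NA_integer_)
  }))
  if (is.null(steps) || nrow(steps) == 0L) steps <- empty_steps()
  graph_from_steps(genes, steps, genomes = genomes)
}

# Core assembly: derive canonical edge table from an ordered step table.
graph_from_steps <- function(genes, steps, genomes = NULL, meta = list()) {
  setorder(steps, genome, contig, start, end)
  edges <- edges_from_steps(steps)
  if (is.null(genomes)) genomes <- sort(unique(steps$genome))
  meta$genomes <- sort(unique(c(genomes, steps$genome)))
  new_pangraph(genes, edges, steps, meta)
}

edges_from_steps <- function(steps) {
  if (nrow(steps) < 2L) return(empty_edges())
  idx <- steps[, .(i = .I[-.N], j = .I[-1L]), by = .(genome, contig)]
  if (nrow(idx) == 0L) return(empty_edges())
  adjdt <- data.table(
    genome = steps$genome[idx$i], contig = steps$contig[idx$i],
    x = steps$og[idx$i], y = steps$og[idx$j],
    sx = steps$score[idx$i], sy = steps$score[idx$j])
  cp <- canonical_pair(adjdt$x, adjdt$y)
  adjdt[, `:=`(src = cp$src, dst = cp$dst,
               sfd = ifelse(cp$swapped, sy, sx),
               srv = ifelse(cp$swapped, sx, sy))]
  # per-contig mean first (an edge counts each supporting contig once), then
  # mean over supporting contigs: S(x|y) = mean_t S(x|y,t)
  percontig <- adjdt[, .(sfd = mean(sfd), srv = mean(srv)),
                     by = .(src, dst, genome, contig)]
  edges <- percontig[, .(
    support = list(sort(paste(genome, contig, sep = "\t"))),
    score_fd = mean(sfd), score_rv = mean(srv)), by = .(src, dst)]
  edges[, `:=`(false_edge = FALSE, low_priority = FALSE)]
  setorder(edges, src, dst)
  edges[]
}

## ---- directed views and traversal ------------------------------------------

# adjacency list over oriented ids 1..2*length(genes); cached per object
graph_adjacency <- function(g) {
  if (!is.null(g$cache$adj)) return(g$cache$adj)
  nn <- 2L * length(g$genes)
  adj <- vector("list", nn)
  if (nrow(g$edges)) {
    src <- c(g$edges$src, og_flip_id(g$edges$dst))
    dst <- c(g$edges$dst, og_flip_id(g$edges$src))
    dd <- unique(data.table(src, dst))
    sp <- split(dd$dst, dd$src)
    adj[as.integer(names(sp))] <- sp
  }
  for (i in seq_len(nn)) if (is.null(adj[[i]])) adj[[i]] <- integer(0)
  g$cache$adj <- adj
  adj
}

# BFS over out-edges from `start`, never entering ids in `blocked`.
# Returns visited oriented ids in BFS order, start excluded.
bfs_reach <- function(adj, start, blocked = integer(0)) {
  seen <- logical(length(adj))
  seen[blocked] <- TRUE
  seen[start] <- TRUE
  queue <- integer(64L)
  queue[1L] <- start
  head <- 1L; tail <- 1L
  while (head <= tail) {
    v <- queue[head]; head <- head + 1L
    for (s in adj[[v]]) {
      if (!seen[s]) {
        seen[s] <- TRUE
        tail <- tail + 1L
        if (tail > length(queue)) queue <- c(queue, integer(length(queue)))
        queue[tail] <- s
      }
    }
  }
  if (tail >= 2L) queue[2:tail] else integer(0)
}

#' Successors of an oriented gene
#'
#' Returns the set `{y : x -> y}` in the directed view of the graph. By skew
#' symmetry, `flip(x)` is a successor of `flip(y)` exactly when `y` is
#' returned here.
#'
#' @param g a `pangraph`.
#' @param x a single oriented gene string such as `">A"`.
#' @return character vector of oriented genes (possibly empty), sorted.
#' @examples
#' g <- toy_graph("TOY1")
#' out_neighbors(g, ">A")
#' @export
out_neighbors <- function(g, x) {
  stopifnot(inherits(g, "pangraph"), length(x) == 1L)
  i <- og_from_str(g$genes, x)
  adj <- graph_adjacency(g)
  sort(og_to_str(g$genes, adj[[i]]))
}

#' Oriented genes reachable from a start
#'
#' Breadth-first closure over out-edges, never entering any member of
#' `avoid`. The start itself is excluded from the result even when it lies on
#' a cycle.
#'
#' @param g a `pangraph`.
#' @param start a single oriented gene string.
#' @param avoid character vector of oriented genes that must not be entered.
#' @return character vector of reachable oriented genes, sorted.
#' @examples
#' g <- toy_graph("TOY1")
#' reachable(g, ">A")
#' reachable(g, ">A", avoid = ">B")
#' @export
reachable <- function(g, start, avoid = character(0)) {
  stopifnot(inherits(g, "pangraph"), length(start) == 1L)
  i <- og_from_str(g$genes, start)
  blk <- if (length(avoid)) og_from_str(g$genes, avoid) else integer(0)
  if (i %in% blk) stop("start must not be in `avoid`")
  adj <- graph_adjacency(g)
  sort(og_to_str(g$genes, bfs_reach(adj, i, blk)))
}

#' Is a gene an inversion?
#'
#' A gene `v` is an inversion when some oriented gene can reach both `>v` and
#' `<v`; equivalently the gene is traversed in both reading directions
#' somewhere in the graph.
#'
#' @param g a `pangraph`.
#' @param v a single gene identifier.
#' @return logical scalar.
#' @examples
#' is_inversion(toy_graph("TOY2"), "B")  # TRUE
#' is_inversion(toy_graph("TOY1"), "B")  # FALSE
#' @export
is_inversion <- function(g, v) {
  stopifnot(inherits(g, "pangraph"), length(v) == 1L)
  k <- match(v, g$genes)
  if (is.na(k)) stop("unknown gene: ", v)
  adj <- graph_adjacency(g)
  # z reaches >v  iff  <v reaches flip(z) (skew symmetry), so the two
  # candidate sets are flips of forward closures from the two orientations
  r_from_rev <- bfs_reach(adj, og_rev(k))
  r_from_fwd <- bfs_reach(adj, og_fwd(k))
  length(intersect(og_flip_id(r_from_rev), og_flip_id(r_from_fwd))) > 0L
}

## ---- methods ----------------------------------------------------------------

#' @export
print.pangraph <- function(x, ...) {
  cat("pangraph: bidirected gene graph\n")
  cat(sprintf("  genes:   %d\n", length(x$genes)))
  cat(sprintf("  edges:   %d (canonical; %d directed views)\n",
              nrow(x$edges), 2L * nrow(x$edges)))
  nw <- if (nrow(x$walks)) nrow(unique(x$walks[, .(genome, contig)])) else 0L
  cat(sprintf("  walks:   %d over %d genome(s)\n", nw, length(x$meta$genomes)))
  invisible(x)
}

#' @export
summary.pangraph <- function(object, ...) {
  g <- object
  deg <- gene_degree(g)
  res <- list(
    n_genes = length(g$genes),
    n_edges = nrow(g$edges),
    n_walks = if (nrow(g$walks)) nrow(unique(g$walks[, .(genome, contig)])) else 0L,
    genomes = g$meta$genomes,
    n_steps = nrow(g$walks),
    max_degree = if (length(deg)) max(deg) else 0L,
    n_false = sum(g$edges$false_edge),
    n_low_priority = sum(g$edges$low_priority))
  class(res) <- "summary.pangraph"
  res
}

#' @export
print.summary.pangraph <- function(x, ...) {
  cat(sprintf("pangraph: %d genes, %d edges, %d walks (%d steps) across %d genomes\n",
              x$n_genes, x$n_edges, x$n_walks, x$n_steps, length(x$genomes)))
  cat(sprintf("  max bidirected degree %d; %d false edge(s), %d low-priority edge(s)\n",
              x$max_degree, x$n_false, x$n_low_priority))
  invisible(x)
}

# bidirected degree: number of canonical edges incident to each gene
# (a self-edge counts once); named integer over g$genes
gene_degree <- function(g) {
  deg <- setNames(integer(length(g$genes)), g$genes)
  if (nrow(g$edges)) {
    ga <- og_gene_id(g$edges$src)
    gb <- og_gene_id(g$edges$dst)
    t1 <- tabulate(ga, nbins = length(g$genes))
    t2 <- tabulate(gb[gb != ga], nbins = length(g$genes))
    deg[] <- t1 + t2
  }
  deg
}

# assert skew-symmetric storage sanity; used by tests and after mutations
check_pangraph <- function(g) {
  stopifnot(inherits(g, "pangraph"))
  if (nrow(g$edges)) {
    cp <- canonical_pair(g$edges$src, g$edges$dst)
    stopifnot(!any(cp$swapped))                        # stored canonically
    stopifnot(!anyDuplicated(g$edges[, .(src, dst)]))  # no multi-edges
    stopifnot(all(og_gene_id(c(g$edges$src, g$edges$dst)) <= length(g$genes)))
  }
  if (nrow(g$walks)) stopifnot(all(og_gene_id(g$walks$og) <= length(g$genes)))
  invisible(TRUE)
}
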