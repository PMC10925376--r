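## Generalized bibubbles on the bidirected gene graph.
##
## U(x,y) is the set of genes reachable from x without passing through x,
## x-bar or y; passage through y-bar is allowed and contributes the exit's
## gene. A pair (x,y) is a generalized bibubble when
##   (i)   U(x,y) = U(y-bar, x-bar) and both are non-empty,
##   (ii)  every interior gene lies on some x -> y walk,
##   (iii) no oriented gene over the interior heads a nested pair with a
##         non-empty two-sided-equal U against x or y (minimality),
##   (iv)  the enclosed subgraph admits at least two distinct x -> y
##         traversals (operationally: out-branching at some oriented gene on
##         the entrance side or, symmetrically, on the twin side),
##   (v)   the entrance and exit genes are cycle equivalent in the net graph
##         (the two-edge cut-set property promised by the separator
##         observation).
## Conditions (iv) and (v) are what separate genuine variation (deletion,
## inversion, tandem copy gain) from an invariant linear run of genes and
## from pseudo-pairs straddling a neighbouring event, which conditions
## (i)-(iii) alone cannot do; see the methods vignette for the derivation.

# integer-level U computation; returns list(genes = sorted gene ids,
# visited = oriented ids entered). x never entered; flip(y) may be entered
# and contributes gene(y).
compute_U_int <- function(adj, x, y, max_nodes = Inf) {
  nn <- length(adj)
  fx <- og_flip_id(x)
  seen <- logical(nn)
  seen[c(x, fx, y)] <- TRUE   # blocked: marked but never enqueued
  queue <- integer(64L)
  queue[1L] <- x
  head <- 1L; tail <- 1L
  while (head <= tail) {
    v <- queue[head]; head <- head + 1L
    for (s in adj[[v]]) {
      if (!seen[s]) {
        seen[s] <- TRUE
        tail <- tail + 1L
        if (tail > max_nodes) return(NULL)   # expansion larger than the cap
        if (tail > length(queue)) queue <- c(queue, integer(length(queue)))
        queue[tail] <- s
      }
    }
  }
  vis <- if (tail >= 2L) queue[2:tail] else integer(0)
  list(genes = sort(unique(og_gene_id(vis))), visited = vis)
}

#' Interior gene set U(x, y)
#'
#' Genes reachable from `x` without passing through `x`, `flip(x)` or `y`.
#' Expansion may pass through `flip(y)`, which contributes the exit's gene
#' and is traversed onwards.
#'
#' @param g a `pangraph`.
#' @param x,y oriented gene strings, `x != y`.
#' @return sorted character vector of gene identifiers.
#' @examples
#' g <- toy_graph("TOY1")
#' compute_U(g, ">A", ">C")   # "B"
#' compute_U(g, ">A", "<C")   # "B" "C": expansion passes through >C
#' @export
compute_U <- function(g, x, y) {
  stopifnot(inherits(g, "pangraph"), length(x) == 1L, length(y) == 1L)
  xi <- og_from_str(g$genes, x)
  yi <- og_from_str(g$genes, y)
  if (xi == yi) stop("x and y must differ")
  g$genes[compute_U_int(graph_adjacency(g), xi, yi)$genes]
}

# branching test for condition (iv): does any oriented gene in `nodes`
# have two or more distinct successors (self-loops count)?
any_branching <- function(adj, nodes) {
  for (v in nodes) if (length(adj[[v]]) >= 2L) return(TRUE)
  FALSE
}

is_bibubble_int <- function(adj, x, y, gene_cls) {
  bibubble_test(adj, x, y, gene_cls) == 1L
}

# full definition check with a three-way result used by the enumerator's
# early stop: 1 bubble, 0 not a bubble but condition (i) held (two-sided
# non-empty equal interior), -1 not a bubble and (i) failed. Once some
# candidate exit returns >= 0 for an entrance, any later exit in search
# order is vetoed by minimality through that candidate, so enumeration can
# stop.
bibubble_test <- function(adj, x, y, gene_cls, cap = Inf) {
  if (og_gene_id(x) == og_gene_id(y)) return(-1L)
  # (v) entrance and exit genes must be cycle equivalent
  if (gene_cls[og_gene_id(x)] != gene_cls[og_gene_id(y)]) return(-1L)
  # `cap` bounds every interior expansion to the traversal budget (a bubble
  # larger than m genes is not reported, matching the enumeration budget);
  # an aborted expansion fails the test or, inside minimality, vetoes
  # nothing. The cap never binds on graphs smaller than the budget.
  maxn <- if (is.finite(cap)) 2 * cap + 2 else Inf
  fx <- og_flip_id(x); fy <- og_flip_id(y)
  ux <- compute_U_int(adj, x, y, maxn)
  if (is.null(ux) || length(ux$genes) == 0L) return(-1L)
  uy <- compute_U_int(adj, fy, fx, maxn)
  if (is.null(uy) || !identical(ux$genes, uy$genes)) return(-1L)
  # (iv) at least two distinct traversals: out-branching on either side.
  # Checked before (ii)/(iii) because it is cheap and rejects the common
  # case of an invariant linear run between co-classed genes.
  if (!any_branching(adj, c(x, ux$visited)) &&
      !any_branching(adj, c(fy, uy$visited))) return(0L)
  # (iii) minimality: no oriented z over the interior genes heads a nested
  # non-empty two-sided pair against x or y
  for (v in ux$genes) {
    for (z in c(og_fwd(v), og_rev(v))) {
      fz <- og_flip_id(z)
      if (z != y && z != x) {
        ua <- compute_U_int(adj, x, z, maxn)
        if (!is.null(ua) && length(ua$genes)) {
          ua2 <- compute_U_int(adj, fz, fx, maxn)
          if (!is.null(ua2) && identical(ua$genes, ua2$genes)) return(0L)
        }
        ub <- compute_U_int(adj, z, y, maxn)
        if (!is.null(ub) && length(ub$genes)) {
          ub2 <- compute_U_int(adj, fy, fz, maxn)
          if (!is.null(ub2) && identical(ub$genes, ub2$genes)) return(0L)
        }
      }
    }
  }
  # (ii) every interior gene v is on some x -> y walk: some orientation z of
  # v has z reachable from x and y reachable from z (the latter via the
  # skew-symmetric closure from flip(y))
  rx <- logical(length(adj)); rx[bfs_reach(adj, x)] <- TRUE
  ry <- logical(length(adj)); ry[bfs_reach(adj, fy)] <- TRUE
  for (v in ux$genes) {
    f <- og_fwd(v); r <- og_rev(v)
    ok <- (rx[f] && ry[r]) || (rx[r] && ry[f])
    if (!ok) return(0L)
  }
  1L
}

#' Test whether a pair of oriented genes is a generalized bibubble
#'
#' Applies the full definition: two-sided non-empty interior equality,
#' walk coverage of every interior gene, minimality against nested pairs,
#' and the requirement that the enclosed subgraph admits more than one
#' distinct traversal (so an invariant linear run of genes is not a bubble).
#'
#' @param g a `pangraph`.
#' @param x,y oriented gene strings.
#' @return logical scalar.
#' @examples
#' g <- toy_graph("TOY1")
#' is_bibubble(g, ">A", ">C")   # TRUE
#' is_bibubble(g, ">A", "<C")   # FALSE: the two sides disagree
#' @export
is_bibubble <- function(g, x, y) {
  stopifnot(inherits(g, "pangraph"))
  xi <- og_from_str(g$genes, x)
  yi <- og_from_str(g$genes, y)
  if (xi == yi) stop("x and y must differ")
  is_bibubble_int(graph_adjacency(g), xi, yi, gene_classes(g))
}

# cycle-equivalence class per gene (integer vector in gene order), cached
gene_classes <- function(g) {
  if (is.null(g$cache$gene_cls)) {
    cls <- cycle_equiv_classes(to_net_graph(g))
    g$cache$gene_cls <- unname(cls[g$genes])
  }
  g$cache$gene_cls
}

# canonical representative of the twin pair {(x,y), (flip(y),flip(x))}:
# prefer a forward-oriented entrance; FNV-1a digest of the entrance breaks
# the tie when both (or neither) entrances read forward
bubble_canonical <- function(g, x, y) {
  tx <- og_flip_id(y)
  f1 <- og_is_fwd(x); f2 <- og_is_fwd(tx)
  if (f1 != f2) return(if (f1) c(x, y) else c(tx, og_flip_id(x)))
  ex <- og_to_str(g$genes, x)
  etx <- og_to_str(g$genes, tx)
  if (fnv1a64(ex) <= fnv1a64(etx)) c(x, y) else c(tx, og_flip_id(x))
}

# assemble the reported bubble table from canonical (x, y) id pairs
bubble_table <- function(g, xs, ys) {
  adj <- graph_adjacency(g)
  n <- length(xs)
  wl <- if (n && nrow(g$walks))
    split(g$walks$og, paste(g$walks$genome, g$walks$contig, sep = "\t")) else list()
  entrance <- character(n); exit <- character(n)
  interior <- vector("list", n)
  has_inv <- logical(n); npaths <- integer(n)
  for (i in seq_len(n)) {
    entrance[i] <- og_to_str(g$genes, xs[i])
    exit[i] <- og_to_str(g$genes, ys[i])
    u <- compute_U_int(adj, xs[i], ys[i])$genes
    interior[[i]] <- sort(g$genes[u])
    rx <- bfs_reach(adj, xs[i])
    has_inv[i] <- any(og_fwd(u) %in% rx & og_rev(u) %in% rx)
    npaths[i] <- count_walk_paths(g, xs[i], ys[i], wl)
  }
  out <- data.table(entrance = entrance, exit = exit,
                    n_interior_genes = lengths(interior),
                    interior = interior,
                    has_inversion = has_inv,
                    n_distinct_walk_paths = npaths)
  out <- out[order(fnv1a64(entrance))]
  out[]
}

# number of distinct oriented x..y sub-walks observed in the stored walks
# (twin occurrences are reverse-complemented into entrance-side form)
count_walk_paths <- function(g, x, y, wl = NULL) {
  if (nrow(g$walks) == 0L) return(0L)
  if (is.null(wl))
    wl <- split(g$walks$og, paste(g$walks$genome, g$walks$contig, sep = "\t"))
  paths <- character(0)
  # nearest-pair scan: an x occurrence matches the next y occurrence with no
  # later x in between
  scan1 <- function(seqv, a, b) {
    px <- which(seqv == a)
    if (!length(px)) return(character(0))
    py <- which(seqv == b)
    if (!length(py)) return(character(0))
    nb <- py[findInterval(px, py) + 1L]          # next b strictly after each a
    ok <- !is.na(nb)
    # keep only the last a before that b
    nxta <- c(px[-1L], Inf)
    ok <- ok & nxta > ifelse(is.na(nb), -Inf, nb)
    if (!any(ok)) return(character(0))
    vapply(which(ok), function(i) paste(seqv[px[i]:nb[i]], collapse = ","),
           character(1))
  }
  gx <- og_gene_id(x)
  for (s in wl) {
    if (!any(og_gene_id(s) == gx)) next
    paths <- c(paths, scan1(s, x, y))
    rc <- rev(og_flip_id(s))   # twin form: scan the reverse complement
    paths <- c(paths, scan1(rc, x, y))
  }
  length(unique(paths))
}

#' Enumerate generalized bibubbles
#'
#' For each candidate entrance, runs a breadth-first search over at most `m`
#' distinct genes, collects exit candidates that are cycle equivalent to the
#' entrance gene in the net graph, and tests candidates with the full
#' definition in search order; the first success is kept (an entrance heads
#' at most one bubble). Twin pairs are reported once, in canonical form, and
#' the result is ordered by the FNV-1a digest of the entrance.
#'
#' @param g a `pangraph`.
#' @param m maximum number of distinct genes traversed per entrance
#'   (entrance excluded); candidates discovered at the boundary are still
#'   tested.
#' @param entrances `"all"` tests every oriented gene; `"branching"` only
#'   entrances with two or more successors (a faster heuristic that can miss
#'   bubbles headed by a degree-one entrance, such as a pure tandem
#'   copy-number gain).
#' @return a `data.table` with columns `entrance`, `exit`,
#'   `n_interior_genes`, `interior` (list of sorted gene ids),
#'   `has_inversion` (an interior gene reachable in both orientations from
#'   the entrance) and `n_distinct_walk_paths`.
#' @examples
#' find_bibubbles(toy_graph("TOY2"))
#' @export
find_bibubbles <- function(g, m = 100L, entrances = c("all", "branching")) {
  stopifnot(inherits(g, "pangraph"))
  entrances <- match.arg(entrances)
  adj <- graph_adjacency(g)
  nn <- length(adj)
  if (nn == 0L) return(bubble_table(g, integer(0), integer(0)))
  gene_cls <- gene_classes(g)
  outdeg <- lengths(adj)
  # a bubble needs out-branching on the entrance side, so an entrance whose
  # unique-successor chain meets no branch point within m genes heads none;
  # propagate "reaches a branch point" along degree-one chains, vectorised
  branchy <- outdeg >= 2L
  nxt <- ifelse(outdeg == 1L, vapply(adj, function(a) if (length(a) == 1L) a else NA_integer_, integer(1)), NA_integer_)
  reach_branch <- branchy
  for (step in seq_len(m)) {
    upd <- !reach_branch & !is.na(nxt)
    if (!any(upd)) break
    nr <- reach_branch
    nr[upd] <- reach_branch[nxt[upd]]
    if (identical(nr, reach_branch)) break
    reach_branch <- nr
  }
  cand_entr <- which(outdeg > 0L & reach_branch)
  if (entrances == "branching") cand_entr <- cand_entr[outdeg[cand_entr] >= 2L]
  res_x <- integer(0); res_y <- integer(0)
  for (x in cand_entr) {
    cx <- gene_cls[og_gene_id(x)]
    seen <- logical(nn)
    queue <- integer(64L)
    queue[1L] <- x
    head <- 1L; tail <- 1L
    genes_seen <- logical(length(g$genes))
    n_genes <- 0L
    # candidates are tested in BFS discovery order as they are dequeued; a
    # test result other than "condition (i) failed" settles the entrance
    # (success, or minimality vetoes every later exit), which keeps the
    # traversal local in long chains
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      expand <- TRUE
      if (v != x) {
        gv <- og_gene_id(v)
        new_gene <- !genes_seen[gv]
        if (new_gene) { genes_seen[gv] <- TRUE; n_genes <- n_genes + 1L }
        if (gv != og_gene_id(x) && gene_cls[gv] == cx) {
          code <- bibubble_test(adj, x, v, gene_cls, cap = m)
          if (code == 1L) {
            res_x <- c(res_x, x); res_y <- c(res_y, v)
            break
          }
          if (code == 0L) break   # minimality vetoes every later exit
        }
        if (new_gene && n_genes > m) expand <- FALSE  # budget: test, don't expand
      }
      if (expand) {
        for (s in adj[[v]]) {
          if (!seen[s] && s != x) {
            seen[s] <- TRUE
            tail <- tail + 1L
            if (tail > length(queue)) queue <- c(queue, integer(length(queue)))
            queue[tail] <- s
          }
        }
      }
    }
  }
  finalize_bubbles(g, res_x, res_y)
}

finalize_bubbles <- function(g, xs, ys) {
  if (length(xs)) {
    canon <- mapply(function(x, y) bubble_canonical(g, x, y), xs, ys)
    key <- paste(canon[1, ], canon[2, ])
    keep <- !duplicated(key)
    xs <- canon[1, keep]; ys <- canon[2, keep]
  }
  bubble_table(g, xs, ys)
}

#' Brute-force bibubble oracle
#'
#' Tests every ordered pair of oriented genes with the full bibubble
#' definition. Quadratic in the number of oriented genes and intended as the
#' reference for [find_bibubbles()] on small graphs; guarded by size.
#'
#' @param g a `pangraph`.
#' @param max_genes size guard; an error is raised above it.
#' @return same format as [find_bibubbles()].
#' @export
find_bibubbles_bruteforce <- function(g, max_genes = 60L) {
  stopifnot(inherits(g, "pangraph"))
  if (length(g$genes) > max_genes)
    stop("find_bibubbles_bruteforce() is limited to ", max_genes, " genes")
  adj <- graph_adjacency(g)
  gene_cls <- gene_classes(g)
  nn <- length(adj)
  res_x <- integer(0); res_y <- integer(0)
  for (x in seq_len(nn)) {
    if (length(adj[[x]]) == 0L) next
    for (y in seq_len(nn)) {
      if (og_gene_id(x) == og_gene_id(y)) next
      if (is_bibubble_int(adj, x, y, gene_cls)) {
        res_x <- c(res_x, x); res_y <- c(res_y, y)
      }
    }
  }
  finalize_bubbles(g, res_x, res_y)
}

#' Write a bubble table as TSV
#'
#' @param bubbles a bubble table from [find_bibubbles()] or
#'   [find_bibubbles_bruteforce()].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_bubble_tsv <- function(bubbles, path) {
  out <- data.table(
    bubble_id = if (nrow(bubbles)) sprintf("bb%04d", seq_len(nrow(bubbles))) else character(0),
    entrance = bubbles$entrance,
    exit = bubbles$exit,
    n_interior_genes = bubbles$n_interior_genes,
    interior_genes = vapply(bubbles$interior, paste, character(1), collapse = ","),
    has_inversion = bubbles$has_inversion,
    n_distinct_walk_paths = bubbles$n_distinct_walk_paths)
  fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
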