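## Seeded synthetic-pangenome generator: ancestral gene order, per-genome
## deletions / inversions / tandem duplications, paralog families, PAF
## emission emulating spliced protein-to-genome alignment, and ground truth
## (walks, events, expected bubbles, copy table).

#' Simulation parameters
#'
#' Defaults describe a small eukaryote-like panel: 200 genes on two
#' chromosomes across 10 genomes, per-gene event rates of 2% deletion, 1%
#' inversion (spans of 1-3 genes) and 1% tandem duplication, 10%
#' single-coding-exon genes, alignment scores around 500 with 1% noise and
#' paralog cross-hits at 93% of the true-locus score.
#'
#' @param n_genes,n_genomes,n_chromosomes panel dimensions.
#' @param p_del,p_inv,p_dup per-gene, per-genome event probabilities.
#' @param inv_span inclusive range of genes covered by one inversion.
#' @param paralog_families,family_size number and size of paralogous gene
#'   families emitting cross-hits.
#' @param paralog_ratio score of a cross-hit relative to the (noisy) score
#'   of the true hit at that locus; the ratio is exact so the r1/r2 score
#'   thresholds behave deterministically.
#' @param score_base,score_noise mean alignment score and its relative s.d.
#' @param gene_len,intergenic_gap geometry (bp) used for coordinates.
#' @param single_exon_frac fraction of genes without introns.
#' @param min_event_spacing minimum number of unaffected genes between event
#'   sites (and a one-gene flank inside each chromosome end); when
#'   `enforce_spacing` is TRUE, conflicting sampled events are dropped and
#'   every surviving event yields one expected bubble.
#' @param enforce_spacing keep only isolated events (the study condition for
#'   end-to-end recovery); set FALSE for dense, messy graphs where no
#'   expected bubble list is derived.
#' @param seed integer seed; all randomness flows from it.
#' @return a configuration list for [simulate_pangenome()].
#' @export
sim_config <- function(n_genes = 200L, n_genomes = 10L, n_chromosomes = 2L,
                       p_del = 0.02, p_inv = 0.01, p_dup = 0.01,
                       inv_span = c(1L, 3L),
                       paralog_families = 0L, family_size = 2L,
                       paralog_ratio = 0.93,
                       score_base = 500, score_noise = 0.01,
                       gene_len = 1000, intergenic_gap = 10000,
                       single_exon_frac = 0.1,
                       min_event_spacing = 3L, enforce_spacing = TRUE,
                       seed = 1L) {
  stopifnot(n_genes >= 1L, n_genomes >= 1L, n_chromosomes >= 1L,
            p_del >= 0, p_del <= 1, p_inv >= 0, p_inv <= 1, p_dup >= 0, p_dup <= 1)
  as.list(environment())
}

#' Simulate a pangenome with known ground truth
#'
#' Splits an ancestral gene order into chromosomes and, in every genome
#' independently, applies deletions (drop a gene), inversions (reverse and
#' flip a span) and tandem duplications (one or two extra adjacent copies)
#' at the configured rates. With `enforce_spacing`, sampled events too close
#' to each other or to a chromosome end are discarded, so each surviving
#' event site is isolated and contributes one expected bubble: the pair of
#' forward-oriented flanking genes enclosing the affected span.
#'
#' @param cfg a [sim_config()].
#' @return an object of class `pg_truth`: a list with `cfg`, `genes`,
#'   `spliced`, `families`, `chrom` (gene to chromosome map), `walks`
#'   (per-genome oriented steps with coordinates and scores), `events`,
#'   `expected_bubbles` (`NULL` unless spacing is enforced) and `copies`
#'   (gene x genome count matrix over genes present somewhere).
#' @export
simulate_pangenome <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  n <- cfg$n_genes
  genes <- sprintf("g%05d", seq_len(n))
  spliced <- stats::runif(n) >= cfg$single_exon_frac
  names(spliced) <- genes
  chrom_of <- sort(rep_len(seq_len(cfg$n_chromosomes), n))
  chrom_name <- sprintf("chr%d", chrom_of)
  genomes <- sprintf("genome%02d", seq_len(cfg$n_genomes))
  families <- list()
  if (cfg$paralog_families > 0L) {
    pool <- sample(n, cfg$paralog_families * cfg$family_size)
    families <- split(genes[pool], rep(seq_len(cfg$paralog_families), each = cfg$family_size))
  }
  # sample candidate events (vectorised per genome; one event type at most
  # per gene and genome, deletion taking precedence over inversion over
  # duplication)
  chrom_last_of <- integer(n)
  for (cj in seq_len(cfg$n_chromosomes)) {
    pos <- which(chrom_of == cj)
    chrom_last_of[pos] <- max(pos)
  }
  ev <- list()
  for (gj in seq_along(genomes)) {
    u1 <- stats::runif(n); u2 <- stats::runif(n); u3 <- stats::runif(n)
    del_pos <- which(u1 < cfg$p_del)
    inv_pos <- which(u1 >= cfg$p_del & u2 < cfg$p_inv)
    dup_pos <- which(u1 >= cfg$p_del & u2 >= cfg$p_inv & u3 < cfg$p_dup)
    if (length(del_pos))
      ev[[length(ev) + 1L]] <- data.table(genome = genomes[gj], type = "del",
                                          s = del_pos, e = del_pos, k = 0L)
    if (length(inv_pos)) {
      spans <- sample(cfg$inv_span[1]:cfg$inv_span[2], length(inv_pos), replace = TRUE)
      ev[[length(ev) + 1L]] <- data.table(
        genome = genomes[gj], type = "inv", s = inv_pos,
        e = pmin(inv_pos + spans - 1L, chrom_last_of[inv_pos]), k = 0L)
    }
    if (length(dup_pos))
      ev[[length(ev) + 1L]] <- data.table(
        genome = genomes[gj], type = "dup", s = dup_pos, e = dup_pos,
        k = sample(1:2, length(dup_pos), replace = TRUE))
  }
  events <- if (length(ev)) rbindlist(ev) else
    data.table(genome = character(), type = character(), s = integer(), e = integer(), k = integer())
  events[, chrom := chrom_of[s]]
  if (cfg$enforce_spacing && nrow(events)) {
    chrom_first_of <- integer(n)
    for (cj in seq_len(cfg$n_chromosomes)) {
      pos <- which(chrom_of == cj)
      chrom_first_of[pos] <- min(pos)
    }
    sites <- unique(events[, .(chrom, s, e)])
    setorder(sites, chrom, s, e)
    keep <- logical(nrow(sites))
    prev_e <- -Inf; prev_chrom <- -1L
    for (i in seq_len(nrow(sites))) {
      flank_ok <- sites$s[i] - 1L >= chrom_first_of[sites$s[i]] &&
        sites$e[i] + 1L <= chrom_last_of[sites$s[i]]
      gap_ok <- sites$chrom[i] != prev_chrom ||
        (sites$s[i] - prev_e - 1L) >= cfg$min_event_spacing
      if (flank_ok && gap_ok) {
        keep[i] <- TRUE
        prev_e <- sites$e[i]; prev_chrom <- sites$chrom[i]
      }
    }
    sites <- sites[keep]
    events <- events[sites, on = c("chrom", "s", "e"), nomatch = NULL]
  }
  setorder(events, genome, chrom, s, e, type)
  # apply events per genome and chromosome (right to left; indices stay valid)
  wk <- list()
  for (gj in seq_along(genomes)) {
    for (cj in seq_len(cfg$n_chromosomes)) {
      idx <- which(chrom_of == cj)
      ori <- rep("+", length(idx))
      evs <- events[genome == genomes[gj] & chrom == cj]
      if (nrow(evs)) {
        setorder(evs, -s)
        for (r in seq_len(nrow(evs))) {
          rows <- which(idx >= evs$s[r] & idx <= evs$e[r])
          if (!length(rows)) next
          if (evs$type[r] == "del") {
            idx <- idx[-rows]; ori <- ori[-rows]
          } else if (evs$type[r] == "inv") {
            idx[rows] <- rev(idx[rows])
            ori[rows] <- rev(ifelse(ori[rows] == "+", "-", "+"))
          } else {
            k <- evs$k[r]
            at <- rows[length(rows)]
            idx <- append(idx, rep(idx[at], k), after = at)
            ori <- append(ori, rep(ori[at], k), after = at)
          }
        }
      }
      if (!length(idx)) next
      ns <- length(idx)
      start <- (seq_len(ns) - 1) * (cfg$gene_len + cfg$intergenic_gap)
      score <- round(cfg$score_base * (1 + stats::rnorm(ns, 0, cfg$score_noise)))
      wk[[length(wk) + 1L]] <- data.table(
        genome = genomes[gj], contig = sprintf("chr%d", cj),
        gene = genes[idx], orient = ori,
        start = start, end = start + cfg$gene_len,
        score = pmax(1, score), spliced = spliced[idx])
    }
  }
  walks <- rbindlist(wk)
  # expected bubbles from isolated event sites showing actual variation
  expected <- NULL
  if (cfg$enforce_spacing) {
    expected <- derive_expected_bubbles(events, genomes, genes, chrom_of)
  }
  copies <- truth_copies(walks, genes, genomes)
  structure(list(cfg = cfg, genes = genes, spliced = spliced,
                 families = families, chrom = setNames(chrom_name, genes),
                 genomes = genomes, walks = walks, events = events,
                 expected_bubbles = expected, copies = copies),
            class = "pg_truth")
}

truth_copies <- function(walks, genes, genomes) {
  pres <- genes[genes %in% walks$gene]
  m <- matrix(0L, nrow = length(pres), ncol = length(genomes),
              dimnames = list(pres, genomes))
  if (nrow(walks)) {
    tab <- walks[, .N, by = .(gene, genome)]
    m[cbind(match(tab$gene, pres), match(tab$genome, genomes))] <- tab$N
  }
  m
}

# the local gene string a genome displays over an isolated site
local_string <- function(type, k, s, e, genes) {
  core <- switch(type,
    none = paste0(">", genes[s:e]),
    del = character(0),
    inv = paste0("<", rev(genes[s:e])),
    dup = c(paste0(">", genes[s:e]), rep(paste0(">", genes[s]), k)))
  paste(core, collapse = "")
}

derive_expected_bubbles <- function(events, genomes, genes, chrom_of) {
  if (nrow(events) == 0L)
    return(data.table(entrance = character(), exit = character(), interior = list()))
  ev_by_site <- split(events, by = c("chrom", "s", "e"), sorted = TRUE)
  sites <- rbindlist(lapply(ev_by_site, function(d) d[1L, .(chrom, s, e)]))
  out <- list()
  for (i in seq_len(nrow(sites))) {
    ss <- sites$s[i]; ee <- sites$e[i]
    evs <- ev_by_site[[i]]
    sig_none <- local_string("none", 0L, ss, ee, genes)
    sig <- rep(sig_none, length(genomes))
    gj <- match(evs$genome, genomes)
    for (r in seq_len(nrow(evs)))
      sig[gj[r]] <- local_string(evs$type[r], evs$k[r], ss, ee, genes)
    if (length(unique(sig)) < 2L) next   # no variation at this site
    # forward flanks are already the canonical (forward-entrance) form
    a <- paste0(">", genes[ss - 1L]); b <- paste0(">", genes[ee + 1L])
    out[[length(out) + 1L]] <- data.table(entrance = a, exit = b,
                                          interior = list(sort(genes[ss:ee])))
  }
  if (!length(out))
    return(data.table(entrance = character(), exit = character(), interior = list()))
  res <- rbindlist(out)
  res[order(fnv1a64(entrance))]
}

#' Gene graph of the simulated truth walks
#'
#' Builds the `pangraph` a perfect pipeline would produce from the
#' simulation, bypassing alignment entirely. Used for oracle testing and as
#' the reference for end-to-end recovery.
#'
#' @param truth a `pg_truth` from [simulate_pangenome()].
#' @return a `pangraph`.
#' @export
truth_graph <- function(truth) {
  stopifnot(inherits(truth, "pg_truth"))
  w <- copy(truth$walks)
  wl <- list()
  if (nrow(w)) {
    setorder(w, genome, contig, start)
    sp <- split(seq_len(nrow(w)), paste(w$genome, w$contig, sep = "\t"))
    for (rows in sp) {
      wl[[length(wl) + 1L]] <- list(
        genome = w$genome[rows[1]], contig = w$contig[rows[1]],
        steps = paste0(ifelse(w$orient[rows] == "+", ">", "<"), w$gene[rows]),
        start = w$start[rows], end = w$end[rows],
        score = w$score[rows], n_introns = as.integer(w$spliced[rows]))
    }
  }
  pangraph_from_walks(wl, genomes = truth$genomes)
}

#' @export
print.pg_truth <- function(x, ...) {
  cat(sprintf("simulated pangenome: %d genes, %d genomes, %d event(s)\n",
              length(x$genes), length(x$genomes), nrow(x$events)))
  if (!is.null(x$expected_bubbles))
    cat(sprintf("  isolated event sites expecting a bubble: %d\n",
                nrow(x$expected_bubbles)))
  invisible(x)
}

#' Emit simulated alignments as PAF, one file per genome
#'
#' Every gene occurrence yields one PAF line at its coordinates with the
#' strand of its orientation and an `AS:i` score; spliced genes carry a
#' `cg:Z` tag with an intron operator, single-exon genes a match-only
#' CIGAR. Members of a paralog family additionally produce cross-hits at
#' each other member's loci at `paralog_ratio` of the (noisy) local score.
#'
#' @param truth a `pg_truth`.
#' @param dir output directory (created if needed).
#' @return named character vector of written file paths (names are genome
#'   ids).
#' @export
emit_paf <- function(truth, dir) {
  stopifnot(inherits(truth, "pg_truth"))
  cfg <- truth$cfg
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  qlen <- max(cfg$gene_len %/% 3, 10)
  fam_of <- list()
  for (f in truth$families) for (m in f) fam_of[[m]] <- setdiff(f, m)
  prot <- function(gene) paste0(gene, ":", gene, ".p1")
  cigar <- function(is_spliced) {
    if (is_spliced) sprintf("%dM%dN%dM", qlen %/% 2, 200L, qlen - qlen %/% 2)
    else sprintf("%dM", qlen)
  }
  cig_spliced <- cigar(TRUE); cig_plain <- cigar(FALSE)
  paths <- setNames(character(length(truth$genomes)), truth$genomes)
  for (gm in truth$genomes) {
    w <- truth$walks[genome == gm]
    setorder(w, contig, start)
    tlen <- w[, .(len = max(end) + cfg$intergenic_gap), by = contig]
    tl <- setNames(tlen$len, tlen$contig)
    # cross-hit rows: one per (occurrence, other family member)
    ww <- copy(w)
    ww[, `:=`(qname = w$gene, sc = w$score, spl = w$spliced)]
    if (length(fam_of)) {
      cross <- list()
      for (u in intersect(names(fam_of), unique(w$gene))) {
        occ <- w[gene == u]
        for (o in fam_of[[u]]) {
          oc <- copy(occ)
          oc[, `:=`(qname = o, sc = round(cfg$paralog_ratio * score),
                    spl = unname(truth$spliced[o]))]
          cross[[length(cross) + 1L]] <- oc
        }
      }
      if (length(cross)) ww <- rbind(ww, rbindlist(cross))
      setorder(ww, contig, start, qname)
    }
    lines <- sprintf("%s\t%d\t0\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t60\tAS:i:%d\tcg:Z:%s",
                     prot(ww$qname), qlen, qlen, ww$orient, ww$contig,
                     as.integer(tl[ww$contig]),
                     as.integer(ww$start), as.integer(ww$end),
                     as.integer(round(0.97 * cfg$gene_len)), as.integer(cfg$gene_len),
                     as.integer(ww$sc), ifelse(ww$spl, cig_spliced, cig_plain))
    paths[gm] <- file.path(dir, paste0(gm, ".paf"))
    writeLines(lines, paths[gm])
  }
  paths
}
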