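## GFA 1.1 with walks. Segments are genes (sequence always "*"), links are
## canonical edges, W lines carry one contig walk each. Tags written:
##   S: LN protein length when known, CN number of genomes containing the gene
##   L: NS number of supporting contigs, SC mean score of the source gene
##      among supporting contigs
## NS/SC/CN are this package's own vocabulary, documented in the README.

#' Write a gene graph as GFA 1.1
#'
#' @param g a `pangraph`.
#' @param path output file path.
#' @return invisibly, the path.
#' @examples
#' f <- tempfile(fileext = ".gfa")
#' write_gfa(toy_graph("TOY1"), f)
#' readLines(f)
#' @export
write_gfa <- function(g, path) {
  stopifnot(inherits(g, "pangraph"))
  lines <- "H\tVN:Z:1.1"
  cn <- integer(length(g$genes))
  if (nrow(g$walks)) {
    pres <- unique(data.table(k = og_gene_id(g$walks$og), genome = g$walks$genome))
    tab <- pres[, .N, by = k]
    cn[tab$k] <- tab$N
  }
  plen <- g$meta$protein_len
  for (i in seq_along(g$genes)) {
    s <- sprintf("S\t%s\t*", g$genes[i])
    if (!is.null(plen) && !is.na(plen[g$genes[i]]))
      s <- paste0(s, sprintf("\tLN:i:%d", as.integer(plen[g$genes[i]])))
    s <- paste0(s, sprintf("\tCN:i:%d", cn[i]))
    lines <- c(lines, s)
  }
  if (nrow(g$edges)) {
    e <- g$edges
    ori <- function(i) ifelse(og_is_fwd(i), "+", "-")
    lines <- c(lines, sprintf(
      "L\t%s\t%s\t%s\t%s\t0M\tNS:i:%d\tSC:f:%g",
      g$genes[og_gene_id(e$src)], ori(e$src),
      g$genes[og_gene_id(e$dst)], ori(e$dst),
      lengths(e$support), ifelse(is.na(e$score_fd), 0, e$score_fd)))
  }
  if (nrow(g$walks)) {
    wk <- g$walks[, .(
      start = if (all(is.na(start))) 0 else min(start, na.rm = TRUE),
      end = if (all(is.na(end))) 0 else max(end, na.rm = TRUE),
      walk = paste(ifelse(og_is_fwd(og), ">", "<"),
                   g$genes[og_gene_id(og)], sep = "", collapse = "")),
      by = .(genome, contig)]
    lines <- c(lines, sprintf("W\t%s\t0\t%s\t%d\t%d\t%s",
                              wk$genome, wk$contig,
                              as.integer(wk$start), as.integer(wk$end), wk$walk))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a GFA 1.1 gene graph
#'
#' Accepts S/L lines and optional W lines. Edges are stored skew
#' symmetrically regardless of the orientation convention of the input
#' links. When W lines are present, per-step placeholder coordinates are
#' assigned inside the walk interval, edge support is recomputed from the
#' walks, and every consecutive walk pair must be a link. GFA 2 input is
#' rejected.
#'
#' @param path GFA file path.
#' @return a `pangraph`.
#' @export
read_gfa <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  rec <- substr(lines, 1L, 1L)
  if (any(rec %in% c("E", "G", "F", "O", "U")) || any(grepl("^H\tVN:Z:2", lines)))
    stop("unsupported version: GFA 2 records found")
  sl <- strsplit(lines[rec == "S"], "\t", fixed = TRUE)
  genes <- sort(vapply(sl, `[[`, character(1), 2L))
  if (anyDuplicated(genes)) stop("duplicate segment names")
  extra <- list()
  plen <- setNames(rep(NA_integer_, length(genes)), genes)
  for (f in sl) {
    tags <- f[-(1:3)]
    ln <- grep("^LN:i:", tags, value = TRUE)
    if (length(ln)) plen[f[2]] <- as.integer(sub("^LN:i:", "", ln[1]))
    other <- tags[!grepl("^(LN|CN):", tags)]
    if (length(other)) extra[[paste0("S:", f[2])]] <- other
  }
  ll <- strsplit(lines[rec == "L"], "\t", fixed = TRUE)
  ex <- integer(0); ey <- integer(0); esc <- numeric(0); ens <- integer(0)
  for (f in ll) {
    if (length(f) < 6L) stop("malformed L line")
    if (!(f[2] %in% genes) || !(f[4] %in% genes))
      stop("L line references unknown segment: ", setdiff(c(f[2], f[4]), genes)[1])
    if (!(f[3] %in% c("+", "-")) || !(f[5] %in% c("+", "-")))
      stop("L line orientations must be + or -")
    x <- og_from_str(genes, paste0(ifelse(f[3] == "+", ">", "<"), f[2]))
    y <- og_from_str(genes, paste0(ifelse(f[5] == "+", ">", "<"), f[4]))
    tags <- if (length(f) > 6L) f[-(1:6)] else character(0)
    sc <- grep("^SC:f:", tags, value = TRUE)
    ns <- grep("^NS:i:", tags, value = TRUE)
    other <- tags[!grepl("^(SC|NS):", tags)]
    if (length(other)) extra[[paste0("L:", length(ex) + 1L)]] <- other
    ex <- c(ex, x); ey <- c(ey, y)
    esc <- c(esc, if (length(sc)) as.numeric(sub("^SC:f:", "", sc[1])) else NA_real_)
    ens <- c(ens, if (length(ns)) as.integer(sub("^NS:i:", "", ns[1])) else NA_integer_)
  }
  edges <- empty_edges()
  if (length(ex)) {
    cp <- canonical_pair(ex, ey)
    ed <- data.table(src = cp$src, dst = cp$dst, swapped = cp$swapped,
                     sc = esc, ns = ens)
    edges <- ed[, .(
      support = list(character(0)),
      score_fd = if (any(!swapped & !is.na(sc))) mean(sc[!swapped], na.rm = TRUE) else NA_real_,
      score_rv = if (any(swapped & !is.na(sc))) mean(sc[swapped], na.rm = TRUE) else NA_real_,
      false_edge = FALSE, low_priority = FALSE), by = .(src, dst)]
    setorder(edges, src, dst)
  }
  steps <- empty_steps()
  wl <- strsplit(lines[rec == "W"], "\t", fixed = TRUE)
  if (length(wl)) {
    stp <- vector("list", length(wl))
    for (i in seq_along(wl)) {
      f <- wl[[i]]
      if (length(f) < 7L) stop("malformed W line")
      mm <- regmatches(f[7], gregexpr("[<>][^<>]+", f[7]))[[1]]
      if (!length(mm)) stop("empty walk on W line")
      og <- og_from_str(genes, mm)
      # per-step coordinates are not stored in GFA; synthesize placeholders
      # that preserve the walk's overall [start, end) interval
      ws <- as.numeric(f[5]); we <- as.numeric(f[6])
      st <- ws + (seq_along(og) - 1) * 2000
      en <- st + 1000
      en[length(en)] <- max(we, en[length(en)])
      stp[[i]] <- data.table(genome = f[2], contig = f[4], og = og,
                             start = st, end = en,
                             score = NA_real_, n_introns = NA_integer_,
                             hit_id = NA_integer_)
    }
    steps <- rbindlist(stp)
    # every consecutive walk pair must be a stored link
    key <- paste(edges$src, edges$dst)
    chk <- steps[, if (.N > 1L) .(x = og[-.N], y = og[-1L]), by = .(genome, contig)]
    if (nrow(chk)) {
      cp <- canonical_pair(chk$x, chk$y)
      if (any(!paste(cp$src, cp$dst) %in% key))
        stop("walk/edge inconsistency: a walk step pair has no L line")
    }
    sup <- steps[, if (.N > 1L) .(x = og[-.N], y = og[-1L]), by = .(genome, contig)]
    if (nrow(sup)) {
      cp <- canonical_pair(sup$x, sup$y)
      sup[, `:=`(src = cp$src, dst = cp$dst)]
      supagg <- sup[, .(support = list(sort(unique(paste(genome, contig, sep = "\t"))))),
                    by = .(src, dst)]
      edges[supagg, support := i.support, on = c("src", "dst")]
    }
  }
  meta <- list(protein_len = plen)
  if (length(extra)) meta$gfa_extra <- extra
  new_pangraph(genes, edges, steps, meta)
}
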