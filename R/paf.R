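#' Parser options for miniprot-style PAF
#'
#' @param score_tags tags searched for the alignment score, in order of
#'   precedence; the first present wins. Falls back to column 10 (residue
#'   matches) with a warning when none is present.
#' @param intron_ops CIGAR operator characters counted as introns in the
#'   `cg:Z` tag; the default covers the miniprot dialect.
#' @return a list of parser options for [read_paf()].
#' @export
paf_options <- function(score_tags = c("AS:i", "ms:i"),
                        intron_ops = c("N", "U", "V")) {
  list(score_tags = score_tags, intron_ops = intron_ops)
}

#' Split a protein name into gene and protein identifiers
#'
#' Protein names of the form `<GeneID>:<ProteinID>` associate several
#' proteins with one gene; the gene id is everything before the first colon.
#' Names without a colon are their own gene id.
#'
#' @param name character vector of protein names.
#' @return a list with character vectors `gene` and `protein`.
#' @examples
#' split_protein_name("OPN1LW:ENSP00000358967")
#' @export
split_protein_name <- function(name) {
  if (any(!nzchar(name))) stop("empty protein name")
  gene <- sub(":.*$", "", name)
  list(gene = gene, protein = name)
}

#' Read a miniprot-style PAF file of protein-to-genome alignments
#'
#' Each line becomes one alignment hit of a protein (query) against a contig
#' (target). Coordinates are 0-based half-open on the target. The alignment
#' score is taken from the first tag present among `cfg$score_tags`; the
#' intron count is the number of intron operators in the `cg:Z` CIGAR tag
#' (0 when the tag is absent).
#'
#' @param path PAF file path.
#' @param genome genome id to attach to every hit (one PAF file per input
#'   assembly); defaults to the file stem.
#' @param cfg parser options from [paf_options()].
#' @return a `data.table` of hits with columns `hit_id`, `protein`, `gene`,
#'   `genome`, `contig`, `tstart`, `tend`, `strand`, `score`, `n_introns`,
#'   `identity`, `qcov`.
#' @export
read_paf <- function(path, genome = NULL, cfg = paf_options()) {
  if (is.null(genome)) genome <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_hits(genome))
  nf <- nchar(lines) - nchar(gsub("\t", "", lines, fixed = TRUE)) + 1L
  if (any(nf < 12L))
    stop(sprintf("malformed PAF in %s: line %d has %d columns (12 required)",
                 path, which(nf < 12L)[1], nf[which(nf < 12L)[1]]))
  cols <- data.table::tstrsplit(lines, "\t", fixed = TRUE, keep = 1:12)
  m <- do.call(cbind, cols)
  # everything after the 12 mandatory fields (empty when no tags)
  tagstr <- sub("^([^\t]*\t){11}[^\t]*", "", lines)
  num <- function(j) suppressWarnings(as.numeric(m[, j]))
  qlen <- num(2); qstart <- num(3); qend <- num(4)
  tlen <- num(7); tstart <- num(8); tend <- num(9)
  nmatch <- num(10); alen <- num(11)
  bad <- which(is.na(qlen) | is.na(tstart) | is.na(tend) | is.na(nmatch) | is.na(alen) |
                 !(m[, 5] %in% c("+", "-")))
  if (length(bad))
    stop(sprintf("malformed PAF in %s: line %d", path, bad[1]))
  grab_tag <- function(tag) {
    # tags are NAME:TYPE:VALUE; `tag` is the NAME
    pat <- paste0("(^|\t)", tag, ":[A-Za-z]:([^\t]*)")
    hasit <- grepl(pat, tagstr)
    out <- rep(NA_character_, length(tagstr))
    out[hasit] <- sub(pat, "\\2", regmatches(tagstr, regexpr(pat, tagstr)))
    out
  }
  score <- rep(NA_real_, length(lines))
  for (tag in cfg$score_tags) {
    val <- suppressWarnings(as.numeric(grab_tag(sub(":.*$", "", tag))))
    score[is.na(score)] <- val[is.na(score)]
  }
  if (anyNA(score)) {
    warning(sprintf("%s: %d line(s) without a score tag; using column 10 (residue matches)",
                    path, sum(is.na(score))))
    score[is.na(score)] <- nmatch[is.na(score)]
  }
  cg <- grab_tag("cg")
  oppat <- sprintf("[0-9]+[%s]", paste(cfg$intron_ops, collapse = ""))
  n_introns <- integer(length(cg))
  has_cg <- !is.na(cg)
  if (any(has_cg)) {
    n_introns[has_cg] <- vapply(gregexpr(oppat, cg[has_cg]),
                                function(r) sum(r > 0L), integer(1))
  }
  sp <- split_protein_name(m[, 1])
  data.table(
    hit_id = seq_along(lines),
    protein = sp$protein, gene = sp$gene,
    genome = genome, contig = m[, 6],
    tstart = tstart, tend = tend, strand = m[, 5],
    score = score, n_introns = n_introns,
    identity = ifelse(alen > 0, nmatch / alen, NA_real_),
    qcov = ifelse(qlen > 0, (qend - qstart) / qlen, NA_real_))
}

empty_hits <- function(genome = character(0)) {
  data.table(hit_id = integer(), protein = character(), gene = character(),
             genome = character(), contig = character(),
             tstart = numeric(), tend = numeric(), strand = character(),
             score = numeric(), n_introns = integer(),
             identity = numeric(), qcov = numeric())
}

#' Read several PAF files, one genome each
#'
#' @param paths character vector of PAF paths; names override the per-file
#'   genome id (unnamed entries use the file stem).
#' @param cfg parser options from [paf_options()].
#' @return combined hit table with globally unique `hit_id`.
#' @export
read_paf_set <- function(paths, cfg = paf_options()) {
  nms <- names(paths)
  if (is.null(nms)) nms <- rep("", length(paths))
  hits <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    gid <- if (nzchar(nms[i])) nms[i] else NULL
    hits[[i]] <- read_paf(paths[i], genome = gid, cfg = cfg)
  }
  out <- rbindlist(hits)
  out[, hit_id := seq_len(.N)]
  out[]
}
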