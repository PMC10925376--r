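#' 64-bit FNV-1a hash of character strings
#'
#' Deterministic, platform-independent hash used throughout the package for
#' tie-breaking: protein choice, best-hit ties, the gene selection order and
#' the canonical form and ordering of bibubbles. Reproducible orderings are
#' what make repeated runs byte-identical.
#'
#' The 64-bit state is carried as four 16-bit limbs in doubles, so no integer
#' overflow can occur in base R.
#'
#' @param x character vector.
#' @return character vector of 16-character lowercase hex digests, one per
#'   element of `x`. Hex digests compare in the same order as the underlying
#'   unsigned 64-bit values.
#' @examples
#' fnv1a64(c("OPN1LW", "rpoB"))
#' @export
fnv1a64 <- function(x) {
  if (!is.character(x)) stop("fnv1a64() expects a character vector")
  n <- length(x)
  if (n == 0L) return(character(0))
  # one pass over all code points: join with a \x01 separator and index back
  lens <- nchar(x, type = "chars")
  codes <- utf8ToInt(enc2utf8(paste(x, collapse = "\x01")))
  starts <- cumsum(c(1L, lens[-n] + 1L))
  maxlen <- max(lens, 0L)
  # offset basis 0xcbf29ce484222325, little-endian 16-bit limbs
  a0 <- rep(8997, n); a1 <- rep(33826, n); a2 <- rep(40164, n); a3 <- rep(52210, n)
  if (maxlen > 0L) {
    for (j in seq_len(maxlen)) {
      act <- which(lens >= j)
      if (!length(act)) break
      a0[act] <- bitwXor(as.integer(a0[act]), codes[starts[act] + j - 1L] %% 256L)
      # multiply by FNV prime 0x100000001b3 = 2^40 + 0x1b3:
      # 16-bit limbs p0 = 0x1b3, p2 = 0x100 (higher products overflow 2^64)
      t0 <- a0[act] * 435
      t1 <- a1[act] * 435
      t2 <- a2[act] * 435 + a0[act] * 256
      t3 <- a3[act] * 435 + a1[act] * 256
      r0 <- t0 %% 65536; c0 <- t0 %/% 65536
      t1 <- t1 + c0
      r1 <- t1 %% 65536; c1 <- t1 %/% 65536
      t2 <- t2 + c1
      r2 <- t2 %% 65536; c2 <- t2 %/% 65536
      r3 <- (t3 + c2) %% 65536
      a0[act] <- r0; a1[act] <- r1; a2[act] <- r2; a3[act] <- r3
    }
  }
  sprintf("%04x%04x%04x%04x", a3, a2, a1, a0)
}

# rank of each string under the FNV-1a order (1 = smallest digest);
# ties in input strings share a rank only if the strings are identical
fnv_rank <- function(x) {
  h <- fnv1a64(x)
  # break exact digest ties (identical strings) stably
  rank(h, ties.method = "first")
}
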