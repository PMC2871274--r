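#' Align a three-letter read to one logical reference space
#'
#' Returns every distinct placement of `read3` in the requested space with
#' Hamming distance at most `m`, by pigeonhole seed-and-extend: the read is
#' seeded with `m + 1` non-overlapping segments, so any placement with at
#' most `m` mismatches carries at least one exact seed and completeness is
#' guaranteed.  Reads too short to carry `m + 1` seeds of the index's `k`
#' fall back to a full sliding-window scan (attribute `fallback`), never to
#' silently dropped hits.  Hits in the G/A spaces (`RCW_GA`, `RCC_GA`) are
#' computed by searching the reverse complement of the query against the
#' corresponding C/T index and reflecting the offsets — identical results by
#' the `RCW_GA = revcomp(W_CT)` identity.
#'
#' `read3` must already be converted for the space searched: C-to-T
#' ([convertRead()] direction `"FW"`) for `W_CT`/`C_CT`, G-to-A
#' (direction `"RC"`) for `RCW_GA`/`RCC_GA`.
#'
#' @param read3 a single converted read string.
#' @param ref a [BSReferenceIndex-class].
#' @param space the logical space to search.
#' @param m maximum mismatches in three-letter space.
#' @param cap stop enumerating after this many hits and flag the read
#'   (attribute `capped`); at that point the read is already multi-hit, so
#'   the downstream uniqueness decision is unaffected.
#' @return `data.frame` with columns `space`, `chrom`, `offset` (0-based
#'   within the space), `mm3`, sorted by `(chrom, offset)`.
#' @examples
#' ref <- buildBSIndex(Biostrings::DNAStringSet(c(c1 = "TTATGG")), k = 2)
#' alignRead("TATG", ref, "W_CT", m = 0)
#' @export
alignRead <- function(read3, ref, space = .SPACE_IDS, m = 3L, cap = 500L) {
  stopifnot(is(ref, "BSReferenceIndex"))
  .check_scalar_string(read3, "read3")
  space <- match.arg(space)
  m <- as.integer(m)
  if (m < 0L) stop("m must be >= 0")
  ga <- space %in% c("RCW_GA", "RCC_GA")
  idx <- if (space %in% c("W_CT", "RCW_GA")) ref@indexW else ref@indexC
  query <- if (ga) .revcomp(read3) else read3
  res <- cpp_align_batch(query, idx@table, m, as.integer(cap))
  n <- nchar(read3)
  gpos <- res$gstart
  ci <- findInterval(gpos, idx@table$chrom_start[-1L]) + 1L
  off <- gpos - idx@table$chrom_start[ci]
  if (ga) {
    L <- diff(idx@table$chrom_start)[ci]
    off <- L - off - n
  }
  out <- data.frame(space = rep(space, length(off)),
                    chrom = idx@chromNames[ci],
                    offset = off, mm3 = res$mm)
  out <- out[order(out$chrom, out$offset), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fallback") <- any(res$fallback)
  attr(out, "capped") <- any(res$capped)
  out
}

#' Brute-force alignment oracle
#'
#' Full sliding-window Hamming scan of a converted read against the
#' sequences of one reference space; defines ground truth for
#' [alignRead()].  Written independently in R (vectorised over windows) so
#' the two routes share no code.
#'
#' @param read3 a single converted read string.
#' @param sequences a named character vector (or [ReferenceSpace-class])
#'   of space sequences.
#' @param m maximum mismatches.
#' @return `data.frame` with columns `chrom`, `offset`, `mm3`, sorted by
#'   `(chrom, offset)`.
#' @export
alignBruteForce <- function(read3, sequences, m) {
  .check_scalar_string(read3, "read3")
  if (is(sequences, "ReferenceSpace"))
    sequences <- setNames(as.character(sequences@sequences),
                          names(sequences@sequences))
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  r <- utf8ToInt(read3)
  n <- length(r)
  ncode <- utf8ToInt("N")
  pieces <- lapply(names(sequences), function(ch) {
    s <- utf8ToInt(sequences[[ch]])
    nw <- length(s) - n + 1L
    if (nw < 1L || n == 0L)
      return(data.frame(chrom = character(0), offset = integer(0),
                        mm3 = integer(0)))
    mm <- integer(nw)
    for (i in seq_len(n)) {
      g <- s[i:(i + nw - 1L)]
      mm <- mm + as.integer(g != r[i] | r[i] == ncode | g == ncode)
    }
    keep <- which(mm <= m)
    data.frame(chrom = rep(ch, length(keep)), offset = keep - 1L,
               mm3 = mm[keep])
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$chrom, out$offset), , drop = FALSE]
  rownames(out) <- NULL
  out
}
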