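#' Pool one read's hits from all logical spaces
#'
#' Concatenates per-space hit tables (as returned by [alignRead()]) and
#' removes duplicate `(space, chrom, offset)` rows.  A tagged FW read pools
#' hits from `W_CT` and `C_CT` only; an UNKNOWN-tag read pools all four
#' spaces.
#'
#' @param ... hit `data.frame`s, or a single list of them.
#' @return combined `data.frame` with columns `space`, `chrom`, `offset`,
#'   `mm3`.
#' @export
mergeHits <- function(...) {
  hl <- list(...)
  if (length(hl) == 1L && is.list(hl[[1L]]) && !is.data.frame(hl[[1L]]))
    hl <- hl[[1L]]
  out <- do.call(rbind, lapply(hl, function(h)
    h[, c("space", "chrom", "offset", "mm3"), drop = FALSE]))
  if (is.null(out))
    return(data.frame(space = character(0), chrom = character(0),
                      offset = integer(0), mm3 = integer(0)))
  out <- out[!duplicated(out[, c("space", "chrom", "offset")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply the uniqueness rule to a read's pooled hits
#'
#' A read is uniquely mapped iff exactly one hit attains the minimum
#' three-letter mismatch count: an alignment is unique when no other hit has
#' the same or fewer mismatches in three-letter space.  A strictly worse hit
#' does not break uniqueness; a tie at the best count discards the read as
#' ambiguous (never assigned at random — random assignment of non-unique
#' reads is exactly what biases downstream methylation estimates).
#'
#' @param hits pooled hits from [mergeHits()].
#' @return a list with `status` (`"unique"`, `"ambiguous"` or `"no_hit"`)
#'   and, when unique, `hit` (the single best row).
#' @export
uniquenessFilter <- function(hits) {
  if (nrow(hits) == 0L) return(list(status = "no_hit", hit = NULL))
  b <- min(hits$mm3)
  at <- which(hits$mm3 == b)
  if (length(at) > 1L) return(list(status = "ambiguous", hit = NULL))
  list(status = "unique", hit = hits[at, , drop = FALSE])
}

.space_to_watson <- function(space, offset, L, n) {
  # 1-based Watson start of the leftmost base, plus the read-form label
  start <- ifelse(space %in% c("W_CT", "RCC_GA"), offset + 1L,
                  L - offset - n + 1L)
  form <- c(W_CT = "+FW", C_CT = "-FW", RCW_GA = "+RC", RCC_GA = "-RC")[space]
  list(start = as.integer(start), form = unname(form))
}

#' Transform a space hit to Watson coordinates
#'
#' Maps a hit's 0-based offset in its logical space to the 1-based Watson
#' coordinate of the read's leftmost base, the read-form label
#' (`W_CT` hosts +FW, `C_CT` -FW, `RCW_GA` +RC, `RCC_GA` -RC), and the
#' original-alphabet reference segment in the orientation matching the
#' read's written sequence (+FW and -RC read along Watson; -FW and +RC along
#' the reverse complement).
#'
#' @param hit a one-row hit `data.frame` (columns `space`, `chrom`,
#'   `offset`).
#' @param readLen read length in bp.
#' @param genome the original genome (`DNAStringSet`).
#' @return list with `chrom`, `start`, `form`, `genomeSeq`.
#' @export
toWatson <- function(hit, readLen, genome) {
  stopifnot(is.data.frame(hit), nrow(hit) == 1L, is(genome, "DNAStringSet"))
  L <- Biostrings::width(genome)[match(hit$chrom, names(genome))]
  tw <- .space_to_watson(hit$space, hit$offset, L, readLen)
  if (tw$start < 1L || tw$start + readLen - 1L > L)
    stop("internal error: transformed coordinates out of bounds")
  seg <- as.character(Biostrings::subseq(genome[[hit$chrom]], tw$start,
                                         width = readLen))
  if (tw$form %in% c("-FW", "+RC")) seg <- .revcomp(seg)
  list(chrom = hit$chrom, start = tw$start, form = tw$form, genomeSeq = seg)
}

#' Recount mismatches with the asymmetric bisulfite rule
#'
#' In the original alphabet, a position matches when the bases are equal, or
#' when (forward forms) the read has T over a genomic C — bisulfite
#' conversion of an unmethylated C — or when (reverse-complement forms) the
#' read has A over a genomic G.  The converse substitutions (read C over
#' genomic T; read G over genomic A) are mismatches, as is N on either side.
#'
#' @param readOrig read sequences (original alphabet, read orientation).
#' @param genomeSeq reference segments in the same orientation.
#' @param form read form(s) (`+FW`, `-FW` use the T/C rule; `+RC`, `-RC`
#'   the A/G rule); recycled to the length of `readOrig`.
#' @return integer vector of mismatch counts.
#' @examples
#' recountMismatches("TTGA", "CTGA", "+FW")  # 0
#' recountMismatches("CTGA", "TTGA", "+FW")  # 1
#' recountMismatches("AAGT", "GAGT", "+RC")  # 0
#' @export
recountMismatches <- function(readOrig, genomeSeq, form) {
  if (!all(form %in% .FORMS)) stop("invalid form label")
  rc <- rep_len(form %in% .RC_FORMS, length(readOrig))
  cpp_bs_mismatches(readOrig, genomeSeq, rc)
}

#' Mismatch-threshold filter
#'
#' Keep iff the recounted original-space mismatch count does not exceed
#' `maxMM`; alignments with more mismatches than the user-defined value are
#' discarded (the threshold itself is kept).
#'
#' @param mmOrig integer vector of recounted mismatch counts.
#' @param maxMM user threshold.
#' @return logical keep vector.
#' @export
qualityFilter <- function(mmOrig, maxMM) mmOrig <= maxMM

# Batch alignment of a query set against one physical index, returning hits
# in Watson coordinates.  `ga` marks queries that are reverse complements of
# G/A-converted reads (logical spaces RCW_GA / RCC_GA).
.batch_space <- function(queries, readIdx, idx, crick, ga, m, cap) {
  res <- cpp_align_batch(queries, idx@table, m, as.integer(cap))
  gpos <- res$gstart
  ci <- findInterval(gpos, idx@table$chrom_start[-1L]) + 1L
  off <- gpos - idx@table$chrom_start[ci]
  L <- diff(idx@table$chrom_start)[ci]
  n <- nchar(queries)[res$read]
  space <- rep(if (!ga && !crick) "W_CT" else if (!ga) "C_CT"
               else if (!crick) "RCW_GA" else "RCC_GA", length(off))
  # offsets of a hit found via the revcomp identity, reflected into the
  # logical G/A space
  if (ga) off <- L - off - n
  tw <- .space_to_watson(space, off, L, n)
  list(df = data.frame(read = readIdx[res$read], space = space,
                       chromIdx = ci, offset = off, start = tw$start,
                       form = tw$form, mm3 = res$mm),
       fallback = readIdx[res$fallback], capped = readIdx[res$capped])
}

#' Map a read set against a reference
#'
#' The full post-tag pipeline: three-letter conversion of each read for the
#' directions its tag class allows, alignment across the corresponding
#' logical reference spaces, pooling and the uniqueness rule, transform to
#' Watson coordinates with form designation, asymmetric-rule mismatch
#' recount in the original alphabet, and the user mismatch threshold.
#' Directional-protocol reads are FW only, so exactly two alignment passes
#' run; tagged reads with an UNKNOWN tag are searched in all four spaces.
#'
#' @param reads a [BSReadSet-class]; tagged-protocol reads must have been
#'   through [classifyTags()].
#' @param ref a [BSReferenceIndex-class].
#' @param m3 maximum mismatches in three-letter space (alignment phase).
#' @param maxMM maximum recounted original-space mismatches (post filter).
#' @param cap per-space hit enumeration cap; reads exceeding it are
#'   discarded as ambiguous (they are multi-hit by then).
#' @param minAlignable reads whose trimmed sequence is shorter than this are
#'   discarded as `too_short`.
#' @return a [BSAlignments-class].
#' @export
mapReads <- function(reads, ref, m3 = 3L, maxMM = 2L, cap = 500L,
                     minAlignable = 20L) {
  stopifnot(is(reads, "BSReadSet"), is(ref, "BSReferenceIndex"))
  if (identical(reads@protocol, "cokus") &&
      identical(reads@seq, reads@trimmed) && length(reads) > 0L)
    stop("tagged-protocol reads must be classified with classifyTags() first")
  m3 <- as.integer(m3)
  genome <- ref@genome
  nr <- length(reads)
  nchar_tr <- nchar(reads@trimmed)
  tooShort <- nchar_tr < minAlignable | is.na(reads@tagClass)
  alive <- which(!tooShort)

  cls <- reads@tagClass
  fwSet <- alive[cls[alive] %in% c("FW", "UNKNOWN")]
  rcSet <- alive[cls[alive] %in% c("RC", "UNKNOWN")]
  qFw <- .ct(reads@trimmed[fwSet])
  # revcomp of the G/A-converted read == C-to-T of the revcomp
  qRc <- .ct(.revcomp(reads@trimmed[rcSet]))

  batches <- list()
  passes <- 0L
  if (length(fwSet)) {
    batches$A <- .batch_space(qFw, fwSet, ref@indexW, crick = FALSE,
                              ga = FALSE, m3, cap)
    batches$B <- .batch_space(qFw, fwSet, ref@indexC, crick = TRUE,
                              ga = FALSE, m3, cap)
    passes <- passes + 2L
  }
  if (length(rcSet)) {
    batches$C <- .batch_space(qRc, rcSet, ref@indexW, crick = FALSE,
                              ga = TRUE, m3, cap)
    batches$D <- .batch_space(qRc, rcSet, ref@indexC, crick = TRUE,
                              ga = TRUE, m3, cap)
    passes <- passes + 2L
  }

  H <- do.call(rbind, lapply(batches, `[[`, "df"))
  cappedReads <- unique(unlist(lapply(batches, `[[`, "capped")))
  fallbackReads <- unique(unlist(lapply(batches, `[[`, "fallback")))
  if (length(fallbackReads))
    message(length(fallbackReads),
            " read(s) too short for pigeonhole seeding; full-scan fallback used")

  reason <- rep(NA_character_, nr)
  reason[tooShort] <- "too_short"

  uniqueRows <- NULL
  if (!is.null(H) && nrow(H)) {
    o <- order(H$read, H$mm3)
    H <- H[o, , drop = FALSE]
    firstIdx <- which(!duplicated(H$read))
    best <- H[firstIdx, , drop = FALSE]
    bi <- match(H$read, best$read)
    nbest <- tabulate(bi[H$mm3 == best$mm3[bi]], nbins = nrow(best))
    isUnique <- nbest == 1L & !(best$read %in% cappedReads)
    uniqueRows <- best[isUnique, , drop = FALSE]
    reason[best$read[!isUnique]] <- "ambiguous"
    reason[setdiff(alive, H$read)] <- "no_hit"
  } else {
    reason[alive] <- "no_hit"
  }
  reason[intersect(alive, cappedReads)] <- "ambiguous"

  hitsGR <- GenomicRanges::GRanges(seqinfo = GenomeInfoDb::Seqinfo(
    seqnames = names(genome), seqlengths = Biostrings::width(genome)))
  mcolsDf <- S4Vectors::DataFrame(readId = character(0), form = character(0),
    strandCode = character(0), readSeq = character(0),
    genomeSeq = character(0), mm3 = integer(0), mmOrig = integer(0),
    methString = character(0))
  S4Vectors::mcols(hitsGR) <- mcolsDf

  if (!is.null(uniqueRows) && nrow(uniqueRows)) {
    u <- uniqueRows
    n <- nchar_tr[u$read]
    stopifnot(all(u$start >= 1L),
              all(u$start + n - 1L <= Biostrings::width(genome)[u$chromIdx]))
    # original-alphabet segment, Watson orientation, then flipped for the
    # forms read along the reverse complement
    seg <- character(nrow(u))
    for (ci in unique(u$chromIdx)) {
      sel <- which(u$chromIdx == ci)
      seg[sel] <- as.character(Biostrings::extractAt(
        genome[[ci]], IRanges::IRanges(u$start[sel], width = n[sel])))
    }
    flip <- u$form %in% c("-FW", "+RC")
    seg[flip] <- .revcomp(seg[flip])
    readSeq <- reads@trimmed[u$read]
    mmOrig <- recountMismatches(readSeq, seg, u$form)
    keep <- qualityFilter(mmOrig, maxMM)
    reason[u$read[!keep]] <- "low_quality"
    u <- u[keep, , drop = FALSE]
    if (nrow(u)) {
      originStrand <- ifelse(u$form %in% c("+FW", "+RC"), "+", "-")
      hitsGR <- GenomicRanges::GRanges(
        seqnames = factor(names(genome)[u$chromIdx], names(genome)),
        ranges = IRanges::IRanges(u$start, width = n[keep]),
        strand = originStrand,
        seqinfo = GenomeInfoDb::Seqinfo(seqnames = names(genome),
                                        seqlengths = Biostrings::width(genome)))
      S4Vectors::mcols(hitsGR) <- S4Vectors::DataFrame(
        readId = reads@id[u$read], form = u$form,
        strandCode = unname(.STRAND_CODE[u$form]),
        readSeq = readSeq[keep], genomeSeq = seg[keep],
        mm3 = u$mm3, mmOrig = mmOrig[keep],
        methString = rep(NA_character_, nrow(u)))
    }
  }

  unm <- which(!is.na(reason))
  new("BSAlignments", hits = hitsGR,
      unmapped = data.frame(readId = reads@id[unm], reason = reason[unm]),
      nReads = nr, protocol = reads@protocol,
      stats = list(alignmentPasses = passes,
                   seedFallbackReads = length(fallbackReads),
                   cappedReads = length(cappedReads),
                   m3 = m3, maxMM = as.integer(maxMM)))
}
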