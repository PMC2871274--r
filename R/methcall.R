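#' Classify the sequence context of a cytosine
#'
#' On the strand carrying the C, the next base G gives CG; otherwise a G two
#' bases downstream gives CHG; otherwise CHH (H is A, C or T).  Context is
#' assigned from the reference genome only, never from reads, so sequencing
#' errors cannot shift context.  Positions running off the chromosome end
#' treat the missing bases as H.
#'
#' @param genome original genome (`DNAStringSet`).
#' @param chrom,pos,strand parallel vectors: chromosome, 1-based Watson
#'   coordinate of the cytosine, and the strand (`"+"`/`"-"`) carrying it.
#' @return character vector, `"CG"`, `"CHG"` or `"CHH"`.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "ACGT"))
#' classifyContext(g, "chr1", 2, "+")  # "CG"
#' @export
classifyContext <- function(genome, chrom, pos, strand) {
  stopifnot(is(genome, "DNAStringSet"))
  n <- length(pos)
  chrom <- rep_len(as.character(chrom), n)
  strand <- rep_len(as.character(strand), n)
  out <- character(n)
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    x <- as.character(genome[[ch]])
    p <- pos[sel]
    plus <- strand[sel] == "+"
    base <- substring(x, p, p)
    if (any(base[plus] != "C"))
      stop("position not a C on the + strand of ", ch)
    if (any(base[!plus] != "G"))
      stop("position not a C on the - strand of ", ch)
    # next bases 5'->3' on the C's strand; complemented lookups for '-'
    b1 <- ifelse(plus, substring(x, p + 1L, p + 1L),
                 chartr("ACGT", "TGCA", substring(x, p - 1L, p - 1L)))
    b2 <- ifelse(plus, substring(x, p + 2L, p + 2L),
                 chartr("ACGT", "TGCA", substring(x, p - 2L, p - 2L)))
    out[sel] <- ifelse(b1 == "G", "CG", ifelse(b2 == "G", "CHG", "CHH"))
  }
  out
}

# Vectorised per-read methylation extraction.  Fragment orientation = the
# origin strand read 5'->3': RC-form reads are flipped back before calling.
.call_reads <- function(readId, form, readSeq, genomeSeq, chrom, start) {
  rc <- form %in% .RC_FORMS
  fragRead <- readSeq
  fragRead[rc] <- .revcomp(fragRead[rc])
  fragRef <- genomeSeq
  fragRef[rc] <- .revcomp(fragRef[rc])
  ext <- cpp_meth_extract(fragRead, fragRef)
  strings <- ext$string
  # report the string in read orientation, one character per read base
  strings[rc] <- vapply(strsplit(strings[rc], ""), function(ch)
    paste(rev(ch), collapse = ""), character(1))
  j <- ext$read
  n <- nchar(readSeq)[j]
  plusOrigin <- form[j] %in% c("+FW", "+RC")
  pos <- ifelse(plusOrigin, start[j] + ext$fragpos - 1L,
                start[j] + n - ext$fragpos)
  list(calls = data.frame(readId = readId[j], chrom = chrom[j], pos = pos,
                          strand = ifelse(plusOrigin, "+", "-"),
                          state = ext$state),
       strings = setNames(strings, readId))
}

#' Per-read methylation calls
#'
#' For every read position whose origin-strand genome base is C: a read C is
#' a methylated call (bisulfite leaves methylated cytosines unchanged), a
#' read T an unmethylated call (unmethylated Cs read as T), and any other
#' base no call.  Sites are reported in Watson coordinates with the strand
#' carrying the C; the per-read methylation string has one character per
#' read base (`M`/`U`/`.`/`-`, read orientation).
#'
#' @param aln a [BSAlignments-class].
#' @param genome the original genome (`DNAStringSet`); used only for
#'   validation here, contexts are assigned in [aggregateCalls()].
#' @return list with `calls` (`data.frame`: `readId`, `chrom`, `pos`,
#'   `strand`, `state` 0/1) and `strings` (named character).
#' @export
callRead <- function(aln, genome) {
  stopifnot(is(aln, "BSAlignments"), is(genome, "DNAStringSet"))
  h <- aln@hits
  mc <- S4Vectors::mcols(h)
  .call_reads(mc$readId, mc$form, mc$readSeq, mc$genomeSeq,
              as.character(GenomeInfoDb::seqnames(h)),
              GenomicRanges::start(h))
}

#' Aggregate methylation calls into per-site counts and context rates
#'
#' Counts are summed per `(chrom, pos, strand)`; calls from reads of the two
#' strands covering the same CG dinucleotide land on their two distinct Cs
#' and are never merged.  Genome-wide rates are pooled
#' (`sum nMeth / sum nTotal * 100` per context), i.e. coverage-weighted, not
#' averaged over sites; a context with zero coverage is `NA`.
#'
#' @param calls the `calls` data frame from [callRead()].
#' @param genome original genome, for context classification.
#' @param strings optional named methylation strings to carry along.
#' @return a [MethylationResult-class].
#' @export
aggregateCalls <- function(calls, genome, strings = character(0)) {
  stopifnot(is(genome, "DNAStringSet"))
  sl <- setNames(Biostrings::width(genome), names(genome))
  if (nrow(calls) == 0L) {
    sites <- GenomicRanges::GRanges(seqlengths = sl)
    S4Vectors::mcols(sites) <- S4Vectors::DataFrame(
      context = character(0), nMeth = integer(0), nTotal = integer(0))
    return(new("MethylationResult", sites = sites,
               summary = c(CG = NA_real_, CHG = NA_real_, CHH = NA_real_),
               strings = strings))
  }
  key <- paste(calls$chrom, calls$pos, calls$strand)
  g <- factor(key)
  nMeth <- as.integer(rowsum(calls$state, g)[, 1L])
  nTotal <- tabulate(g, nbins = nlevels(g))
  first <- match(levels(g), key)
  chrom <- calls$chrom[first]
  pos <- calls$pos[first]
  strand <- calls$strand[first]
  context <- classifyContext(genome, chrom, pos, strand)
  sites <- GenomicRanges::GRanges(
    seqnames = factor(chrom, names(genome)),
    ranges = IRanges::IRanges(pos, width = 1L),
    strand = strand, seqlengths = sl)
  S4Vectors::mcols(sites) <- S4Vectors::DataFrame(
    context = context, nMeth = nMeth, nTotal = nTotal)
  sites <- GenomicRanges::sort(sites, ignore.strand = TRUE)
  rate <- function(ctx) {
    tot <- sum(S4Vectors::mcols(sites)$nTotal[S4Vectors::mcols(sites)$context == ctx])
    if (tot == 0L) return(NA_real_)
    100 * sum(S4Vectors::mcols(sites)$nMeth[S4Vectors::mcols(sites)$context == ctx]) / tot
  }
  new("MethylationResult", sites = sites,
      summary = c(CG = rate("CG"), CHG = rate("CHG"), CHH = rate("CHH")),
      strings = strings)
}

#' Call methylation over a mapping result
#'
#' Runs [callRead()] and [aggregateCalls()] over all uniquely mapped,
#' quality-passed reads.
#'
#' @inheritParams callRead
#' @return a [MethylationResult-class].
#' @export
callMethylation <- function(aln, genome) {
  cr <- callRead(aln, genome)
  aggregateCalls(cr$calls, genome, cr$strings)
}
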