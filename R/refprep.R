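#' Load a reference genome from FASTA
#'
#' Reads a (multi-)FASTA file into an uppercase [Biostrings::DNAStringSet].
#' Record names are truncated at the first whitespace.  Only the letters
#' A, C, G, T and N are admitted in the reference.
#'
#' @param path path to a FASTA file.
#' @return a named `DNAStringSet`, one entry per FASTA record.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1 test", "acgtN"), fa)
#' loadFasta(fa)
#' @export
loadFasta <- function(path) {
  .check_scalar_string(path, "path")
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0L) stop("empty FASTA file: ", path)
  first <- readLines(path, n = 1L)
  if (!startsWith(first, ">"))
    stop("malformed FASTA at line 1: expected '>', got: ",
         substr(first, 1L, 30L))
  g <- tryCatch(Biostrings::readDNAStringSet(path),
                error = function(e) stop("malformed FASTA file '", path,
                                         "': ", conditionMessage(e),
                                         call. = FALSE))
  if (length(g) == 0L) stop("FASTA file contains no records: ", path)
  names(g) <- sub("\\s.*$", "", names(g))
  if (anyDuplicated(names(g)) || any(!nzchar(names(g))))
    stop("chromosome names must be unique and non-empty")
  g <- Biostrings::DNAStringSet(toupper(as.character(g)))
  bad <- Biostrings::letterFrequency(g, "ACGTN")
  if (any(bad != Biostrings::width(g)))
    stop("reference sequences may only contain A, C, G, T, N")
  g
}

#' Convert a genome to the four three-letter reference spaces
#'
#' Produces `W_CT` (Watson with C-to-T), `C_CT` (Crick, i.e. the reverse
#' complement of Watson, with C-to-T), `RCW_GA` (reverse complement of
#' Watson with G-to-A) and `RCC_GA` (reverse complement of Crick = Watson,
#' with G-to-A).  C-to-T conversion makes bisulfite-induced T/C differences
#' invisible for forward-form reads; G-to-A does the same for
#' reverse-complement-form reads.  By complementarity,
#' `RCW_GA = revcomp(W_CT)` and `RCC_GA = revcomp(C_CT)` character for
#' character, which is why only two physical indexes are ever built.
#'
#' @param genome a named [Biostrings::DNAStringSet] (see [loadFasta()]).
#' @return named list of the four [ReferenceSpace-class] objects.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "TACG"))
#' sp <- convertReference(g)
#' as.character(sp$W_CT@sequences)  # "TATG"
#' as.character(sp$C_CT@sequences)  # "TGTA"
#' @export
convertReference <- function(genome) {
  stopifnot(is(genome, "DNAStringSet"))
  w <- as.character(genome)
  crick <- setNames(.revcomp(w), names(w))
  mk <- function(id, seqs, conv)
    new("ReferenceSpace", spaceId = id,
        sequences = Biostrings::DNAStringSet(seqs), conversion = conv)
  list(W_CT   = mk("W_CT",   .ct(w),     "C_to_T"),
       C_CT   = mk("C_CT",   .ct(crick), "C_to_T"),
       RCW_GA = mk("RCW_GA", .ga(crick), "G_to_A"),
       RCC_GA = mk("RCC_GA", .ga(w),     "G_to_A"))
}

#' Build a seed index over one reference space
#'
#' Indexes every N-free k-mer occurrence of the space's sequences.
#' Positions are 0-based and ascending within each k-mer.
#'
#' @param space a [ReferenceSpace-class].
#' @param k seed length in bp; must not exceed the longest chromosome
#'   (and at most 13 to bound table memory).
#' @return a [SeedIndex-class].
#' @seealso [lookupSeed()], [buildBSIndex()]
#' @export
buildIndex <- function(space, k) {
  stopifnot(is(space, "ReferenceSpace"))
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k > max(Biostrings::width(space@sequences)))
    stop("k = ", k, " exceeds the longest chromosome")
  tab <- cpp_build_index(as.character(space@sequences), k)
  new("SeedIndex", k = k, spaceId = space@spaceId, table = tab,
      chromNames = names(space@sequences))
}

#' Look up a k-mer in a seed index
#'
#' @param index a [SeedIndex-class].
#' @param kmer a string of length `k`; k-mers containing N are never indexed
#'   and return zero rows.
#' @return `data.frame` with columns `chrom` and `offset` (0-based),
#'   ascending.
#' @export
lookupSeed <- function(index, kmer) {
  stopifnot(is(index, "SeedIndex"))
  .check_scalar_string(kmer, "kmer")
  k <- index@k
  if (nchar(kmer) != k) stop("kmer must have length k = ", k)
  empty <- data.frame(chrom = character(0), offset = integer(0))
  codes <- match(strsplit(kmer, "")[[1]], c("A", "C", "G", "T")) - 1L
  if (anyNA(codes)) return(empty)
  code <- sum(codes * 4^((k - 1):0))
  tab <- index@table
  lo <- tab$bucket[code + 1L]
  hi <- tab$bucket[code + 2L]
  if (hi <= lo) return(empty)
  gpos <- tab$pos[(lo + 1L):hi]
  ci <- findInterval(gpos, tab$chrom_start[-1L]) + 1L
  data.frame(chrom = index@chromNames[ci],
             offset = gpos - tab$chrom_start[ci])
}

#' Build the full bisulfite reference index
#'
#' Converts the genome to its four three-letter spaces and builds the two
#' physical seed indexes (over `W_CT` and `C_CT`) used by [mapReads()].
#'
#' For full sensitivity at `m` mismatches the aligner needs `m + 1`
#' non-overlapping seeds per read, so choose `k <= floor(readLen / (m + 1))`
#' (post tag trimming); reads too short for that fall back to a full scan.
#' The default `k = 12` suits long reads and sub-100-Mb genomes; 36-mers at
#' `m = 3` want `k = 9` (directional) or `k = 7` (tagged, 31 bp after
#' trimming).
#'
#' @param genome a named [Biostrings::DNAStringSet].
#' @param k seed length in bp.
#' @return a [BSReferenceIndex-class].
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "TACGGATCAATCG"))
#' ref <- buildBSIndex(g, k = 3)
#' referenceSpace(ref, "W_CT")
#' @export
buildBSIndex <- function(genome, k = 12L) {
  stopifnot(is(genome, "DNAStringSet"))
  if (is.null(names(genome))) stop("genome sequences must be named")
  spaces <- convertReference(genome)
  k <- as.integer(k)
  new("BSReferenceIndex", genome = genome, spaces = spaces, k = k,
      indexW = buildIndex(spaces$W_CT, k),
      indexC = buildIndex(spaces$C_CT, k),
      formatVersion = 1L)
}
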