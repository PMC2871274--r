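#' Write a read set to FASTQ
#'
#' @param reads a [BSReadSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFastq <- function(reads, path) {
  stopifnot(is(reads, "BSReadSet"))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(reads))
    writeLines(paste(paste0("@", reads@id), reads@seq, "+", reads@qual,
                     sep = "\n"), con)
  invisible(path)
}

.MAP_COLS <- c("read_id", "strand_code", "chrom", "start", "read_seq",
               "genome_seq", "mismatches_orig", "methylation_string")

#' Write / read the mapping table
#'
#' Tab-separated, one row per uniquely mapped read, with columns `read_id`,
#' `strand_code` (++ / +- / -+ / --), `chrom`, `start` (1-based Watson
#' coordinate of the leftmost base), `read_seq`, `genome_seq`,
#' `mismatches_orig` and `methylation_string` (`.` when not computed).
#'
#' @param aln a [BSAlignments-class].
#' @param path output path.
#' @param meth optional [MethylationResult-class] supplying per-read
#'   methylation strings.
#' @return `path` (writer) or a `data.frame` with an additional `form`
#'   column (reader).
#' @export
writeMappingTSV <- function(aln, path, meth = NULL) {
  stopifnot(is(aln, "BSAlignments"))
  mc <- S4Vectors::mcols(aln@hits)
  ms <- mc$methString
  if (!is.null(meth)) {
    stopifnot(is(meth, "MethylationResult"))
    idx <- match(mc$readId, names(methStrings(meth)))
    ms <- unname(methStrings(meth)[idx])
  }
  ms[is.na(ms)] <- "."
  df <- data.frame(read_id = mc$readId, strand_code = mc$strandCode,
                   chrom = as.character(seqnames(aln@hits)),
                   start = start(aln@hits), read_seq = mc$readSeq,
                   genome_seq = mc$genomeSeq, mismatches_orig = mc$mmOrig,
                   methylation_string = ms)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMappingTSV
#' @export
readMappingTSV <- function(path) {
  df <- utils::read.delim(path, colClasses = c(
    read_id = "character", strand_code = "character", chrom = "character",
    start = "integer", read_seq = "character", genome_seq = "character",
    mismatches_orig = "integer", methylation_string = "character"))
  if (!identical(names(df), .MAP_COLS))
    stop("not a mapping table: ", path)
  code2form <- setNames(names(.STRAND_CODE), .STRAND_CODE)
  df$form <- unname(code2form[df$strand_code])
  df
}

#' Write alignments as SAM
#'
#' Minimal single-end SAM: mandatory fields plus custom tags `XO:Z` (read
#' form), `XM:i` (original-alphabet mismatches under the asymmetric rule)
#' and `X3:i` (three-letter mismatches).  Reads written along the reference
#' forward strand (flag 16 for forms read along the reverse complement).
#'
#' @param aln a [BSAlignments-class].
#' @param genome the original genome (for header lengths).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSAM <- function(aln, genome, path) {
  stopifnot(is(aln, "BSAlignments"), is(genome, "DNAStringSet"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", names(genome), width(genome))),
             con)
  h <- aln@hits
  if (length(h)) {
    mc <- S4Vectors::mcols(h)
    rev <- mc$form %in% c("-FW", "+RC")
    seq <- mc$readSeq
    seq[rev] <- .revcomp(seq[rev])
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tXO:Z:%s\tXM:i:%d\tX3:i:%d",
                       mc$readId, ifelse(rev, 16L, 0L),
                       as.character(seqnames(h)), start(h), nchar(seq), seq,
                       mc$form, mc$mmOrig, mc$mm3), con)
  }
  invisible(path)
}

#' Write the per-site methylation table
#'
#' Tab-separated per-cytosine output (CGmap-like): `chrom`, `pos` (1-based
#' Watson), `strand`, `context`, `n_methylated`, `n_total`.
#'
#' @param meth a [MethylationResult-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCGmap <- function(meth, path) {
  stopifnot(is(meth, "MethylationResult"))
  s <- methSites(meth)
  mc <- S4Vectors::mcols(s)
  df <- data.frame(chrom = as.character(seqnames(s)), pos = start(s),
                   strand = as.character(strand(s)), context = mc$context,
                   n_methylated = mc$nMeth, n_total = mc$nTotal)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Format the rate summary as a key-value block
#'
#' @param meth a [MethylationResult-class].
#' @return character vector of `key<TAB>value` lines (rates in percent,
#'   `NA` for uncovered contexts).
#' @export
formatRateSummary <- function(meth) {
  s <- methSummary(meth)
  sprintf("rate_%s\t%s", names(s),
          ifelse(is.na(s), "NA", formatC(s, format = "f", digits = 4)))
}

#' Serialize / load a reference index
#'
#' The on-disk form is an RDS container with a format version; loading
#' checks the version so stale indexes fail loudly.
#'
#' @param ref a [BSReferenceIndex-class].
#' @param path path to the index file.
#' @return `path` / the restored [BSReferenceIndex-class].
#' @export
saveBSIndex <- function(ref, path) {
  stopifnot(is(ref, "BSReferenceIndex"))
  saveRDS(list(format = ref@formatVersion,
               package = as.character(utils::packageVersion("methylMapR")),
               index = ref), path)
  invisible(path)
}

#' @rdname saveBSIndex
#' @export
loadBSIndex <- function(path) {
  if (!file.exists(path)) stop("index file not found: ", path)
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, 1L) ||
      !is(obj$index, "BSReferenceIndex"))
    stop("not a version-1 reference index: ", path)
  obj$index
}
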