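#' Read bisulfite reads from FASTQ
#'
#' Parses a 4-line-record FASTQ file, preserving input order and uppercasing
#' sequences.  Qualities are carried through to output but never used in
#' alignment or filtering (reads are modelled as discrete base calls).
#'
#' @param path path to a FASTQ file.
#' @param protocol `"lister"` (directional; every read is an FW read, no
#'   tags) or `"cokus"` (tagged; classify with [classifyTags()] before
#'   mapping).
#' @return a [BSReadSet-class].
#' @export
readFastq <- function(path, protocol = c("lister", "cokus")) {
  .check_scalar_string(path, "path")
  protocol <- match.arg(protocol)
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ record at end of file (", length(lines),
         " lines is not a multiple of 4)")
  n <- length(lines) %/% 4L
  if (n == 0L) return(.new_readset(character(0), character(0), character(0),
                                   protocol))
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seq <- toupper(lines[seq(2L, by = 4L, length.out = n)])
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
  if (length(bad))
    stop("malformed FASTQ record ", bad[1L], " (near line ",
         (bad[1L] - 1L) * 4L + 1L, ")")
  id <- sub("\\s.*$", "", substring(hdr, 2L))
  mis <- which(nchar(seq) != nchar(qual))
  if (length(mis))
    stop("sequence/quality length mismatch in record '", id[mis[1L]], "'")
  .new_readset(id, seq, qual, protocol)
}

.new_readset <- function(id, seq, qual, protocol, tagClass = NULL,
                         trimmed = NULL) {
  if (is.null(tagClass))
    tagClass <- if (identical(protocol, "lister"))
      rep("FW", length(id)) else rep(NA_character_, length(id))
  if (is.null(trimmed)) trimmed <- seq
  new("BSReadSet", id = as.character(id), seq = seq, qual = qual,
      protocol = protocol, tagClass = tagClass, trimmed = trimmed)
}

#' Construct a read set in memory
#'
#' Convenience constructor mirroring [readFastq()] for programmatic use
#' (e.g. the simulator).
#'
#' @param id,seq,qual parallel character vectors; `qual` defaults to a
#'   constant placeholder.
#' @inheritParams readFastq
#' @return a [BSReadSet-class].
#' @export
BSReadSet <- function(id, seq, qual = strrep("I", nchar(seq)),
                      protocol = c("lister", "cokus")) {
  .new_readset(id, toupper(seq), qual, match.arg(protocol))
}

#' Tag configuration constructors
#'
#' `tagConfig()` builds a [TagConfig-class] from explicit patterns;
#' `defaultTagConfig()` returns the package's shipped defaults.  The tagged
#' protocol's real 5-bp tags are produced by DpnI digestion of the library
#' adapters and are chemistry-specific, so they are configuration here, not
#' constants; the defaults are synthetic patterns (FW `GATCT`, RC `GATCA`)
#' chosen only to exercise the mechanism, and real libraries should supply
#' their own.
#'
#' @param fwPatterns,rcPatterns patterns (over A, C, G, T, N; N matches any
#'   base) identifying forward- and reverse-complement-form reads.
#' @param tagLength tag length in bp.
#' @return a [TagConfig-class].
#' @export
tagConfig <- function(fwPatterns, rcPatterns, tagLength = 5L) {
  new("TagConfig", tagLength = as.integer(tagLength),
      fwPatterns = toupper(fwPatterns), rcPatterns = toupper(rcPatterns))
}

#' @rdname tagConfig
#' @export
defaultTagConfig <- function() tagConfig("GATCT", "GATCA", 5L)

#' Read a tag configuration from file
#'
#' Two-column whitespace-separated text: class (`FW` or `RC`) and pattern.
#' Lines starting with `#` are ignored.
#'
#' @param path path to the tag file.
#' @return a [TagConfig-class].
#' @export
readTagConfig <- function(path) {
  tab <- utils::read.table(path, col.names = c("class", "pattern"),
                           colClasses = "character", comment.char = "#")
  if (!all(tab$class %in% c("FW", "RC")))
    stop("tag classes in ", path, " must be FW or RC")
  lens <- unique(nchar(tab$pattern))
  if (length(lens) != 1L) stop("all tag patterns must have equal length")
  tagConfig(tab$pattern[tab$class == "FW"], tab$pattern[tab$class == "RC"],
            lens)
}

.match_patterns <- function(prefix, patterns) {
  hit <- rep(FALSE, length(prefix))
  for (p in patterns)
    hit <- hit | grepl(paste0("^", gsub("N", ".", p, fixed = TRUE)), prefix)
  hit
}

#' Classify and trim protocol tags
#'
#' Compares the first `tagLength` bases of every read against the FW
#' patterns, then the RC patterns (N in a pattern matches any base).  On a
#' match the tag class is set accordingly; reads matching neither are
#' `UNKNOWN` and are later aligned as if they could be both FW and RC.  The
#' tag bases are trimmed in every case — the tag region is adapter-derived,
#' not genomic, under this protocol, and aligning it would only inflate
#' mismatch counts.
#'
#' @param reads a [BSReadSet-class] with `protocol == "cokus"`.
#' @param cfg a [TagConfig-class].
#' @return the read set with `tagClass` set and tags trimmed.
#' @export
classifyTags <- function(reads, cfg = defaultTagConfig()) {
  stopifnot(is(reads, "BSReadSet"), is(cfg, "TagConfig"))
  if (!identical(reads@protocol, "cokus"))
    stop("tag classification applies to the tagged ('cokus') protocol only")
  tl <- cfg@tagLength
  prefix <- substr(reads@seq, 1L, tl)
  cls <- rep("UNKNOWN", length(reads))
  cls[.match_patterns(prefix, cfg@rcPatterns)] <- "RC"
  cls[.match_patterns(prefix, cfg@fwPatterns)] <- "FW"  # FW checked first
  short <- nchar(reads@seq) <= tl
  cls[short] <- NA_character_
  initialize(reads, tagClass = cls,
             trimmed = ifelse(short, "", substring(reads@seq, tl + 1L)))
}

#' Three-letter conversion of a read
#'
#' Forward-direction reads have every C replaced by T; reverse-complement
#' direction reads have every G replaced by A.  Length is preserved and the
#' map is idempotent.
#'
#' @param x character vector of (trimmed) read sequences.
#' @param direction `"FW"` or `"RC"`.
#' @return converted character vector.
#' @examples
#' convertRead("TCCG", "FW")  # "TTTG"
#' convertRead("TCCG", "RC")  # "TCCA"
#' @export
convertRead <- function(x, direction = c("FW", "RC")) {
  direction <- match.arg(direction)
  if (direction == "FW") .ct(x) else .ga(x)
}
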