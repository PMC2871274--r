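#' @include utils.R
NULL

# ---------------------------------------------------------------- reference --

#' Converted reference space
#'
#' One of the four logical reference spaces used for three-letter alignment:
#' `W_CT` (Watson, C-to-T), `C_CT` (Crick, C-to-T), `RCW_GA` (reverse
#' complement of Watson, G-to-A) and `RCC_GA` (reverse complement of Crick,
#' G-to-A; identical to Watson with G-to-A).  Coordinates within a space are
#' 0-based, half-open; [toWatson()] maps them back to 1-based Watson
#' coordinates together with the read-form label.
#'
#' @slot spaceId one of `"W_CT"`, `"C_CT"`, `"RCW_GA"`, `"RCC_GA"`.
#' @slot sequences converted chromosome sequences ([Biostrings::DNAStringSet]).
#' @slot conversion `"C_to_T"` or `"G_to_A"`.
#' @exportClass ReferenceSpace
setClass("ReferenceSpace",
  slots = c(spaceId = "character", sequences = "DNAStringSet",
            conversion = "character"))

setValidity("ReferenceSpace", function(object) {
  msg <- character(0)
  if (!(object@spaceId %in% .SPACE_IDS))
    msg <- c(msg, "spaceId must be one of W_CT, C_CT, RCW_GA, RCC_GA")
  if (!(object@conversion %in% c("C_to_T", "G_to_A")))
    msg <- c(msg, "conversion must be C_to_T or G_to_A")
  banned <- if (identical(object@conversion, "C_to_T")) "C" else "G"
  if (length(object@sequences) &&
      sum(Biostrings::letterFrequency(object@sequences, banned)) > 0)
    msg <- c(msg, sprintf("a %s space must not contain the letter %s",
                          object@conversion, banned))
  if (length(msg)) msg else TRUE
})

setMethod("show", "ReferenceSpace", function(object) {
  cat("ReferenceSpace", object@spaceId, "(", object@conversion, "):",
      length(object@sequences), "sequence(s),",
      sum(Biostrings::width(object@sequences)), "bp total\n")
})

#' Seed index over a converted reference space
#'
#' A k-mer occurrence table over the three-letter sequences of one reference
#' space.  k-mers containing N are not indexed; positions are 0-based and
#' ascending within each k-mer.  Query with [lookupSeed()].
#'
#' @slot k seed length (bp).
#' @slot spaceId the reference space indexed.
#' @slot table internal occurrence table (encoded sequence, bucket offsets,
#'   sorted positions) consumed by the C++ alignment core.
#' @slot chromNames chromosome names, in index order.
#' @exportClass SeedIndex
setClass("SeedIndex",
  slots = c(k = "integer", spaceId = "character", table = "list",
            chromNames = "character"))

setMethod("show", "SeedIndex", function(object) {
  cat("SeedIndex over", object@spaceId, "- k =", object@k, ",",
      length(object@table$pos), "indexed positions on",
      length(object@chromNames), "sequence(s)\n")
})

#' Reference genome with converted spaces and seed indexes
#'
#' Holds the original genome, its four logical three-letter reference
#' spaces, and the two physical seed indexes (over `W_CT` and `C_CT`) the
#' aligner uses; hits in the two G/A spaces are recovered through the
#' reverse-complement identity `RCW_GA = revcomp(W_CT)`,
#' `RCC_GA = revcomp(C_CT)`, so the four-space contract is preserved with
#' half the index memory.  Build with [buildBSIndex()].
#'
#' @slot genome original genome ([Biostrings::DNAStringSet], uppercase).
#' @slot spaces named list of the four [ReferenceSpace-class] objects.
#' @slot k seed length used for the indexes.
#' @slot indexW,indexC [SeedIndex-class] over `W_CT` and `C_CT`.
#' @slot formatVersion serialization format version.
#' @exportClass BSReferenceIndex
setClass("BSReferenceIndex",
  slots = c(genome = "DNAStringSet", spaces = "list", k = "integer",
            indexW = "SeedIndex", indexC = "SeedIndex",
            formatVersion = "integer"))

setValidity("BSReferenceIndex", function(object) {
  msg <- character(0)
  if (!identical(sort(names(object@spaces)), sort(.SPACE_IDS)))
    msg <- c(msg, "spaces must be a named list with the four space ids")
  nm <- names(object@genome)
  if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm)))
    msg <- c(msg, "chromosome names must be unique and non-empty")
  for (sp in object@spaces)
    if (!identical(unname(Biostrings::width(sp@sequences)),
                   unname(Biostrings::width(object@genome))))
      msg <- c(msg, paste0(sp@spaceId, ": converted lengths differ from genome"))
  if (length(msg)) msg else TRUE
})

setMethod("show", "BSReferenceIndex", function(object) {
  cat("BSReferenceIndex:", length(object@genome), "sequence(s),",
      sum(Biostrings::width(object@genome)), "bp; seed k =", object@k, "\n")
  cat("  spaces:", paste(names(object@spaces), collapse = ", "), "\n")
})

#' @describeIn BSReferenceIndex-class the original genome.
#' @param x,object a `BSReferenceIndex`.
#' @export
refGenome <- function(x) {
  stopifnot(is(x, "BSReferenceIndex"))
  x@genome
}

#' @describeIn BSReferenceIndex-class one converted [ReferenceSpace-class]
#'   (`space` is one of the four space ids).
#' @param space a space id.
#' @export
referenceSpace <- function(x, space = .SPACE_IDS) {
  stopifnot(is(x, "BSReferenceIndex"))
  space <- match.arg(space)
  x@spaces[[space]]
}

#' @describeIn BSReferenceIndex-class seed length of the indexes.
#' @export
seedLength <- function(x) {
  stopifnot(is(x, "BSReferenceIndex"))
  x@k
}

# -------------------------------------------------------------------- reads --

#' Tag configuration for the tagged (non-directional) protocol
#'
#' The tagged library protocol leaves a fixed-length, adapter-derived tag at
#' the 5' end of every read whose pattern identifies the read direction (FW
#' vs RC).  The tag sequences themselves are chemistry-specific
#' configuration; patterns are strings over A, C, G, T and N (N matches any
#' base).  See [defaultTagConfig()] for the synthetic defaults shipped with
#' the package.
#'
#' @slot tagLength tag length in bp (conventionally 5).
#' @slot fwPatterns,rcPatterns character vectors of patterns, all of length
#'   `tagLength`, disjoint between the two classes.
#' @exportClass TagConfig
setClass("TagConfig",
  slots = c(tagLength = "integer", fwPatterns = "character",
            rcPatterns = "character"))

setValidity("TagConfig", function(object) {
  msg <- character(0)
  pats <- c(object@fwPatterns, object@rcPatterns)
  if (length(pats) == 0L) msg <- c(msg, "at least one tag pattern is required")
  if (any(nchar(pats) != object@tagLength))
    msg <- c(msg, "every pattern must have length tagLength")
  if (any(grepl("[^ACGTN]", pats)))
    msg <- c(msg, "patterns may only contain A, C, G, T, N")
  if (length(intersect(object@fwPatterns, object@rcPatterns)))
    msg <- c(msg, "fwPatterns and rcPatterns must be disjoint")
  if (length(msg)) msg else TRUE
})

#' A set of bisulfite-sequencing reads
#'
#' Reads with their qualities (parsed and carried through, never used in
#' alignment), protocol, tag class and tag-trimmed sequence.  Under the
#' directional (`"lister"`-style) protocol every read is an FW read and no
#' trimming occurs; under the tagged (`"cokus"`-style) protocol
#' [classifyTags()] assigns `FW`/`RC`/`UNKNOWN` from the first `tagLength`
#' bases and trims them (the tag region is adapter-derived, not genomic, so
#' it is trimmed even when unmatched).
#'
#' @slot id read identifiers.
#' @slot seq read sequences as read from FASTQ (uppercased).
#' @slot qual per-read quality strings (same lengths as `seq`).
#' @slot protocol `"lister"` (directional) or `"cokus"` (tagged).
#' @slot tagClass per-read `"FW"`, `"RC"`, `"UNKNOWN"`, or `NA` before
#'   classification.
#' @slot trimmed tag-trimmed sequences (equal to `seq` when untrimmed).
#' @exportClass BSReadSet
setClass("BSReadSet",
  slots = c(id = "character", seq = "character", qual = "character",
            protocol = "character", tagClass = "character",
            trimmed = "character"))

setValidity("BSReadSet", function(object) {
  msg <- character(0)
  n <- length(object@id)
  if (length(object@seq) != n || length(object@qual) != n ||
      length(object@tagClass) != n || length(object@trimmed) != n)
    msg <- c(msg, "id, seq, qual, tagClass and trimmed must have equal length")
  else {
    if (any(nchar(object@qual) != nchar(object@seq)))
      msg <- c(msg, "quality strings must match sequence lengths")
    if (!(object@protocol %in% c("lister", "cokus")))
      msg <- c(msg, "protocol must be 'lister' or 'cokus'")
    if (!all(object@tagClass %in% c("FW", "RC", "UNKNOWN", NA_character_)))
      msg <- c(msg, "tagClass values must be FW, RC, UNKNOWN or NA")
    if (identical(object@protocol, "lister") &&
        !all(object@tagClass %in% "FW"))
      msg <- c(msg, "directional protocol reads must all be FW")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "BSReadSet", function(object) {
  cat("BSReadSet:", length(object@id), "reads, protocol =", object@protocol, "\n")
  if (length(object@id)) {
    tc <- table(factor(object@tagClass, c("FW", "RC", "UNKNOWN")), useNA = "ifany")
    cat("  tag classes:", paste(names(tc), tc, sep = "=", collapse = ", "), "\n")
    cat("  read lengths:", paste(range(nchar(object@seq)), collapse = "-"), "bp\n")
  }
})

setMethod("length", "BSReadSet", function(x) length(x@id))

#' @describeIn BSReadSet-class read identifiers.
#' @param x a `BSReadSet`.
#' @export
readIds <- function(x) {
  stopifnot(is(x, "BSReadSet"))
  x@id
}

#' @describeIn BSReadSet-class tag-trimmed sequences, named by read id.
#' @export
trimmedSeq <- function(x) {
  stopifnot(is(x, "BSReadSet"))
  setNames(x@trimmed, x@id)
}

#' @describeIn BSReadSet-class per-read tag classes.
#' @export
tagClass <- function(x) {
  stopifnot(is(x, "BSReadSet"))
  setNames(x@tagClass, x@id)
}

# --------------------------------------------------------------- alignments --

#' Mapping result for a read set
#'
#' Unique, quality-passed alignments in Watson coordinates plus, for every
#' other read, the reason it was not mapped (`no_hit`, `ambiguous`,
#' `low_quality`, `too_short`).  Alignments are a [GenomicRanges::GRanges]
#' (1-based start of the leftmost Watson base; strand is the origin strand of
#' the fragment) with metadata columns `readId`, `form` (+FW/+RC/-FW/-RC),
#' `strandCode` (++/+-/-+/--), `readSeq` (trimmed, as written), `genomeSeq`
#' (original-alphabet reference segment in read orientation), `mm3`
#' (three-letter mismatches) and `mmOrig` (asymmetric-rule mismatches).
#'
#' @slot hits the alignments (`GRanges`).
#' @slot unmapped `data.frame` with columns `readId`, `reason`.
#' @slot nReads total reads submitted.
#' @slot protocol library protocol of the read set.
#' @slot stats list of run statistics (alignment passes, seed fallbacks, ...).
#' @exportClass BSAlignments
setClass("BSAlignments",
  slots = c(hits = "GRanges", unmapped = "data.frame", nReads = "integer",
            protocol = "character", stats = "list"))

setValidity("BSAlignments", function(object) {
  msg <- character(0)
  mc <- S4Vectors::mcols(object@hits)
  need <- c("readId", "form", "strandCode", "readSeq", "genomeSeq",
            "mm3", "mmOrig")
  if (!all(need %in% colnames(mc)))
    msg <- c(msg, paste("hits must carry mcols:", paste(need, collapse = ", ")))
  else {
    if (!all(mc$form %in% .FORMS)) msg <- c(msg, "invalid form label")
    if (identical(object@protocol, "lister") &&
        !all(mc$form %in% c("+FW", "-FW")))
      msg <- c(msg, "directional protocol cannot produce RC forms")
  }
  if (!all(c("readId", "reason") %in% names(object@unmapped)))
    msg <- c(msg, "unmapped must have columns readId, reason")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BSAlignments", function(object) {
  n <- object@nReads
  nu <- length(object@hits)
  cat("BSAlignments (protocol =", object@protocol, ")\n")
  cat(sprintf("  total reads:      %d\n", n))
  cat(sprintf("  uniquely mapped:  %d (%.1f%%)\n", nu,
              if (n > 0) 100 * nu / n else NA_real_))
  if (nrow(object@unmapped)) {
    rs <- table(object@unmapped$reason)
    for (r in names(rs)) cat(sprintf("  discarded %-12s %d\n", paste0(r, ":"), rs[[r]]))
  }
  if (!is.null(object@stats$alignmentPasses))
    cat("  alignment passes: ", object@stats$alignmentPasses, "\n")
})

#' @describeIn BSAlignments-class the unique alignments as a `GRanges`.
#' @param x a `BSAlignments`.
#' @export
mappedReads <- function(x) {
  stopifnot(is(x, "BSAlignments"))
  x@hits
}

#' @describeIn BSAlignments-class unmapped reads and their reason codes.
#' @export
unmappedReads <- function(x) {
  stopifnot(is(x, "BSAlignments"))
  x@unmapped
}

#' @describeIn BSAlignments-class run statistics (totals, passes, discards).
#' @export
runStats <- function(x) {
  stopifnot(is(x, "BSAlignments"))
  n <- x@nReads
  nu <- length(x@hits)
  c(list(totalReads = n, uniquelyMapped = nu,
         pctUnique = if (n > 0) 100 * nu / n else NA_real_,
         discards = if (nrow(x@unmapped)) table(x@unmapped$reason) else table(character(0))),
    x@stats)
}

# -------------------------------------------------------------- methylation --

#' Per-cytosine methylation calls and context rates
#'
#' Per-site calls are a [GenomicRanges::GRanges] of width-1 cytosine
#' positions (strand = strand carrying the C) with metadata columns
#' `context` (CG/CHG/CHH), `nMeth` and `nTotal`.  The summary holds the
#' pooled genome-wide rate per context in percent
#' (`sum(nMeth)/sum(nTotal) * 100`); a context with zero coverage is `NA`,
#' not 0.  Per-read methylation strings use one character per read base:
#' `M` methylated C, `U` unmethylated C, `.` no call at a genomic C, `-` not
#' a genomic C position (read orientation).
#'
#' @slot sites per-site calls (`GRanges`).
#' @slot summary named numeric, `c(CG=, CHG=, CHH=)`, percent.
#' @slot strings per-read methylation strings, named by read id.
#' @exportClass MethylationResult
setClass("MethylationResult",
  slots = c(sites = "GRanges", summary = "numeric", strings = "character"))

setValidity("MethylationResult", function(object) {
  msg <- character(0)
  mc <- S4Vectors::mcols(object@sites)
  if (!all(c("context", "nMeth", "nTotal") %in% colnames(mc)))
    msg <- c(msg, "sites must carry mcols context, nMeth, nTotal")
  else if (length(object@sites) &&
           (any(mc$nMeth < 0) || any(mc$nMeth > mc$nTotal)))
    msg <- c(msg, "0 <= nMeth <= nTotal violated")
  if (!identical(names(object@summary), c("CG", "CHG", "CHH")))
    msg <- c(msg, "summary must be named CG, CHG, CHH")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MethylationResult", function(object) {
  cat("MethylationResult:", length(object@sites), "cytosine sites\n")
  s <- object@summary
  cat(sprintf("  rates (%%): CG=%s CHG=%s CHH=%s\n",
              format(s[["CG"]], digits = 4), format(s[["CHG"]], digits = 4),
              format(s[["CHH"]], digits = 4)))
})

#' @describeIn MethylationResult-class per-site calls as a `GRanges`.
#' @param x a `MethylationResult`.
#' @export
methSites <- function(x) {
  stopifnot(is(x, "MethylationResult"))
  x@sites
}

#' @describeIn MethylationResult-class pooled per-context rates in percent.
#' @export
methSummary <- function(x) {
  stopifnot(is(x, "MethylationResult"))
  x@summary
}

#' @describeIn MethylationResult-class per-read methylation strings.
#' @export
methStrings <- function(x) {
  stopifnot(is(x, "MethylationResult"))
  x@strings
}

# ---------------------------------------------------------------- simulator --

#' Simulated methylome
#'
#' Ground-truth methylation state for every cytosine on both strands,
#' produced by [simulateMethylome()].  `states` holds, per chromosome, two
#' data frames (`plus`, `minus`) with columns `pos` (1-based Watson
#' coordinate of the C), `context` and `meth` (logical).
#'
#' @slot states per-chromosome state tables.
#' @slot params the methylation probabilities used, `c(CG=, CHG=, CHH=)`.
#' @exportClass BSMethylome
setClass("BSMethylome", slots = c(states = "list", params = "numeric"))

setMethod("show", "BSMethylome", function(object) {
  ns <- sum(vapply(object@states, function(ch)
    nrow(ch$plus) + nrow(ch$minus), numeric(1)))
  cat("BSMethylome:", ns, "cytosines;",
      sprintf("pCG=%.3g pCHG=%.3g pCHH=%.3g\n",
              object@params[["CG"]], object@params[["CHG"]],
              object@params[["CHH"]]))
})

#' Simulation configuration
#'
#' Parameters of one synthetic bisulfite-read experiment; see [simConfig()].
#'
#' @slot nReads number of reads to simulate.
#' @slot readLen total read length in bp (tag included under the tagged
#'   protocol), default 36.
#' @slot protocol `"lister"` or `"cokus"`.
#' @slot pCG,pCHG,pCHH per-context methylation probabilities.
#' @slot errorProfile per-cycle substitution probability, length `readLen`.
#' @slot rngSeed integer seed making the run deterministic.
#' @slot tagConfig [TagConfig-class] used to prepend tags (tagged protocol).
#' @exportClass SimConfig
setClass("SimConfig",
  slots = c(nReads = "integer", readLen = "integer", protocol = "character",
            pCG = "numeric", pCHG = "numeric", pCHH = "numeric",
            errorProfile = "numeric", rngSeed = "integer",
            tagConfig = "TagConfig"))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  p <- c(object@pCG, object@pCHG, object@pCHH)
  if (any(p < 0) || any(p > 1))
    msg <- c(msg, "methylation probabilities must lie in [0, 1]")
  if (length(object@errorProfile) != object@readLen)
    msg <- c(msg, "errorProfile must have length readLen")
  if (any(object@errorProfile < 0) || any(object@errorProfile > 1))
    msg <- c(msg, "errorProfile entries must lie in [0, 1]")
  if (!(object@protocol %in% c("lister", "cokus")))
    msg <- c(msg, "protocol must be 'lister' or 'cokus'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0("SimConfig: %d reads x %d bp, protocol = %s, ",
                     "pCG=%.3g pCHG=%.3g pCHH=%.3g, mean error=%.4g, seed=%d\n"),
              object@nReads, object@readLen, object@protocol, object@pCG,
              object@pCHG, object@pCHH, mean(object@errorProfile),
              object@rngSeed))
})
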