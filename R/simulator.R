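#' Default per-cycle error profile
#'
#' Substitution probability per sequencing cycle, rising linearly from
#' `from` at the first cycle to `to` at the last — the characteristic
#' towards-the-3'-end deterioration of short-read base calling.  The default
#' endpoints give a mean per-base error of about 1.2%.
#'
#' @param readLen read length (number of cycles).
#' @param from,to error probability at the first and last cycle.
#' @return numeric vector of length `readLen`.
#' @export
defaultErrorProfile <- function(readLen, from = 0.001, to = 0.023) {
  if (readLen == 1L) return(from)
  seq(from, to, length.out = readLen)
}

#' Simulation configuration
#'
#' @param nReads number of reads.
#' @param readLen total read length in bp; under the tagged protocol the
#'   first `tagLength` bases are the tag, so the genomic fragment is
#'   `readLen - tagLength` bp.
#' @param protocol `"lister"` (directional, forms +FW/-FW) or `"cokus"`
#'   (tagged, all four forms).
#' @param pCG,pCHG,pCHH per-context methylation probabilities.  Defaults
#'   emulate a methylome with CG-only methylation at rate 0.72.
#' @param errorProfile per-cycle substitution probabilities (length
#'   `readLen`); all-zero for error-free reads.
#' @param rngSeed integer seed; identical seeds give byte-identical output.
#' @param tagCfg [TagConfig-class] for the tagged protocol.
#' @return a [SimConfig-class].
#' @export
simConfig <- function(nReads, readLen = 36L,
                      protocol = c("lister", "cokus"),
                      pCG = 0.72, pCHG = 0, pCHH = 0,
                      errorProfile = rep(0, readLen), rngSeed = 1L,
                      tagCfg = defaultTagConfig()) {
  new("SimConfig", nReads = as.integer(nReads), readLen = as.integer(readLen),
      protocol = match.arg(protocol), pCG = pCG, pCHG = pCHG, pCHH = pCHH,
      errorProfile = errorProfile, rngSeed = as.integer(rngSeed),
      tagConfig = tagCfg)
}

#' Simulate a reference genome with repeat structure
#'
#' Generates an i.i.d. background at roughly mammalian base composition
#' (41% GC) and then plants pairs of near-identical repeats: segments are
#' copied to random positions with a small per-base divergence.  Real
#' chromosomes owe most of their sub-100% mapability to such repeats, so a
#' purely i.i.d. genome would make multi-mapping (and error-induced
#' mismapping between repeat copies) unrealistically rare.
#'
#' @param length chromosome length in bp.
#' @param nChrom number of chromosomes (length is per chromosome).
#' @param repeatFraction fraction of the genome occupied by planted repeat
#'   copies.
#' @param repeatLength length of each repeat unit in bp.
#' @param divergence per-base substitution divergence between repeat copies.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return a named `DNAStringSet`.
#' @export
simulateGenome <- function(length, nChrom = 1L, repeatFraction = 0.2,
                           repeatLength = 1000L, divergence = 0.02,
                           seed = NULL) {
  .with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    freq <- c(0.295, 0.205, 0.205, 0.295)
    seqs <- vapply(seq_len(nChrom), function(i) {
      x <- sample(bases, length, replace = TRUE, prob = freq)
      nCopies <- floor(length * repeatFraction / repeatLength)
      if (nCopies >= 1L && length >= 2L * repeatLength) {
        for (r in seq_len(nCopies)) {
          src <- sample.int(length - repeatLength + 1L, 1L)
          dst <- sample.int(length - repeatLength + 1L, 1L)
          unit <- x[src:(src + repeatLength - 1L)]
          mut <- which(runif(repeatLength) < divergence)
          if (base::length(mut))
            unit[mut] <- sample(bases, base::length(mut), replace = TRUE)
          x[dst:(dst + repeatLength - 1L)] <- unit
        }
      }
      paste(x, collapse = "")
    }, character(1))
    Biostrings::DNAStringSet(setNames(seqs, paste0("chr", seq_len(nChrom))))
  })
}

.context_of_strand <- function(x, cpos, minus = FALSE) {
  # context of Cs at Watson positions cpos; on '-' the C sits under a
  # Watson G and its downstream neighbours lie to the left
  d <- if (minus) -1L else 1L
  b1 <- substring(x, cpos + d, cpos + d)
  b2 <- substring(x, cpos + 2L * d, cpos + 2L * d)
  g1 <- if (minus) "C" else "G"   # a Watson C complements to a Crick G
  ifelse(b1 == g1, "CG", ifelse(b2 == g1, "CHG", "CHH"))
}

#' Simulate a methylome
#'
#' Independently methylates every genomic cytosine on both strands with the
#' probability of its context.  Deterministic given `seed`.
#'
#' @param genome a named `DNAStringSet`.
#' @param pCG,pCHG,pCHH per-context methylation probabilities.
#' @param seed integer seed, or `NULL`.
#' @return a [BSMethylome-class].
#' @export
simulateMethylome <- function(genome, pCG = 0.72, pCHG = 0, pCHH = 0,
                              seed = NULL) {
  stopifnot(is(genome, "DNAStringSet"))
  p <- c(CG = pCG, CHG = pCHG, CHH = pCHH)
  if (any(p < 0) || any(p > 1)) stop("probabilities must lie in [0, 1]")
  .with_seed(seed, {
    states <- lapply(as.character(genome), function(x) {
      chars <- strsplit(x, "")[[1]]
      one <- function(pos, minus) {
        ctx <- .context_of_strand(x, pos, minus)
        data.frame(pos = pos, context = ctx,
                   meth = runif(length(pos)) < p[ctx])
      }
      list(plus = one(which(chars == "C"), FALSE),
           minus = one(which(chars == "G"), TRUE))
    })
    new("BSMethylome", states = states, params = p)
  })
}

# bisulfite-converted strand sequence under a fixed methylome:
# unmethylated C -> T, methylated C unchanged.  Returned 5'->3' on the
# requested strand ('minus' gives the Crick string).
.converted_strand <- function(x, st, minus = FALSE) {
  chars <- strsplit(x, "")[[1]]
  tab <- if (minus) st$minus else st$plus
  if (minus) {
    crick <- rev(chartr("ACGT", "TGCA", chars))
    unm <- length(chars) - tab$pos[!tab$meth] + 1L  # Crick index of Watson pos
    crick[unm] <- "T"
    paste(crick, collapse = "")
  } else {
    chars[tab$pos[!tab$meth]] <- "T"
    paste(chars, collapse = "")
  }
}

#' Simulate bisulfite reads with ground truth
#'
#' Read origins are sampled uniformly over valid (chromosome, form, start)
#' triples; the bisulfite rule is applied on the origin strand under the
#' fixed methylome; RC forms emit the reverse complement of the converted
#' fragment; tagged-protocol reads are prepended with the form-appropriate
#' tag pattern (N wildcards sampled uniformly); per-cycle errors (uniform
#' substitution to one of the three other bases) are applied last.
#' Deterministic given `cfg@rngSeed`.
#'
#' Truth records the post-trim leftmost Watson coordinate and the form, in
#' exactly the convention [mapReads()] reports, so evaluation is a pure
#' equality check.
#'
#' @param genome a named `DNAStringSet`.
#' @param methylome a [BSMethylome-class] for this genome.
#' @param cfg a [SimConfig-class].
#' @return list with `reads` (a [BSReadSet-class]) and `truth`
#'   (`data.frame`: `readId`, `chrom`, `start`, `form`, `nErrors`).
#' @export
simulateReads <- function(genome, methylome, cfg) {
  stopifnot(is(genome, "DNAStringSet"), is(methylome, "BSMethylome"),
            is(cfg, "SimConfig"))
  cokus <- identical(cfg@protocol, "cokus")
  tagLen <- if (cokus) cfg@tagConfig@tagLength else 0L
  fragLen <- cfg@readLen - tagLen
  if (fragLen < 1L) stop("readLen must exceed the tag length")
  L <- setNames(width(genome), names(genome))
  if (fragLen > min(L)) stop("fragment length exceeds shortest chromosome")
  nvalid <- L - fragLen + 1L
  forms <- if (cokus) .FORMS else c("+FW", "-FW")

  .with_seed(cfg@rngSeed, {
    n <- cfg@nReads
    chromIdx <- sample.int(length(L), n, replace = TRUE, prob = nvalid)
    start <- as.integer(floor(runif(n) * nvalid[chromIdx]) + 1L)  # leftmost Watson base
    form <- sample(forms, n, replace = TRUE)

    convW <- convC <- character(length(L))
    for (i in seq_along(L)) {
      x <- as.character(genome[[i]])
      convW[i] <- .converted_strand(x, methylome@states[[i]], minus = FALSE)
      convC[i] <- .converted_strand(x, methylome@states[[i]], minus = TRUE)
    }

    plusOrigin <- form %in% c("+FW", "+RC")
    frag <- character(n)
    frag[plusOrigin] <- substring(convW[chromIdx[plusOrigin]],
                                  start[plusOrigin],
                                  start[plusOrigin] + fragLen - 1L)
    crickStart <- L[chromIdx] - start - fragLen + 2L
    frag[!plusOrigin] <- substring(convC[chromIdx[!plusOrigin]],
                                   crickStart[!plusOrigin],
                                   crickStart[!plusOrigin] + fragLen - 1L)
    isRC <- form %in% .RC_FORMS
    frag[isRC] <- .revcomp(frag[isRC])

    reads <- frag
    if (cokus) {
      tags <- character(n)
      fwRead <- !isRC
      pickTag <- function(patterns, k) {
        pat <- patterns[sample.int(length(patterns), k, replace = TRUE)]
        m <- do.call(rbind, strsplit(pat, ""))
        wild <- m == "N"
        m[wild] <- sample(c("A", "C", "G", "T"), sum(wild), replace = TRUE)
        apply(m, 1L, paste, collapse = "")
      }
      if (any(fwRead)) tags[fwRead] <- pickTag(cfg@tagConfig@fwPatterns,
                                               sum(fwRead))
      if (any(isRC)) tags[isRC] <- pickTag(cfg@tagConfig@rcPatterns,
                                           sum(isRC))
      reads <- paste0(tags, reads)
    }

    nErrors <- integer(n)
    if (any(cfg@errorProfile > 0)) {
      mat <- do.call(rbind, strsplit(reads, ""))
      bases <- c("A", "C", "G", "T")
      for (cyc in seq_len(cfg@readLen)) {
        e <- cfg@errorProfile[cyc]
        if (e <= 0) next
        hit <- which(runif(n) < e)
        hit <- hit[mat[hit, cyc] %in% bases]  # N cycles carry no base call
        if (length(hit)) {
          cur <- mat[hit, cyc]
          # uniform substitution to one of the three other bases
          shift <- sample.int(3L, length(hit), replace = TRUE)
          mat[hit, cyc] <- bases[(match(cur, bases) - 1L + shift) %% 4L + 1L]
          nErrors[hit] <- nErrors[hit] + 1L
        }
      }
      reads <- apply(mat, 1L, paste, collapse = "")
    }

    id <- sprintf("read_%d", seq_len(n))
    list(reads = .new_readset(id, reads, strrep("I", nchar(reads)),
                              cfg@protocol),
         truth = data.frame(readId = id, chrom = names(L)[chromIdx],
                            start = start, form = form, nErrors = nErrors))
  })
}

#' Evaluate a mapping result against simulator truth
#'
#' Mapability is the percentage of reads mapped uniquely; accuracy is the
#' ratio of correctly mapped reads (reported chromosome, start and form all
#' equal to the simulated origin) over all uniquely mapped reads, in
#' percent; methylation rates are pooled per context over the uniquely
#' mapped reads.
#'
#' @param aln a [BSAlignments-class].
#' @param truth the truth table from [simulateReads()].
#' @param genome the original genome (for methylation rates); omit to skip
#'   rate computation.
#' @return named list: `nReads`, `nUnique`, `pctUnique`, `accuracy`
#'   (`NA` when nothing mapped), `rateCG`, `rateCHG`, `rateCHH`.
#' @export
evaluateMapping <- function(aln, truth, genome = NULL) {
  stopifnot(is(aln, "BSAlignments"), is.data.frame(truth))
  h <- aln@hits
  mc <- S4Vectors::mcols(h)
  ti <- match(mc$readId, truth$readId)
  if (anyNA(ti))
    stop("mapped read(s) absent from the truth table: ",
         mc$readId[which(is.na(ti))[1L]])
  nu <- length(h)
  correct <- as.character(seqnames(h)) == truth$chrom[ti] &
    start(h) == truth$start[ti] & mc$form == truth$form[ti]
  rates <- c(rateCG = NA_real_, rateCHG = NA_real_, rateCHH = NA_real_)
  if (!is.null(genome) && nu > 0L) {
    s <- methSummary(callMethylation(aln, genome))
    rates <- c(rateCG = unname(s[["CG"]]), rateCHG = unname(s[["CHG"]]),
               rateCHH = unname(s[["CHH"]]))
  }
  c(list(nReads = aln@nReads, nUnique = nu,
         pctUnique = if (aln@nReads > 0) 100 * nu / aln@nReads else NA_real_,
         accuracy = if (nu > 0L) 100 * mean(correct) else NA_real_),
    as.list(rates))
}
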