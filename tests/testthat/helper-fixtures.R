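# Fixtures are generated in code; heavyweight ones are cached per session.

.fixture_cache <- new.env(parent = emptyenv())

# random DNA string (optionally with N) under a local seed
random_dna <- function(n, withN = FALSE, seed = NULL) {
  draw <- function() {
    if (withN)
      sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
             prob = c(0.24, 0.24, 0.24, 0.24, 0.04))
    else sample(c("A", "C", "G", "T"), n, replace = TRUE)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  paste(draw(), collapse = "")
}

genome1 <- function(seq, name = "chr1") {
  Biostrings::DNAStringSet(setNames(seq, name))
}

write_tmp_fasta <- function(seqs, names = paste0("chr", seq_along(seqs))) {
  path <- tempfile(fileext = ".fa")
  writeLines(as.vector(rbind(paste0(">", names), seqs)), path)
  path
}

write_tmp_fastq <- function(id, seq, qual = strrep("I", nchar(seq))) {
  path <- tempfile(fileext = ".fastq")
  writeLines(as.vector(rbind(paste0("@", id), seq, "+", qual)), path)
  path
}

# the study-scale simulation shared by the acceptance suite: a 2 Mb
# repeat-bearing genome, a CG-only methylome (p = 0.72), and 50,000
# error-free 36-mers under each protocol, mapped by the full pipeline
acceptance_fixture <- function() {
  if (!is.null(.fixture_cache$acc)) return(.fixture_cache$acc)
  g <- simulateGenome(2e6, seed = 101)
  my <- simulateMethylome(g, pCG = 0.72, pCHG = 0, pCHH = 0, seed = 102)

  simL <- simulateReads(g, my, simConfig(nReads = 50000, readLen = 36L,
                                         protocol = "lister", rngSeed = 103))
  refL <- buildBSIndex(g, k = 9L)   # floor(36 / (3 + 1))
  alnL <- mapReads(simL$reads, refL, m3 = 3L, maxMM = 2L)
  evL <- evaluateMapping(alnL, simL$truth, g)

  simC <- simulateReads(g, my, simConfig(nReads = 50000, readLen = 36L,
                                         protocol = "cokus", rngSeed = 104))
  refC <- buildBSIndex(g, k = 7L)   # floor(31 / (3 + 1)) post-trim
  alnC <- mapReads(classifyTags(simC$reads), refC, m3 = 3L, maxMM = 2L)
  evC <- evaluateMapping(alnC, simC$truth, g)

  .fixture_cache$acc <- list(genome = g, methylome = my,
                             simL = simL, alnL = alnL, evL = evL,
                             simC = simC, alnC = alnC, evC = evC)
  .fixture_cache$acc
}
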