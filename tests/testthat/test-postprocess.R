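test_that("merging pools spaces and removes duplicate placements", {
  h1 <- data.frame(space = "W_CT", chrom = "c", offset = 3L, mm3 = 1L)
  h2 <- data.frame(space = c("C_CT", "W_CT"), chrom = "c",
                   offset = c(5L, 3L), mm3 = c(2L, 1L))
  m <- mergeHits(h1, h2)
  expect_identical(nrow(m), 2L)
  expect_identical(nrow(mergeHits(list())), 0L)
})

test_that("the uniqueness rule keeps single best hits and drops ties", {
  mk <- function(mm) data.frame(space = rep("W_CT", length(mm)),
                                chrom = rep("c", length(mm)),
                                offset = seq_along(mm), mm3 = mm)
  # a strictly worse hit does not break uniqueness
  u <- uniquenessFilter(mk(c(1L, 2L)))
  expect_identical(u$status, "unique")
  expect_identical(u$hit$mm3, 1L)
  # a tie at the best count is ambiguous
  expect_identical(uniquenessFilter(mk(c(1L, 1L)))$status, "ambiguous")
  # single hit is unique; no hits is unmapped
  expect_identical(uniquenessFilter(mk(2L))$status, "unique")
  expect_identical(uniquenessFilter(mk(integer(0)))$status, "no_hit")
})

test_that("space offsets transform to Watson coordinates and forms", {
  g <- genome1(random_dna(60, seed = 91))
  hit <- function(space, off) data.frame(space = space, chrom = "chr1",
                                         offset = off)
  # W_CT offset 0 -> Watson start 1, form +FW
  tw <- toWatson(hit("W_CT", 0L), readLen = 10L, genome = g)
  expect_identical(tw$start, 1L)
  expect_identical(tw$form, "+FW")
  expect_identical(tw$genomeSeq, substr(as.character(g)[[1]], 1, 10))
  # C_CT offset p -> start L - p - n + 1, form -FW, revcomp segment
  tw2 <- toWatson(hit("C_CT", 7L), readLen = 10L, genome = g)
  expect_identical(tw2$start, 60L - 7L - 10L + 1L)
  expect_identical(tw2$form, "-FW")
  seg <- substr(as.character(g)[[1]], tw2$start, tw2$start + 9L)
  expect_identical(tw2$genomeSeq,
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(seg))))
  expect_identical(toWatson(hit("RCW_GA", 7L), 10L, g)$form, "+RC")
  expect_identical(toWatson(hit("RCC_GA", 7L), 10L, g)$start, 8L)
  expect_error(toWatson(hit("W_CT", 55L), 10L, g), "out of bounds")
})

test_that("C_CT transform round-trips through re-extraction", {
  # take a Crick-strand fragment, align its converted form, and confirm
  # the reported Watson window contains the original fragment
  g <- genome1(random_dna(400, seed = 17))
  ref <- buildBSIndex(g, k = 6)
  crick <- as.character(Biostrings::reverseComplement(g[[1]]))
  p <- 123L; n <- 30L
  frag <- substr(crick, p + 1L, p + n)
  h <- alignRead(convertRead(frag, "FW"), ref, "C_CT", m = 0, cap = 1e5)
  expect_true(p %in% h$offset)
  tw <- toWatson(data.frame(space = "C_CT", chrom = "chr1", offset = p),
                 n, g)
  expect_identical(tw$genomeSeq, frag)
})

test_that("the asymmetric bisulfite rule counts mismatches positionally", {
  # forward forms: read T over genomic C is a match ...
  expect_identical(recountMismatches("TTGA", "CTGA", "+FW"), 0L)
  # ... but read C over genomic T is a mismatch
  expect_identical(recountMismatches("CTGA", "TTGA", "+FW"), 1L)
  # reverse-complement forms: read A over genomic G matches ...
  expect_identical(recountMismatches("AAGT", "GAGT", "+RC"), 0L)
  # ... and read G over genomic A does not
  expect_identical(recountMismatches("GAGT", "AAGT", "-RC"), 1L)
  # the asymmetry is positional, not compositional
  expect_identical(recountMismatches("TC", "CT", "-FW"), 1L)
  # N never matches, on either side
  expect_identical(recountMismatches("NA", "NA", "+FW"), 1L)
  expect_error(recountMismatches("ACG", "AC", "+FW"), "length")
})

test_that("the mismatch threshold is 'larger than', and monotone", {
  expect_false(qualityFilter(3L, 2L))
  expect_true(qualityFilter(0L, 0L))
  expect_true(qualityFilter(2L, 2L))  # equal to the threshold is kept
  mm <- c(0L, 1L, 2L, 3L, 4L)
  for (t in 0:3)
    expect_true(all(which(qualityFilter(mm, t)) %in%
                    which(qualityFilter(mm, t + 1L))))
})

test_that("the pipeline rejects unclassified tagged reads", {
  g <- genome1(random_dna(500, seed = 5))
  ref <- buildBSIndex(g, k = 5)
  rs <- BSReadSet("r", substr(as.character(g)[[1]], 1, 30),
                  protocol = "cokus")
  expect_error(mapReads(rs, ref), "classifyTags")
})

test_that("reads discarded by the pipeline carry reason codes", {
  g <- genome1(random_dna(2000, seed = 6))
  ref <- buildBSIndex(g, k = 5)
  w <- as.character(g)[[1]]
  reads <- BSReadSet(
    c("short", "nohit", "good"),
    c("ACGTACGT",                       # < minAlignable
      strrep("A", 40),                  # present nowhere at m = 0..3
      substr(w, 101, 140)),
    protocol = "lister")
  aln <- mapReads(reads, ref, m3 = 1L)
  un <- unmappedReads(aln)
  expect_identical(un$reason[un$readId == "short"], "too_short")
  expect_identical(un$reason[un$readId == "nohit"], "no_hit")
  expect_true("good" %in% S4Vectors::mcols(mappedReads(aln))$readId)
})

test_that("recounted mismatches above the threshold discard the read", {
  w <- random_dna(600, seed = 44)
  g <- genome1(w)
  ref <- buildBSIndex(g, k = 6)
  frag <- substr(w, 201, 230)
  tpos <- which(strsplit(frag, "")[[1]] == "T")[1:3]
  read <- frag
  for (p in tpos) substr(read, p, p) <- "C"  # read C over genomic T, x3
  # three-letter space hides all three (read C -> T over genomic T)
  rs <- BSReadSet("r", read, protocol = "lister")
  aln2 <- mapReads(rs, ref, m3 = 0L, maxMM = 2L)
  expect_identical(unmappedReads(aln2)$reason, "low_quality")
  aln3 <- mapReads(rs, ref, m3 = 0L, maxMM = 3L)
  expect_identical(S4Vectors::mcols(mappedReads(aln3))$mmOrig, 3L)
})

test_that("simulated origins are recovered exactly (round trip)", {
  g <- simulateGenome(30000, repeatFraction = 0, seed = 71)
  my <- simulateMethylome(g, 0.5, 0.1, 0.02, seed = 72)
  for (proto in c("lister", "cokus")) {
    cfg <- simConfig(nReads = 300, protocol = proto, rngSeed = 73)
    sim <- simulateReads(g, my, cfg)
    reads <- if (proto == "cokus") classifyTags(sim$reads) else sim$reads
    ref <- buildBSIndex(g, k = if (proto == "cokus") 7 else 9)
    aln <- mapReads(reads, ref)
    h <- mappedReads(aln)
    mc <- S4Vectors::mcols(h)
    ti <- match(mc$readId, sim$truth$readId)
    expect_true(all(start(h) == sim$truth$start[ti]))
    expect_true(all(mc$form == sim$truth$form[ti]))
    expect_true(all(mc$mm3 == 0L))
    expect_true(all(mc$mmOrig == 0L))
  }
})

test_that("per-read uniqueness agrees with exhaustive enumeration", {
  # pipeline decision vs mergeHits + uniquenessFilter over oracle hit sets
  g <- genome1(random_dna(3000, seed = 81))
  ref <- buildBSIndex(g, k = 5)
  my <- simulateMethylome(g, 0.5, 0, 0, seed = 82)
  sim <- simulateReads(g, my, simConfig(nReads = 60, readLen = 24L,
                                        protocol = "lister", rngSeed = 83))
  aln <- mapReads(sim$reads, ref, m3 = 2L, maxMM = 24L)
  mapped <- S4Vectors::mcols(mappedReads(aln))$readId
  for (i in seq_len(60)) {
    r3 <- convertRead(trimmedSeq(sim$reads)[[i]], "FW")
    hits <- mergeHits(lapply(c("W_CT", "C_CT"), function(sp) {
      h <- alignBruteForce(r3, referenceSpace(ref, sp), m = 2L)
      if (nrow(h)) h$space <- sp else h$space <- character(0)
      h
    }))
    expected <- uniquenessFilter(hits)$status
    expect_identical(readIds(sim$reads)[i] %in% mapped,
                     expected == "unique")
  }
})
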