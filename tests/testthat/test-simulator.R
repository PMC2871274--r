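test_that("methylome simulation respects degenerate probabilities", {
  g <- genome1(random_dna(2000, seed = 11))
  none <- simulateMethylome(g, 0, 0, 0, seed = 1)
  expect_false(any(none@states[[1]]$plus$meth))
  expect_false(any(none@states[[1]]$minus$meth))
  all_cg <- simulateMethylome(g, 1, 0, 0, seed = 1)
  st <- all_cg@states[[1]]$plus
  expect_true(all(st$meth[st$context == "CG"]))
  expect_false(any(st$meth[st$context != "CG"]))
})

test_that("methylome rates concentrate around their probability", {
  g <- genome1(random_dna(4e5, seed = 12))  # ~2.5e4 CG sites
  my <- simulateMethylome(g, 0.5, 0, 0, seed = 2)
  st <- rbind(my@states[[1]]$plus, my@states[[1]]$minus)
  cg <- st[st$context == "CG", ]
  expect_gt(nrow(cg), 1e4)
  se <- sqrt(0.25 / nrow(cg))
  expect_lt(abs(mean(cg$meth) - 0.5), 3 * se)
})

test_that("bisulfite conversion of simulated fragments follows the rule", {
  # a 4 bp genome with a single valid origin per strand pins the fragment
  g <- genome1("ACGT")
  un <- simulateMethylome(g, 0, 0, 0, seed = 3)
  sim <- simulateReads(g, un, simConfig(nReads = 40, readLen = 4L,
                                        protocol = "lister", rngSeed = 4))
  # unmethylated: every C reads as T; both strands of ACGT convert to ATGT
  expect_true(all(trimmedSeq(sim$reads) == "ATGT"))
  me <- simulateMethylome(g, 1, 0, 0, seed = 3)
  sim2 <- simulateReads(g, me, simConfig(nReads = 40, readLen = 4L,
                                         protocol = "lister", rngSeed = 4))
  # methylated Cs are unchanged
  fw <- sim2$truth$form == "+FW"
  expect_true(all(trimmedSeq(sim2$reads)[fw] == "ACGT"))
})

test_that("tagged-protocol reads carry form-appropriate tags and RC reads
           are reverse complements", {
  g <- genome1("ACGT")
  un <- simulateMethylome(g, 0, 0, 0, seed = 5)
  cfg <- simConfig(nReads = 200, readLen = 9L, protocol = "cokus",
                   rngSeed = 6)
  sim <- simulateReads(g, un, cfg)
  seqs <- sim$reads@seq
  tags <- substr(seqs, 1, 5)
  payload <- substring(seqs, 6)
  isRC <- sim$truth$form %in% c("+RC", "-RC")
  expect_true(all(tags[!isRC] == "GATCT"))
  expect_true(all(tags[isRC] == "GATCA"))
  expect_true(all(payload[!isRC] == "ATGT"))
  expect_true(all(payload[isRC] == "ACAT"))  # revcomp of the converted fragment
  expect_setequal(unique(sim$truth$form), c("+FW", "+RC", "-FW", "-RC"))
})

test_that("identical seeds reproduce FASTQ and truth byte for byte", {
  g <- simulateGenome(5000, seed = 21)
  my <- simulateMethylome(g, 0.7, 0.1, 0.01, seed = 22)
  cfg <- simConfig(nReads = 100, protocol = "cokus",
                   errorProfile = defaultErrorProfile(36), rngSeed = 23)
  s1 <- simulateReads(g, my, cfg)
  s2 <- simulateReads(g, my, cfg)
  f1 <- tempfile(); f2 <- tempfile()
  writeFastq(s1$reads, f1); writeFastq(s2$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(s1$truth, s2$truth)
})

test_that("per-cycle errors are injected at the configured rate", {
  g <- simulateGenome(50000, repeatFraction = 0, seed = 31)
  my <- simulateMethylome(g, 0, 0, 0, seed = 32)
  cfg <- simConfig(nReads = 3000, protocol = "lister",
                   errorProfile = rep(0.02, 36), rngSeed = 33)
  sim <- simulateReads(g, my, cfg)
  expected <- 3000 * 36 * 0.02
  expect_lt(abs(sum(sim$truth$nErrors) - expected), 4 * sqrt(expected))
  clean <- simulateReads(g, my, simConfig(nReads = 100, protocol = "lister",
                                          rngSeed = 33))
  expect_true(all(clean$truth$nErrors == 0L))
})

test_that("the evaluator computes mapability, accuracy and guards", {
  g <- simulateGenome(20000, repeatFraction = 0, seed = 41)
  my <- simulateMethylome(g, 0.72, 0, 0, seed = 42)
  sim <- simulateReads(g, my, simConfig(nReads = 200, protocol = "lister",
                                        rngSeed = 43))
  aln <- mapReads(sim$reads, buildBSIndex(g, k = 9))
  ev <- evaluateMapping(aln, sim$truth, g)
  expect_identical(ev$nReads, 200L)
  expect_identical(ev$accuracy, 100)
  expect_identical(ev$pctUnique, 100 * ev$nUnique / 200)
  # a mapped read missing from truth is an error
  expect_error(evaluateMapping(aln, sim$truth[-1, ], g), "absent")
  # zero unique reads: accuracy NA, not 0
  empty <- mapReads(BSReadSet("x", strrep("A", 36), protocol = "lister"),
                    buildBSIndex(g, k = 9))
  expect_true(is.na(evaluateMapping(
    empty, data.frame(readId = "x", chrom = "chr1", start = 1L,
                      form = "+FW", nErrors = 0L))$accuracy))
})

test_that("simulated genomes have the requested size and repeat content", {
  g <- simulateGenome(30000, nChrom = 2, seed = 51)
  expect_identical(unname(width(g)), c(30000L, 30000L))
  expect_identical(names(g), c("chr1", "chr2"))
  # planted repeats create ambiguous placements; a repeat-free genome of
  # this size should map (nearly) everything uniquely
  my <- simulateMethylome(g, 0, 0, 0, seed = 52)
  sim <- simulateReads(g, my, simConfig(nReads = 500, protocol = "lister",
                                        rngSeed = 53))
  aln <- mapReads(sim$reads, buildBSIndex(g, k = 9))
  expect_lt(runStats(aln)$pctUnique, 100)
  expect_gt(sum(unmappedReads(aln)$reason == "ambiguous"), 0)
})
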