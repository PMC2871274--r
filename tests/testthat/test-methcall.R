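test_that("cytosine context classification follows the CG/CHG/CHH rules", {
  expect_identical(classifyContext(genome1("ACGT"), "chr1", 2, "+"), "CG")
  expect_identical(classifyContext(genome1("ACAGT"), "chr1", 2, "+"), "CHG")
  expect_identical(classifyContext(genome1("ACATT"), "chr1", 2, "+"), "CHH")
  # minus strand: the C sits under a Watson G, neighbours read leftwards
  g <- genome1("ACGT")
  expect_identical(classifyContext(g, "chr1", 3, "-"), "CG")
  expect_identical(classifyContext(genome1("CCTGA"), "chr1", 4, "-"), "CHG")
  # running off the chromosome end counts as H
  expect_identical(classifyContext(genome1("AC"), "chr1", 2, "+"), "CHH")
  expect_identical(classifyContext(genome1("GA"), "chr1", 1, "-"), "CHH")
  expect_error(classifyContext(g, "chr1", 1, "+"), "not a C")
})

test_that("read C over genomic C is methylated, read T unmethylated", {
  g <- genome1("CCGATTTTTTTTTTTTTTTTTTTT")
  map <- data.frame(read_id = "r1", form = "+FW", chrom = "chr1",
                    start = 1L, read_seq = "TCGA", genome_seq = "CCGA")
  meth <- callMethylationFromTable(map, g)
  s <- methSites(meth)
  expect_identical(start(s), c(1L, 2L))
  expect_identical(S4Vectors::mcols(s)$nMeth, c(0L, 1L))
  expect_identical(S4Vectors::mcols(s)$nTotal, c(1L, 1L))
  expect_identical(unname(methStrings(meth)["r1"]), "UM--")
})

test_that("read bases other than C/T over a genomic C give no call", {
  g <- genome1("CAAATTTTTTTTTTTTTTTTTTTT")
  map <- data.frame(read_id = "r1", form = "+FW", chrom = "chr1",
                    start = 1L, read_seq = "AAAA", genome_seq = "CAAA")
  meth <- callMethylationFromTable(map, g)
  expect_identical(length(methSites(meth)), 0L)
  expect_identical(unname(methStrings(meth)["r1"]), ".---")
  # a read with no genomic C beneath it yields an empty call list
  map2 <- transform(map, read_seq = "AAAA", genome_seq = "AAAA", start = 2L)
  expect_identical(length(methSites(callMethylationFromTable(map2, g))), 0L)
})

test_that("per-site counts accumulate over reads", {
  g <- genome1("ACGTTTTTTTTTTTTTTTTTTTTT")
  map <- data.frame(read_id = paste0("r", 1:4), form = "+FW",
                    chrom = "chr1", start = 1L,
                    read_seq = c("ACGT", "ACGT", "ACGT", "ATGT"),
                    genome_seq = "ACGT")
  s <- methSites(callMethylationFromTable(map, g))
  expect_identical(S4Vectors::mcols(s)$nMeth, 3L)
  expect_identical(S4Vectors::mcols(s)$nTotal, 4L)
})

test_that("the two strands of a CG dinucleotide stay distinct sites", {
  g <- genome1("ACGTTTTTTTTTTTTTTTTTTTTT")
  map <- data.frame(read_id = c("plus", "minus"),
                    form = c("+FW", "-FW"), chrom = "chr1", start = 1L,
                    read_seq = c("ACGT", "ACGT"),
                    genome_seq = c("ACGT", "ACGT"))
  s <- methSites(callMethylationFromTable(map, g))
  expect_identical(length(s), 2L)
  expect_identical(start(s), c(2L, 3L))
  expect_identical(as.character(strand(s)), c("+", "-"))
  expect_identical(unique(S4Vectors::mcols(s)$context), "CG")
})

test_that("observation counts are conserved end to end", {
  g <- simulateGenome(20000, repeatFraction = 0, seed = 61)
  my <- simulateMethylome(g, 0.6, 0.2, 0.05, seed = 62)
  sim <- simulateReads(g, my, simConfig(nReads = 400, protocol = "lister",
                                        rngSeed = 63))
  aln <- mapReads(sim$reads, buildBSIndex(g, k = 9))
  meth <- callMethylation(aln, g)
  mc <- S4Vectors::mcols(mappedReads(aln))
  # count (read base in {C,T}) over genomic-C incidences independently,
  # from the read/genome segment pairs
  inc <- sum(mapply(function(r, gs, form) {
    if (form %in% c("+RC", "-RC")) {
      r <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(r)))
      gs <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(gs)))
    }
    rb <- strsplit(r, "")[[1]]
    gb <- strsplit(gs, "")[[1]]
    sum(gb == "C" & rb %in% c("C", "T"))
  }, mc$readSeq, mc$genomeSeq, mc$form))
  expect_identical(sum(S4Vectors::mcols(methSites(meth))$nTotal), inc)
})

test_that("rates are pooled per context and NA when uncovered", {
  g <- genome1("ACGTTTTTTTTTTTTTTTTTTTTT")
  map <- data.frame(read_id = paste0("r", 1:2), form = "+FW",
                    chrom = "chr1", start = 1L,
                    read_seq = c("ACGT", "ATGT"), genome_seq = "ACGT")
  s <- methSummary(callMethylationFromTable(map, g))
  expect_identical(unname(s[["CG"]]), 50)
  expect_true(is.na(s[["CHG"]]))
  expect_true(is.na(s[["CHH"]]))
})
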