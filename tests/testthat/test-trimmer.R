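## Boundary-index construction and adapter read-through trimming.

toyIndex <- function(ampliconSeq, adapter = defaultAdapter(), k = 12) {
  ref <- DNAStringSet(c(chr1 = paste0(ampliconSeq, strrep("T", 30))))
  bed <- makeBed("chr1", 0, nchar(ampliconSeq), "amp1")
  buildBoundaryIndex(loadAmpliconDesign(bed), ref, adapter, k = k)
}

test_that("boundary index records both termini with the amplicon length", {
  set.seed(1)
  aseq <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                collapse = "")
  idx <- toyIndex(aseq)
  expect_s4_class(idx, "BoundaryIndex")
  expect_equal(nrow(idx@entries), 2L)
  expect_equal(unique(idx@entries$len), 120L)
  expect_setequal(idx@entries$terminus, c("5p", "3p"))
  ## 5' key is the first k reference bases; 3' key the revcomp of the last k
  expect_equal(idx@entries$kmer[idx@entries$terminus == "5p"],
               substr(aseq, 1, 12))
  expect_equal(idx@entries$kmer[idx@entries$terminus == "3p"],
               as.character(Biostrings::reverseComplement(
                 DNAStringSet(substr(aseq, 109, 120)))))
})

test_that("index construction guards k and reference bounds", {
  set.seed(2)
  aseq <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                collapse = "")
  expect_error(toyIndex(aseq, k = 200), "shortest amplicon")
  ref <- DNAStringSet(c(chr1 = substr(aseq, 1, 50)))
  bed <- makeBed("chr1", 0, 120, "ampX")
  expect_error(buildBoundaryIndex(loadAmpliconDesign(bed), ref,
                                  defaultAdapter()), "ampX")
})

test_that("colliding terminal k-mers keep all candidates", {
  shared <- strrep("ACGT", 3)  # 12-mer shared 5' start
  set.seed(3)
  tail1 <- paste(sample(c("A", "C", "G", "T"), 108, replace = TRUE),
                 collapse = "")
  tail2 <- paste(sample(c("A", "C", "G", "T"), 88, replace = TRUE),
                 collapse = "")
  ref <- DNAStringSet(c(chr1 = paste0(shared, tail1, "TTTTT",
                                      shared, tail2)))
  bed <- makeBed("chr1", c(0, 125), c(120, 225), c("a1", "a2"))
  idx <- buildBoundaryIndex(loadAmpliconDesign(bed), ref, defaultAdapter())
  expect_equal(sum(idx@entries$kmer == shared), 2L)
})

test_that("a read running through the boundary is trimmed at the junction", {
  set.seed(4)
  aseq <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                collapse = "")
  idx <- toyIndex(aseq)
  adapter <- defaultAdapter()

  read <- paste0(aseq, substr(adapter, 1, 30))  # 150 bp with read-through
  out <- trimRead(read, strrep("I", 150), idx)
  expect_equal(out$decision$action, "trimmed")
  expect_equal(out$decision$trim_pos, 120L)
  expect_equal(out$seq, aseq)
  expect_equal(nchar(out$qual), 120L)

  ## read ending before the boundary: untrimmed
  short <- substr(aseq, 1, 100)
  out2 <- trimRead(short, strrep("I", 100), idx)
  expect_equal(out2$decision$action, "untrimmed")
  expect_equal(out2$seq, short)

  ## unrelated sequence: unassigned and unchanged
  set.seed(5)
  rand <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
                collapse = "")
  out3 <- trimRead(rand, strrep("I", 150), idx)
  expect_equal(out3$decision$action, "unassigned")
  expect_equal(out3$seq, rand)
})

test_that("trimming tolerates mismatches up to the limit and counts N as mismatch", {
  set.seed(6)
  aseq <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                collapse = "")
  idx <- toyIndex(aseq)
  read <- paste0(aseq, substr(defaultAdapter(), 1, 30))
  ## one substitution inside the k-mer
  mut <- read
  substr(mut, 5, 5) <- if (substr(mut, 5, 5) == "A") "C" else "A"
  expect_equal(trimRead(mut, NULL, idx, maxMismatch = 1)$decision$action,
               "trimmed")
  expect_equal(trimRead(mut, NULL, idx, maxMismatch = 0)$decision$action,
               "unassigned")
  ## two Ns in the k-mer exceed maxMismatch = 1
  mut2 <- read
  substr(mut2, 2, 3) <- "NN"
  expect_equal(trimRead(mut2, NULL, idx, maxMismatch = 1)$decision$action,
               "unassigned")
})

test_that("paired trimming recovers planted junctions on error-free reads", {
  sim <- simulatePanelReads(nAmplicons = 30, nReadPairs = 500,
                            readthroughFraction = 0.5,
                            substitutionRate = 0, seed = 7)
  idx <- buildBoundaryIndex(sim$design, sim$reference, defaultAdapter())
  o1 <- tempfile(fileext = ".fastq"); o2 <- tempfile(fileext = ".fastq")
  st <- trimFastq(sim$fastq_r1, sim$fastq_r2, idx, o1, o2,
                  truth = sim$truth)
  expect_equal(st$reads_total, 1000L)
  expect_gte(st$correctly_trimmed_fraction, 0.99)
  ## planted read-through fraction recovered within binomial 99% CI
  plantedRt <- mean(!is.na(sim$truth$trim_pos))
  phat <- st$reads_trimmed / st$reads_total
  ci <- 2.576 * sqrt(plantedRt * (1 - plantedRt) / st$reads_total)
  expect_lt(abs(phat - plantedRt), ci + 1e-9)
})

test_that("zero planted read-through leaves outputs byte-identical", {
  sim <- simulatePanelReads(nAmplicons = 15, nReadPairs = 150,
                            readthroughFraction = 0, seed = 8)
  idx <- buildBoundaryIndex(sim$design, sim$reference, defaultAdapter())
  o1 <- tempfile(fileext = ".fastq"); o2 <- tempfile(fileext = ".fastq")
  st <- trimFastq(sim$fastq_r1, sim$fastq_r2, idx, o1, o2)
  expect_equal(st$reads_trimmed, 0L)
  expect_identical(readLines(o1), readLines(sim$fastq_r1))
  expect_identical(readLines(o2), readLines(sim$fastq_r2))
})

test_that("sequencing errors degrade trimming only slightly", {
  sim <- simulatePanelReads(nAmplicons = 30, nReadPairs = 500,
                            readthroughFraction = 0.5,
                            substitutionRate = 0.01, seed = 9)
  idx <- buildBoundaryIndex(sim$design, sim$reference, defaultAdapter())
  o1 <- tempfile(fileext = ".fastq"); o2 <- tempfile(fileext = ".fastq")
  st <- trimFastq(sim$fastq_r1, sim$fastq_r2, idx, o1, o2,
                  maxMismatch = 2, truth = sim$truth)
  expect_gte(st$correctly_trimmed_fraction, 0.95)
})

test_that("output reads are prefixes of inputs with qualities in lockstep", {
  sim <- simulatePanelReads(nAmplicons = 20, nReadPairs = 200,
                            readthroughFraction = 0.5,
                            substitutionRate = 0.005, seed = 10)
  idx <- buildBoundaryIndex(sim$design, sim$reference, defaultAdapter())
  o1 <- tempfile(fileext = ".fastq"); o2 <- tempfile(fileext = ".fastq")
  trimFastq(sim$fastq_r1, sim$fastq_r2, idx, o1, o2)
  inp <- readDNAStringSet(sim$fastq_r1, format = "fastq",
                          with.qualities = TRUE)
  out <- readDNAStringSet(o1, format = "fastq", with.qualities = TRUE)
  expect_true(all(as.character(out) ==
                    substr(as.character(inp), 1, width(out))))
  expect_equal(nchar(as.character(S4Vectors::mcols(out)$qualities)),
               width(out))
})

test_that("trimming is idempotent", {
  sim <- simulatePanelReads(nAmplicons = 20, nReadPairs = 200,
                            readthroughFraction = 0.5, seed = 11)
  idx <- buildBoundaryIndex(sim$design, sim$reference, defaultAdapter())
  o1 <- tempfile(fileext = ".fastq"); o2 <- tempfile(fileext = ".fastq")
  trimFastq(sim$fastq_r1, sim$fastq_r2, idx, o1, o2)
  p1 <- tempfile(fileext = ".fastq"); p2 <- tempfile(fileext = ".fastq")
  st2 <- trimFastq(o1, o2, idx, p1, p2)
  expect_equal(st2$reads_trimmed, 0L)
  expect_identical(readLines(p1), readLines(o1))
})

test_that("no over-trimming beyond the chance-match probability on clean reads", {
  ## reads that extend past the boundary into RANDOM (non-adapter) sequence:
  ## a false trim requires a chance adapter-prefix match at the junction;
  ## with span s = 10 compared bases and <= 1 mismatch on uniform sequence,
  ## P(chance match) = sum_{m<=1} C(s,m) 3^m 0.25^s = (1 + 3s) * 0.25^s.
  n <- 10000
  sim <- simulatePanelReads(nAmplicons = 40, nReadPairs = 10,
                            ampliconLenRange = c(90, 120),
                            readthroughFraction = 0, seed = 12)
  amp <- amplicons(sim$design)
  chromStr <- as.character(sim$reference[["chr1"]])
  aseqs <- substring(chromStr, start(amp), end(amp))
  set.seed(12)
  pick <- sample(length(aseqs), n, replace = TRUE)
  fill <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = ""),
    character(1))
  reads <- paste0(aseqs[pick], fill)
  fq <- tempfile(fileext = ".fastq")
  x <- DNAStringSet(reads)
  names(x) <- sprintf("r%05d", seq_len(n))
  writeXStringSet(x, fq, format = "fastq",
                  qualities = BStringSet(strrep("I", nchar(reads))))
  st <- trimFastq(fq, NULL, buildBoundaryIndex(sim$design, sim$reference,
                                               defaultAdapter()),
                  tempfile(fileext = ".fastq"))
  s <- 10
  pChance <- (1 + 3 * s) * 0.25^s
  ## 99.9% binomial upper bound around the analytic probability
  bound <- pChance + 3.1 * sqrt(pChance / n) + 3 / n
  expect_lte(st$reads_trimmed / st$reads_total, bound)
})

test_that("mate id mismatches are reported with the record index", {
  sim <- simulatePanelReads(nAmplicons = 10, nReadPairs = 20, seed = 13)
  idx <- buildBoundaryIndex(sim$design, sim$reference, defaultAdapter())
  r2 <- readLines(sim$fastq_r2)
  r2[5] <- "@renamed_read"
  bad <- tempfile(fileext = ".fastq")
  writeLines(r2, bad)
  expect_error(trimFastq(sim$fastq_r1, bad, idx, tempfile(), tempfile()),
               "mate id mismatch at record 2")
})
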