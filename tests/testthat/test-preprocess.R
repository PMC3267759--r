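AD3 <- "TGGAATTCTCGGGTGCCAAGG"
AD5 <- "GTTCAGAGTTCTACAGTCCGACGATC"

mkread <- function(insert, rl = 44L) substr(paste0(insert, strrep(AD3, 4)), 1, rl)

test_that("a poly(A) insert is discarded with reason polyA", {
  cl <- cleanReads(mkread(strrep("A", 20)), NULL, AD3, AD5)
  expect_equal(unname(discardCounts(cl$report)[["polyA"]]), 1L)
  expect_length(cl$inserts, 0L)
})

test_that("a 17 nt insert with a perfect adapter is discarded as too_short", {
  cl <- cleanReads(mkread("GCGCGTTCGTAGCTAGC"), NULL, AD3, AD5)
  expect_equal(unname(discardCounts(cl$report)[["too_short"]]), 1L)
})

test_that("an 18 nt insert survives and is trimmed exactly", {
  ins <- "GCGCGTTCGTAGCTAGCC"
  cl <- cleanReads(mkread(ins), NULL, AD3, AD5)
  expect_identical(cl$inserts, ins)
})

test_that("rules fire in their fixed order", {
  reads <- c(mkread("GCATGCATGCATGCATGCAT"),      # clean
             mkread(paste0(substr(AD5, 1, 12), "CCGGTT")), # 5' pollution
             paste(rep("G", 44), collapse = ""),  # no 3' adapter
             substr(strrep(AD3, 4), 1, 44))       # adapter dimer
  quals <- c(strrep("#", 44), rep(strrep("I", 44), 3)) # first: low quality
  cl <- cleanReads(reads, quals, AD3, AD5)
  expect_identical(cl$reason,
                   c("low_quality", "adapter5_pollution", "no_3p_adapter",
                     "no_insert"))
  expect_equal(cl$report@rawTotal, 4L)
  expect_equal(cl$report@cleanTotal, 0L)
})

test_that("cleaning report discard counts equal the manifest exactly", {
  sim <- smallSim()
  cl <- cleanReads(as.character(sim$reads), as.character(sim$qualities),
                   sim$config$adapter3p, sim$config$adapter5p)
  for (jc in names(junkReasonMap))
    expect_equal(unname(discardCounts(cl$report)[[junkReasonMap[[jc]]]]),
                 sum(sim$manifest$origin == jc), info = jc)
  # and the surviving inserts are exactly the manifest inserts
  expect_identical(cl$inserts, sim$manifest$insert[cl$keptIndex])
})

test_that("collapse matches a dictionary tally and conserves counts", {
  sim <- smallSim()
  cl <- cleanReads(as.character(sim$reads), as.character(sim$qualities),
                   sim$config$adapter3p, sim$config$adapter5p)
  ur <- collapseReads(cl$inserts)
  expect_equal(sum(readCounts(ur)), length(cl$inserts))
  # hash-map oracle
  env <- new.env()
  for (s in chartr("T", "U", cl$inserts)) {
    env[[s]] <- (if (is.null(env[[s]])) 0L else env[[s]]) + 1L
  }
  expect_equal(length(ur), length(ls(env)))
  seqs <- as.character(readSequences(ur))
  for (i in seq_along(seqs))
    expect_equal(readCounts(ur)[i], env[[seqs[i]]])
  # sorted by descending count, ties lexicographic
  cts <- readCounts(ur)
  expect_true(all(diff(cts) <= 0))
  ties <- which(diff(cts) == 0)
  expect_true(all(seqs[ties] < seqs[ties + 1L]))
})

test_that("collapse is idempotent and order-independent", {
  set.seed(601)
  ins <- sample(c("ACGUACGUACGUACGUACGU", "GGCAUCGAUCGAUCGAUCGAUC",
                  "ACGUACGUACGUACGUACGU"), 300, replace = TRUE)
  a <- collapseReads(ins)
  b <- collapseReads(sample(ins))
  expect_identical(as.character(readSequences(a)),
                   as.character(readSequences(b)))
  expect_identical(readCounts(a), readCounts(b))
  again <- collapseReads(as.character(readSequences(a)), readCounts(a))
  expect_identical(readCounts(again), readCounts(a))
  expect_equal(length(collapseReads(character(0))), 0L)
})

test_that("length distribution is count-weighted and sums to one", {
  ur <- UniqueReadSet("ACGUACGUACGUACGUACGUAC", 10L)
  ld <- lengthDistribution(ur)
  expect_equal(ld$readFraction, 1)
  expect_equal(ld$length, 22L)
  ur2 <- UniqueReadSet(c(strrep("G", 21), strrep("C", 22), strrep("U", 25)),
                       c(50L, 30L, 20L))
  ld2 <- lengthDistribution(ur2)
  expect_equal(sum(ld2$readFraction), 1, tolerance = 1e-12)
  expect_equal(sum(ld2$readFraction[ld2$length >= 21 & ld2$length <= 23]),
               0.80)
})

test_that("malformed inputs are rejected", {
  expect_error(cleanReads("ACGT", "II", AD3, AD5),
               "quality strings differ")
  expect_error(cleanReads(c("ACGT", "ACGT"), "IIII", AD3, AD5),
               "differ in length")
  expect_error(cleanReads("ACGT", NULL, "", AD5), "non-empty")
})

test_that("FASTQ round-trips through cleaning", {
  sim <- smallSim()
  fq <- tempfile(fileext = ".fastq")
  Biostrings::writeXStringSet(sim$reads[1:500], fq, format = "fastq",
                              qualities = sim$qualities[1:500])
  fromFile <- cleanReads(fq, adapter3p = sim$config$adapter3p,
                         adapter5p = sim$config$adapter5p)
  direct <- cleanReads(as.character(sim$reads[1:500]),
                       as.character(sim$qualities[1:500]),
                       sim$config$adapter3p, sim$config$adapter5p)
  expect_identical(fromFile$inserts, direct$inserts)
  unlink(fq)
})
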