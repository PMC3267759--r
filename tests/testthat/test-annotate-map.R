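test_that("a read matching a reference window is annotated with its class", {
  set.seed(701)
  rr <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  ref <- data.frame(id = "rrna1", class = "rRNA", sequence = rr)
  read <- chartr("T", "U", substr(rr, 50, 70))
  ur <- UniqueReadSet(read, 5L)
  ann <- annotateNcRNA(ur, ref)
  expect_equal(length(ann$annotated), 1L)
  expect_equal(readAnnotations(ann$annotated), "rRNA")
  expect_equal(length(ann$remaining), 0L)
})

test_that("multi-class hits resolve by the fixed priority", {
  seqs <- paste(rep("ACGT", 20), collapse = "")
  ref <- data.frame(id = c("sno1", "trna1"),
                    class = c("snoRNA", "tRNA"),
                    sequence = c(seqs, seqs))
  ur <- UniqueReadSet(chartr("T", "U", substr(seqs, 1, 20)), 1L)
  ann <- annotateNcRNA(ur, ref)
  expect_equal(readAnnotations(ann$annotated), "tRNA")
})

test_that("an empty reference warns and leaves all reads unannotated", {
  ur <- UniqueReadSet("ACGUACGUACGUACGUACGU", 1L)
  expect_warning(ann <- annotateNcRNA(ur, NULL), "empty")
  expect_equal(length(ann$remaining), 1L)
  expect_equal(length(ann$annotated), 0L)
})

test_that("annotation partitions simulated reads exactly as the manifest says", {
  sim <- smallSim()
  cl <- cleanReads(as.character(sim$reads), as.character(sim$qualities),
                   sim$config$adapter3p, sim$config$adapter5p)
  ur <- collapseReads(cl$inserts)
  ann <- annotateNcRNA(ur, sim$ncrnaRef)
  expect_equal(length(ann$annotated) + length(ann$remaining), length(ur))
  m <- sim$manifest
  contSeqs <- unique(chartr("T", "U",
    m$insert[m$origin %in% c("rRNA", "tRNA", "snRNA", "snoRNA")]))
  miSeqs <- unique(chartr("T", "U", m$insert[m$origin == "miRNA"]))
  annSeqs <- as.character(readSequences(ann$annotated))
  expect_true(all(contSeqs %in% annSeqs))     # 100% contaminants annotated
  expect_false(any(miSeqs %in% annSeqs))      # 0% miRNA-origin annotated
})

test_that("the k-mer index records plus-strand positions and skips short contigs", {
  idx <- buildGenomeIndex(c(chr = "ACGTACGTACGT"), k = 8L)
  expect_identical(idx@table$chr[["ACGTACGT"]], c(1L, 5L))
  expect_warning(buildGenomeIndex(c(a = "ACGTACGTACGT", tiny = "ACG"),
                                  k = 8L), "shorter than k")
  expect_error(buildGenomeIndex(c(chr = "ACGTACGT"), k = 4L), "at least 8")
})

test_that("a planted read maps to exactly its locus; N-reads map nowhere", {
  sim <- smallSim()
  idx <- buildGenomeIndex(sim$genome)
  hp <- sim$hairpins[1, ]
  ur <- UniqueReadSet(hp$mature, 10L)
  mp <- mapReads(ur, idx)
  expect_true(mp$mapped[1])
  gsub <- substr(as.character(sim$genome[[hp$contig]]), hp$start + 1L,
                 hp$end)
  expect_true(all(mp$hits$start >= hp$start & mp$hits$end <= hp$end))
  bad <- UniqueReadSet(strrep("N", 20), 1L)
  mpb <- mapReads(bad, idx)
  expect_false(mpb$mapped[1])
  expect_equal(nrow(mpb$hits), 0L)
})

test_that("every reported locus is verified by substring equality", {
  sim <- smallSim()
  cl <- cleanReads(as.character(sim$reads), as.character(sim$qualities),
                   sim$config$adapter3p, sim$config$adapter5p)
  ur <- collapseReads(cl$inserts)
  ur <- ur[seq_len(min(200L, length(ur)))]
  idx <- buildGenomeIndex(sim$genome)
  mp <- mapReads(ur, idx)
  g <- as.character(sim$genome[[1]])
  for (h in seq_len(nrow(mp$hits))) {
    read <- chartr("U", "T",
                   as.character(readSequences(ur)[[mp$hits$readIndex[h]]]))
    win <- substr(g, mp$hits$start[h] + 1L, mp$hits$end[h])
    if (mp$hits$strand[h] == "-")
      win <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(win)))
    expect_identical(win, read)
  }
})

test_that("index-based mapping equals a naive full scan", {
  set.seed(702)
  g <- paste(sample(c("A", "C", "G", "T"), 50000, TRUE), collapse = "")
  genome <- c(toy = g)
  idx <- buildGenomeIndex(genome)
  # 100 probes: planted windows (some reverse-complemented) + random
  probes <- character(100)
  for (i in 1:100) {
    if (i <= 70) {
      st <- sample(49000, 1)
      p <- substr(g, st, st + sample(18:28, 1))
      if (i %% 2 == 0)
        p <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(p)))
      probes[i] <- p
    } else {
      probes[i] <- paste(sample(c("A", "C", "G", "T"), 22, TRUE),
                         collapse = "")
    }
  }
  ur <- UniqueReadSet(probes[!duplicated(probes)], 1L)
  mp <- mapReads(ur, idx, maxLoci = 100L)
  for (i in seq_len(length(ur))) {
    oracle <- naiveScanLoci(chartr("U", "T",
                                   as.character(readSequences(ur)[[i]])),
                            genome)
    got <- mp$hits[mp$hits$readIndex == i, c("contig", "start", "strand")]
    rownames(got) <- rownames(oracle) <- NULL
    expect_equal(got, oracle, info = i)
  }
})

test_that("the multi-mapping cap flags and truncates", {
  g <- paste(rep("ACGTACGTACGTACGTACGTACGT", 50), collapse = "")
  idx <- buildGenomeIndex(c(rep = g))
  ur <- UniqueReadSet(chartr("T", "U", substr(g, 1, 20)), 1L)
  mp <- mapReads(ur, idx, maxLoci = 5L)
  expect_true(mp$multiMapped[1])
  expect_equal(sum(mp$hits$readIndex == 1), 5L)
})
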