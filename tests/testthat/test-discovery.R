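MIR1 <- "UGGAAUGUAAAGAAGUAUGUAU"
LET7H <- "UGAGGUAGUAAGUUGUGUUGU"

test_that("seed extraction returns positions 2-8", {
  expect_equal(extractSeed(MIR1), "GGAAUGU")
  expect_equal(extractSeed(LET7H), "GAGGUAG")
  expect_error(extractSeed("UGAGGUA"), "at least 8")
})

test_that("a read identical to a catalog mature matches with zero edits", {
  catalog <- data.frame(name = "cca-miR-1", species = "cca",
                        sequence = MIR1)
  ur <- UniqueReadSet(MIR1, 100L)
  mk <- matchKnown(ur, catalog)
  expect_equal(nrow(mk$matches), 1L)
  expect_equal(mk$matches$edits, 0L)
  expect_equal(mk$matches$name, "cca-miR-1")
})

test_that("an end-trimmed variant still matches its entry", {
  catalog <- data.frame(name = "cca-miR-1", species = "cca",
                        sequence = MIR1)
  trimmed <- substr(MIR1, 1, nchar(MIR1) - 2)
  mk <- matchKnown(UniqueReadSet(trimmed, 10L), catalog)
  expect_equal(mk$matches$name, "cca-miR-1")
  expect_equal(mk$matches$edits, 2L)
  # a different seed never matches
  other <- UniqueReadSet("CCGAAUGUAAAGAAGUAUGUAU", 10L)
  expect_equal(nrow(matchKnown(other, catalog)$matches), 0L)
})

test_that("match decisions equal a brute-force all-pairs edit check", {
  set.seed(801)
  catalog <- data.frame(name = sprintf("mir-%02d", 1:50),
                        species = "dre",
                        sequence = vapply(1:50, function(i)
                          randomRNA(sample(20:23, 1)), character(1)))
  # brute-force predicate, written independently over char vectors
  bruteMatch <- function(read) {
    best <- NA_integer_; bestE <- Inf
    for (ci in seq_len(nrow(catalog))) {
      cs <- catalog$sequence[ci]
      if (substr(read, 2, 8) != substr(cs, 2, 8)) next
      dl <- abs(nchar(read) - nchar(cs))
      if (dl > 5) next
      L <- min(nchar(read), nchar(cs))
      mm <- sum(utf8ToInt(substr(read, 1, L)) != utf8ToInt(substr(cs, 1, L)))
      if (mm > 2) next
      if (mm + dl < bestE) { bestE <- mm + dl; best <- ci }
    }
    best
  }
  reads <- c(vapply(1:40, function(i) randomRNA(22), character(1)),
             # reads derived from catalog entries so matches actually occur
             vapply(1:20, function(i) {
               cs <- catalog$sequence[sample(50, 1)]
               substr(cs, 1, nchar(cs) - sample(0:3, 1))
             }, character(1)))
  reads <- reads[nchar(reads) >= 18 & !duplicated(reads)]
  ur <- UniqueReadSet(reads, seq_along(reads))
  mk <- matchKnown(ur, catalog)
  got <- rep(NA_integer_, length(reads))
  got[mk$matches$readIndex] <- match(mk$matches$name, catalog$name)
  expect_identical(got, vapply(reads, bruteMatch, integer(1),
                               USE.NAMES = FALSE))
})

test_that("length-variant trims cluster into one category led by the top count", {
  s22 <- "UGAGGUAGUAAGUUGUGUUGUC"
  reads <- UniqueReadSet(c(s22, substr(s22, 1, 21), substr(s22, 1, 20)),
                         c(100L, 10L, 5L))
  cats <- clusterCategories(reads, rep("let-7h", 3))
  expect_length(cats, 1L)
  expect_equal(as.character(readSequences(representativeRead(cats[[1]]))),
               s22)
  expect_equal(length(cats[[1]]), 3L)
})

test_that("different seeds yield different categories", {
  reads <- UniqueReadSet(c(MIR1, LET7H), c(5L, 6L))
  cats <- clusterCategories(reads, c("miR-1", "let-7h"))
  expect_length(cats, 2L)
})

test_that("clustering is permutation-invariant with a max-count representative", {
  set.seed(802)
  for (rep in 1:20) {
    cloud <- randomIsomirCloud()
    perm <- sample(length(cloud$sequences))
    a <- clusterCategories(UniqueReadSet(cloud$sequences, cloud$counts),
                           rep("x", length(cloud$sequences)))
    b <- clusterCategories(UniqueReadSet(cloud$sequences[perm],
                                         cloud$counts[perm]),
                           rep("x", length(cloud$sequences)))
    expect_length(a, 1L)
    expect_length(b, 1L)
    expect_equal(as.character(readSequences(representativeRead(a[[1]]))),
                 cloud$mature)
    expect_equal(as.character(readSequences(representativeRead(b[[1]]))),
                 cloud$mature)
    expect_equal(sum(readCounts(a[[1]]@members)), sum(cloud$counts))
  }
})

test_that("count ties break to the lexicographically smallest sequence", {
  s <- "CCGAGGUAGUAAGUUGUGUUGU"
  reads <- UniqueReadSet(c(s, substr(s, 1, 21)), c(10L, 10L))
  cats <- clusterCategories(reads, c("x", "x"))
  expect_equal(as.character(readSequences(representativeRead(cats[[1]]))),
               substr(s, 1, 21)) # prefix sorts before its extension
})

test_that("conservation classes follow the species-group definitions", {
  expect_equal(conservationClass(c("dre")), "teleost_only")
  expect_equal(conservationClass(character(0)), "carp_specific")
  expect_equal(conservationClass(c("xtr", "dre", "gga", "mmu", "hsa")),
               "vertebrate_conserved")
  expect_equal(conservationClass(c("cel", "hsa")), "pan_bilaterian")
  expect_equal(conservationClass(c("dre", "hsa")), "partially_conserved")
  expect_error(conservationClass("zzz"), "zzz")
})

test_that("teleost-only table rows all classify teleost_only", {
  t2 <- loadPublishedTable("T2")
  sets <- tableSpeciesSets(t2)
  classes <- vapply(sets, conservationClass, character(1))
  expect_true(all(classes == "teleost_only"))
  expect_length(classes, 31L)
})

test_that("category partition against the table catalog is exclusive and exhaustive", {
  catalog <- publishedTableCatalog()
  t2 <- loadPublishedTable("T2")
  ur <- UniqueReadSet(t2$Sequence[1:5], t2$Frequency[1:5])
  mk <- matchKnown(ur, catalog)
  cats <- clusterCategories(mk$matched, mk$matchName)
  cons <- conservationPartition(cats, catalog)
  expect_equal(nrow(cons), length(cats))
  expect_true(all(cons$class == "teleost_only"))
})

test_that("external-set overlap fractions are exact", {
  reads <- UniqueReadSet(c(MIR1, LET7H), c(5L, 6L))
  cats <- clusterCategories(reads, c("cca-miR-1", "cca-let-7h"))
  nms <- vapply(cats, categoryName, character(1))
  expect_equal(compareExternalSet(cats, nms), 1.0)
  expect_equal(compareExternalSet(cats, character(0)), 0.0)
  expect_equal(compareExternalSet(cats, c("hno-miR-1", "other")), 0.5)
  expect_error(compareExternalSet(list(), "x"), "empty")
})
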