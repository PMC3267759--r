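test_that("zero hairpins gives a genome with no planted loci", {
  cfg <- simulationConfig(nHairpins = 0L, genomeLength = 5000L,
                          totalReads = 100L, contaminantFraction = 0.5,
                          junkFraction = 0.5, seed = 1L)
  gen <- generateGenome(cfg)
  expect_equal(nrow(gen$hairpins), 0L)
  expect_equal(sum(Biostrings::width(gen$genome)), 5000L)
})

test_that("an infeasible configuration fails up front with no partial output", {
  expect_error(simulationConfig(nHairpins = 100L, genomeLength = 5000L),
               "genome too short")
})

test_that("generation and simulation are byte-identical under a fixed seed", {
  cfg <- simulationConfig(nHairpins = 4L, genomeLength = 8000L,
                          totalReads = 2000L, seed = 11L)
  run <- function() {
    gen <- generateGenome(cfg)
    rd <- simulateReads(cfg, gen$hairpins, gen$ncrnaRef)
    d <- tempfile()
    writeSimulation(c(gen, rd), d)
    sums <- tools::md5sum(list.files(d, full.names = TRUE))
    names(sums) <- basename(names(sums))
    unlink(d, recursive = TRUE)
    sums
  }
  expect_identical(run(), run())
})

test_that("every planted precursor passes the novel-miRNA criteria", {
  sim <- smallSim()
  hp <- sim$hairpins
  for (i in seq_len(nrow(hp))) {
    fold <- foldMFE(hp$precursor[i])
    crit <- hairpinCriteria(fold, hp$matureStart[i],
                            hp$matureStart[i] + nchar(hp$mature[i]) - 1L,
                            count = Inf)
    expect_true(all(crit), info = hp$name[i])
    # mature is an exact substring of the precursor, inside one arm
    expect_identical(substr(hp$precursor[i], hp$matureStart[i],
                            hp$matureStart[i] + nchar(hp$mature[i]) - 1L),
                     hp$mature[i])
  }
  # planted half on each strand, at non-overlapping loci
  expect_equal(sum(hp$strand == "+"), nrow(hp) / 2)
  ord <- order(hp$start)
  expect_true(all(hp$start[ord][-1] >= hp$end[ord][-nrow(hp)]))
})

test_that("the manifest accounts for every emitted read", {
  sim <- smallSim()
  expect_equal(nrow(sim$manifest), sim$config$totalReads)
  expect_equal(length(sim$reads), sim$config$totalReads)
  expect_identical(sim$manifest$id, names(sim$reads))
  expect_true(all(table(sim$manifest$id) == 1L))
})

test_that("with no junk or contaminants every insert is a planted mature variant", {
  cfg <- simulationConfig(nHairpins = 3L, genomeLength = 6000L,
                          totalReads = 1000L, contaminantFraction = 0,
                          junkFraction = 0, seed = 21L)
  gen <- generateGenome(cfg)
  rd <- simulateReads(cfg, gen$hairpins, gen$ncrnaRef)
  expect_true(all(rd$manifest$origin == "miRNA"))
  variants <- unlist(lapply(gen$hairpins$matureContext, function(ctx)
    vapply(17:27, function(L) substr(chartr("U", "T", ctx), 1, L),
           character(1))))
  expect_true(all(rd$manifest$insert %in% variants))
  expect_true(all(abs(rd$manifest$insertLength - cfg$matureLength) <= 5))
})

test_that("an isomiR profile concentrated on offset 0 gives 100% 21-23 nt inserts", {
  prof <- defaultIsomirProfile() * 0
  prof["0"] <- 1
  cfg <- simulationConfig(nHairpins = 2L, genomeLength = 4000L,
                          totalReads = 500L, contaminantFraction = 0,
                          junkFraction = 0, isomirProfile = prof,
                          seed = 22L)
  gen <- generateGenome(cfg)
  rd <- simulateReads(cfg, gen$hairpins, gen$ncrnaRef)
  expect_true(all(rd$manifest$insertLength == 22L))
})

test_that("simulating contaminants without a reference fails", {
  cfg <- simulationConfig(nHairpins = 2L, genomeLength = 4000L,
                          totalReads = 100L, seed = 23L)
  gen <- generateGenome(cfg)
  expect_error(simulateReads(cfg, gen$hairpins, NULL), "ncRNA reference")
})

test_that("Ct simulation honours the ddCt identities at zero noise", {
  ct <- simulateCtTable(c(`30dph` = 1, `1y` = 1, `2y` = 1),
                        nReplicates = 3, noiseSd = 0, seed = 1)
  res <- deltaDeltaCt(ct, "30dph")
  expect_true(all(foldChanges(res)$ddCt == 0))
  ct2 <- simulateCtTable(c(`30dph` = 1, `2y` = 2), nReplicates = 3,
                         noiseSd = 0, seed = 1)
  # a true fold of 2 puts the target exactly one cycle below the calibrator
  expect_equal(mean(ct2$ct_target[ct2$group == "2y"]),
               mean(ct2$ct_target[ct2$group == "30dph"]) - 1)
  expect_error(simulateCtTable(c(a = 1, b = -2)), "positive")
  expect_error(simulateCtTable(c(a = 2, b = 1)), "calibrator")
})
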