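test_that("the calibrator group's fold is identically 1", {
  ct <- simulateCtTable(c(`30dph` = 1, `1y` = 2, `2y` = 8),
                        nReplicates = 5, noiseSd = 0.3, seed = 7)
  res <- deltaDeltaCt(ct, "30dph")
  tab <- foldChanges(res)
  expect_identical(tab$fold[tab$group == "30dph"], 1)
  expect_identical(tab$ddCt[tab$group == "30dph"], 0)
})

test_that("one cycle below the calibrator doubles the fold", {
  ct <- data.frame(mirna = "m", group = rep(c("cal", "g"), each = 2),
                   replicate = c(1, 2, 1, 2),
                   ct_target = c(25, 25, 24, 24),
                   ct_reference = 18)
  tab <- foldChanges(deltaDeltaCt(ct, "cal"))
  expect_equal(tab$fold[tab$group == "g"], 2)
})

test_that("simulated fold changes are recovered within tolerance", {
  truth <- c(`30dph` = 1, `1y` = 2, `2y` = 8)
  ct <- simulateCtTable(truth, nReplicates = 5, noiseSd = 0.1, seed = 99)
  tab <- foldChanges(deltaDeltaCt(ct, "30dph"))
  for (g in names(truth)) {
    got <- tab$fold[tab$group == g]
    expect_lt(abs(got - truth[[g]]) / truth[[g]], 0.15)
  }
  expect_true(all(is.finite(tab$foldSem)))
})

test_that("folds are invariant to a constant Ct shift", {
  ct <- simulateCtTable(c(a = 1, b = 4), nReplicates = 3, noiseSd = 0.2,
                        seed = 3, calibrator = "a")
  shifted <- ct
  shifted$ct_target <- shifted$ct_target + 5
  shifted$ct_reference <- shifted$ct_reference + 5
  expect_equal(foldChanges(deltaDeltaCt(ct, "a"))$fold,
               foldChanges(deltaDeltaCt(shifted, "a"))$fold)
})

test_that("a missing calibrator fails naming the miRNA", {
  ct <- data.frame(mirna = "miR-9", group = "g", replicate = 1:2,
                   ct_target = c(25, 25.1), ct_reference = 18)
  expect_error(deltaDeltaCt(ct, "cal"), "miR-9")
})

test_that("ANOVA handles identical and degenerate groups as specified", {
  a <- oneWayAnova(c(1, 2, 3, 1, 2, 3), rep(c("x", "y"), each = 3))
  expect_equal(a$F, 0)
  expect_equal(a$p, 1)
  d <- oneWayAnova(c(0, 0, 1, 1), rep(c("x", "y"), each = 2))
  expect_true(is.infinite(d$F))
  expect_equal(d$p, 0)
  expect_true(d$degenerate)
  expect_error(oneWayAnova(1:4, rep("x", 4)), "2 groups")
})

test_that("ANOVA agrees with the standard linear-model route", {
  set.seed(901)
  for (i in 1:5) {
    y <- rnorm(15, mean = rep(c(0, 0.5, 1), each = 5))
    g <- rep(c("a", "b", "c"), each = 5)
    mine <- oneWayAnova(y, g)
    ref <- anova(stats::aov(y ~ g))
    expect_equal(mine$F, ref$`F value`[1], tolerance = 1e-10)
    expect_equal(mine$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
  }
})

test_that("expression results propagate into the ANOVA table", {
  ct <- simulateCtTable(c(a = 1, b = 8), nReplicates = 5, noiseSd = 0.05,
                        seed = 5, calibrator = "a")
  res <- deltaDeltaCt(ct, "a")
  av <- anovaTable(res)
  expect_equal(nrow(av), 1L)
  expect_lt(av$p, 0.01) # an 8-fold change at low noise is detectable
})

test_that("tissue specificity calls planted specific rows and only them", {
  tissues <- c("muscle", "heart", "gut", "liver", "kidney", "skin",
               "gill", "eye", "brain")
  m <- matrix(1, nrow = 5, ncol = length(tissues),
              dimnames = list(c("miR-1", "miR-133a-3p", "miR-206",
                                "let-7a", "miR-143"), tissues))
  m["miR-1", ] <- c(10, 8, 5, 0.1, 0.1, 0.2, 0.1, 6, 0.1)
  m["miR-133a-3p", ] <- c(12, 9, 4, 0.2, 0.1, 0.1, 0.2, 0.1, 0.1)
  m["miR-206", ] <- c(20, 1, 1, 0.1, 0.2, 0.1, 0.1, 0.1, 0.3)
  calls <- tissueSpecificity(m)
  expect_identical(calls$call,
                   c("specific", "specific", "specific",
                     "ubiquitous", "ubiquitous"))
  expect_match(calls$tissues[1], "muscle")
  # single-tissue and constant rows
  one <- matrix(c(5, 0, 0), nrow = 1,
                dimnames = list("m", c("t1", "t2", "t3")))
  expect_equal(tissueSpecificity(one)$tissues, "t1")
  zero <- matrix(0, nrow = 1, ncol = 3,
                 dimnames = list("z", c("t1", "t2", "t3")))
  expect_warning(zc <- tissueSpecificity(zero), "all-zero")
  expect_equal(zc$call, "ubiquitous")
})
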