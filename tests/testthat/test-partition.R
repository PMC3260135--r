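refAreas <- function() projectedAreas(UnitCellGeometry(), roundTo = 10)

test_that("H-correction subtracts the overlap rate exactly", {
  cc <- correctCounts(countRateTriple(1.66, 4.55, 7.02))
  expect_equal(cc$Cp_G, 2.89)
  expect_equal(cc$Cp_V, 5.36)
  cc2 <- correctCounts(countRateTriple(3.16, 5.2, 6.03))
  expect_equal(c(cc2$Cp_G, cc2$Cp_V), c(2.04, 2.87))
  # a uniform field has no fibril-specific signal
  u <- correctCounts(countRateTriple(3.3, 3.3, 3.3))
  expect_equal(c(u$Cp_G, u$Cp_V), c(0, 0))
  # misassigned regions raise instead of clamping
  expect_error(correctCounts(countRateTriple(5, 4, 7)),
               "negative corrected count")
})

test_that("partition reproduces the published per-sample fractions", {
  tab <- externalFraction(readCountTable(referenceCountsFixture()), refAreas())
  expect_equal(tab$X_ext, c(0.7595, 0.8405, 0.8543), tolerance = 5e-4)
  expect_equal(tab$Cp_G, tab$ref_Cp_G)
  expect_equal(tab$Cp_V, tab$ref_Cp_V)
})

test_that("partition limiting cases", {
  a <- refAreas()
  # no gap mineral -> everything external
  t1 <- externalFraction(countRateTriple(2, 2, 6), a)
  expect_equal(t1$X_ext, 1.0)
  # no plates anywhere -> everything in the gaps
  t0 <- externalFraction(countRateTriple(0, 3, 0), a)
  expect_equal(t0$X_ext, 0.0)
  expect_error(externalFraction(countRateTriple(0, 0, 0), a),
               "undefined")
})

test_that("partition is scale invariant and monotone in the count rates", {
  a <- projectedAreas(UnitCellGeometry())
  base <- externalFraction(countRateTriple(1.66, 4.55, 7.02), a)$X_ext
  for (k in c(0.01, 0.5, 7, 1000)) {
    xk <- externalFraction(countRateTriple(1.66 * k, 4.55 * k, 7.02 * k),
                           a)$X_ext
    expect_equal(xk, base)
  }
  xg <- sapply(seq(2, 6, by = 0.5), function(cg)
    externalFraction(countRateTriple(1.66, cg, 7.02), a)$X_ext)
  expect_true(all(diff(xg) < 0))
  xv <- sapply(seq(2, 9, by = 0.5), function(cv)
    externalFraction(countRateTriple(1.66, 4.55, cv), a)$X_ext)
  expect_true(all(diff(xv) > 0))
})

test_that("summary uses the population SD", {
  s <- summarizePartition(c(0.7595, 0.8405, 0.8543))
  expect_equal(s$mean, 0.8181, tolerance = 1e-4)
  expect_equal(s$spread, 0.0418, tolerance = 1e-3)
  expect_equal(s$n, 3L)
  expect_equal(summarizePartition(c(0.5))$spread, 0)
  expect_equal(summarizePartition(c(0, 1)),
               list(mean = 0.5, spread = 0.5, n = 2L))
  expect_error(summarizePartition(numeric()), "at least one")
})

test_that("Ca:P stoichiometry check", {
  r <- caPRatioCheck(167, 100)
  expect_equal(r$ratio, 1.67)
  expect_true(r$in_range)
  expect_false(caPRatioCheck(100, 100)$in_range)
  expect_equal(caPRatioCheck(334, 100, sensitivityRatio = 2)$ratio, 1.67)
  expect_error(caPRatioCheck(100, 0), "P counts")
})

test_that("reference-table reproduction is order invariant and strict", {
  rep <- reproduceReferenceTable()
  expect_equal(rep$table$X_ext, rep$table$ref_X_ext, tolerance = 5e-4)
  expect_equal(rep$summary$n, 3L)

  # permuted rows give the same per-sample results keyed by label
  tab <- readCountTable(referenceCountsFixture())
  perm <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab[c(3, 1, 2), ], perm, row.names = FALSE)
  rep2 <- reproduceReferenceTable(perm)
  m <- match(rep$table$sample, rep2$table$sample)
  expect_equal(rep2$table$X_ext[m], rep$table$X_ext)

  # corrupted fixture (C_G < C_O) fails loudly
  bad <- tab
  bad$C_G[2] <- 1.0
  badPath <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad, badPath, row.names = FALSE)
  expect_error(reproduceReferenceTable(badPath), "negative corrected count")
})

test_that("partition report writes per-sample rows plus a summary", {
  path <- withr::local_tempfile(fileext = ".csv")
  writePartitionReport(reproduceReferenceTable(), path)
  out <- read.csv(path)
  expect_equal(nrow(out), 4L)
  expect_match(out$sample[4], "81.8% \\+/- 4.2%")
})
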