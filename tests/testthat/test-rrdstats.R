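mkRecords <- function(values, nuclei, gene = "G", tissue = "T1") {
  data.frame(tissue_id = tissue, gene = gene, nucleus_id = nuclei,
             x = 0, y = 0, edt_at_spot = values, max_edt = 1, rrp = values)
}

test_that("buildRRD pools all alleles of all nuclei without averaging", {
  set.seed(41)
  rec <- mkRecords(runif(240), rep(1:120, each = 2))
  rrd <- buildRRD(rec, "G", "T1")
  expect_equal(nAlleles(rrd), 240L)
  expect_equal(nNuclei(rrd), 120L)

  # nuclei with 1, 2 and 3 alleles all contribute every allele
  rec2 <- mkRecords(runif(6) , c(1, 2, 2, 3, 3, 3))
  expect_warning(rrd2 <- buildRRD(rec2, "G", "T1"), "only 3 nuclei")
  expect_equal(nAlleles(rrd2), 6L)

  expect_error(buildRRD(rec, "NOPE", "T1"), "no allele records")
  bad <- mkRecords(c(0.5, 1.2), c(1, 2))
  expect_error(buildRRD(bad, "G", "T1"), "\\[0, 1\\]")
})

test_that("PND pooling conserves counts and ignores input order", {
  set.seed(42)
  rrds <- lapply(1:7, function(i) {
    n <- sample(90:170, 1)
    suppressWarnings(buildRRD(mkRecords(runif(2 * n), rep(seq_len(n), 2),
                                        tissue = paste0("N", i)),
                              "G", paste0("N", i)))
  })
  pnd <- buildPND(rrds)
  expect_equal(length(rrpValues(pnd)), sum(vapply(rrds, nAlleles, 1L)))
  expect_equal(nNuclei(pnd), sum(vapply(rrds, nNuclei, 1L)))

  perm <- buildPND(rrds[sample(7)])
  expect_equal(sort(rrpValues(perm)), sort(rrpValues(pnd)))

  other <- suppressWarnings(buildRRD(mkRecords(runif(4), 1:4, gene = "H"),
                                     "H", "T1"))
  expect_error(buildPND(list(rrds[[1]], other)), "mixed genes")
  expect_error(buildPND(rrds[1]), "at least two")
})

test_that("the KS statistic matches the brute-force ECDF gap and is symmetric", {
  expect_error(ksTwoSample(numeric(0), 1:3), "non-empty")
  same <- c(0.1, 0.5, 0.9)
  expect_equal(ksTwoSample(same, same)$D, 0)
  expect_equal(ksTwoSample(same, same)$p, 1)
  expect_equal(ksTwoSample(c(0.1, 0.2, 0.3), c(0.6, 0.7, 0.8))$D, 1)

  set.seed(43)
  for (i in 1:20) {
    a <- round(runif(sample(5:40, 1)), 2)  # rounding forces ties too
    b <- round(runif(sample(5:40, 1)), 2)
    expect_equal(ksTwoSample(a, b, exact = "never")$D, bruteForceKSD(a, b))
    expect_identical(ksTwoSample(a, b), ksTwoSample(b, a))
  }
})

test_that("repositioning calls carry significance and direction correctly", {
  set.seed(44)
  ref <- rbeta(960, 2, 2)
  nullRRD <- suppressWarnings(
    buildRRD(mkRecords(sample(ref, 240), rep(1:120, 2)), "G", "T1"))
  res <- callRepositioning(nullRRD, ref)
  expect_s4_class(res, "RepositioningResult")

  # identical distributions: never significant
  selfRes <- callRepositioning(nullRRD, rrpValues(nullRRD))
  expect_equal(selfRes@direction, "NS")
  expect_false(selfRes@significant)

  # strong peripheral shift: significant with direction P
  periRRD <- suppressWarnings(
    buildRRD(mkRecords(rbeta(240, 2, 5), rep(1:120, 2), tissue = "T2"),
             "G", "T2"))
  resP <- callRepositioning(periRRD, ref)
  expect_true(resP@significant)
  expect_equal(resP@direction, "P")
  expect_lt(resP@medianDiff, 0)

  # strong internal shift: direction I
  intRRD <- suppressWarnings(
    buildRRD(mkRecords(rbeta(240, 5, 2), rep(1:120, 2), tissue = "T3"),
             "G", "T3"))
  expect_equal(callRepositioning(intRRD, ref)@direction, "I")
})

test_that("significance rate under the null stays near alpha and power grows", {
  set.seed(45)
  # moderate-n null calibration (the full 2000-replicate check is in the
  # acceptance suite)
  hits <- sum(replicate(400, {
    ksTwoSample(rbeta(240, 2, 2), rbeta(960, 2, 2), exact = "never")$p < 0.01
  }))
  expect_lt(hits / 400, 0.03)

  # monotone power in the shift magnitude and the sample size
  power <- function(n, shape2) mean(replicate(60, {
    ksTwoSample(rbeta(n, 2, shape2), rbeta(960, 2, 2), exact = "never")$p < 0.01
  }))
  expect_gte(power(240, 3), power(240, 2.3) - 0.05)
  expect_gte(power(240, 2.6), power(60, 2.6) - 0.05)
})

test_that("cross-comparison covers all pairs and separates mixtures", {
  set.seed(46)
  mk <- function(i, shape2 = 2) suppressWarnings(
    buildRRD(mkRecords(rbeta(200, 2, shape2), rep(1:100, 2),
                       tissue = paste0("T", i)), "G", paste0("T", i)))
  rrds <- lapply(1:10, mk)
  cx <- crossCompare(rrds)
  expect_equal(cx$nPairs, 45)
  expect_true(isSymmetric(cx$pMatrix))
  expect_true(all(diag(cx$pMatrix) == 1))
  expect_lt(cx$fractionSignificant, 0.1)

  # two well-separated clusters: every between-cluster pair significant
  clustered <- c(lapply(1:4, mk), lapply(5:8, mk, shape2 = 6))
  cx2 <- crossCompare(clustered)
  between <- cx2$pMatrix[1:4, 5:8]
  expect_true(all(between < 0.01))
})

test_that("compareToPND builds the reference from the normals and calls all tissues", {
  set.seed(47)
  recs <- do.call(rbind, c(
    lapply(1:3, function(i)
      mkRecords(rbeta(200, 2, 2), rep(1:100, 2), tissue = paste0("N", i))),
    list(mkRecords(rbeta(200, 2, 6), rep(1:100, 2), tissue = "C1"))))
  calls <- suppressWarnings(
    compareToPND(recs, "G", normalTissues = c("N1", "N2", "N3")))
  expect_equal(nrow(calls), 4L)
  expect_equal(calls$call[calls$tissue_id == "C1"], "P")
  expect_true(all(calls$call[calls$tissue_id != "C1"] == "NS"))

  # leave-one-out shrinks the reference for normals only
  loo <- suppressWarnings(
    compareToPND(recs, "G", c("N1", "N2", "N3"), leaveOneOut = TRUE))
  expect_equal(loo$call[loo$tissue_id == "C1"], "P")
})
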