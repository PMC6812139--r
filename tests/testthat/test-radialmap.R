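test_that("computeEDT matches hand calculations and rejects bad masks", {
  m <- matrix(0, 5, 5); m[2:4, 2:4] <- 1
  e <- computeEDT(m)
  expect_equal(e[3, 3], 2)
  expect_equal(e[2, 2], 1)
  expect_equal(max(e), 2)
  expect_true(all(e[m == 0] == 0))

  d <- discMask(50)
  expect_gte(max(computeEDT(d)), 49)
  expect_lte(max(computeEDT(d)), 51)

  expect_error(computeEDT(matrix(0, 4, 4)), "empty")
  expect_error(computeEDT(matrix(1, 4, 4)), "background")
  two <- matrix(0, 5, 5); two[2, 2] <- 1; two[4, 4] <- 1
  expect_error(computeEDT(two), "2 foreground components")
  expect_silent(computeEDT(two, single = FALSE))
})

test_that("computeEDT equals the brute-force oracle on random masks", {
  set.seed(21)
  for (i in 1:25) {
    m <- matrix(rbinom(30 * 30, 1, runif(1, 0.3, 0.8)), 30, 30)
    if (!any(m > 0) || !any(m == 0)) next
    expect_equal(computeEDT(m, single = FALSE), bruteForceEDT(m))
  }
})

test_that("rrp normalization follows the disc geometry", {
  d <- discMask(50)
  e <- computeEDT(d)
  ctr <- which(e == max(e), arr.ind = TRUE)[1, ]

  expect_equal(rrpOfSpot(ctr[2], ctr[1], e), 1.0)

  # boundary pixel: minimum attainable rrp = 1/maxEdt
  bnd <- which(d > 0 & e == min(e[d > 0]), arr.ind = TRUE)[1, ]
  expect_equal(rrpOfSpot(bnd[2], bnd[1], e), 1 / max(e), tolerance = 1e-8)

  # analytic (R - r)/R at radial distance 25
  expect_equal(rrpOfSpot(ctr[2] + 25, ctr[1], e), 0.5, tolerance = 0.03)

  expect_warning(v <- rrpOfSpot(1, 1, e), "outside")
  expect_true(is.na(v))
})

test_that("rrp values are invariant to scaling and rotation of the mask", {
  set.seed(22)
  m <- generateNucleusMask(nucleusShapeParams(meanRadius = 25))
  e1 <- computeEDT(m)
  sp <- placeSpots(m, radialModel("beta", 2, 2), copyNumber = 40)
  r1 <- vapply(seq_len(nrow(sp)), function(i)
    rrpOfSpot(sp$x[i], sp$y[i], e1), numeric(1))

  # 2x nearest-neighbour upscale changes each rrp by <= 0.02
  big <- m[rep(seq_len(nrow(m)), each = 2), rep(seq_len(ncol(m)), each = 2)]
  e2 <- computeEDT(big)
  r2 <- vapply(seq_len(nrow(sp)), function(i)
    rrpOfSpot(2 * sp$x[i] - 0.5, 2 * sp$y[i] - 0.5, e2), numeric(1))
  expect_lt(max(abs(r1 - r2)), 0.02)

  # 90-degree rotation leaves the rrp multiset unchanged exactly
  rot <- t(m)[, rev(seq_len(nrow(m)))]
  e3 <- computeEDT(rot)
  nr <- nrow(m)
  r3 <- vapply(seq_len(nrow(sp)), function(i)
    rrpOfSpot(nr + 1 - sp$y[i], sp$x[i], e3), numeric(1))
  expect_equal(sort(r3), sort(r1))
})

test_that("spot detection finds rendered spots and resists pure noise", {
  set.seed(23)
  m <- generateNucleusMask(nucleusShapeParams(meanRadius = 20))

  # noise-free single spot: exactly one detection within 1 px of truth
  sp <- placeSpots(m, radialModel("beta", 2, 2), copyNumber = 1)
  ch <- renderChannel(dim(m), sp, noiseSd = 0)
  det <- detectSpots(ch, m)
  expect_equal(nrow(det), 1L)
  expect_lte(sqrt((det$x - sp$x)^2 + (det$y - sp$y)^2), 1)

  # two well-separated noisy spots (noise = peak/10): both recovered
  repeat {
    sp2 <- placeSpots(m, radialModel("beta", 2, 2), copyNumber = 2)
    if (min(dist(sp2[, c("x", "y")])) > 10) break
  }
  ch2 <- renderChannel(dim(m), sp2, noiseSd = 5, peak = 50)
  det2 <- detectSpots(ch2, m)
  expect_equal(nrow(det2), 2L)
  for (i in 1:2)
    expect_lte(min(sqrt((det2$x - sp2$x[i])^2 + (det2$y - sp2$y[i])^2)), 1)

  # pure-noise nuclei: false-positive rate below 5%
  set.seed(24)
  fp <- 0L
  for (i in 1:200) {
    mm <- generateNucleusMask(nucleusShapeParams())
    nn <- renderChannel(dim(mm), NULL, noiseSd = 5)
    if (nrow(detectSpots(nn, mm)) > 0) fp <- fp + 1L
  }
  expect_lt(fp / 200, 0.05)
})

test_that("mapTissue measures a simulated tissue and excludes border nuclei", {
  sim <- simulateTissue(simTissueConfig(nNuclei = 30, canvasSize = c(520, 520),
                                        noiseSd = 0, rngSeed = 31))
  rec <- mapTissue(labelMask(sim), sim@channels, tissueId = "S1")
  expect_equal(attr(rec, "nNucleiUsed"), 30L)
  # copy number 2 everywhere: close to 60 records (spot merging tolerated)
  expect_gte(nrow(rec), 0.85 * 60)
  expect_lte(nrow(rec), 60)
  expect_true(all(rec$rrp >= 0 & rec$rrp <= 1))

  # truth recovery on the matched alleles
  errs <- truthErrors(rec, truthTable(sim))
  expect_gte(mean(errs <= 0.05), 0.95)

  expect_error(mapTissue(labelMask(sim), list(sim@channels[[1]])), "named")

  # a mask whose only nucleus touches the border yields an empty table
  lone <- matrix(0L, 30, 30); lone[1:10, 5:15] <- 1L
  expect_warning(empty <- mapTissue(lone, list(G = matrix(0, 30, 30))),
                 "border")
  expect_equal(nrow(empty), 0L)
})

test_that("mapSpotTable bypasses detection with identical normalization", {
  sim <- simulateTissue(simTissueConfig(nNuclei = 10, canvasSize = c(350, 350),
                                        rngSeed = 33))
  tr <- truthTable(sim)
  rec <- suppressWarnings(
    mapSpotTable(tr[, c("gene", "x", "y")], labelMask(sim), tissueId = "S"))
  expect_equal(nrow(rec), nrow(tr))
  expect_equal(rec$rrp, tr$realized_rrp, tolerance = 1e-8)
})
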