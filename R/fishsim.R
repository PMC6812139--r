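#' Construct a radial positioning model
#'
#' @param family `"beta"`, `"uniform"` or `"point_mass"`.
#' @param shape1,shape2 beta shape parameters (family `"beta"`).
#' @param at fixed RRP in \[0, 1\] (family `"point_mass"`).
#' @return a [RadialModel-class].
#' @examples
#' radialModel("beta", 2, 5)      # periphery-shifted
#' radialModel("point_mass", at = 1)  # nuclear center
#' @export
radialModel <- function(family = c("beta", "uniform", "point_mass"),
                        shape1 = NULL, shape2 = NULL, at = NULL) {
  family <- match.arg(family)
  params <- switch(family,
    beta = {
      if (is.null(shape1) || is.null(shape2))
        stop("beta family needs shape1 and shape2")
      c(shape1 = shape1, shape2 = shape2)
    },
    uniform = numeric(0),
    point_mass = {
      if (is.null(at)) stop("point_mass family needs 'at'")
      c(at = at)
    })
  new("RadialModel", family = family, params = params)
}

#' @rdname sampleRRP
setMethod("sampleRRP", "RadialModel", function(model, n) {
  switch(model@family,
    beta = rbeta(n, model@params[["shape1"]], model@params[["shape2"]]),
    uniform = runif(n),
    point_mass = rep(model@params[["at"]], n))
})

#' Nucleus shape parameters for the simulator
#'
#' Parameters of the star-shaped nucleus model used by
#' [generateNucleusMask()]: an ellipse of geometric mean radius
#' `meanRadius` (axis ratio set by the sampled eccentricity) whose boundary
#' radius is modulated by low-order random harmonics ("wobble") to emulate the
#' irregular but convex-ish outlines of epithelial nuclei.
#'
#' @param meanRadius mean geometric radius in pixels (must be >= 5).
#' @param radiusCV coefficient of variation of the per-nucleus radius.
#' @param eccentricityRange range \[lo, hi) in \[0, 1) the per-nucleus
#'   eccentricity is drawn from.
#' @param wobbleAmp total boundary modulation as a fraction of the radius;
#'   must be < 0.5 so masks stay simply connected.
#' @param wobbleOrder number of harmonics in the boundary modulation.
#' @return a validated list of class `"NucleusShapeParams"`.
#' @examples
#' nucleusShapeParams(meanRadius = 20)
#' @export
nucleusShapeParams <- function(meanRadius = 20, radiusCV = 0.15,
                               eccentricityRange = c(0, 0.6),
                               wobbleAmp = 0.08, wobbleOrder = 6L) {
  if (meanRadius < 5)
    stop("meanRadius must be at least 5 px (degenerate nucleus)")
  if (radiusCV < 0) stop("radiusCV must be non-negative")
  if (length(eccentricityRange) != 2L || any(eccentricityRange < 0) ||
      any(eccentricityRange >= 1) ||
      eccentricityRange[1] > eccentricityRange[2])
    stop("eccentricityRange must be an increasing pair within [0, 1)")
  if (wobbleAmp < 0 || wobbleAmp >= 0.5)
    stop("wobbleAmp must be in [0, 0.5) to keep masks simply connected")
  structure(list(meanRadius = meanRadius, radiusCV = radiusCV,
                 eccentricityRange = eccentricityRange,
                 wobbleAmp = wobbleAmp, wobbleOrder = as.integer(wobbleOrder)),
            class = "NucleusShapeParams")
}

#' Generate one synthetic nucleus mask
#'
#' Draws a nucleus from the shape model and rasterizes it as a binary matrix.
#' The nucleus is star-shaped (its boundary is a single-valued function of the
#' polar angle), hence simply connected, and is padded so that the foreground
#' never touches the matrix border. Uses the current RNG state; seed with
#' `set.seed()` for reproducibility.
#'
#' @param shape a [nucleusShapeParams()] object.
#' @return binary integer matrix (1 = nucleus) with a background margin.
#' @examples
#' set.seed(7)
#' m <- generateNucleusMask(nucleusShapeParams(meanRadius = 12))
#' sum(m) / (pi * 12^2)  # area close to the disc area
#' @export
generateNucleusMask <- function(shape = nucleusShapeParams()) {
  if (!inherits(shape, "NucleusShapeParams"))
    stop("shape must be created by nucleusShapeParams()")
  r0 <- max(5, rnorm(1, shape$meanRadius, shape$radiusCV * shape$meanRadius))
  ecc <- runif(1, shape$eccentricityRange[1], shape$eccentricityRange[2])
  theta <- runif(1, 0, pi)
  # semi-axes with geometric mean r0 and major/minor ratio 1/sqrt(1 - e^2)
  stretch <- (1 - ecc^2)^(-1 / 4)
  a <- r0 * stretch
  b <- r0 / stretch
  k <- seq_len(shape$wobbleOrder)
  amp <- if (shape$wobbleAmp > 0 && shape$wobbleOrder > 0) {
    z <- rnorm(shape$wobbleOrder)
    z / sqrt(sum(z^2)) * shape$wobbleAmp
  } else numeric(shape$wobbleOrder)
  phase <- runif(shape$wobbleOrder, 0, 2 * pi)

  half <- ceiling(a * (1 + shape$wobbleAmp)) + 2L
  n <- 2L * half + 1L
  ctr <- half + 1L
  xx <- matrix(rep(seq_len(n) - ctr, each = n), n, n)   # col offsets
  yy <- matrix(rep(seq_len(n) - ctr, times = n), n, n)  # row offsets
  # rotate into the ellipse frame
  u <- cos(theta) * xx + sin(theta) * yy
  v <- -sin(theta) * xx + cos(theta) * yy
  rho <- sqrt((u / a)^2 + (v / b)^2)        # 1 on the unwobbled boundary
  phi <- atan2(v / b, u / a)
  mod <- matrix(1, n, n)
  for (i in k)
    mod <- mod + amp[i] * cos(i * phi + phase[i])
  mask <- matrix(as.integer(rho <= mod), n, n)
  mask
}

#' Place FISH alleles at target radial positions on a mask
#'
#' For each allele a target RRP is drawn from `model`, and a pixel is chosen
#' uniformly among the foreground pixels whose normalized EDT lies within
#' `tol` of the target; when no pixel qualifies (targets beyond the
#' attainable pixel grid, e.g. a target of exactly 0 on a mask whose minimum
#' normalized EDT is 1/maxEDT) the placement snaps to the pixels of the
#' nearest attainable EDT level, so extreme targets land on the boundary or
#' EDT-maximum pixels rather than in a widened band. The spot center is the
#' chosen pixel center, and the realized RRP (the pixel's normalized EDT) is
#' recorded alongside the target.
#'
#' @param mask binary nucleus mask (single foreground component).
#' @param model a [RadialModel-class] for the target RRPs.
#' @param copyNumber number of alleles to place (>= 1).
#' @param tol initial normalized-EDT matching tolerance.
#' @return data.frame with columns `x`, `y` (1-based col/row pixel centers),
#'   `target_rrp`, `realized_rrp`.
#' @examples
#' set.seed(1)
#' m <- generateNucleusMask(nucleusShapeParams(meanRadius = 15, wobbleAmp = 0))
#' placeSpots(m, radialModel("point_mass", at = 1), copyNumber = 2)
#' @export
placeSpots <- function(mask, model, copyNumber = 2L, tol = 0.02) {
  if (!any(mask > 0)) stop("mask is empty")
  if (copyNumber < 1L) stop("copyNumber must be >= 1")
  edt <- computeEDT(mask)
  maxEdt <- max(edt)
  fg <- which(mask > 0)
  nedt <- edt[fg] / maxEdt
  targets <- sampleRRP(model, copyNumber)
  idx <- vapply(targets, function(t) {
    hit <- which(abs(nedt - t) <= tol)
    if (!length(hit))
      hit <- which(abs(nedt - t) <= min(abs(nedt - t)) + 1e-12)
    hit[sample.int(length(hit), 1L)]
  }, integer(1))
  pix <- fg[idx]
  nr <- nrow(mask)
  data.frame(x = ((pix - 1L) %/% nr) + 1L,
             y = ((pix - 1L) %% nr) + 1L,
             target_rrp = targets,
             realized_rrp = nedt[idx])
}

#' Render a FISH intensity channel from spot positions
#'
#' Each spot contributes an isotropic 2D Gaussian blob; Gaussian background
#' noise is added and the image is clipped at zero. Peak amplitude defaults to
#' ten times the noise standard deviation (or 100 for noise-free renders).
#'
#' @param dim image dimensions `c(nrow, ncol)`.
#' @param spots data.frame with columns `x`, `y` (may be empty).
#' @param psfSigma Gaussian sigma of the emulated point-spread function in
#'   pixels (>= 0.5).
#' @param noiseSd standard deviation of the additive background noise.
#' @param peak peak amplitude of each blob.
#' @return numeric intensity matrix.
#' @examples
#' img <- renderChannel(c(32, 32), data.frame(x = 16, y = 16), noiseSd = 0)
#' which(img == max(img), arr.ind = TRUE)
#' @export
renderChannel <- function(dim, spots, psfSigma = 1.5, noiseSd = 5,
                          peak = if (noiseSd > 0) 10 * noiseSd else 100) {
  if (psfSigma < 0.5) stop("psfSigma must be at least 0.5 px")
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  img <- matrix(0, dim[1], dim[2])
  if (!is.null(spots) && nrow(spots)) {
    w <- ceiling(5 * psfSigma)
    for (i in seq_len(nrow(spots))) {
      x0 <- spots$x[i]; y0 <- spots$y[i]
      rows <- max(1L, floor(y0) - w):min(dim[1], ceiling(y0) + w)
      cols <- max(1L, floor(x0) - w):min(dim[2], ceiling(x0) + w)
      blob <- peak *
        exp(-outer((rows - y0)^2, (cols - x0)^2, "+") / (2 * psfSigma^2))
      img[rows, cols] <- img[rows, cols] + blob
    }
  }
  if (noiseSd > 0)
    img <- img + matrix(rnorm(length(img), 0, noiseSd), dim[1], dim[2])
  pmax(img, 0)
}

#' Simulated tissue configuration
#'
#' Bundles everything [simulateTissue()] needs: the number of nuclei (default
#' 120, a typical per-tissue analysis count for FFPE epithelial nuclei), the
#' genes with their radial models and allele copy-number distributions, the
#' canvas, the imaging emulation parameters and the RNG seed.
#'
#' @param nNuclei number of nuclei to place (>= 1).
#' @param genes named list; each element is a list with components `model`
#'   (a [RadialModel-class]) and optionally `copyProb` (probabilities over
#'   copy numbers 1-4; default a point mass on 2 alleles).
#' @param canvasSize canvas `c(nrow, ncol)` in pixels.
#' @param shape a [nucleusShapeParams()] object.
#' @param psfSigma,noiseSd,peak passed to [renderChannel()].
#' @param rngSeed integer seed; all simulator randomness flows from it.
#' @param maxAttempts placement attempts per nucleus before giving up.
#' @return a validated list of class `"SimTissueConfig"`.
#' @examples
#' simTissueConfig(nNuclei = 10, canvasSize = c(300, 300))
#' @export
simTissueConfig <- function(nNuclei = 120L,
                            genes = list(GENE = list(
                              model = radialModel("beta", 2, 2))),
                            canvasSize = c(1200L, 1200L),
                            shape = nucleusShapeParams(),
                            psfSigma = 1.5, noiseSd = 5,
                            peak = if (noiseSd > 0) 10 * noiseSd else 100,
                            rngSeed = 1L, maxAttempts = 200L) {
  if (nNuclei < 1L) stop("nNuclei must be >= 1")
  if (is.null(names(genes)) || any(!nzchar(names(genes))))
    stop("genes must be a named list")
  genes <- lapply(genes, function(g) {
    if (!is(g$model, "RadialModel"))
      stop("each gene needs a RadialModel in $model")
    if (is.null(g$copyProb)) g$copyProb <- c(0, 1, 0, 0)
    if (length(g$copyProb) != 4L || any(g$copyProb < 0) ||
        abs(sum(g$copyProb) - 1) > 1e-8)
      stop("copyProb must be 4 probabilities over copy numbers 1-4 summing to 1")
    g
  })
  structure(list(nNuclei = as.integer(nNuclei), genes = genes,
                 canvasSize = as.integer(canvasSize), shape = shape,
                 psfSigma = psfSigma, noiseSd = noiseSd, peak = peak,
                 rngSeed = as.integer(rngSeed),
                 maxAttempts = as.integer(maxAttempts)),
            class = "SimTissueConfig")
}

#' Simulate a labeled tissue image with FISH channels
#'
#' Places non-overlapping nuclei on the canvas by rejection sampling, draws
#' per-nucleus allele copy numbers and target RRPs for every gene, renders one
#' intensity channel per gene, and records the ground truth of every placed
#' spot. Fully deterministic given `config$rngSeed`.
#'
#' @param config a [simTissueConfig()] object.
#' @return a [SimTissue-class].
#' @examples
#' sim <- simulateTissue(simTissueConfig(nNuclei = 5, canvasSize = c(250, 250),
#'                                       rngSeed = 42))
#' sim
#' @export
simulateTissue <- function(config) {
  if (!inherits(config, "SimTissueConfig"))
    stop("config must be created by simTissueConfig()")
  set.seed(config$rngSeed)
  nr <- config$canvasSize[1]; nc <- config$canvasSize[2]
  labels <- matrix(0L, nr, nc)
  placed <- 0L
  for (i in seq_len(config$nNuclei)) {
    ok <- FALSE
    for (att in seq_len(config$maxAttempts)) {
      m <- generateNucleusMask(config$shape)
      mh <- nrow(m); mw <- ncol(m)
      if (mh + 2L > nr || mw + 2L > nc) next
      r0 <- sample.int(nr - mh - 1L, 1L) + 1L
      c0 <- sample.int(nc - mw - 1L, 1L) + 1L
      rows <- r0:(r0 + mh - 1L); cols <- c0:(c0 + mw - 1L)
      # 1-px clearance: candidate pixels plus their neighborhood must be free
      rpad <- max(1L, r0 - 1L):min(nr, r0 + mh)
      cpad <- max(1L, c0 - 1L):min(nc, c0 + mw)
      if (any(labels[rpad, cpad] > 0L)) next
      labels[rows, cols][m > 0] <- i
      placed <- placed + 1L
      ok <- TRUE
      break
    }
    if (!ok)
      stop("could only place ", placed, " of ", config$nNuclei,
           " nuclei; enlarge the canvas or reduce nNuclei")
  }

  truth <- vector("list", config$nNuclei * length(config$genes))
  ti <- 0L
  spotsByGene <- lapply(config$genes, function(g) NULL)
  for (i in seq_len(config$nNuclei)) {
    sub <- extractNucleus(labels, i)
    for (gn in names(config$genes)) {
      g <- config$genes[[gn]]
      cn <- sample.int(4L, 1L, prob = g$copyProb)
      sp <- placeSpots(sub$mask, g$model, cn)
      sp$x <- sp$x + sub$offset[2]; sp$y <- sp$y + sub$offset[1]
      ti <- ti + 1L
      truth[[ti]] <- data.frame(nucleus_id = i, gene = gn, sp[, c("x", "y")],
                                target_rrp = sp$target_rrp,
                                realized_rrp = sp$realized_rrp)
      spotsByGene[[gn]] <- rbind(spotsByGene[[gn]], sp[, c("x", "y")])
    }
  }
  truth <- do.call(rbind, truth[seq_len(ti)])
  channels <- lapply(spotsByGene, function(sp)
    renderChannel(config$canvasSize, sp, config$psfSigma, config$noiseSd,
                  config$peak))
  new("SimTissue", labelMask = labels, channels = channels,
      truth = truth, config = unclass(config))
}

# bounding-box extraction of one labeled nucleus, padded by one background px;
# offset maps sub-image (row, col) back to canvas coordinates
extractNucleus <- function(labels, lab) {
  hit <- which(labels == lab, arr.ind = TRUE)
  if (!nrow(hit)) stop("label ", lab, " not present")
  r1 <- max(1L, min(hit[, 1]) - 1L); r2 <- min(nrow(labels), max(hit[, 1]) + 1L)
  c1 <- max(1L, min(hit[, 2]) - 1L); c2 <- min(ncol(labels), max(hit[, 2]) + 1L)
  sub <- labels[r1:r2, c1:c2, drop = FALSE]
  list(mask = matrix(as.integer(sub == lab), nrow(sub), ncol(sub)),
       offset = c(r1 - 1L, c1 - 1L),
       bbox = c(r1, r2, c1, c2))
}
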