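#' Euclidean distance transform of a nucleus mask
#'
#' Assigns every foreground pixel its exact Euclidean distance (in isotropic
#' pixel units) to the nearest background pixel of the image; background
#' pixels hold 0. Distances are measured to background pixels present in the
#' matrix -- there is no implicit background outside the borders, so masks
#' whose foreground touches the border should be padded (or excluded, as
#' [mapTissue()] does for border nuclei).
#'
#' @param mask binary matrix (> 0 = foreground).
#' @param single if `TRUE` (default), require exactly one foreground
#'   component (8-connectivity) and error otherwise; set to `FALSE` for
#'   arbitrary masks.
#' @return numeric matrix of distances with `max` attained inside the mask.
#' @examples
#' m <- matrix(0, 5, 5); m[2:4, 2:4] <- 1
#' computeEDT(m)  # edge pixels 1, center 2
#' @export
computeEDT <- function(mask, single = TRUE) {
  if (!any(mask > 0)) stop("mask is empty")
  if (!any(mask == 0)) stop("mask has no background pixels")
  m <- matrix(as.numeric(mask > 0), nrow(mask), ncol(mask))
  if (single) {
    ncomp <- max(EBImage::bwlabel(m))
    if (ncomp != 1L)
      stop("mask has ", ncomp, " foreground components; expected exactly 1")
  }
  d <- EBImage::distmap(m, metric = "euclidean")
  matrix(as.numeric(d), nrow(mask), ncol(mask))
}

#' Spot detection parameters
#'
#' @param tophatRadius radius in pixels of the disc structuring element for
#'   the white top-hat background suppression.
#' @param minArea minimum connected-component area in pixels for a detection
#'   (>= 1).
#' @param noiseFloorSigmas the binarization threshold is never below this
#'   multiple of the robust background spread (MAD) of the in-nucleus raw
#'   intensities; keeps the Otsu split from chasing noise texture in nuclei
#'   that carry no signal. Set to 0 to disable.
#' @return a validated list of class `"SpotParams"`.
#' @examples
#' spotParams(tophatRadius = 5, minArea = 4)
#' @export
spotParams <- function(tophatRadius = 5L, minArea = 4L,
                       noiseFloorSigmas = 3) {
  if (minArea < 1L) stop("minArea must be >= 1")
  if (tophatRadius < 1L) stop("tophatRadius must be >= 1")
  if (noiseFloorSigmas < 0) stop("noiseFloorSigmas must be non-negative")
  structure(list(tophatRadius = as.integer(tophatRadius),
                 minArea = as.integer(minArea),
                 noiseFloorSigmas = noiseFloorSigmas),
            class = "SpotParams")
}

# Otsu threshold of a value vector (between-class variance maximization on a
# fixed-bin histogram). EBImage's otsu() operates on whole images; spot
# detection thresholds only the in-nucleus top-hat intensities, so the
# histogram must be restricted to a pixel subset.
otsuLevel <- function(v, levels = 256L) {
  rng <- range(v)
  if (diff(rng) == 0) return(Inf)  # flat image: nothing above threshold
  h <- tabulate(pmin(levels, 1L + floor((v - rng[1]) / diff(rng) * levels)),
                nbins = levels)
  w <- cumsum(h)
  mu <- cumsum(h * seq_len(levels))
  muT <- mu[levels]
  n <- w[levels]
  between <- (muT * w - mu * n)^2 / (w * (n - w))
  between[!is.finite(between)] <- -Inf
  k <- which.max(between)
  rng[1] + k / levels * diff(rng)
}

#' Detect FISH spots within one nucleus
#'
#' White top-hat filtering (disc of radius `params$tophatRadius`) suppresses
#' smooth background, an Otsu threshold computed on the in-nucleus enhanced
#' intensities binarizes the signal (floored at `noiseFloorSigmas` background
#' MADs so signal-free nuclei do not yield noise detections), and connected
#' components with area >= `params$minArea` are reported by the unweighted
#' geometric centroid of their pixels. Zero detections is a valid result.
#'
#' @param channel intensity matrix, same geometry as `mask`.
#' @param mask binary nucleus mask.
#' @param params a [spotParams()] object.
#' @return data.frame with columns `x`, `y` (sub-pixel centroids, 1-based
#'   col/row) and `area`; zero rows when nothing is detected.
#' @export
detectSpots <- function(channel, mask, params = spotParams()) {
  if (!identical(dim(channel), dim(mask)))
    stop("channel and mask geometries differ")
  brush <- EBImage::makeBrush(2L * params$tophatRadius + 1L, shape = "disc")
  th <- EBImage::whiteTopHat(channel, brush)
  inside <- mask > 0
  # robust background sd; quartile-based so zero-clipped noise is handled
  q <- quantile(channel[inside], c(0.5, 0.75), names = FALSE)
  sigma <- (q[2] - q[1]) / 0.6744898
  level <- max(otsuLevel(th[inside]), params$noiseFloorSigmas * sigma)
  bin <- matrix(0L, nrow(mask), ncol(mask))
  bin[inside & th > level] <- 1L
  if (!any(bin > 0))
    return(data.frame(x = numeric(0), y = numeric(0), area = integer(0)))
  lab <- EBImage::bwlabel(bin)
  pix <- which(lab > 0)
  comp <- as.integer(lab[pix])
  nr <- nrow(mask)
  rows <- ((pix - 1L) %% nr) + 1L
  cols <- ((pix - 1L) %/% nr) + 1L
  area <- tabulate(comp)
  keep <- which(area >= params$minArea)
  if (!length(keep))
    return(data.frame(x = numeric(0), y = numeric(0), area = integer(0)))
  cx <- vapply(keep, function(k) mean(cols[comp == k]), numeric(1))
  cy <- vapply(keep, function(k) mean(rows[comp == k]), numeric(1))
  data.frame(x = cx, y = cy, area = area[keep])
}

#' Normalized radial position of a spot
#'
#' The EDT at the sub-pixel spot center is obtained by bilinear interpolation
#' of the nucleus EDT map and divided by the maximal nuclear EDT, giving the
#' relative radial position (RRP): 0 at the nuclear periphery, 1 at the EDT
#' maximum. Values are clamped to \[0, 1\].
#'
#' @param x,y sub-pixel center (1-based col/row pixel-center convention).
#' @param edt EDT matrix from [computeEDT()].
#' @param maxEdt maximal EDT of the nucleus (defaults to `max(edt)`).
#' @return the RRP, or `NA` (with a warning) when the center lies outside
#'   the mask support of the EDT.
#' @examples
#' m <- matrix(0, 21, 21); m[2:20, 2:20] <- 1
#' e <- computeEDT(m)
#' rrpOfSpot(11, 11, e)  # center pixel -> 1
#' @export
rrpOfSpot <- function(x, y, edt, maxEdt = max(edt)) {
  nr <- nrow(edt); nc <- ncol(edt)
  if (x < 1 || x > nc || y < 1 || y > nr) {
    warning("spot center (", x, ", ", y, ") outside the image; skipped")
    return(NA_real_)
  }
  x0 <- floor(x); y0 <- floor(y)
  x1 <- min(x0 + 1L, nc); y1 <- min(y0 + 1L, nr)
  fx <- x - x0; fy <- y - y0
  val <- (1 - fx) * (1 - fy) * edt[y0, x0] + fx * (1 - fy) * edt[y0, x1] +
         (1 - fx) * fy * edt[y1, x0] + fx * fy * edt[y1, x1]
  if (edt[round(y), round(x)] == 0) {
    warning("spot center (", x, ", ", y, ") outside the nucleus mask; skipped")
    return(NA_real_)
  }
  min(1, max(0, val / maxEdt))
}

#' Split a label mask into per-nucleus regions
#'
#' Extracts each labeled nucleus with a one-pixel background pad, computes
#' its EDT and maximal EDT, and flags nuclei touching the image border
#' (their EDT would be truncated, biasing the normalization).
#'
#' @param labels integer label matrix (0 = background).
#' @return named list of regions, each a list with `label`, `mask`, `edt`,
#'   `maxEdt`, `offset` (row/col offset of the sub-image), and
#'   `borderTouching`.
#' @export
nucleusRegions <- function(labels) {
  labs <- sort(unique(as.integer(labels[labels > 0])))
  if (!length(labs)) stop("label mask contains no nuclei")
  nr <- nrow(labels); nc <- ncol(labels)
  out <- lapply(labs, function(lab) {
    sub <- extractNucleus(labels, lab)
    border <- any(which(labels == lab, arr.ind = TRUE)[, 1] %in% c(1L, nr)) ||
      any(which(labels == lab, arr.ind = TRUE)[, 2] %in% c(1L, nc))
    if (border)
      return(list(label = lab, borderTouching = TRUE))
    edt <- computeEDT(sub$mask)
    list(label = lab, mask = sub$mask, edt = edt, maxEdt = max(edt),
         offset = sub$offset, borderTouching = FALSE)
  })
  names(out) <- paste0("nucleus_", labs)
  out
}

#' Map a tissue image to per-allele radial positions
#'
#' The core measurement: iterates the segmented nuclei of a label mask,
#' detects FISH spots per gene channel within each nucleus, and converts each
#' spot to an [RRD-class]-ready allele record with its normalized radial
#' position. Nuclei touching the image border are excluded. All detected
#' alleles of a nucleus are included, regardless of copy number.
#'
#' @param labels integer label mask.
#' @param channels named list of intensity matrices, one per gene.
#' @param params a [spotParams()] object.
#' @param tissueId tissue identifier recorded in the output.
#' @return data.frame with columns `tissue_id`, `gene`, `nucleus_id`, `x`,
#'   `y`, `edt_at_spot`, `max_edt`, `rrp`; the number of non-border nuclei
#'   analyzed is attached as attribute `"nNucleiUsed"`.
#' @export
mapTissue <- function(labels, channels, params = spotParams(),
                      tissueId = "tissue") {
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("channels must be a named list (gene = intensity matrix)")
  regions <- nucleusRegions(labels)
  used <- Filter(function(r) !r$borderTouching, regions)
  if (!length(used)) {
    warning("no nuclei left after border exclusion; empty record table")
    empty <- data.frame(tissue_id = character(0), gene = character(0),
                        nucleus_id = integer(0), x = numeric(0), y = numeric(0),
                        edt_at_spot = numeric(0), max_edt = numeric(0),
                        rrp = numeric(0))
    attr(empty, "nNucleiUsed") <- 0L
    return(empty)
  }
  rec <- list()
  for (r in used) {
    rr <- r$offset[1] + seq_len(nrow(r$mask))
    cc <- r$offset[2] + seq_len(ncol(r$mask))
    for (gn in names(channels)) {
      ch <- channels[[gn]]
      if (!identical(dim(ch), dim(labels)))
        stop("channel '", gn, "' geometry differs from the label mask")
      sp <- detectSpots(ch[rr, cc, drop = FALSE], r$mask, params)
      if (!nrow(sp)) next
      rrp <- vapply(seq_len(nrow(sp)), function(i)
        rrpOfSpot(sp$x[i], sp$y[i], r$edt, r$maxEdt), numeric(1))
      keep <- !is.na(rrp)
      if (!any(keep)) next
      rec[[length(rec) + 1L]] <- data.frame(
        tissue_id = tissueId, gene = gn, nucleus_id = r$label,
        x = sp$x[keep] + r$offset[2], y = sp$y[keep] + r$offset[1],
        edt_at_spot = rrp[keep] * r$maxEdt, max_edt = r$maxEdt,
        rrp = rrp[keep])
    }
  }
  out <- if (length(rec)) do.call(rbind, rec) else {
    warning("no spots detected in any nucleus")
    data.frame(tissue_id = character(0), gene = character(0),
               nucleus_id = integer(0), x = numeric(0), y = numeric(0),
               edt_at_spot = numeric(0), max_edt = numeric(0), rrp = numeric(0))
  }
  rownames(out) <- NULL
  attr(out, "nNucleiUsed") <- length(used)
  out
}

#' Radial positions for pre-detected spot coordinates
#'
#' Bypasses spot detection: assigns externally supplied spot centers to
#' nuclei of a label mask and computes their RRPs. Spots falling on
#' background or in border-touching nuclei are dropped with a warning.
#'
#' @param spotTable data.frame with columns `gene`, `x`, `y` (1-based
#'   col/row sub-pixel centers).
#' @param labels integer label mask.
#' @param tissueId tissue identifier for the output records.
#' @return allele record data.frame as in [mapTissue()].
#' @export
mapSpotTable <- function(spotTable, labels, tissueId = "tissue") {
  need <- c("gene", "x", "y")
  if (!all(need %in% names(spotTable)))
    stop("spotTable must have columns: ", paste(need, collapse = ", "))
  regions <- nucleusRegions(labels)
  rec <- list()
  dropped <- 0L
  for (i in seq_len(nrow(spotTable))) {
    x <- spotTable$x[i]; y <- spotTable$y[i]
    lab <- labels[round(y), round(x)]
    if (lab == 0L) { dropped <- dropped + 1L; next }
    r <- regions[[paste0("nucleus_", lab)]]
    if (r$borderTouching) { dropped <- dropped + 1L; next }
    rrp <- suppressWarnings(
      rrpOfSpot(x - r$offset[2], y - r$offset[1], r$edt, r$maxEdt))
    if (is.na(rrp)) { dropped <- dropped + 1L; next }
    rec[[length(rec) + 1L]] <- data.frame(
      tissue_id = tissueId, gene = spotTable$gene[i],
      nucleus_id = r$label, x = x, y = y,
      edt_at_spot = rrp * r$maxEdt, max_edt = r$maxEdt, rrp = rrp)
  }
  if (dropped)
    warning(dropped, " spot(s) outside usable nuclei were skipped")
  out <- if (length(rec)) do.call(rbind, rec) else
    data.frame(tissue_id = character(0), gene = character(0),
               nucleus_id = integer(0), x = numeric(0), y = numeric(0),
               edt_at_spot = numeric(0), max_edt = numeric(0), rrp = numeric(0))
  rownames(out) <- NULL
  attr(out, "nNucleiUsed") <- sum(!vapply(regions, `[[`, TRUE, "borderTouching"))
  out
}
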