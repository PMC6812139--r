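#' Build a relative radial distribution (RRD)
#'
#' Pools every detected allele of every nucleus of one gene in one tissue
#' into a single RRP value set -- no per-nucleus averaging, and nuclei with
#' 1, 2, 3 or 4 detected alleles all contribute every allele. A warning is
#' emitted when fewer than `minNuclei` nuclei support the distribution
#' (sparse RRDs make the KS comparison fragile); the analysis proceeds.
#'
#' @param records allele record data.frame from [mapTissue()] (columns
#'   `tissue_id`, `gene`, `nucleus_id`, `rrp`).
#' @param gene,tissueId which records to pool.
#' @param minNuclei nucleus-count warning threshold (default 88).
#' @return an [RRD-class].
#' @export
buildRRD <- function(records, gene, tissueId, minNuclei = 88L) {
  sel <- records$gene == gene & records$tissue_id == tissueId
  if (!any(sel))
    stop("no allele records for gene '", gene, "' in tissue '", tissueId, "'")
  v <- records$rrp[sel]
  if (any(is.na(v)) || any(v < 0 | v > 1))
    stop("rrp values must lie in [0, 1] with no NAs")
  nn <- length(unique(records$nucleus_id[sel]))
  if (nn < minNuclei)
    warning("RRD for ", gene, " in ", tissueId, " built from only ", nn,
            " nuclei (< ", minNuclei, ")")
  new("RRD", gene = gene, tissueId = tissueId, values = as.numeric(v),
      nNuclei = as.integer(nn), nAlleles = length(v))
}

#' Build a pooled normal distribution (PND)
#'
#' Concatenates the RRDs of one gene across normal tissues into the pooled
#' reference distribution. Order-independent up to value order; allele and
#' nucleus counts are conserved exactly.
#'
#' @param rrds list of [RRD-class] objects of the same gene (>= 2).
#' @return a [PND-class].
#' @export
buildPND <- function(rrds) {
  if (length(rrds) < 2L) stop("a PND needs at least two source RRDs")
  if (!all(vapply(rrds, is, TRUE, "RRD")))
    stop("all inputs must be RRD objects")
  genes <- unique(vapply(rrds, geneName, character(1)))
  if (length(genes) != 1L)
    stop("cannot pool mixed genes into one PND: ",
         paste(genes, collapse = ", "))
  new("PND", gene = genes,
      sourceTissues = vapply(rrds, tissueName, character(1)),
      values = unlist(lapply(rrds, rrpValues), use.names = FALSE),
      nNuclei = sum(vapply(rrds, nNuclei, integer(1))))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs; the p-value
#' comes from the asymptotic two-sample Kolmogorov distribution with
#' effective sample size n_a n_b / (n_a + n_b), or from the exact Smirnov
#' distribution for small samples (`"auto"` switches to exact below a
#' combined n of 50). Symmetric in its arguments.
#'
#' @param a,b numeric samples (non-empty).
#' @param exact `"auto"`, `"never"` or `"always"`.
#' @return list with elements `D` and `p`.
#' @examples
#' ksTwoSample(c(0.1, 0.2, 0.3), c(0.6, 0.7, 0.8))$D  # disjoint supports: 1
#' @export
ksTwoSample <- function(a, b, exact = c("auto", "never", "always")) {
  exact <- match.arg(exact)
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  useExact <- switch(exact, auto = (length(a) + length(b)) < 50L,
                     never = FALSE, always = TRUE)
  ht <- suppressWarnings(stats::ks.test(a, b, exact = useExact))
  list(D = unname(ht$statistic), p = ht$p.value)
}

#' Call directional repositioning of a tissue RRD against a reference
#'
#' Compares the RRD with the reference (usually the gene's PND) by the
#' two-sample KS test; the comparison is significant iff `p < alpha`
#' (strict). Significant shifts are labeled `"I"` (more internal) when the
#' RRD median RRP exceeds the reference median, `"P"` (more peripheral) when
#' below; an exact median tie falls back to the mean difference. Both
#' statistics are recorded in the result.
#'
#' @param rrd an [RRD-class].
#' @param reference a [PND-class], [RRD-class] or numeric RRP vector.
#' @param alpha significance level (default 0.01).
#' @param exact passed to [ksTwoSample()].
#' @return a [RepositioningResult-class].
#' @export
callRepositioning <- function(rrd, reference, alpha = 0.01,
                              exact = c("auto", "never", "always")) {
  if (!is(rrd, "RRD")) stop("rrd must be an RRD")
  ref <- if (is.numeric(reference)) reference else rrpValues(reference)
  if (!length(ref)) stop("reference is empty")
  ks <- ksTwoSample(rrpValues(rrd), ref, exact = match.arg(exact))
  medDiff <- median(rrpValues(rrd)) - median(ref)
  meanDiff <- mean(rrpValues(rrd)) - mean(ref)
  sig <- ks$p < alpha
  dir <- if (!sig) "NS"
  else if (medDiff > 0) "I"
  else if (medDiff < 0) "P"
  else if (meanDiff > 0) "I" else "P"
  new("RepositioningResult", gene = geneName(rrd), tissueId = tissueName(rrd),
      ksD = ks$D, pValue = ks$p, alpha = alpha, significant = sig,
      direction = dir, medianDiff = medDiff, meanDiff = meanDiff)
}

#' Pairwise cross-comparison of RRDs
#'
#' KS-tests every unordered pair of tissues for one gene and reports the
#' symmetric p-value and D matrices plus the fraction of significant pairs.
#'
#' @param rrds list of [RRD-class] objects of the same gene (>= 2).
#' @param alpha significance level.
#' @param exact passed to [ksTwoSample()].
#' @return list with `pMatrix`, `dMatrix`, `nPairs`, `nSignificant`,
#'   `fractionSignificant`.
#' @export
crossCompare <- function(rrds, alpha = 0.01,
                         exact = c("auto", "never", "always")) {
  exact <- match.arg(exact)
  if (length(rrds) < 2L) stop("need at least two RRDs")
  genes <- unique(vapply(rrds, geneName, character(1)))
  if (length(genes) != 1L)
    stop("cross-comparison requires a single gene; got: ",
         paste(genes, collapse = ", "))
  ids <- vapply(rrds, tissueName, character(1))
  n <- length(rrds)
  p <- matrix(1, n, n, dimnames = list(ids, ids))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ks <- ksTwoSample(rrpValues(rrds[[i]]), rrpValues(rrds[[j]]), exact)
    p[i, j] <- p[j, i] <- ks$p
    d[i, j] <- d[j, i] <- ks$D
  }
  nPairs <- n * (n - 1L) / 2L
  nSig <- sum(p[upper.tri(p)] < alpha)
  list(pMatrix = p, dMatrix = d, nPairs = nPairs, nSignificant = nSig,
       fractionSignificant = nSig / nPairs)
}

#' Compare every tissue of a cohort against the pooled normal reference
#'
#' Builds per-tissue RRDs for one gene, pools the normal tissues into the
#' PND, and calls repositioning for every assayed tissue. Following the
#' pooled-reference convention, a normal tissue compared against the PND is
#' not removed from it first; set `leaveOneOut = TRUE` to exclude each
#' tissue's own alleles from its reference.
#'
#' @param records allele record data.frame ([mapTissue()] format).
#' @param gene gene to analyze.
#' @param normalTissues ids of the tissues pooled into the PND.
#' @param alpha significance level.
#' @param leaveOneOut drop the compared tissue's own values from the PND.
#' @param minNuclei passed to [buildRRD()].
#' @return data.frame with one row per assayed tissue: `tissue_id`, `gene`,
#'   `n_nuclei`, `n_alleles`, `ks_D`, `p_value`, `call`.
#' @export
compareToPND <- function(records, gene, normalTissues, alpha = 0.01,
                         leaveOneOut = FALSE, minNuclei = 88L) {
  tissues <- unique(records$tissue_id[records$gene == gene])
  if (!length(tissues)) stop("no records for gene '", gene, "'")
  missing <- setdiff(normalTissues, tissues)
  if (length(missing))
    stop("normal tissues with no records for ", gene, ": ",
         paste(missing, collapse = ", "))
  rrds <- lapply(tissues, function(tt)
    buildRRD(records, gene, tt, minNuclei = minNuclei))
  names(rrds) <- tissues
  pnd <- buildPND(rrds[normalTissues])
  rows <- lapply(tissues, function(tt) {
    ref <- if (leaveOneOut && tt %in% normalTissues)
      buildPND(rrds[setdiff(normalTissues, tt)]) else pnd
    res <- callRepositioning(rrds[[tt]], ref, alpha = alpha)
    data.frame(tissue_id = tt, gene = gene,
               n_nuclei = nNuclei(rrds[[tt]]),
               n_alleles = nAlleles(rrds[[tt]]),
               ks_D = res@ksD, p_value = res@pValue, call = res@direction)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cumulative distribution of an RRD on a fixed grid
#'
#' Evaluates the empirical CDF on a regular RRP grid, the form used for
#' cumulative-frequency plots of RRDs against their PND.
#'
#' @param x an [RRD-class], [PND-class] or numeric vector.
#' @param grid RRP evaluation grid.
#' @return data.frame with columns `rrp` and `ecdf`.
#' @export
cumulativeRRD <- function(x, grid = seq(0, 1, by = 0.01)) {
  v <- if (is.numeric(x)) x else rrpValues(x)
  data.frame(rrp = grid, ecdf = ecdf(v)(grid))
}
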