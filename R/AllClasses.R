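#' @import methods
#' @importFrom stats median rnorm runif rbeta ks.test quantile ecdf sd setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

#' Radial positioning model
#'
#' Describes the distribution on \[0, 1\] from which target relative radial
#' positions (RRPs) are drawn when simulating FISH alleles. An RRP of 0 is the
#' nuclear periphery and 1 the nuclear center. Three families are supported:
#' `"beta"` (two strictly positive shape parameters), `"uniform"`, and
#' `"point_mass"` (a single fixed RRP).
#'
#' @slot family character, one of `"beta"`, `"uniform"`, `"point_mass"`.
#' @slot params named numeric vector of family parameters: `shape1`/`shape2`
#'   for `"beta"`, `at` for `"point_mass"`, empty for `"uniform"`.
#'
#' @seealso [radialModel()], [sampleRRP()]
#' @exportClass RadialModel
setClass("RadialModel",
  representation(family = "character", params = "numeric"))

setValidity("RadialModel", function(object) {
  msg <- NULL
  if (length(object@family) != 1L ||
      !object@family %in% c("beta", "uniform", "point_mass"))
    msg <- c(msg, "family must be one of 'beta', 'uniform', 'point_mass'")
  else if (object@family == "beta") {
    if (!all(c("shape1", "shape2") %in% names(object@params)) ||
        any(object@params[c("shape1", "shape2")] <= 0))
      msg <- c(msg, "beta family requires strictly positive shape1 and shape2")
  } else if (object@family == "point_mass") {
    if (!"at" %in% names(object@params) ||
        object@params[["at"]] < 0 || object@params[["at"]] > 1)
      msg <- c(msg, "point_mass requires 'at' in [0, 1]")
  }
  if (is.null(msg)) TRUE else msg
})

#' Simulated tissue image
#'
#' Output container of [simulateTissue()]: an integer label mask (0 =
#' background, k = nucleus k, labels consecutive from 1), one rendered
#' intensity channel per gene, and the ground-truth allele table with the
#' sampled target RRP and the realized (pixel-grid) RRP of every placed spot.
#'
#' @slot labelMask integer matrix of nucleus labels.
#' @slot channels named list of numeric intensity matrices, one per gene.
#' @slot truth data.frame with columns `nucleus_id`, `gene`, `x`, `y`,
#'   `target_rrp`, `realized_rrp`. Coordinates are 1-based (col, row)
#'   pixel-center positions.
#' @slot config the [simTissueConfig()] list used to generate the object.
#'
#' @exportClass SimTissue
setClass("SimTissue",
  representation(labelMask = "matrix", channels = "list",
                 truth = "data.frame", config = "list"))

setValidity("SimTissue", function(object) {
  msg <- NULL
  labs <- sort(unique(as.integer(object@labelMask)))
  labs <- labs[labs > 0L]
  if (length(labs) && !identical(labs, seq_along(labs)))
    msg <- c(msg, "nucleus labels must be consecutive from 1")
  need <- c("nucleus_id", "gene", "x", "y", "target_rrp", "realized_rrp")
  if (!all(need %in% names(object@truth)))
    msg <- c(msg, paste("truth must have columns:", paste(need, collapse = ", ")))
  if (is.null(msg)) TRUE else msg
})

#' Relative radial distribution (RRD)
#'
#' The pooled set of relative radial positions (RRPs) of one gene across all
#' analyzed nuclei of one tissue. Every detected allele contributes one value,
#' regardless of how many alleles a nucleus carries; there is no per-nucleus
#' averaging.
#'
#' @slot gene gene symbol.
#' @slot tissueId tissue identifier.
#' @slot values numeric vector of RRPs in \[0, 1\].
#' @slot nNuclei number of nuclei the alleles came from.
#' @slot nAlleles number of pooled alleles (`length(values)`).
#'
#' @seealso [buildRRD()], [buildPND()], [callRepositioning()]
#' @exportClass RRD
setClass("RRD",
  representation(gene = "character", tissueId = "character",
                 values = "numeric", nNuclei = "integer", nAlleles = "integer"))

setValidity("RRD", function(object) {
  msg <- NULL
  if (length(object@values) == 0L)
    msg <- c(msg, "an RRD must contain at least one allele")
  if (any(object@values < 0 | object@values > 1))
    msg <- c(msg, "all RRP values must lie in [0, 1]")
  if (object@nAlleles != length(object@values))
    msg <- c(msg, "nAlleles must equal length(values)")
  if (object@nNuclei < 1L || object@nAlleles < object@nNuclei)
    msg <- c(msg, "need nAlleles >= nNuclei >= 1")
  if (is.null(msg)) TRUE else msg
})

#' Pooled normal distribution (PND)
#'
#' The concatenated RRP values of one gene across all normal tissues; the
#' standard reference against which per-tissue RRDs are compared when calling
#' repositioning.
#'
#' @slot gene gene symbol.
#' @slot sourceTissues ids of the pooled normal tissues.
#' @slot values concatenated RRP values.
#' @slot nNuclei total nucleus count over the source RRDs.
#'
#' @seealso [buildPND()]
#' @exportClass PND
setClass("PND",
  representation(gene = "character", sourceTissues = "character",
                 values = "numeric", nNuclei = "integer"))

setValidity("PND", function(object) {
  msg <- NULL
  if (length(object@values) == 0L) msg <- c(msg, "PND has no values")
  if (any(object@values < 0 | object@values > 1))
    msg <- c(msg, "all RRP values must lie in [0, 1]")
  if (length(object@sourceTissues) < 2L)
    msg <- c(msg, "a PND pools at least two tissues")
  if (is.null(msg)) TRUE else msg
})

#' Repositioning comparison result
#'
#' Result of comparing a tissue RRD against a reference distribution with the
#' two-sample Kolmogorov-Smirnov test. The call is significant iff
#' `pValue < alpha` (strict); significant comparisons are labeled `"I"`
#' (more internal: tissue median RRP above the reference median) or `"P"`
#' (more peripheral), otherwise `"NS"`.
#'
#' @slot gene,tissueId identity of the compared RRD.
#' @slot ksD KS statistic D in \[0, 1\].
#' @slot pValue KS p-value.
#' @slot alpha significance level used.
#' @slot significant logical.
#' @slot direction `"NS"`, `"I"` or `"P"`.
#' @slot medianDiff median(RRD) - median(reference), the direction statistic.
#' @slot meanDiff mean difference, the fallback used on exact median ties.
#'
#' @seealso [callRepositioning()]
#' @exportClass RepositioningResult
setClass("RepositioningResult",
  representation(gene = "character", tissueId = "character", ksD = "numeric",
                 pValue = "numeric", alpha = "numeric", significant = "logical",
                 direction = "character", medianDiff = "numeric",
                 meanDiff = "numeric"))

setValidity("RepositioningResult", function(object) {
  msg <- NULL
  if (!object@direction %in% c("NS", "I", "P"))
    msg <- c(msg, "direction must be 'NS', 'I' or 'P'")
  if (object@significant != (object@pValue < object@alpha))
    msg <- c(msg, "significant must equal (pValue < alpha)")
  if ((object@direction == "NS") == object@significant)
    msg <- c(msg, "direction is 'NS' iff the comparison is not significant")
  if (is.null(msg)) TRUE else msg
})

#' Marker performance report
#'
#' False-negative / false-positive accounting for a gene-positioning marker
#' rule evaluated on a call table. Positives are the assayed tissues of the
#' target subgroup; a tissue is flagged when at least one evidence gene shows
#' the required repositioning direction. The false negative rate is the
#' fraction of positives not flagged; the false positive rate is the fraction
#' of the configured negative pool that is flagged.
#'
#' @slot evidence named character vector, gene -> required direction
#'   (`"I"`, `"P"` or `"any"`).
#' @slot nPositive,nNegative counted (fully assayed) tissues per pool.
#' @slot flaggedPositives,falseNegatives,falsePositives counts.
#' @slot fnr,fpr rates; `NaN` when the corresponding pool is empty.
#' @slot excluded tissue ids dropped because an evidence gene was not assayed.
#'
#' @seealso [evaluateMarker()]
#' @exportClass MarkerPerformance
setClass("MarkerPerformance",
  representation(evidence = "character", nPositive = "integer",
                 nNegative = "integer", flaggedPositives = "integer",
                 falseNegatives = "integer", falsePositives = "integer",
                 fnr = "numeric", fpr = "numeric", excluded = "character"))

setValidity("MarkerPerformance", function(object) {
  msg <- NULL
  if (object@flaggedPositives + object@falseNegatives != object@nPositive)
    msg <- c(msg, "flaggedPositives + falseNegatives must equal nPositive")
  if (is.null(msg)) TRUE else msg
})
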