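#' Accessors for radialFISH classes
#'
#' Small accessor generics for the S4 containers: `geneName()` and
#' `tissueName()` return identity fields, `rrpValues()` the pooled RRP vector,
#' `nNuclei()`/`nAlleles()` the sample-size bookkeeping, `truthTable()`,
#' `labelMask()` and `channelImage()` the components of a [SimTissue-class].
#'
#' @param object an object of one of the package classes.
#' @param ... further arguments for methods.
#' @return the accessed component.
#' @name accessors
#' @aliases geneName tissueName rrpValues nNuclei nAlleles truthTable
#'   labelMask channelImage
NULL

#' @rdname accessors
#' @export
setGeneric("geneName", function(object) standardGeneric("geneName"))
#' @rdname accessors
#' @export
setGeneric("tissueName", function(object) standardGeneric("tissueName"))
#' @rdname accessors
#' @export
setGeneric("rrpValues", function(object) standardGeneric("rrpValues"))
#' @rdname accessors
#' @export
setGeneric("nNuclei", function(object) standardGeneric("nNuclei"))
#' @rdname accessors
#' @export
setGeneric("nAlleles", function(object) standardGeneric("nAlleles"))
#' @rdname accessors
#' @export
setGeneric("truthTable", function(object) standardGeneric("truthTable"))
#' @rdname accessors
#' @export
setGeneric("labelMask", function(object) standardGeneric("labelMask"))
#' @rdname accessors
#' @export
setGeneric("channelImage", function(object, gene) standardGeneric("channelImage"))

#' Sample target relative radial positions from a model
#'
#' Draws `n` values on \[0, 1\] from a [RadialModel-class] using the current
#' RNG state.
#'
#' @param model a [RadialModel-class].
#' @param n number of draws.
#' @return numeric vector of length `n` in \[0, 1\].
#' @examples
#' set.seed(1)
#' sampleRRP(radialModel("beta", shape1 = 2, shape2 = 2), 5)
#' @export
setGeneric("sampleRRP", function(model, n) standardGeneric("sampleRRP"))

#' @rdname accessors
setMethod("geneName", "RRD", function(object) object@gene)
#' @rdname accessors
setMethod("geneName", "PND", function(object) object@gene)
#' @rdname accessors
setMethod("geneName", "RepositioningResult", function(object) object@gene)
#' @rdname accessors
setMethod("tissueName", "RRD", function(object) object@tissueId)
#' @rdname accessors
setMethod("tissueName", "RepositioningResult", function(object) object@tissueId)
#' @rdname accessors
setMethod("rrpValues", "RRD", function(object) object@values)
#' @rdname accessors
setMethod("rrpValues", "PND", function(object) object@values)
#' @rdname accessors
setMethod("nNuclei", "RRD", function(object) object@nNuclei)
#' @rdname accessors
setMethod("nNuclei", "PND", function(object) object@nNuclei)
#' @rdname accessors
setMethod("nAlleles", "RRD", function(object) object@nAlleles)
#' @rdname accessors
setMethod("nAlleles", "PND", function(object) length(object@values))
#' @rdname accessors
setMethod("truthTable", "SimTissue", function(object) object@truth)
#' @rdname accessors
setMethod("labelMask", "SimTissue", function(object) object@labelMask)
#' @rdname accessors
setMethod("channelImage", "SimTissue", function(object, gene) {
  if (!gene %in% names(object@channels))
    stop("no channel for gene '", gene, "'")
  object@channels[[gene]]
})

setMethod("show", "RadialModel", function(object) {
  p <- if (length(object@params))
    paste0("(", paste(names(object@params), signif(object@params, 4),
                      sep = "=", collapse = ", "), ")") else ""
  cat("RadialModel:", object@family, p, "\n")
})

setMethod("show", "SimTissue", function(object) {
  cat("SimTissue:", max(object@labelMask), "nuclei,",
      length(object@channels), "gene channel(s) [",
      paste(names(object@channels), collapse = ", "), "]\n")
  cat("  canvas:", paste(dim(object@labelMask), collapse = " x "),
      "px;", nrow(object@truth), "ground-truth alleles\n")
})

setMethod("show", "RRD", function(object) {
  cat("RRD of", object@gene, "in", object@tissueId, "--",
      object@nAlleles, "alleles from", object@nNuclei, "nuclei; median RRP",
      signif(median(object@values), 3), "\n")
})

setMethod("show", "PND", function(object) {
  cat("PND of", object@gene, "--", length(object@values), "alleles,",
      object@nNuclei, "nuclei from", length(object@sourceTissues),
      "normal tissues\n")
})

setMethod("show", "RepositioningResult", function(object) {
  cat(sprintf("%s in %s vs reference: D = %.3f, p = %.3g -> %s\n",
              object@gene, object@tissueId, object@ksD, object@pValue,
              switch(object@direction, NS = "not significant",
                     I = "more internal", P = "more peripheral")))
})

setMethod("show", "MarkerPerformance", function(object) {
  ev <- paste(names(object@evidence), object@evidence, sep = ":",
              collapse = ", ")
  cat("Marker rule [", ev, "]\n", sep = "")
  cat(sprintf("  positives: %d (flagged %d) -> FNR %.1f%%\n",
              object@nPositive, object@flaggedPositives, 100 * object@fnr))
  cat(sprintf("  negatives: %d (flagged %d) -> FPR %.1f%%\n",
              object@nNegative, object@falsePositives, 100 * object@fpr))
  if (length(object@excluded))
    cat("  excluded (not fully assayed):",
        paste(object@excluded, collapse = ", "), "\n")
})
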