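#' Read and write the package's tabular formats
#'
#' All tables are tab-delimited UTF-8 text with a header row. `readCallTable`
#' / `writeCallTable` handle repositioning call tables (`tissue_id`, `gene`,
#' `call`), `readAlleleTable` / `writeAlleleTable` the per-allele record
#' tables of [mapTissue()], and `readClinicalTable` / `writeClinicalTable`
#' the clinical metadata. Readers validate the column schema and report
#' offending rows.
#'
#' @param path file path.
#' @param x table to write.
#' @return readers return a data.frame; writers return `path` invisibly.
#' @name tableIO
NULL

checkColumns <- function(df, need, what, path) {
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(what, " file '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "))
  df
}

#' @rdname tableIO
#' @export
readCallTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  df <- checkColumns(df, c("tissue_id", "gene", "call"), "call table", path)
  bad <- which(!df$call %in% c("NS", "I", "P"))
  if (length(bad))
    stop("invalid call value(s) in '", path, "' at row(s): ",
         paste(bad, collapse = ", "))
  dup <- duplicated(df[, c("tissue_id", "gene")])
  if (any(dup))
    stop("duplicate (tissue, gene) rows in '", path, "': ",
         paste(unique(paste(df$tissue_id[dup], df$gene[dup])), collapse = ", "))
  df
}

#' @rdname tableIO
#' @export
writeCallTable <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname tableIO
#' @export
readAlleleTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  checkColumns(df, c("tissue_id", "gene", "nucleus_id", "x", "y", "rrp"),
               "allele table", path)
  bad <- which(is.na(df$rrp) | df$rrp < 0 | df$rrp > 1)
  if (length(bad))
    stop("rrp outside [0, 1] in '", path, "' at row(s): ",
         paste(bad, collapse = ", "))
  df
}

#' @rdname tableIO
#' @export
writeAlleleTable <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname tableIO
#' @export
readClinicalTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                   na.strings = c("NA", ""))
  checkColumns(df, c("tissue_id", "tissue_class", "gleason_score",
                     "gleason_primary", "gleason_secondary", "gleason_grade",
                     "tnm"), "clinical table", path)
  badClass <- which(!df$tissue_class %in% c("normal", "benign_disease",
                                            "cancer"))
  if (length(badClass))
    stop("invalid tissue_class in '", path, "' at row(s): ",
         paste(badClass, collapse = ", "))
  for (i in seq_len(nrow(df))) {
    tryCatch(parseTNM(ifelse(is.na(df$tnm[i]), "Unknown", df$tnm[i])),
             error = function(e)
               stop("row ", i, " (", df$tissue_id[i], "): ",
                    conditionMessage(e), call. = FALSE))
  }
  df
}

#' @rdname tableIO
#' @export
writeClinicalTable <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write 16-bit TIFF images
#'
#' `writeLabelMask`/`readLabelMask` store integer nucleus labels;
#' `writeChannel`/`readChannel` store intensity images (clamped to the
#' 16-bit range on write).
#'
#' @param x integer label matrix or numeric intensity matrix.
#' @param path TIFF file path.
#' @return readers return a matrix; writers return `path` invisibly.
#' @name imageIO
NULL

#' @rdname imageIO
#' @export
writeLabelMask <- function(x, path) {
  if (max(x) > 65535L) stop("more than 65535 labels")
  tiff::writeTIFF(x / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname imageIO
#' @export
readLabelMask <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' @rdname imageIO
#' @export
writeChannel <- function(x, path) {
  tiff::writeTIFF(round(pmin(pmax(x, 0), 65535)) / 65535, path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' @rdname imageIO
#' @export
readChannel <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(m * 65535, nrow(m), ncol(m))
}

#' Write a simulated tissue to disk
#'
#' Writes the label mask and the per-gene channels as 16-bit TIFFs, the
#' ground-truth allele table as TSV, and the configuration echo as YAML-like
#' structured text.
#'
#' @param sim a [SimTissue-class].
#' @param outdir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisible character vector of the written paths.
#' @export
writeSimTissue <- function(sim, outdir, prefix = "sim") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(outdir, paste0(prefix, "_labels.tif"))
  writeLabelMask(labelMask(sim), paths)
  for (gn in names(sim@channels)) {
    p <- file.path(outdir, paste0(prefix, "_", gn, ".tif"))
    writeChannel(sim@channels[[gn]], p)
    paths <- c(paths, p)
  }
  tp <- file.path(outdir, paste0(prefix, "_truth.tsv"))
  write.table(truthTable(sim), tp, sep = "\t", quote = FALSE,
              row.names = FALSE)
  cp <- file.path(outdir, paste0(prefix, "_config.txt"))
  cfg <- sim@config
  writeLines(c(
    paste0("nNuclei: ", cfg$nNuclei),
    paste0("canvasSize: ", paste(cfg$canvasSize, collapse = " x ")),
    paste0("genes: ", paste(names(cfg$genes), collapse = ", ")),
    paste0("psfSigma: ", cfg$psfSigma),
    paste0("noiseSd: ", cfg$noiseSd),
    paste0("peak: ", cfg$peak),
    paste0("rngSeed: ", cfg$rngSeed)), cp)
  invisible(c(paths, tp, cp))
}

#' Load and cross-validate a cohort bundle
#'
#' Reads the clinical table and the call table (or an allele table), checks
#' the schemas, and cross-references the tissue ids: call/allele rows whose
#' tissue is absent from the clinical table are an error listing the
#' orphans.
#'
#' @param clinicalPath path to a clinical TSV.
#' @param callsPath optional path to a call TSV.
#' @param allelesPath optional path to an allele TSV.
#' @return list with components `clinical` (with subgroups assigned),
#'   `calls` (or `NULL`), `alleles` (or `NULL`) and `provenance`.
#' @export
loadCohort <- function(clinicalPath, callsPath = NULL, allelesPath = NULL) {
  clinical <- assignSubgroups(readClinicalTable(clinicalPath))
  calls <- if (!is.null(callsPath)) readCallTable(callsPath) else NULL
  alleles <- if (!is.null(allelesPath)) readAlleleTable(allelesPath) else NULL
  for (tab in list(calls, alleles)) {
    if (is.null(tab)) next
    orphans <- setdiff(unique(tab$tissue_id), clinical$tissue_id)
    if (length(orphans))
      stop("tissue id(s) absent from the clinical table: ",
           paste(orphans, collapse = ", "))
  }
  list(clinical = clinical, calls = calls, alleles = alleles,
       provenance = list(
         clinicalPath = clinicalPath, callsPath = callsPath,
         allelesPath = allelesPath, when = format(Sys.time()),
         package = as.character(packageVersion("radialFISH"))))
}

#' Load the bundled prostate worked-example cohort
#'
#' A curated cohort of 32 prostate cancers, 16 normal and 9 benign-disease
#' prostate tissues with per-gene repositioning calls (SP100, TGFB3, SATB1,
#' LMNA) against pooled normal references, plus Gleason/TNM/risk metadata.
#' Blank cells of the published summary matrix conflate "not significant"
#' and "not assayed"; this encoding makes the assay matrix explicit (absent
#' row = not assayed), reconciled from the per-subgroup denominators of the
#' source study's summary tables. See the fixture file headers for the
#' per-tissue notes.
#'
#' @return list with `clinical` (subgroups assigned) and `calls`, as in
#'   [loadCohort()].
#' @examples
#' cohort <- loadProstateCohort()
#' table(cohort$clinical$tissue_class)
#' @export
loadProstateCohort <- function() {
  loadCohort(
    system.file("extdata", "prostate_clinical.tsv", package = "radialFISH",
                mustWork = TRUE),
    system.file("extdata", "prostate_calls.tsv", package = "radialFISH",
                mustWork = TRUE))
}

#' Simulate a multi-tissue cohort
#'
#' Generates one [SimTissue-class] per row of `tissues`, using per-class
#' radial models, and returns the cohort pieces the pipeline consumes.
#' Per-tissue seeds are derived deterministically from `seed`.
#'
#' @param tissues data.frame with columns `tissue_id` and `tissue_class`.
#' @param modelsByClass named list mapping tissue class to a named list of
#'   per-gene [RadialModel-class] objects (every class must provide the same
#'   gene set).
#' @param baseConfig a [simTissueConfig()] whose `genes` models are
#'   overridden per class; sizes, shape and imaging settings are shared.
#' @param seed master seed for the cohort.
#' @return named list of [SimTissue-class] objects.
#' @export
simulateCohort <- function(tissues, modelsByClass,
                           baseConfig = simTissueConfig(), seed = 1L) {
  genes <- names(modelsByClass[[1]])
  sims <- list()
  for (i in seq_len(nrow(tissues))) {
    cls <- tissues$tissue_class[i]
    if (!cls %in% names(modelsByClass))
      stop("no radial models for tissue class '", cls, "'")
    cfg <- baseConfig
    cfg$genes <- lapply(genes, function(g) {
      spec <- baseConfig$genes[[g]]
      if (is.null(spec)) spec <- list(copyProb = c(0, 1, 0, 0))
      spec$model <- modelsByClass[[cls]][[g]]
      spec
    })
    names(cfg$genes) <- genes
    cfg$rngSeed <- (seed * 1000L + i) %% .Machine$integer.max
    sims[[tissues$tissue_id[i]]] <- simulateTissue(cfg)
  }
  sims
}

#' Run the full synthetic-cohort pipeline
#'
#' Chains the whole analysis end to end on simulated data: simulate ->
#' measure ([mapTissue()]) -> compare against the pooled normal reference
#' ([compareToPND()]) -> summarize. Deterministic given `seed`. All
#' intermediate tables and a summary JSON are written under `outdir`.
#'
#' @param tissues,modelsByClass,baseConfig,seed passed to
#'   [simulateCohort()].
#' @param spotPars a [spotParams()] object for the measurement stage.
#' @param alpha significance level for repositioning calls.
#' @param outdir output directory, or `NULL` to skip writing.
#' @param minNuclei passed to [buildRRD()] via [compareToPND()].
#' @return list with `alleles`, `calls` (per-tissue comparison rows), and
#'   `summary` (per-gene repositioning fractions among non-normal tissues).
#' @export
runFullPipeline <- function(tissues, modelsByClass,
                            baseConfig = simTissueConfig(),
                            spotPars = spotParams(), alpha = 0.01,
                            seed = 1L, outdir = NULL, minNuclei = 88L) {
  stages <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  sims <- stages("simulate",
                 simulateCohort(tissues, modelsByClass, baseConfig, seed))
  alleles <- stages("map", {
    recs <- lapply(names(sims), function(id)
      mapTissue(labelMask(sims[[id]]), sims[[id]]@channels, spotPars, id))
    do.call(rbind, recs)
  })
  normals <- tissues$tissue_id[tissues$tissue_class == "normal"]
  if (length(normals) < 2L)
    stop("pipeline needs at least two normal tissues for the PND")
  genes <- names(modelsByClass[[1]])
  calls <- stages("compare", {
    rows <- lapply(genes, function(g)
      compareToPND(alleles, g, normals, alpha = alpha,
                   minNuclei = minNuclei))
    do.call(rbind, rows)
  })
  nonNormal <- setdiff(unique(calls$tissue_id), normals)
  summary <- stages("report", {
    lapply(setNames(genes, genes), function(g) {
      sub <- calls[calls$gene == g & calls$tissue_id %in% nonNormal, ]
      list(n = nrow(sub), repositioned = sum(sub$call != "NS"),
           internal = sum(sub$call == "I"),
           peripheral = sum(sub$call == "P"),
           fraction = if (nrow(sub)) sum(sub$call != "NS") / nrow(sub)
                      else NaN)
    })
  })
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    writeAlleleTable(alleles, file.path(outdir, "alleles.tsv"))
    write.table(calls, file.path(outdir, "comparisons.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(seed = seed, alpha = alpha, genes = genes, summary = summary),
      file.path(outdir, "summary.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  list(alleles = alleles, calls = calls, summary = summary)
}
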