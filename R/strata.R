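#' Parse TNM staging strings
#'
#' Splits strings like `"T3N0M1"`, `"T2a N0"`, `"T2N0"` or `"Unknown"` into
#' their T, N and M components. Sub-stage letters are retained on T and M;
#' absent N or M components are `"unknown"`.
#'
#' @param text character vector of TNM strings.
#' @return data.frame with character columns `T`, `N`, `M` (values such as
#'   `"T3"`, `"T2a"`, `"N0"`, `"M1b"`, or `"unknown"`).
#' @examples
#' parseTNM(c("T3N0M1", "T2N0", "Unknown"))
#' @export
parseTNM <- function(text) {
  pat <- "^T([1-4])([a-c]?)(N([01]))?(M([01])([a-c]?))?$"
  out <- data.frame(T = rep("unknown", length(text)),
                    N = "unknown", M = "unknown")
  for (i in seq_along(text)) {
    s <- gsub("[[:space:]]", "", text[i])
    if (is.na(s) || !nzchar(s) || tolower(s) == "unknown") next
    m <- regmatches(s, regexec(pat, s))[[1]]
    if (!length(m))
      stop("unparsable TNM string: '", text[i], "'")
    out$T[i] <- paste0("T", m[2], m[3])
    if (nzchar(m[4])) out$N[i] <- paste0("N", m[5])
    if (nzchar(m[6])) out$M[i] <- paste0("M", m[7], m[8])
  }
  out
}

# first digit of a reported Gleason grade ("4", "4-5", "GG3"...); NA if none
gradeDigit <- function(g) {
  d <- regmatches(g, regexpr("[1-5]", g))
  ifelse(lengths(regmatches(g, gregexpr("[1-5]", g))) > 0,
         suppressWarnings(as.integer(substr(d, 1, 1))), NA_integer_)
}

#' Assign clinical subgroups to a cohort table
#'
#' Derives the stratification subgroups used throughout the package from the
#' raw clinical fields of cancer records:
#' * `gleason_group`: scores 2-6 are `"low"`, 7 `"intermediate"`, 8-10
#'   `"high"`;
#' * `grade_group`: from the reported predominant Gleason grade (first digit
#'   of `gleason_grade`, so `"4-5"` buckets as GG4/5): 1-2 `"GG1/2"`, 3
#'   `"GG3"`, 4-5 `"GG4/5"`;
#' * `t_group`: sub-stages collapse (T2a/b/c to T2, T3a to T3) into
#'   `"T1/T2"` vs `"T3/T4"`;
#' * `met_group`: `"N1/M1"` if either N1 or M1; `"N0M0"` when N0 with M0 or
#'   M unrecorded (an N0 record without a distant-metastasis entry is counted
#'   non-metastatic); otherwise `"unknown"`;
#' * `risk`: see [classifyRisk()].
#'
#' Non-cancer rows get `NA` in every subgroup column.
#'
#' @param clinical data.frame with columns `tissue_id`, `tissue_class`
#'   (`"normal"`, `"benign_disease"`, `"cancer"`), `gleason_score`,
#'   `gleason_primary`, `gleason_secondary`, `gleason_grade`, `tnm`.
#' @return the input with columns `T`, `N`, `M`, `gleason_group`,
#'   `grade_group`, `t_group`, `met_group`, `risk` appended.
#' @export
assignSubgroups <- function(clinical) {
  need <- c("tissue_id", "tissue_class", "gleason_score", "gleason_grade", "tnm")
  if (!all(need %in% names(clinical)))
    stop("clinical table must have columns: ", paste(need, collapse = ", "))
  if (any(duplicated(clinical$tissue_id)))
    stop("duplicate tissue_id in clinical table")
  known <- !is.na(clinical$gleason_score) &
    !is.na(clinical$gleason_primary) & !is.na(clinical$gleason_secondary)
  bad <- known & (clinical$gleason_primary + clinical$gleason_secondary !=
                    clinical$gleason_score)
  if (any(bad))
    stop("Gleason grades do not sum to the score for: ",
         paste(clinical$tissue_id[bad], collapse = ", "))
  tnm <- parseTNM(ifelse(is.na(clinical$tnm), "Unknown", clinical$tnm))
  cancer <- clinical$tissue_class == "cancer"

  gs <- clinical$gleason_score
  gleason_group <- ifelse(is.na(gs), "unknown",
                   ifelse(gs <= 6, "low",
                   ifelse(gs == 7, "intermediate", "high")))
  gd <- gradeDigit(as.character(clinical$gleason_grade))
  grade_group <- ifelse(is.na(gd), "unknown",
                 ifelse(gd <= 2, "GG1/2", ifelse(gd == 3, "GG3", "GG4/5")))
  tBase <- sub("([a-c])$", "", tnm$T)
  t_group <- ifelse(tnm$T == "unknown", "unknown",
             ifelse(tBase %in% c("T1", "T2"), "T1/T2", "T3/T4"))
  mBase <- sub("([a-c])$", "", tnm$M)
  met_group <- ifelse(tnm$N == "N1" | mBase == "M1", "N1/M1",
               ifelse(tnm$N == "N0" & mBase %in% c("M0", "unknown"),
                      "N0M0", "unknown"))
  out <- cbind(clinical, tnm)
  out$gleason_group <- ifelse(cancer, gleason_group, NA_character_)
  out$grade_group <- ifelse(cancer, grade_group, NA_character_)
  out$t_group <- ifelse(cancer, t_group, NA_character_)
  out$met_group <- ifelse(cancer, met_group, NA_character_)
  out$risk <- classifyRisk(out)
  out
}

#' Composite clinical risk classification
#'
#' High-risk criteria are evaluated first so that partially known records can
#' still classify as high: Gleason score 8-10, and/or T3/T4, and/or N1,
#' and/or M1. Otherwise, with organ-confined non-metastatic disease (T1/T2
#' and N0M0), Gleason 2-6 is low risk and Gleason 7 intermediate; anything
#' short of those criteria is `"unknown"`. Non-cancer rows get `NA`.
#'
#' @param clinical a clinical data.frame; subgroup columns are derived on the
#'   fly if [assignSubgroups()] has not been run.
#' @return character vector of `"low"`, `"intermediate"`, `"high"`,
#'   `"unknown"`, or `NA` for non-cancer rows.
#' @export
classifyRisk <- function(clinical) {
  if (!all(c("t_group", "met_group") %in% names(clinical))) {
    tnm <- parseTNM(ifelse(is.na(clinical$tnm), "Unknown", clinical$tnm))
    tBase <- sub("([a-c])$", "", tnm$T)
    mBase <- sub("([a-c])$", "", tnm$M)
    clinical$t_group <- ifelse(tnm$T == "unknown", "unknown",
                        ifelse(tBase %in% c("T1", "T2"), "T1/T2", "T3/T4"))
    clinical$met_group <- ifelse(tnm$N == "N1" | mBase == "M1", "N1/M1",
                          ifelse(tnm$N == "N0" &
                                   mBase %in% c("M0", "unknown"),
                                 "N0M0", "unknown"))
  }
  gs <- clinical$gleason_score
  high <- (!is.na(gs) & gs >= 8) | clinical$t_group == "T3/T4" |
    clinical$met_group == "N1/M1"
  confined <- clinical$t_group == "T1/T2" & clinical$met_group == "N0M0"
  risk <- ifelse(high, "high",
          ifelse(!is.na(gs) & gs <= 6 & confined, "low",
          ifelse(!is.na(gs) & gs == 7 & confined, "intermediate", "unknown")))
  ifelse(clinical$tissue_class == "cancer", risk, NA_character_)
}

# assayed (tissue, gene) lookup helpers on a call table
callOf <- function(calls, tissue, gene) {
  v <- calls$call[calls$tissue_id == tissue & calls$gene == gene]
  if (!length(v)) NA_character_ else v[1]
}

#' Multiplexed marker evaluation per tissue
#'
#' Evaluates an any-of evidence set (gene, required direction) on a call
#' table: a tissue is flagged when at least one evidence gene shows the
#' required repositioning direction (`"any"` matches `"I"` or `"P"`).
#' Tissues missing an assay for any evidence gene are excluded and reported
#' via the `"excluded"` attribute.
#'
#' @param calls call table: data.frame with columns `tissue_id`, `gene`,
#'   `call` (values `"NS"`, `"I"`, `"P"`); absent rows mean not assayed.
#' @param evidence named character vector, e.g.
#'   `c(SP100 = "I", TGFB3 = "I")`; values `"I"`, `"P"` or `"any"`.
#' @param tissues tissues to evaluate (default: all in `calls`).
#' @return named logical vector over the evaluable tissues, with excluded
#'   tissue ids in `attr(, "excluded")`.
#' @export
multiplexCalls <- function(calls, evidence, tissues = unique(calls$tissue_id)) {
  if (!length(evidence) || is.null(names(evidence)))
    stop("evidence must be a non-empty named character vector")
  if (!all(evidence %in% c("I", "P", "any")))
    stop("evidence directions must be 'I', 'P' or 'any'")
  res <- logical(0)
  excluded <- character(0)
  for (tt in tissues) {
    cl <- vapply(names(evidence), function(g) callOf(calls, tt, g),
                 character(1))
    if (any(is.na(cl))) {
      excluded <- c(excluded, tt)
      next
    }
    hit <- mapply(function(obs, want)
      if (want == "any") obs %in% c("I", "P") else obs == want,
      cl, evidence)
    res[tt] <- any(hit)
  }
  attr(res, "excluded") <- excluded
  res
}

#' Evaluate a gene-positioning marker rule
#'
#' Counts marker performance with the subgroup-biomarker convention: the
#' positives are the assayed tissues of the target subgroup; the negatives
#' are whatever pool the analysis dictates (typically normal + benign
#' disease tissues plus cancers of the other subgroups). A tissue counts
#' only when every evidence gene was assayed in it. The false negative rate
#' is the fraction of positives not flagged by the evidence; the false
#' positive rate is the fraction of negatives flagged.
#'
#' @param calls call table (see [multiplexCalls()]).
#' @param positives,negatives character vectors of tissue ids; they must not
#'   overlap.
#' @param evidence named character vector, gene -> `"I"`, `"P"` or `"any"`.
#' @return a [MarkerPerformance-class]. Rates are `NaN` (flagged, not
#'   silently zero) when a pool has no fully assayed member.
#' @export
evaluateMarker <- function(calls, positives, negatives, evidence) {
  if (length(intersect(positives, negatives)))
    stop("positives and negatives overlap: ",
         paste(intersect(positives, negatives), collapse = ", "))
  fp <- multiplexCalls(calls, evidence, positives)
  fn <- multiplexCalls(calls, evidence, negatives)
  nPos <- length(fp); nNeg <- length(fn)
  flaggedPos <- sum(fp); flaggedNeg <- sum(fn)
  if (nPos == 0L || nNeg == 0L)
    warning("empty ", if (nPos == 0L) "positive" else "negative",
            " pool after assay filtering; rate undefined (NaN)")
  new("MarkerPerformance", evidence = evidence,
      nPositive = nPos, nNegative = as.integer(nNeg),
      flaggedPositives = as.integer(flaggedPos),
      falseNegatives = as.integer(nPos - flaggedPos),
      falsePositives = as.integer(flaggedNeg),
      fnr = (nPos - flaggedPos) / nPos, fpr = flaggedNeg / nNeg,
      excluded = c(attr(fp, "excluded"), attr(fn, "excluded")))
}

#' Repositioning breakdown by clinical subgroup
#'
#' For one gene, tabulates per subgroup: how many assayed cancers repositioned
#' at all (`"any"`), and among the repositioned ones, how many moved internal
#' vs peripheral -- the standard subgroup breakdown of a positioning-pattern
#' analysis.
#'
#' @param calls call table (see [multiplexCalls()]).
#' @param clinical clinical table with subgroup columns (run
#'   [assignSubgroups()] first).
#' @param gene gene to summarize.
#' @param groupBy a subgroup column of `clinical` (e.g. `"gleason_group"`,
#'   `"grade_group"`, `"t_group"`, `"met_group"`, `"risk"`), or `"all"` for a
#'   single pooled row.
#' @param tissueClass which tissue classes to include (default cancers).
#' @return data.frame with one row per subgroup level: `group`, `n_assayed`,
#'   `n_repositioned`, `pct_any`, `n_internal`, `pct_internal`,
#'   `n_peripheral`, `pct_peripheral`. Percentages among zero denominators
#'   are `NaN`.
#' @export
subgroupSummary <- function(calls, clinical, gene, groupBy = "all",
                            tissueClass = "cancer") {
  if (groupBy != "all" && !groupBy %in% names(clinical))
    stop("no column '", groupBy, "' in the clinical table")
  cl <- clinical[clinical$tissue_class %in% tissueClass, , drop = FALSE]
  gcalls <- calls[calls$gene == gene & calls$tissue_id %in% cl$tissue_id, ]
  grp <- if (groupBy == "all") rep("all", nrow(gcalls)) else
    cl[[groupBy]][match(gcalls$tissue_id, cl$tissue_id)]
  levelsOf <- if (groupBy == "all") "all" else
    unique(c(intersect(c("low", "intermediate", "high", "GG1/2", "GG3",
                         "GG4/5", "T1/T2", "T3/T4", "N0M0", "N1/M1",
                         "unknown"), grp), sort(unique(grp))))
  rows <- lapply(levelsOf, function(lv) {
    sel <- gcalls$call[grp == lv]
    nAss <- length(sel)
    nRep <- sum(sel %in% c("I", "P"))
    nI <- sum(sel == "I"); nP <- sum(sel == "P")
    data.frame(group = lv, n_assayed = nAss, n_repositioned = nRep,
               pct_any = 100 * nRep / nAss,
               n_internal = nI, pct_internal = 100 * nI / nRep,
               n_peripheral = nP, pct_peripheral = 100 * nP / nRep)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
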