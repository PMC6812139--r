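test_that("TNM strings parse into retained components", {
  p <- parseTNM(c("T3N0M1", "T2N0", "Unknown", "T3aN0M0", "T2N1M1c"))
  expect_equal(p$T, c("T3", "T2", "unknown", "T3a", "T2"))
  expect_equal(p$N, c("N0", "N0", "unknown", "N0", "N1"))
  expect_equal(p$M, c("M1", "unknown", "unknown", "M0", "M1c"))
  expect_error(parseTNM("T9X"), "unparsable TNM string: 'T9X'")
})

test_that("subgroup assignment follows the clinical grouping rules", {
  clin <- data.frame(
    tissue_id = paste0("X", 1:6), tissue_class = "cancer",
    gleason_score = c(6, 7, 9, 4, 8, 7),
    gleason_primary = c(3, 3, 4, 2, 4, NA),
    gleason_secondary = c(3, 4, 5, 2, 4, NA),
    gleason_grade = c("3", "4", "5", "2", "4-5", NA),
    tnm = c("T2N0M0", "T2N0M0", "T3N0", "T4N1M1", "Unknown", "T2N0"))
  s <- assignSubgroups(clin)
  expect_equal(s$gleason_group,
               c("low", "intermediate", "high", "low", "high", "intermediate"))
  expect_equal(s$grade_group,
               c("GG3", "GG4/5", "GG4/5", "GG1/2", "GG4/5", "unknown"))
  expect_equal(s$t_group,
               c("T1/T2", "T1/T2", "T3/T4", "T3/T4", "unknown", "T1/T2"))
  # N0 with unrecorded M counts as non-metastatic
  expect_equal(s$met_group,
               c("N0M0", "N0M0", "N0M0", "N1/M1", "unknown", "N0M0"))
  expect_equal(s$risk,
               c("low", "intermediate", "high", "high", "high", "intermediate"))

  # every cancer gets exactly one level per dimension (partition property)
  for (col in c("gleason_group", "grade_group", "t_group", "met_group", "risk"))
    expect_true(all(!is.na(s[[col]])))

  # benign tissues carry no subgroups
  ben <- assignSubgroups(data.frame(
    tissue_id = "B", tissue_class = "benign_disease", gleason_score = NA,
    gleason_primary = NA, gleason_secondary = NA, gleason_grade = NA,
    tnm = NA))
  expect_true(all(is.na(ben[, c("gleason_group", "risk")])))

  # inconsistent grade decomposition is rejected
  bad <- clin; bad$gleason_secondary[1] <- 4
  expect_error(assignSubgroups(bad), "do not sum")
})

test_that("risk classification puts high-risk criteria first", {
  mk <- function(score, tnm) data.frame(
    tissue_id = "X", tissue_class = "cancer", gleason_score = score,
    gleason_primary = NA, gleason_secondary = NA, gleason_grade = NA,
    tnm = tnm)
  expect_equal(assignSubgroups(mk(6, "T2N0M0"))$risk, "low")
  expect_equal(assignSubgroups(mk(4, "T4N1M1"))$risk, "high")
  expect_equal(assignSubgroups(mk(8, "Unknown"))$risk, "high")   # partial record
  expect_equal(assignSubgroups(mk(6, "T3N1M0"))$risk, "high")    # N1 alone
  expect_equal(assignSubgroups(mk(7, "T1N0M0"))$risk, "intermediate")
  expect_equal(assignSubgroups(mk(6, "Unknown"))$risk, "unknown")
})

test_that("multiplexed evidence is any-of and excludes unassayed tissues", {
  calls <- data.frame(
    tissue_id = c("A", "A", "B", "B", "C", "C", "D"),
    gene = c("SP100", "TGFB3", "SP100", "TGFB3", "SP100", "TGFB3", "SP100"),
    call = c("I", "NS", "P", "I", "NS", "NS", "I"))
  ev <- c(SP100 = "I", TGFB3 = "I")
  fl <- multiplexCalls(calls, ev)
  expect_true(fl[["A"]])           # SP100 internal matches
  expect_true(fl[["B"]])           # opposite SP100, but TGFB3 internal matches
  expect_false(fl[["C"]])          # both NS
  expect_equal(attr(fl, "excluded"), "D")  # TGFB3 not assayed

  expect_error(multiplexCalls(calls, c(SP100 = "up")), "'I', 'P' or 'any'")
  expect_error(multiplexCalls(calls, character(0)), "non-empty")
})

test_that("marker evaluation accounts exactly for flags, FNs and FPs", {
  calls <- data.frame(
    tissue_id = c("P1", "P2", "P3", "N1", "N2", "N3", "N4"),
    gene = "G",
    call = c("P", "NS", "P", "NS", "P", "NS", "NS"))
  perf <- evaluateMarker(calls, positives = c("P1", "P2", "P3"),
                         negatives = c("N1", "N2", "N3", "N4"),
                         evidence = c(G = "P"))
  expect_equal(perf@nPositive, 3L)
  expect_equal(perf@falseNegatives, 1L)
  expect_equal(perf@fnr, 1 / 3)
  expect_equal(perf@falsePositives, 1L)
  expect_equal(perf@fpr, 1 / 4)
  # accounting identity
  expect_equal(perf@flaggedPositives + perf@falseNegatives, perf@nPositive)

  # evidence flagged in every positive: FNR 0
  all1 <- evaluateMarker(calls, positives = c("P1", "P3"),
                         negatives = c("N1", "N3"), evidence = c(G = "P"))
  expect_equal(all1@fnr, 0)

  expect_error(evaluateMarker(calls, "P1", "P1", c(G = "P")), "overlap")
  expect_warning(
    und <- evaluateMarker(calls, positives = "ZZZ", negatives = "N1",
                          evidence = c(G = "P")),
    "empty positive pool")
  expect_true(is.nan(und@fnr))
})

test_that("subgroup summaries break calls down with explicit denominators", {
  cohort <- loadProstateCohort()
  s <- subgroupSummary(cohort$calls, cohort$clinical, "SP100", "all")
  expect_equal(s$n_assayed, 27L)
  expect_equal(s$n_repositioned, 12L)
  expect_equal(s$pct_internal, 100 * 5 / 12)

  g <- subgroupSummary(cohort$calls, cohort$clinical, "SP100", "gleason_group")
  lowRow <- g[g$group == "low", ]
  expect_equal(lowRow$n_repositioned, 6L)
  expect_equal(lowRow$pct_peripheral, 100)  # low-Gleason shifts all peripheral

  # empty subgroup rows come back as 0/0 with NaN percentages
  none <- subgroupSummary(cohort$calls[0, ], cohort$clinical, "SP100", "all")
  expect_equal(none$n_assayed, 0L)
  expect_true(is.nan(none$pct_any))
})
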