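test_that("every fixture loads with the documented key values", {
  inf <- fcd_fixture("crosstab_inferior")
  expect_identical(unname(diag(inf)), c(7L, 15L, 8L, 2L))
  lat <- fcd_fixture("crosstab_lateral")
  expect_identical(sum(lat), 40L)
  wbg <- fcd_fixture("walls_by_group")
  expect_identical(wbg$fcd_n[wbg$wall == "lateral"], c(2L, 22L, 3L, 2L))
  expect_identical(wbg$control_n[wbg$wall == "inferior"], c(0L, 4L, 5L, 2L))
  rates <- fcd_fixture("cutoff_rates")
  expect_identical(rates$cutoff, 0:6)
  conf <- fcd_fixture("confusion_cutoff4")
  expect_identical(c(conf$tp, conf$fn, conf$fp, conf$tn), c(27L, 2L, 2L, 9L))
  marg <- fcd_fixture("marginal_scores")
  expect_identical(unname(marg), c(2L, 7L, 13L, 7L, 6L, 4L, 1L))
  mis <- fcd_fixture("misdiagnosed_cases")
  expect_identical(nrow(mis), 4L)
  expect_identical(fcd_score(mis$lateral_score, mis$inferior_score),
                   c(3L, 2L, 4L, 4L))
})

test_that("a corrupted fixture file trips the integrity check", {
  dir <- tempfile(); dir.create(dir)
  src <- system.file("extdata", package = "fcdscore")
  file.copy(list.files(src, full.names = TRUE), dir)
  path <- file.path(dir, "crosstab_lateral.csv")
  txt <- readLines(path)
  txt[3] <- "1,2,20,1,2"  # total becomes 41
  writeLines(txt, path)
  expect_error(fcd_fixture("crosstab_lateral", dir = dir), "integrity")
  expect_error(fcd_fixture("bogus_name"), "arg")
})

test_that("reconstruction finds the unique feasible orientation", {
  rec <- reconstruct_distributions(fcd_fixture("cutoff_rates"))
  expect_identical(rec$orientation, "b_is_fcd_cumulative")
  expect_identical(unname(rec$dist_pos$counts), c(2L, 7L, 12L, 6L, 2L, 0L, 0L))
  expect_identical(rec$dist_pos$n, 29L)
  expect_identical(rec$dist_neg$n, 11L)
  # forced by the 1.00 rate rows: no intact ear below score 2
  expect_identical(unname(rec$dist_neg$counts[c("0", "1")]), c(0L, 0L))
  expect_lt(rec$residual, 0.01)
  # the summed marginal equals the independently printed distribution
  expect_identical(unname(rec$dist_pos$counts + rec$dist_neg$counts),
                   unname(fcd_fixture("marginal_scores")))
})

test_that("reconstruction round-trip regenerates the printed rates", {
  rec <- reconstruct_distributions(fcd_fixture("cutoff_rates"))
  rates <- fcd_fixture("cutoff_rates")
  mt <- metrics_table(rec$dist_pos, rec$dist_neg)
  expect_true(all(abs(mt$sensitivity_intact_pos - rates$sensitivity) <= 0.005))
  expect_true(all(abs(mt$specificity_intact_pos - rates$specificity) <= 0.005))
})

test_that("infeasible or ambiguous rate tables raise explicit errors", {
  rates <- fcd_fixture("cutoff_rates")
  bad <- rates
  bad$specificity <- c(0, 0.5, 0.31, 0.72, 0.93, 1, 1)  # non-monotone cumulative
  expect_error(reconstruct_distributions(bad), "infeasible|ambiguous")
  expect_error(reconstruct_distributions(rates[-1, ]), "cutoff 0\\.\\.6")
  expect_error(reconstruct_distributions(rates, n_pos = 0), "positive")
})

test_that("verify_consistency passes on shipped fixtures", {
  rep <- verify_consistency()
  expect_true(all(rep$pass))
  expect_setequal(rep$check,
                  c("kappa_lateral", "kappa_inferior", "table2_percentages",
                    "reconstruction", "confusion_cutoff4", "marginal_scores",
                    "auc", "table3_roundtrip", "optimal_cutoff"))
})

test_that("fault injection fails only the targeted check", {
  lat <- fcd_fixture("crosstab_lateral")
  lat[2, 2] <- lat[2, 2] - 2L
  lat[2, 3] <- lat[2, 3] + 2L  # total still 40, agreement changed
  rep <- verify_consistency(fixtures = list(crosstab_lateral = lat))
  expect_false(rep$pass[rep$check == "kappa_lateral"])
  expect_true(all(rep$pass[rep$check != "kappa_lateral"]))

  marg <- fcd_fixture("marginal_scores")
  marg["0"] <- marg["0"] + 1L
  marg["1"] <- marg["1"] - 1L
  rep2 <- verify_consistency(fixtures = list(marginal_scores = marg))
  expect_false(rep2$pass[rep2$check == "marginal_scores"])
  expect_true(all(rep2$pass[rep2$check != "marginal_scores"]))
})

test_that("paper_cohort realizes every printed margin simultaneously", {
  cohort <- paper_cohort()
  expect_identical(nrow(cohort), 40L)
  expect_identical(anyDuplicated(cohort$ear_id), 0L)
  # observer cross-tabs per wall
  expect_equal(unname(score_crosstab(cohort$obs1_L, cohort$obs2_L)),
               unname(fcd_fixture("crosstab_lateral")))
  expect_equal(unname(score_crosstab(cohort$obs1_I, cohort$obs2_I)),
               unname(fcd_fixture("crosstab_inferior")))
  # consensus equals the shared score wherever the observers agree
  agree_L <- cohort$obs1_L == cohort$obs2_L
  expect_identical(cohort$consensus_L[agree_L], cohort$obs1_L[agree_L])
  agree_I <- cohort$obs1_I == cohort$obs2_I
  expect_identical(cohort$consensus_I[agree_I], cohort$obs1_I[agree_I])
  # consensus per-wall margins by surgical group
  wbg <- fcd_fixture("walls_by_group")
  pos <- cohort[cohort$surgical_finding == "dehiscent", ]
  neg <- cohort[cohort$surgical_finding == "intact", ]
  expect_identical(tabulate(pos$consensus_L + 1L, 4L),
                   wbg$fcd_n[wbg$wall == "lateral"])
  expect_identical(tabulate(neg$consensus_L + 1L, 4L),
                   wbg$control_n[wbg$wall == "lateral"])
  expect_identical(tabulate(pos$consensus_I + 1L, 4L),
                   wbg$fcd_n[wbg$wall == "inferior"])
  expect_identical(tabulate(neg$consensus_I + 1L, 4L),
                   wbg$control_n[wbg$wall == "inferior"])
  # composite-score distributions equal the reconstruction
  rec <- reconstruct_distributions(fcd_fixture("cutoff_rates"))
  expect_identical(
    unname(score_distribution(fcd_score(pos$consensus_L, pos$consensus_I))$counts),
    unname(rec$dist_pos$counts))
  expect_identical(
    unname(score_distribution(fcd_score(neg$consensus_L, neg$consensus_I))$counts),
    unname(rec$dist_neg$counts))
})
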