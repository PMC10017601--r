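# Hanley-McNeil standard error of an empirical AUC estimate.
auc_se <- function(a, n_pos, n_neg) {
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  sqrt((a * (1 - a) + (n_pos - 1) * (q1 - a^2) + (n_neg - 1) * (q2 - a^2)) /
         (n_pos * n_neg))
}

test_that("cohort_model validates its parameters", {
  expect_s3_class(cohort_model(), "cohort_model")
  expect_error(cohort_model(prevalence = 0), "prevalence")
  expect_error(cohort_model(pi_L_pos = c(0.5, 0.5, 0.1, 0)), "pi_L_pos")
  expect_error(cohort_model(epsilon_obs = 1), "epsilon_obs")
  expect_error(cohort_model(n_ears = 0), "n_ears")
})

test_that("identical seeds yield byte-identical cohorts and CSV exports", {
  m <- cohort_model(n_ears = 200, seed = 77L)
  c1 <- simulate_cohort(m)
  c2 <- simulate_cohort(m)
  expect_identical(c1$records, c2$records)
  f1 <- tempfile(); f2 <- tempfile(); g1 <- tempfile(); g2 <- tempfile()
  write_cohort_csv(c1$records, f1, g1)
  write_cohort_csv(c2$records, f2, g2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(g1), readLines(g2))
  # a different seed changes the draw
  c3 <- simulate_cohort(cohort_model(n_ears = 200, seed = 78L))
  expect_false(identical(c1$records, c3$records))
})

test_that("error-free observers reproduce the latent scores with kappa 1", {
  m <- cohort_model(n_ears = 300, epsilon_obs = 0, epsilon_consensus = 0,
                    probe_error = 0, seed = 5L)
  cohort <- simulate_cohort(m)$records
  expect_identical(cohort$obs1_L, cohort$latent_L)
  expect_identical(cohort$obs2_I, cohort$latent_I)
  expect_identical(cohort$surgical_finding, cohort$truth)
  expect_equal(cohen_kappa(score_crosstab(cohort$obs1_L, cohort$obs2_L))$kappa, 1)
  expect_equal(theoretical_kappa(m, "lateral"), 1)
})

test_that("prevalence 1 yields an all-dehiscent cohort flagged downstream", {
  m <- cohort_model(n_ears = 50, prevalence = 1, seed = 9L)
  cohort <- simulate_cohort(m)$records
  expect_true(all(cohort$surgical_finding == "dehiscent"))
  expect_error(score_distribution(integer(0)), "0\\.\\.6")
})

test_that("theoretical_kappa hits the independence and degenerate limits", {
  # one effective latent category: observers independent, kappa 0
  m0 <- cohort_model(pi_L_pos = c(0, 1, 0, 0), pi_L_neg = c(0, 1, 0, 0),
                     epsilon_obs = 0.3)
  expect_equal(theoretical_kappa(m0, "lateral"), 0, tolerance = 1e-12)
  mdeg <- cohort_model(pi_L_pos = c(0, 1, 0, 0), pi_L_neg = c(0, 1, 0, 0),
                       epsilon_obs = 0)
  expect_error(theoretical_kappa(mdeg, "lateral"), "degenerate")
})

test_that("theoretical_auc hits the 0.5 and 1 limits", {
  same <- cohort_model(pi_L_pos = c(0.2, 0.3, 0.4, 0.1),
                       pi_L_neg = c(0.2, 0.3, 0.4, 0.1),
                       pi_I_pos = c(0.1, 0.2, 0.3, 0.4),
                       pi_I_neg = c(0.1, 0.2, 0.3, 0.4))
  expect_equal(theoretical_auc(same), 0.5, tolerance = 1e-12)
  sep <- cohort_model(pi_L_pos = c(1, 0, 0, 0), pi_I_pos = c(0.5, 0.5, 0, 0),
                      pi_L_neg = c(0, 0, 1, 0), pi_I_neg = c(0, 0, 0.5, 0.5),
                      epsilon_consensus = 0)
  expect_equal(theoretical_auc(sep), 1, tolerance = 1e-12)
})

test_that("empirical kappa and AUC at n = 20000 match the closed forms", {
  m <- cohort_model(n_ears = 20000, seed = 2024L)
  cohort <- simulate_cohort(m)$records
  for (wall in c("lateral", "inferior")) {
    cols <- if (wall == "lateral") c("obs1_L", "obs2_L") else c("obs1_I", "obs2_I")
    kr <- cohen_kappa(score_crosstab(cohort[[cols[1]]], cohort[[cols[2]]]))
    expect_lt(abs(kr$kappa - theoretical_kappa(m, wall)), 3 * kr$se)
  }
  pos <- cohort$truth == "dehiscent"
  dp <- score_distribution(fcd_score(cohort$consensus_L, cohort$consensus_I)[pos],
                           "FCD")
  dn <- score_distribution(fcd_score(cohort$consensus_L, cohort$consensus_I)[!pos],
                           "control")
  a_emp <- as.numeric(auc_ordinal(dp, dn))
  a_th <- theoretical_auc(m)
  expect_lt(abs(a_emp - a_th), 3 * auc_se(a_th, dp$n, dn$n))
})

test_that("sensitivity and specificity recover within 0.03 over 20 seeds", {
  m0 <- cohort_model(n_ears = 5000, probe_error = 0)
  th <- theoretical_metrics(m0)
  best <- th$cutoff[which.max(th$youden)]
  sens <- spec <- numeric(20)
  for (i in 1:20) {
    cohort <- simulate_cohort(cohort_model(n_ears = 5000, seed = 100L + i))$records
    grp <- split_by_finding(cohort)
    dp <- score_distribution(fcd_score(grp$dehiscent$consensus_L,
                                       grp$dehiscent$consensus_I), "FCD")
    dn <- score_distribution(fcd_score(grp$intact$consensus_L,
                                       grp$intact$consensus_I), "control")
    cf <- confusion_at_cutoff(dp, dn, best)
    sens[i] <- cf$tp / dp$n
    spec[i] <- cf$tn / dn$n
  }
  expect_lt(abs(mean(sens) - th$sensitivity[th$cutoff == best]), 0.03)
  expect_lt(abs(mean(spec) - th$specificity[th$cutoff == best]), 0.03)
})

test_that("walls are conditionally independent given truth in the generator", {
  cohort <- simulate_cohort(cohort_model(n_ears = 20000, seed = 55L))$records
  pos <- cohort[cohort$truth == "dehiscent", ]
  tab <- table(factor(pos$consensus_L, 0:3), factor(pos$consensus_I, 0:3))
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
  expect_lt(mi, 0.01)  # plug-in bias is about df/(2n) ~ 3e-4 here
})

test_that("empirical per-group wall-score margins match the convolved model", {
  m <- cohort_model(n_ears = 5000, seed = 321L)
  cohort <- simulate_cohort(m)$records
  K <- fcdscore:::confusion_kernel(m$epsilon_obs)
  expected <- as.numeric(t(K) %*% m$pi_L_pos)  # observer margin given truth
  pos <- cohort$truth == "dehiscent"
  emp <- tabulate(cohort$obs1_L[pos] + 1L, 4L) / sum(pos)
  expect_true(max(abs(emp - expected)) < 0.02)
})
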