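test_that("median split halves the cohort with ties to the low group", {
  expect_equal(unname(median_split(c(1, 2, 3, 4))), c("low", "low", "high", "high"))
  expect_equal(unname(median_split(c(1, 2, 2, 3))), c("low", "low", "low", "high"))
  set.seed(9)
  s <- runif(1000)
  expect_true(sum(median_split(s) == "high") %in% c(499L, 500L))
  expect_error(median_split(rep(1, 10)), "degenerate")
  expect_error(median_split(c(1, 2)), ">= 4")
})

test_that("Kaplan-Meier estimator matches the closed form on small samples", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n_risk, c(3L, 2L, 1L))
  all_cens <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_equal(nrow(all_cens), 0L)   # S identically 1, no steps
  # censored observations shrink the risk set without a step
  km2 <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$survival, c(2 / 3, 0))
  expect_true(all(diff(km2$survival) <= 0) && all(km2$survival >= 0))
})

test_that("Kaplan-Meier curve agrees with the survival package", {
  skip_if_not_installed("survival")
  surv <- gen_survival_cohort(200, hr = 0.5, censoring_rate = 0.3, seed = 5)
  km <- km_estimate(surv$time_months, surv$event)
  fit <- survival::survfit(survival::Surv(time_months, event) ~ 1, data = surv)
  idx <- fit$n.event > 0
  expect_equal(km$time, fit$time[idx], tolerance = 1e-12)
  expect_equal(km$survival, fit$surv[idx], tolerance = 1e-12)
})

test_that("log-rank statistic is null on identical groups and matches survdiff", {
  t <- c(3, 5, 7, 9, 11, 13); e <- c(1, 0, 1, 1, 0, 1)
  lr <- logrank_test(c(t, t), c(e, e), rep(c("a", "b"), each = 6))
  expect_equal(lr$statistic, 0)
  expect_equal(lr$p_value, 1)
  skip_if_not_installed("survival")
  surv <- gen_survival_cohort(300, hr = 0.6, censoring_rate = 0.2, seed = 3)
  lr2 <- logrank_test(surv$time_months, surv$event, surv$group)
  sd2 <- survival::survdiff(survival::Surv(time_months, event) ~ group,
                            data = surv)
  expect_equal(lr2$statistic, sd2$chisq, tolerance = 1e-8)
})

test_that("log-rank is invariant to time-unit rescaling", {
  surv <- gen_survival_cohort(200, hr = 0.5, seed = 8)
  a <- logrank_test(surv$time_months, surv$event, surv$group)
  b <- logrank_test(surv$time_months * 30.44, surv$event, surv$group)
  expect_equal(a$statistic, b$statistic)
})

test_that("binary Cox fit recovers planted hazard ratios and matches coxph", {
  surv <- gen_survival_cohort(1000, hr = 0.4, censoring_rate = 0, seed = 3)
  cx <- cox_hr_binary(surv$time_months, surv$event, surv$group)
  expect_gt(cx$hr, 0.32); expect_lt(cx$hr, 0.50)
  expect_true(cx$ci_low < cx$hr && cx$hr < cx$ci_high)
  skip_if_not_installed("survival")
  fit <- survival::coxph(survival::Surv(time_months, event) ~ group == "high",
                         data = surv, ties = "breslow")
  expect_equal(cx$log_hr, unname(stats::coef(fit)), tolerance = 1e-6)
  expect_equal(cx$se, sqrt(unname(stats::vcov(fit)[1, 1])), tolerance = 1e-6)
  # Efron ties agree with coxph too
  cxe <- cox_hr_binary(ceiling(surv$time_months), surv$event,
                       surv$group, ties = "efron")
  fite <- survival::coxph(
    survival::Surv(ceiling(time_months), event) ~ group == "high",
    data = surv, ties = "efron")
  expect_equal(cxe$log_hr, unname(stats::coef(fite)), tolerance = 1e-5)
})

test_that("null data give hazard ratios near 1 and degenerate cases are flagged", {
  surv <- gen_survival_cohort(500, hr = 1, censoring_rate = 0, seed = 12)
  cx <- cox_hr_binary(surv$time_months, surv$event, surv$group)
  expect_lt(abs(cx$log_hr), 0.25)
  one_event <- cox_hr_binary(c(1, 2, 3, 4), c(1, 0, 0, 0),
                             c("high", "high", "low", "low"))
  expect_true(one_event$degenerate)
})

test_that("Cox log-HR bias shrinks with sample size on planted data", {
  bias <- vapply(c(100, 400, 1600), function(n) {
    est <- vapply(1:5, function(s) {
      surv <- gen_survival_cohort(n, hr = 0.4, censoring_rate = 0,
                                  seed = 1000 * s + n)
      cox_hr_binary(surv$time_months, surv$event, surv$group)$log_hr
    }, 0)
    abs(mean(est) - log(0.4))
  }, 0)
  expect_lt(bias[3], 0.1)
  expect_lt(bias[3], bias[1] + 0.05)
})

test_that("signature scores average the signature genes present", {
  mat <- rbind(A = c(2, 4), B = c(4, 6), C = c(9, 9))
  colnames(mat) <- c("s1", "s2")
  expect_equal(as.numeric(signature_score(mat, c("A", "B"))), c(3, 5))
  expect_equal(as.numeric(signature_score(mat, "A")), c(2, 4))
  sc <- signature_score(mat, c("A", "B", "MISSING"))
  expect_equal(attr(sc, "missing_genes"), "MISSING")
  expect_error(signature_score(mat, "NOPE"), "no signature gene")
})

test_that("strict prognostic filter applies the p, HR and case-count gates", {
  crit <- screen_criteria()
  surv <- gen_survival_cohort(500, hr = 0.4, censoring_rate = 0.1, seed = 21)
  unit <- data.frame(cohort_id = "K1", time = surv$time_months,
                     event = surv$event, score = surv$score)
  res <- screen_prognostic(list(g1 = unit), crit)
  expect_true(res$passes_strict)
  expect_true(res$passes_default)
  # small cohort fails on the case-count gate alone
  small <- gen_survival_cohort(100, hr = 0.4, censoring_rate = 0, seed = 22)
  res2 <- screen_prognostic(list(g1 = data.frame(
    cohort_id = "K2", time = small$time_months, event = small$event,
    score = small$score)), crit)
  expect_false(res2$passes_strict)
  # HR gate: effect too weak for the strict filter even when significant
  weak <- gen_survival_cohort(2000, hr = 0.7, censoring_rate = 0, seed = 23)
  res3 <- screen_prognostic(list(g1 = data.frame(
    cohort_id = "K3", time = weak$time_months, event = weak$event,
    score = weak$score)), crit)
  expect_false(res3$passes_strict)
  expect_lt(res3$logrank_p, 0.001)
})

test_that("signature screening recovers the planted prognostic direction", {
  hits <- vapply(1:10, function(s) {
    surv <- gen_survival_cohort(400, hr = 0.4, censoring_rate = 0.2,
                                seed = 500 + s)
    # six signature genes correlated with the prognostic group score
    mat <- t(vapply(1:6, function(i) surv$score * 2 + rnorm(400, sd = 0.3),
                    numeric(400)))
    rownames(mat) <- sprintf("SIG%d", 1:6)
    colnames(mat) <- surv$sample
    sc <- signature_score(mat, rownames(mat))
    unit <- survival_unit_table(surv, sc, "K")
    res <- screen_prognostic(list(sig1 = unit), screen_criteria())
    res$hr < 1
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})
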