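test_that("confounder model specifications nest", {
  s1 <- cox_model_spec(1); s2 <- cox_model_spec(2); s3 <- cox_model_spec(3)
  expect_true(all(s1$covariates %in% s2$covariates))
  expect_true(all(s2$covariates %in% s3$covariates))
  expect_true("income" %in% s3$covariates && !"income" %in% s2$covariates)
  expect_error(cox_model_spec(4), "level")
})

test_that("single-source fit on a null cohort centers on zero", {
  prof <- default_source_profiles()
  coh <- generate_cohort(prof, cohort_config(
    n_participants = 6000,
    true_log_hr = setNames(rep(0, 5), prof$sources), seed = 31))
  fit <- fit_cox(coh, "true_oil", cox_model_spec(1))
  expect_lt(abs(fit$beta / fit$table$se), 3)
  expect_equal(fit$model, "single-source")
})

test_that("a known oil hazard is recovered within sampling error end to end through the Cox module", {
  coh <- small_cohort()
  fit <- fit_cox(coh, source_cols(), cox_model_spec(3))
  truth <- cohort_config()$true_log_hr
  z <- (fit$beta[["true_oil"]] - truth[["oil"]]) / fit$table$se[fit$table$exposure == "true_oil"]
  expect_lt(abs(z), 3)
  expect_equal(fit$model, "multisource")
  expect_equal(fit$events, sum(coh$event))
})

test_that("the stratified fit is invariant to relabeling subcohorts", {
  coh <- small_cohort()
  fit1 <- fit_cox(coh, "true_traffic", cox_model_spec(1))
  relab <- coh
  relab$subcohort <- c(9, 3, 7, 1)[relab$subcohort]
  fit2 <- fit_cox(relab, "true_traffic", cox_model_spec(1))
  expect_equal(fit1$beta, fit2$beta, tolerance = 1e-10)
})

test_that("degenerate and invalid inputs are rejected", {
  coh <- small_cohort()
  expect_error(fit_cox(coh, character(0)), "no exposure")
  expect_error(fit_cox(coh, "nope", cox_model_spec(1)), "nope")
  tiny <- coh[1:8, ]
  tiny$subcohort <- 1:8   # one subject per stratum
  expect_error(fit_cox(tiny, "true_oil", cox_model_spec(1)), "fewer than 2")
  bad <- coh
  bad$exit_age[1] <- bad$entry_age[1]
  expect_error(fit_cox(bad, "true_oil", cox_model_spec(1)), "entry age")
})

test_that("hazard ratios transform correctly for arbitrary increments", {
  coh <- small_cohort()
  fit <- fit_cox(coh, source_cols(), cox_model_spec(1))
  t <- fit$table
  # per-IQR equals per-unit raised to the IQR power
  expect_equal(t$hr_per_iqr, t$hr_per_unit^t$iqr, tolerance = 1e-12)
  h0 <- hr_per_increment(fit, setNames(rep(0, 5), t$exposure))
  expect_equal(h0$hr, rep(1, 5))
  expect_equal(h0$ci_low, rep(1, 5))
  h1 <- hr_per_increment(fit, setNames(rep(1, 5), t$exposure))
  expect_equal(h1$hr, t$hr_per_unit)
  expect_error(hr_per_increment(fit, 1:2), "one increment")
})

test_that("cumulative risk index identities hold exactly", {
  fake <- structure(list(
    table = data.frame(exposure = c("a", "b"),
                       beta = c(log(1.05), log(1.10)),
                       se = c(0.01, 0.02),
                       iqr = c(1, 1)),
    beta = setNames(c(log(1.05), log(1.10)), c("a", "b")),
    vcov = diag(c(1e-4, 4e-4))), class = "hazard_result")
  cri <- cumulative_risk_index(fake, c(a = 1, b = 1))
  expect_equal(cri$cri, 1.155)
  # single-source reduction
  fake1 <- structure(list(
    table = data.frame(exposure = "a", beta = log(1.13), se = 0.04, iqr = 2),
    beta = c(a = log(1.13)), vcov = matrix(16e-4)), class = "hazard_result")
  cri1 <- cumulative_risk_index(fake1, c(a = 1))
  expect_equal(cri1$cri, 1.13)
  expect_equal(cumulative_risk_index(fake1, c(a = 2))$cri, 1.13^2)
  # null reduction: CRI = 1 with CI containing 1
  fake0 <- fake
  fake0$beta[] <- 0
  cri0 <- cumulative_risk_index(fake0, c(a = 1, b = 1))
  expect_equal(cri0$cri, 1)
  expect_true(cri0$ci_low <= 1 && cri0$ci_high >= 1)
  expect_error(cumulative_risk_index(fake, c(a = 1)), "one increment per")
})

test_that("the delta-method CI matches the fitted covariance on a real fit", {
  coh <- small_cohort()
  fit <- fit_cox(coh, source_cols(), cox_model_spec(1))
  x <- setNames(fit$table$iqr, fit$table$exposure)
  cri <- cumulative_risk_index(fit, x)
  v <- drop(t(x) %*% fit$vcov %*% x)
  expect_equal(cri$se, sqrt(v))
  expect_equal(cri$cri, exp(sum(fit$beta * x)))
})

test_that("multisource and single-source estimates agree for independent exposures", {
  prof <- default_source_profiles()
  cfg <- cohort_config(n_participants = 8000, seed = 37,
                       exposure_config = campaign_config(
                         source_correlation = diag(5), seed = 37))
  coh <- generate_cohort(prof, cfg)
  multi <- fit_cox(coh, source_cols(), cox_model_spec(1))
  for (s in c("true_oil", "true_traffic")) {
    single <- fit_cox(coh, s, cox_model_spec(1))
    diff <- abs(multi$beta[[s]] - single$beta[[s]])
    pooled_se <- sqrt(multi$table$se[multi$table$exposure == s]^2 +
                        single$table$se[single$table$exposure == s]^2)
    expect_lt(diff, 3 * pooled_se)
  }
})

test_that("selection bias check: ratio is exactly 1 when nothing is excluded and departs under outcome-dependent missingness", {
  coh <- small_cohort()
  same <- selection_bias_check(coh, coh, "true_oil")
  expect_equal(same$hr_ratio, 1, tolerance = 1e-12)

  # ignorable missingness: completely random 20% exclusion
  set.seed(41)
  keep <- runif(nrow(coh)) > 0.2
  mcar <- selection_bias_check(coh, coh[keep, ], source_cols())
  expect_lt(max(abs(log(mcar$hr_ratio))), 0.15)

  # adversarial: preferentially drop high-traffic-exposure cases
  risky <- coh$event == 1 & coh$true_traffic > median(coh$true_traffic)
  drop <- risky & runif(nrow(coh)) < 0.6
  adv <- selection_bias_check(coh, coh[!drop, ], "true_traffic")
  expect_lt(adv$hr_ratio, 1)
})
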