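test_that("projecting the monitoring sites reproduces the training contributions bit for bit", {
  camp <- std_campaign()
  model <- std_model()
  proj <- project_exposures(camp$table, model, quiet = TRUE)
  expect_identical(proj$contributions, model$contributions$contributions)
  expect_identical(proj$intercept, model$contributions$intercept)
})

test_that("a participant with zero exposures gets zero source mass and total b0", {
  model <- std_model()
  polls <- c("NO2", "BC", "Cu", "Fe", "K", "Ni", "Si", "V", "Zn")
  zero <- as.data.frame(as.list(setNames(rep(0, length(polls)), polls)))
  proj <- project_exposures(zero, model, quiet = TRUE)
  expect_equal(unname(unlist(proj$contributions)), rep(0, 5),
               tolerance = 1e-12)
  expect_equal(proj$fitted, model$intercept, tolerance = 1e-12)
})

test_that("projection is affine: convex combinations of rows map to the same combinations of masses", {
  camp <- std_campaign()
  model <- std_model()
  polls <- c("NO2", "BC", "Cu", "Fe", "K", "Ni", "Si", "V", "Zn")
  a <- camp$table[1, polls]
  b <- camp$table[2, polls]
  lam <- 0.3
  mix <- lam * a + (1 - lam) * b
  pa <- as.matrix(project_exposures(a, model, quiet = TRUE)$contributions)
  pb <- as.matrix(project_exposures(b, model, quiet = TRUE)$contributions)
  pm <- as.matrix(project_exposures(mix, model, quiet = TRUE)$contributions)
  expect_equal(pm, lam * pa + (1 - lam) * pb, tolerance = 1e-10)
})

test_that("projections are invariant to a consistent unit rescaling of a pollutant", {
  camp <- std_campaign()
  model <- std_model()
  scaled_model <- model
  # express Ni in ng/m3 instead of ug/m3 in both data and stored parameters
  i <- match("Ni", model$standardization$pollutants)
  scaled_model$standardization$mean[i] <- model$standardization$mean[i] * 1000
  scaled_model$standardization$sd[i] <- model$standardization$sd[i] * 1000
  tab <- camp$table
  tab$Ni <- tab$Ni * 1000
  p0 <- project_exposures(camp$table, model, quiet = TRUE)
  p1 <- project_exposures(tab, scaled_model, quiet = TRUE)
  expect_equal(p1$contributions, p0$contributions, tolerance = 1e-9)
})

test_that("cohort projections track the generating source masses at low noise", {
  model <- std_model()
  coh <- small_cohort()
  proj <- project_exposures(coh, model, quiet = TRUE)
  for (s in default_source_profiles()$sources) {
    expect_gt(cor(proj$contributions[[s]], coh[[paste0("true_", s)]]), 0.85)
  }
})

test_that("exposure summaries use the linear-interpolation quantile convention", {
  x <- data.frame(src = c(1, 2, 3, 4, 100))
  s <- summarize_exposures(x)
  # brute-force type-7 interpolation oracle
  q7 <- function(v, p) {
    v <- sort(v); h <- (length(v) - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    v[lo] + (h - lo) * (v[hi] - v[lo])
  }
  expect_equal(s$p25, q7(x$src, 0.25))
  expect_equal(s$p75, q7(x$src, 0.75))
  expect_equal(s$p5, q7(x$src, 0.05))
  expect_equal(s$iqr, q7(x$src, 0.75) - q7(x$src, 0.25))
  # constant exposure has zero IQR
  expect_equal(summarize_exposures(data.frame(c = rep(2, 10)))$iqr, 0)
})

test_that("a fixture tuned to a 2.86 traffic IQR is measured as 2.86", {
  # quartiles of the fixture sit at 1.0 and 3.86 by construction
  traffic <- c(0.2, 1.0, 1.0, 1.0, 2.0, 2.9, 3.86, 3.86, 3.86, 5.4)
  s <- summarize_exposures(data.frame(traffic = traffic))
  expect_equal(s$iqr, 2.86)
})

test_that("grouped summaries cover every group and source", {
  coh <- small_cohort()
  model <- std_model()
  proj <- project_exposures(coh, model, quiet = TRUE)
  s <- summarize_exposures(proj, grouping = coh$subcohort)
  expect_equal(nrow(s), length(unique(coh$subcohort)) * 5)
  expect_true(all(s$iqr >= 0))
})
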