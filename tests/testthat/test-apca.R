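test_that("standardization matches hand computation and is invertible", {
  df <- data.frame(x = c(1, 2, 3, 4), y = c(10, 10, 20, 40))
  out <- standardize(df, c("x", "y"))
  expect_equal(unname(out$standardization$mean), c(2.5, 20))
  expect_equal(unname(out$standardization$sd),
               c(sd(df$x), sqrt(200)))
  expect_lt(max(abs(colMeans(out$z))), 1e-12)
  expect_equal(unname(apply(out$z, 2, sd)), c(1, 1))
  # round trip
  back <- sweep(sweep(out$z, 2, out$standardization$sd, "*"),
                2, out$standardization$mean, "+")
  expect_equal(unname(back), unname(as.matrix(df)), tolerance = 1e-14)
  df$z <- 5
  expect_error(standardize(df, c("x", "z")), "z")
})

test_that("two-pollutant PCA has the closed-form eigenvalues 1 +/- r", {
  set.seed(10)
  x <- rnorm(80)
  y <- 0.6 * x + rnorm(80)
  z <- standardize(data.frame(x = x, y = y), c("x", "y"))$z
  r <- cor(z)[1, 2]
  p <- fit_pca(z, 2)
  expect_equal(p$eigenvalues, c(1 + abs(r), 1 - abs(r)), tolerance = 1e-12)
})

test_that("full-rank loadings reproduce the correlation matrix spectrally", {
  camp <- std_campaign()
  z <- standardize(camp$table, pca_pollutants(adjust_k = FALSE))$z
  p <- fit_pca(z, ncol(z))
  expect_equal(p$loadings %*% t(p$loadings), p$cormat, tolerance = 1e-10,
               ignore_attr = TRUE)
  # sign convention: dominant loading of each factor is positive
  expect_true(all(apply(p$loadings, 2, function(l) l[which.max(abs(l))]) > 0))
})

test_that("varimax leaves rank-1 structure unchanged up to sign", {
  l <- matrix(c(0.9, 0.8, 0.7, 0.6), 4, 1,
              dimnames = list(paste0("p", 1:4), "F1"))
  sol <- rotate_loadings(l, method = "varimax")
  expect_equal(unname(sol$pattern), unname(l), tolerance = 1e-12)
})

test_that("promax pattern matches an independent Procrustes-definition oracle", {
  camp <- std_campaign()
  z <- standardize(camp$table, pca_pollutants(adjust_k = FALSE))$z
  load <- fit_pca(z, 5)$loadings
  kappa <- 1.6
  sol <- rotate_loadings(load, method = "promax", kappa = kappa)

  # textbook construction, coded independently: varimax, then oblique
  # Procrustes toward the |loading|^kappa * sign(loading) target
  v <- stats::varimax(load, normalize = TRUE)
  lv <- unclass(v$loadings)
  q <- sign(lv) * abs(lv)^kappa
  u <- solve(t(lv) %*% lv) %*% t(lv) %*% q
  u <- u %*% diag(sqrt(diag(solve(t(u) %*% u))))
  pat <- lv %*% u
  phi <- solve(t(u) %*% u)
  # align oracle columns to the canonical (sorted, sign-fixed) solution
  mt <- match_factors(sol$pattern, pat)
  ord <- mt$assignment$candidate
  expect_equal(unname(sol$pattern),
               unname(sweep(pat[, ord], 2, mt$assignment$sign, "*")),
               tolerance = 1e-8)
  expect_equal(unname(sol$factor_correlation),
               unname(sweep(sweep(phi[ord, ord], 1, mt$assignment$sign, "*"),
                            2, mt$assignment$sign, "*")),
               tolerance = 1e-8)
})

test_that("factor correlation is a valid correlation matrix and rotated variance partitions", {
  sol <- std_model()$solution
  phi <- sol$factor_correlation
  expect_equal(unname(diag(phi)), rep(1, 5))
  expect_equal(phi, t(phi), tolerance = 1e-12)
  expect_true(all(sol$eigenvalues > 0))
  expect_equal(sol$eigenvalues, sort(sol$eigenvalues, decreasing = TRUE))
  expect_lte(max(sol$cumulative_variance), 1 + 1e-10)
})

test_that("regression scoring weights equal the loadings for an orthonormal solution", {
  set.seed(12)
  l <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  sol <- structure(list(pattern = l, factor_correlation = diag(5)),
                   class = "rotated_solution")
  w <- score_coefficients(sol, diag(5))
  expect_equal(unname(w), unname(l), tolerance = 1e-12)
})

test_that("full-rank varimax scoring reconstructs the standardized data", {
  camp <- std_campaign()
  z <- standardize(camp$table, pca_pollutants(adjust_k = FALSE))$z
  p <- fit_pca(z, ncol(z))
  sol <- rotate_loadings(p$loadings, method = "varimax")
  w <- score_coefficients(sol, p$cormat)
  expect_equal(z %*% w %*% t(sol$pattern), z, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("absolute scores vanish for the all-zero sample and the map is affine", {
  model <- std_model()
  polls <- c("NO2", "BC", "Cu", "Fe", "K", "Ni", "Si", "V", "Zn")
  zero <- as.data.frame(as.list(setNames(rep(0, length(polls)), polls)))
  expect_equal(unname(absolute_scores(zero, model)[1, ]), rep(0, 5),
               tolerance = 1e-12)
  # doubling concentrations doubles the absolute score (linear through 0)
  rec <- std_campaign()$table[3, ]
  s1 <- absolute_scores(rec, model)
  rec2 <- rec
  rec2[polls] <- 2 * rec2[polls]
  expect_equal(unname(absolute_scores(rec2, model)), unname(2 * s1),
               tolerance = 1e-10)
  expect_error(absolute_scores(rec[c("NO2", "BC")], model), "K, Si")
  norm_cols <- c("NO2", "BC", "Cu", "Fe", "Kw", "Ni")
  rec_kw <- rec
  rec_kw$Kw <- rec_kw$K - model$soil_k$slope * rec_kw$Si
  expect_error(absolute_scores(rec_kw[norm_cols], model), "Si")
})

test_that("an exactly linear PM2.5 is apportioned to machine precision", {
  set.seed(13)
  apcs <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  b <- c(2, -1, 0.5)
  pm <- 4 + drop(apcs %*% b)
  out <- suppressMessages(apportion_mass(pm, apcs))
  expect_equal(out$mass_coefficients$slope, b, tolerance = 1e-10)
  expect_equal(out$intercept, 4, tolerance = 1e-10)
  expect_equal(out$fitted, pm, tolerance = 1e-10)
  # all-positive contributions give a zero negative fraction
  apcs2 <- matrix(abs(rnorm(200)), 100, 2)
  out2 <- apportion_mass(abs(rnorm(100)) + drop(apcs2 %*% c(1, 2)), apcs2)
  expect_equal(out2$negative_fraction, 0)
  expect_error(apportion_mass(pm, apcs[, c(1, 1, 2)]), "rank")
})

test_that("sulfur apportionment recovers a single-channel construction and matches the OLS oracle", {
  model <- std_model()
  contrib <- model$contributions
  x <- as.matrix(contrib$contributions)
  s_single <- 0.3 * x[, "oil"]
  sc <- apportion_sulfur(s_single, contrib)
  expect_equal(sc$slope[sc$source == "oil"], 0.3, tolerance = 1e-8)
  expect_lt(max(abs(sc$slope[!sc$source %in% c("oil")])), 1e-8)

  set.seed(14)
  s_rand <- rlnorm(nrow(x), 0, 0.3)
  sc2 <- apportion_sulfur(s_rand, contrib)
  oracle <- unname(coef(lm(s_rand ~ x)))
  expect_equal(sc2$slope, oracle, tolerance = 1e-10)

  # orthogonal-by-construction sulfur: slopes ~ 0, intercept ~ mean
  resid_s <- residuals(lm(s_rand ~ x)) + mean(s_rand)
  sc3 <- apportion_sulfur(resid_s, contrib)
  expect_lt(max(abs(sc3$slope[-1])), 1e-10)
  expect_equal(sc3$slope[1], mean(s_rand), tolerance = 1e-10)
})

test_that("source profiles recover generating fractions and the normal-equations oracle", {
  model <- std_model()
  contrib <- model$contributions
  x <- as.matrix(contrib$contributions)
  # a pollutant that IS one source's contribution loads 1 on it, 0 elsewhere
  fake <- data.frame(copy = x[, "traffic"])
  pr <- source_profiles(fake, contrib)
  expect_equal(pr$fraction[pr$source == "traffic"], 1, tolerance = 1e-8)
  expect_lt(max(abs(pr$fraction[!pr$source %in% c("traffic")])), 1e-8)

  # normal-equations oracle on a real pollutant
  bc <- std_campaign()$table$BC
  pr2 <- source_profiles(data.frame(BC = bc), contrib)
  xx <- cbind(1, x)
  oracle <- drop(solve(t(xx) %*% xx, t(xx) %*% bc))
  expect_equal(pr2$fraction, unname(oracle), tolerance = 1e-8)

  # the generating traffic-BC mass fraction (0.252) is recovered at low noise
  bc_hat <- pr2$fraction[pr2$source == "traffic"]
  expect_lt(abs(bc_hat - 0.252), 0.02)
})

test_that("factor matching recovers permutations, signs, and survives noise", {
  set.seed(15)
  ref <- matrix(rnorm(45), 9, 5)
  perm <- c(3, 5, 1, 2, 4)
  cand <- ref[, perm]
  cand[, 2] <- -cand[, 2]
  mt <- match_factors(ref, cand)
  expect_equal(order(perm), mt$assignment$candidate[order(mt$assignment$reference)])
  expect_equal(mt$assignment$congruence, rep(1, 5), tolerance = 1e-12)
  expect_equal(mt$assignment$sign[mt$assignment$candidate == 2], -1)

  self <- match_factors(ref, ref)
  expect_equal(self$assignment$candidate, 1:5)

  noisy <- ref + matrix(rnorm(45, 0, 0.02), 9, 5)
  expect_true(all(match_factors(ref, noisy)$assignment$congruence >= 0.99))

  # unequal factor counts: min matched, surplus reported
  mt2 <- match_factors(ref[, 1:3], ref)
  expect_equal(nrow(mt2$assignment), 3)
  expect_equal(sort(mt2$unmatched$candidate), c(4, 5))
})

test_that("the five-factor solution satisfies the retention rules on the standard fixture", {
  sol <- std_model()$solution
  expect_true(all(sol$eigenvalues > 1.0))
  expect_gt(max(sol$cumulative_variance), 0.80)
})

test_that("stratified folds partition the site set and degenerate k is rejected", {
  camp <- std_campaign()
  expect_error(kfold_robustness(camp$table, k = 1), "at least 2")
  rb <- suppressWarnings(suppressMessages(
    kfold_robustness(camp$table[1:100, ], k = 5, seed = 3)))
  expect_length(rb$folds, 100)
  expect_setequal(unique(rb$folds), 1:5)
  expect_equal(sum(tabulate(rb$folds, 5)), 100)
})
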