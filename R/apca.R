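# Absolute principal component analysis (APCA) receptor model.
#
# The method: (a) z-score the pollutant matrix and run a correlation-matrix
# PCA; (b) rotate the retained components (Varimax or Promax) and identify
# sources from their tracer loadings; (c) convert component scores to
# absolute scores by subtracting the score of an artificial sample whose raw
# concentrations are all zero; (d) regress PM2.5 mass on the absolute scores
# to apportion mass to each source, with unapportioned mass in the
# intercept.  Sulfur, excluded from the source-identification PCA, is
# apportioned afterwards by regressing it on the source contributions.

#' Default pollutant set entering the source-identification PCA
#'
#' Sulfur and PM2.5 are excluded by default: S is a general marker of
#' fossil-fuel combustion formed secondarily, and keeping it out sharpens
#' the separation of primary sources.  Potassium enters as its soil-adjusted
#' form `Kw` when the adjustment is applied.
#' @param adjust_k use soil-adjusted potassium (`Kw`) instead of raw `K`.
#' @param include_sulfur add `S` to the PCA pollutant set (sensitivity
#'   analysis).
#' @return Character vector of pollutant column names.
#' @export
pca_pollutants <- function(adjust_k = TRUE, include_sulfur = FALSE) {
  p <- c("NO2", "BC", "Cu", "Fe", if (adjust_k) "Kw" else "K",
         "Ni", "Si", "V", "Zn")
  if (include_sulfur) p <- c(p, "S")
  p
}

#' Z-score a pollutant matrix, storing the standardization
#'
#' @param table data frame containing the pollutant columns.
#' @param pollutants pollutant column names, in the order to be stored.
#' @return A list with `z` (the standardized matrix) and `standardization`
#'   (per-pollutant mean and standard deviation, denominator `n - 1`, plus
#'   the stored pollutant order).
#' @export
standardize <- function(table, pollutants) {
  x <- as.matrix(table[pollutants])
  if (!all(is.finite(x))) stop("non-finite values in pollutant matrix")
  sdv <- apply(x, 2, stats::sd)
  if (any(sdv == 0))
    stop("zero-variance pollutant column(s): ",
         paste(pollutants[sdv == 0], collapse = ", "))
  mu <- colMeans(x)
  z <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
  list(z = z,
       standardization = list(mean = mu, sd = sdv, pollutants = pollutants))
}

#' Principal component analysis of the pollutant correlation matrix
#'
#' Loadings are the eigenvectors of the correlation matrix scaled by the
#' square root of their eigenvalues, with each component's sign flipped so
#' its largest-magnitude loading is positive.
#'
#' @param z standardized pollutant matrix.
#' @param n_factors number of components to retain.
#' @return A list with `loadings` (pollutants x factors), `eigenvalues`
#'   (all, descending) and `cormat` (the correlation matrix).
#' @export
fit_pca <- function(z, n_factors) {
  if (!all(is.finite(z))) stop("non-finite values in input")
  if (n_factors > ncol(z)) stop("n_factors exceeds the number of pollutants")
  r <- stats::cor(z)
  e <- eigen(r, symmetric = TRUE)
  load <- e$vectors[, seq_len(n_factors), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(n_factors)], 0)), n_factors)
  for (j in seq_len(n_factors)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  rownames(load) <- colnames(z)
  colnames(load) <- paste0("F", seq_len(n_factors))
  list(loadings = load, eigenvalues = e$values, cormat = r)
}

# Flip factor signs so the dominant loading of each factor is positive
# (ties broken by first pollutant in stored order), and reorder factors by
# decreasing rotated eigenvalue.  Phi is permuted/reflected consistently.
.canonicalize <- function(pattern, phi, ss) {
  k <- ncol(pattern)
  for (j in seq_len(k)) {
    i <- which.max(abs(pattern[, j]))
    if (pattern[i, j] < 0) {
      pattern[, j] <- -pattern[, j]
      phi[j, ] <- -phi[j, ]
      phi[, j] <- -phi[, j]
    }
  }
  ord <- order(ss, decreasing = TRUE)
  list(pattern = pattern[, ord, drop = FALSE],
       phi = phi[ord, ord, drop = FALSE], ss = ss[ord])
}

#' Rotate a PCA loading matrix (Varimax or Promax)
#'
#' Varimax maximizes the standard Kaiser row-normalized varimax criterion.
#' Promax follows it with an oblique Procrustes rotation toward the
#' elementwise `|loading|^kappa * sign(loading)` target, allowing the
#' factors to correlate.
#'
#' @param loadings unrotated loading matrix (pollutants x factors).
#' @param method `"promax"` (default) or `"varimax"`.
#' @param kappa Promax power (default 1.6).
#' @param eigenvalue_basis how the per-factor variance after rotation is
#'   computed for oblique solutions: `"partition"` (default) is the column
#'   sum of pattern times structure loadings, the standard oblique
#'   decomposition that sums to the total communality so the cumulative
#'   fraction stays in (0, 1]; `"structure"` and `"pattern"` are the column
#'   sums of squared structure or pattern loadings.  All three coincide for
#'   orthogonal rotations.
#' @return An object of class `rotated_solution`: `pattern`,
#'   `factor_correlation`, `eigenvalues` (after rotation, descending),
#'   `cumulative_variance` (per-factor cumulative fraction of total
#'   variance), `rotation`, `kappa`, `n_factors`.  Factors are ordered by
#'   decreasing rotated eigenvalue with the dominant loading of each factor
#'   made positive.
#' @export
rotate_loadings <- function(loadings, method = c("promax", "varimax"),
                            kappa = 1.6,
                            eigenvalue_basis = c("partition", "structure",
                                                 "pattern")) {
  method <- match.arg(method)
  eigenvalue_basis <- match.arg(eigenvalue_basis)
  k <- ncol(loadings)
  if (k == 1) {
    pattern <- loadings
    phi <- diag(1)
  } else if (method == "varimax") {
    v <- stats::varimax(loadings, normalize = TRUE)
    pattern <- unclass(v$loadings)
    phi <- diag(k)
  } else {
    if (kappa <= 1) stop("promax kappa must exceed 1")
    pr <- stats::promax(loadings, m = kappa)
    pattern <- unclass(pr$loadings)
    # factor correlation of the oblique solution: with pattern = L %*% U,
    # Phi = (U'U)^{-1}; promax's column normalization makes diag(Phi) = 1
    u <- pr$rotmat
    phi <- solve(t(u) %*% u)
    phi <- (phi + t(phi)) / 2
  }
  structure_mat <- pattern %*% phi
  ss <- switch(eigenvalue_basis,
               partition = colSums(pattern * structure_mat),
               structure = colSums(structure_mat^2),
               pattern = colSums(pattern^2))
  cc <- .canonicalize(pattern, phi, ss)
  dimnames(cc$pattern) <- list(rownames(loadings), paste0("F", seq_len(k)))
  dimnames(cc$phi) <- list(colnames(cc$pattern), colnames(cc$pattern))
  structure(list(n_factors = k,
                 pattern = cc$pattern,
                 factor_correlation = cc$phi,
                 eigenvalues = unname(cc$ss),
                 cumulative_variance = cumsum(unname(cc$ss)) / nrow(loadings),
                 rotation = method,
                 kappa = if (method == "promax") kappa else NA_real_),
            class = "rotated_solution")
}

#' @export
print.rotated_solution <- function(x, digits = 2, ...) {
  cat(sprintf("%d-factor %s solution%s\n", x$n_factors, x$rotation,
              if (!is.na(x$kappa)) sprintf(" (kappa = %g)", x$kappa) else ""))
  print(round(x$pattern, digits))
  cat("eigenvalue (after rotation):",
      paste(round(x$eigenvalues, 2), collapse = "  "), "\n")
  cat("cumulative variance:",
      paste(sprintf("%.1f%%", 100 * x$cumulative_variance), collapse = "  "), "\n")
  invisible(x)
}

#' Regression-method factor score coefficients
#'
#' Scoring weights `W = R^{-1} S`, where `S = pattern %*% factor_correlation`
#' is the structure matrix.  If the correlation matrix is numerically
#' ill-conditioned a small ridge is added to the diagonal and a message
#' reports the regularization strength.
#'
#' @param solution a [rotate_loadings()] result.
#' @param cormat the pollutant correlation matrix the PCA was fitted on.
#' @param condition_threshold condition-number threshold above which the
#'   ridge fallback engages.
#' @return Pollutants x factors matrix of scoring weights.
#' @export
score_coefficients <- function(solution, cormat, condition_threshold = 1e10) {
  s <- solution$pattern %*% solution$factor_correlation
  ev <- eigen(cormat, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) / max(min(ev), .Machine$double.eps) > condition_threshold) {
    lambda <- 1e-8 * mean(diag(cormat))
    message("correlation matrix ill-conditioned; ridge regularization ",
            "with lambda = ", format(lambda))
    cormat <- cormat + diag(lambda, ncol(cormat))
  }
  w <- solve(cormat, s)
  dimnames(w) <- dimnames(s)
  w
}

#' Absolute principal component scores
#'
#' Standardizes new records with the model's stored means and standard
#' deviations, scores them with the model's regression weights, and
#' subtracts the score of the artificial zero-concentration sample (whose
#' standardized value is `-mean/sd` per pollutant).  A record with all raw
#' concentrations equal to zero therefore has absolute score exactly zero on
#' every factor.
#'
#' @param records data frame of raw concentrations (soil-adjusted potassium
#'   is recomputed from `K` and `Si` with the model's stored slope when the
#'   model used it).
#' @param model an [fit_apca()] model.
#' @return Records x factors matrix of absolute scores.
#' @export
absolute_scores <- function(records, model) {
  stopifnot(inherits(model, "apca_model"))
  records <- .ensure_kw(records, model)
  polls <- model$standardization$pollutants
  missing <- setdiff(polls, names(records))
  if (length(missing))
    stop("records lack pollutant column(s): ", paste(missing, collapse = ", "))
  x <- as.matrix(records[polls])
  mu <- model$standardization$mean
  sdv <- model$standardization$sd
  z <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
  scores <- z %*% model$score_coefficients
  sweep(scores, 2, model$zero_sample_scores, "-")
}

# Recompute Kw from raw K and Si with the model's stored campaign slope;
# never re-estimated on new records.
.ensure_kw <- function(records, model) {
  if (is.null(model$soil_k)) return(records)
  if (!"Kw" %in% model$standardization$pollutants) return(records)
  if (!all(c("K", "Si") %in% names(records))) {
    if ("Kw" %in% names(records)) return(records)
    stop("records lack pollutant column(s): K, Si (needed to form Kw)")
  }
  records$Kw <- records$K - model$soil_k$slope * records$Si
  records
}

#' Apportion PM2.5 mass to sources by regression on absolute scores
#'
#' Ordinary least squares of PM2.5 mass on the absolute principal component
#' scores, with intercept.  The contribution of source `p` at record `i` is
#' `b_p * APCS[i, p]`; mass not attributable to any identified source sits
#' in the intercept.  Negative contributions are retained — they are a
#' rotation diagnostic, not a constraint — and their cell fraction is
#' reported.
#'
#' @param pm25 PM2.5 mass vector (micrograms per cubic metre).
#' @param apcs records x factors matrix of absolute scores.
#' @param labels optional source labels for the factor columns.
#' @param ids optional record identifiers.
#' @return An object of class `source_contributions`: `contributions`
#'   (records x sources data frame of mass, micrograms per cubic metre),
#'   `intercept`, `fitted`, `negative_fraction`, `mass_coefficients`
#'   (slopes with standard errors).
#' @export
apportion_mass <- function(pm25, apcs, labels = colnames(apcs), ids = NULL) {
  apcs <- as.matrix(apcs)
  if (is.null(labels)) labels <- paste0("F", seq_len(ncol(apcs)))
  if (length(pm25) != nrow(apcs)) stop("pm25 and apcs are misaligned")
  if (nrow(apcs) <= ncol(apcs) + 1)
    stop("need more records than factors + 1")
  if (qr(cbind(1, apcs))$rank < ncol(apcs) + 1)
    stop("rank-deficient absolute-score matrix")
  fit <- stats::lm(pm25 ~ apcs)
  cf <- stats::coef(fit)
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  b0 <- unname(cf[1])
  b <- unname(cf[-1])
  contrib <- sweep(apcs, 2, b, "*")
  colnames(contrib) <- labels
  neg <- sum(b < 0)
  if (neg > 0)
    message(neg, " source(s) received a negative mass slope ",
            "(non-interpretable source)")
  .source_contributions(contrib, b0, ids = ids,
                        mass_coefficients = data.frame(
                          source = labels, slope = b, se = se[-1],
                          row.names = NULL),
                        intercept_se = unname(se[1]))
}

.source_contributions <- function(contrib, intercept, ids = NULL,
                                  mass_coefficients = NULL,
                                  intercept_se = NA_real_) {
  contrib <- as.data.frame(contrib)
  structure(list(ids = ids,
                 contributions = contrib,
                 intercept = intercept,
                 intercept_se = intercept_se,
                 fitted = rowSums(contrib) + intercept,
                 negative_fraction = mean(as.matrix(contrib) < 0),
                 mass_coefficients = mass_coefficients),
            class = "source_contributions")
}

#' @export
print.source_contributions <- function(x, ...) {
  cat(sprintf("Source contributions: %d records x %d sources, intercept %.2f ug/m3\n",
              nrow(x$contributions), ncol(x$contributions), x$intercept))
  cat(sprintf("  mean contributions: %s\n",
              paste(sprintf("%s %.2f", names(x$contributions),
                            colMeans(x$contributions)), collapse = ", ")))
  cat(sprintf("  negative contribution cells: %.1f%%\n",
              100 * x$negative_fraction))
  invisible(x)
}

#' Apportion particulate sulfur among identified sources
#'
#' Sulfur is kept out of the source-identification PCA and apportioned
#' afterwards: OLS of S on the per-source mass contributions, with
#' intercept.  The intercept is the "unexplained" secondary S; it is
#' reported separately and never folded into a source.
#'
#' @param S sulfur concentration vector.
#' @param contributions a [apportion_mass()] result.
#' @return Data frame of per-source slopes (sulfur mass per unit source
#'   PM2.5 mass) with standard errors; the intercept row is labelled
#'   `secondary`.
#' @export
apportion_sulfur <- function(S, contributions) {
  stopifnot(inherits(contributions, "source_contributions"))
  x <- as.matrix(contributions$contributions)
  if (length(S) != nrow(x)) stop("S and contributions are misaligned")
  if (qr(cbind(1, x))$rank < ncol(x) + 1)
    stop("rank-deficient contribution matrix")
  fit <- stats::lm(S ~ x)
  cf <- stats::coef(fit)
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  data.frame(source = c("secondary", colnames(x)),
             slope = unname(cf), se = unname(se), row.names = NULL)
}

#' Source compositional profiles
#'
#' For each pollutant, a multivariate OLS on all source mass contributions
#' jointly; the slope is the pollutant mass per unit of that source's PM2.5
#' mass — the source's fractional composition.  Units must be harmonized
#' (micrograms per cubic metre) beforehand.  Negative slopes are reported
#' as-is with their standard errors.
#'
#' @param pollutant_table data frame of pollutant concentrations.
#' @param contributions a [apportion_mass()] result aligned with the table.
#' @return An object of class `source_profile_estimate`: long data frame
#'   with columns `pollutant`, `source` (including `intercept`), `fraction`,
#'   `se`.
#' @export
source_profiles <- function(pollutant_table, contributions) {
  stopifnot(inherits(contributions, "source_contributions"))
  x <- as.matrix(contributions$contributions)
  out <- do.call(rbind, lapply(names(pollutant_table), function(pol) {
    y <- pollutant_table[[pol]]
    fit <- stats::lm(y ~ x)
    cf <- stats::coef(fit)
    se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
    data.frame(pollutant = pol,
               source = c("intercept", colnames(x)),
               fraction = unname(cf), se = unname(se), row.names = NULL)
  }))
  class(out) <- c("source_profile_estimate", class(out))
  out
}

# Map a factor to a source name through its dominant tracer loading.
.TRACER_MAP <- list(
  traffic = c("NO2", "BC", "Cu", "Fe"),
  oil = c("Ni", "V"),
  soil = c("Si"),
  biomass_agriculture = c("Kw", "K"),
  industry = c("Zn")
)

#' Label factors by their dominant tracer pollutant
#' @param pattern rotated pattern matrix with pollutant rownames.
#' @return Character vector of unique source labels.
#' @export
assign_source_labels <- function(pattern) {
  labs <- vapply(seq_len(ncol(pattern)), function(j) {
    dom <- rownames(pattern)[which.max(abs(pattern[, j]))]
    hit <- names(.TRACER_MAP)[vapply(.TRACER_MAP, function(tr) dom %in% tr,
                                     logical(1))]
    if (length(hit)) hit[1] else paste0("factor", j)
  }, character(1))
  make.unique(labs, sep = "_")
}

#' Fit the full APCA receptor model
#'
#' Runs the complete apportionment on a monitoring table: optional
#' soil-potassium adjustment, standardization, correlation-matrix PCA,
#' rotation, regression-method scoring, absolute scores, PM2.5 mass
#' apportionment, sulfur apportionment, source labelling, and source
#' compositional profiles.
#'
#' @param table monitoring table with pollutant columns and `PM2.5`.
#' @param n_factors number of retained components (default 5).
#' @param rotation `"promax"` (default) or `"varimax"`.
#' @param kappa Promax power (default 1.6).
#' @param adjust_k apply the soil-adjusted potassium transformation
#'   (default TRUE).
#' @param include_sulfur include S in the source-identification PCA
#'   (sensitivity analysis; default FALSE).
#' @param k_decile decile of lowest K/Si ratio samples for the soil-K fit.
#' @param pollutants PCA pollutant set; defaults to
#'   [pca_pollutants()] under the chosen flags.
#' @param eigenvalue_basis passed to [rotate_loadings()].
#' @return An object of class `apca_model` carrying the standardization,
#'   rotated solution, score coefficients, zero-sample scores, mass and
#'   sulfur coefficients, source labels, soil-K adjustment, training
#'   contributions and estimated source profiles.
#' @export
fit_apca <- function(table, n_factors = 5,
                     rotation = c("promax", "varimax"), kappa = 1.6,
                     adjust_k = TRUE, include_sulfur = FALSE,
                     k_decile = 0.10, pollutants = NULL,
                     eigenvalue_basis = "partition") {
  rotation <- match.arg(rotation)
  tab <- table
  soil_k <- NULL
  if (adjust_k) {
    if (!all(c("K", "Si") %in% names(tab)))
      stop("soil-K adjustment requires K and Si columns")
    soil_k <- estimate_soil_k_slope(tab$K, tab$Si, decile = k_decile)
    tab$Kw <- suppressMessages(apply_soil_adjustment(tab$K, tab$Si, soil_k))
  }
  if (is.null(pollutants))
    pollutants <- pca_pollutants(adjust_k = adjust_k,
                                 include_sulfur = include_sulfur)
  pollutants <- intersect(pollutants, names(tab))
  std <- standardize(tab, pollutants)
  pca <- fit_pca(std$z, n_factors)
  sol <- rotate_loadings(pca$loadings, method = rotation, kappa = kappa,
                         eigenvalue_basis = eigenvalue_basis)
  w <- score_coefficients(sol, pca$cormat)
  z0 <- -std$standardization$mean / std$standardization$sd
  zero_scores <- drop(z0 %*% w)
  labels <- assign_source_labels(sol$pattern)
  colnames(w) <- labels
  colnames(sol$pattern) <- labels
  dimnames(sol$factor_correlation) <- list(labels, labels)
  names(zero_scores) <- labels

  model <- structure(list(standardization = std$standardization,
                          solution = sol,
                          eigenvalues_unrotated = pca$eigenvalues,
                          cormat = pca$cormat,
                          score_coefficients = w,
                          zero_sample_scores = zero_scores,
                          soil_k = soil_k,
                          source_labels = labels,
                          mass_coefficients = NULL,
                          sulfur_coefficients = NULL),
                     class = "apca_model")

  apcs <- absolute_scores(table, model)
  mass <- suppressMessages(
    apportion_mass(tab$PM2.5, apcs, labels = labels, ids = table$site_id))
  model$mass_coefficients <- mass$mass_coefficients
  model$intercept <- mass$intercept
  model$intercept_se <- mass$intercept_se
  if ("S" %in% names(tab))
    model$sulfur_coefficients <- apportion_sulfur(tab$S, mass)
  # Training contributions via the projection path, so projecting the
  # monitoring sites reproduces them bit for bit.
  model$contributions <- project_exposures(table, model, quiet = TRUE)
  prof_cols <- unique(c(pollutants, intersect(c("S", "PM2.5"), names(tab))))
  model$profiles <- source_profiles(tab[prof_cols], model$contributions)
  model
}

#' @export
print.apca_model <- function(x, ...) {
  cat(sprintf("APCA model: %d pollutants, %d factors, %s rotation\n",
              length(x$standardization$pollutants), x$solution$n_factors,
              x$solution$rotation))
  cat("  sources:", paste(x$source_labels, collapse = ", "), "\n")
  cat(sprintf("  cumulative variance: %.1f%%\n",
              100 * utils::tail(x$solution$cumulative_variance, 1)))
  mc <- x$mass_coefficients
  cat(sprintf("  mass slopes (ug/m3 per score): %s; intercept %.2f ug/m3\n",
              paste(sprintf("%s %.2f", mc$source, mc$slope), collapse = ", "),
              x$intercept))
  invisible(x)
}

#' Tucker congruence coefficient between two loading vectors
#' @param x,y numeric vectors.
#' @export
tucker_congruence <- function(x, y) {
  sum(x * y) / sqrt(sum(x^2) * sum(y^2))
}

# All permutations of seq_len(n); exact assignment needs n <= 8 here.
.permutations <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))
  }))
}

#' Match the factors of two rotated solutions
#'
#' Finds the one-to-one assignment of candidate factors to reference
#' factors maximizing total absolute Tucker congruence (exact assignment by
#' enumeration; factor counts here are small), then flips signs so matched
#' congruences are positive.  With unequal factor counts the smaller set is
#' matched and the surplus reported as unmatched.
#'
#' @param reference,candidate `rotated_solution` objects or bare pattern
#'   matrices over the same pollutant set.
#' @return A list with `assignment` (data frame `reference`, `candidate`,
#'   `sign`, `congruence`), `unmatched`, and the full `congruence_matrix`.
#' @export
match_factors <- function(reference, candidate) {
  ref <- if (inherits(reference, "rotated_solution")) reference$pattern else as.matrix(reference)
  cand <- if (inherits(candidate, "rotated_solution")) candidate$pattern else as.matrix(candidate)
  if (nrow(ref) != nrow(cand))
    stop("reference and candidate must share the pollutant set")
  a <- ncol(ref); b <- ncol(cand)
  cm <- matrix(0, a, b, dimnames = list(colnames(ref), colnames(cand)))
  for (i in seq_len(a)) for (j in seq_len(b))
    cm[i, j] <- tucker_congruence(ref[, i], cand[, j])
  if (max(a, b) > 8)
    stop("exact factor matching supported for at most 8 factors")
  if (a <= b) {
    perms <- .permutations(b)[, seq_len(a), drop = FALSE]
    perms <- unique(perms)
    tot <- apply(perms, 1, function(p) sum(abs(cm[cbind(seq_len(a), p)])))
    best <- perms[which.max(tot), ]
    asg <- data.frame(reference = seq_len(a), candidate = as.integer(best))
    unmatched <- list(candidate = setdiff(seq_len(b), best))
  } else {
    perms <- .permutations(a)[, seq_len(b), drop = FALSE]
    perms <- unique(perms)
    tot <- apply(perms, 1, function(p) sum(abs(cm[cbind(p, seq_len(b))])))
    best <- perms[which.max(tot), ]
    asg <- data.frame(reference = as.integer(best), candidate = seq_len(b))
    unmatched <- list(reference = setdiff(seq_len(a), best))
  }
  cong <- cm[cbind(asg$reference, asg$candidate)]
  asg$sign <- ifelse(cong < 0, -1, 1)
  asg$congruence <- abs(cong)
  asg <- asg[order(asg$reference), , drop = FALSE]
  rownames(asg) <- NULL
  list(assignment = asg, unmatched = unmatched, congruence_matrix = cm)
}

#' Stratified fivefold robustness evaluation of the apportionment
#'
#' Partitions the monitoring sites into `k` folds stratified by site type
#' and region, refits the APCA on each training set of `(k-1)/k` of the
#' sites, matches each fold's factors to the full-data model, and reports
#' per-fold, per-factor congruence together with mass-coefficient deltas.
#' Stratum cells smaller than `k` are merged into a rest cell with a
#' warning.
#'
#' @param table monitoring table with `site_type` and `region` columns.
#' @param k number of folds (default 5).
#' @param seed seed for the fold assignment.
#' @param ... arguments passed to [fit_apca()].
#' @return A list with `full` (the full-data model), `fold_models`,
#'   `folds` (fold index per site) and `report` (data frame `fold`,
#'   `source`, `congruence`, `slope_full`, `slope_fold`, `slope_delta`).
#' @export
kfold_robustness <- function(table, k = 5, seed = 1L, ...) {
  if (k < 2) stop("k must be at least 2 (a single fold is degenerate)")
  strat <- interaction(table$site_type, table$region, drop = TRUE)
  small <- names(which(table(strat) < k))
  if (length(small)) {
    warning("stratum cell(s) smaller than k merged: ",
            paste(small, collapse = ", "))
    levels(strat)[levels(strat) %in% small] <- "rest"
    # keep absorbing the smallest remaining stratum until every cell holds
    # at least k sites (or everything is one cell)
    while (min(table(strat)) < k && nlevels(strat) > 1) {
      sizes <- sort(table(strat))
      levels(strat)[levels(strat) %in% names(sizes)[1:2]] <-
        names(sizes)[2]
    }
    if (nlevels(strat) == 1 && length(strat) < k)
      stop("a stratum remains smaller than k after merging")
  }
  set.seed(seed)
  fold <- integer(nrow(table))
  for (s in levels(strat)) {
    idx <- which(strat == s)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  full <- fit_apca(table, ...)
  fold_models <- vector("list", k)
  report <- NULL
  for (f in seq_len(k)) {
    m <- fit_apca(table[fold != f, , drop = FALSE], ...)
    fold_models[[f]] <- m
    mt <- match_factors(full$solution, m$solution)
    slope_full <- full$mass_coefficients$slope[mt$assignment$reference]
    slope_fold <- m$mass_coefficients$slope[mt$assignment$candidate] *
      mt$assignment$sign
    report <- rbind(report, data.frame(
      fold = f,
      source = full$source_labels[mt$assignment$reference],
      congruence = mt$assignment$congruence,
      slope_full = slope_full, slope_fold = slope_fold,
      slope_delta = slope_fold - slope_full, row.names = NULL))
  }
  list(full = full, fold_models = fold_models, folds = fold, report = report)
}
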