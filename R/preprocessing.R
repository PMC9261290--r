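#' Estimate the soil-associated potassium slope from silicon
#'
#' Particulate potassium traces biomass burning but is also present in
#' crustal soil dust.  To isolate the non-soil potassium, the soil component
#' is estimated by regressing K on Si over the samples with the lowest
#' K/Si ratios — those most dominated by crustal material — taking the
#' lowest `decile` fraction of samples.
#'
#' @param K,Si concentration vectors (same units), equal length of at
#'   least 10.
#' @param decile fraction of lowest-ratio samples used in the fit
#'   (default 0.10).
#' @return An object of class `soil_k_adjustment` with fields `slope`,
#'   `intercept`, `decile`, `n_used`.
#' @details The subset size is `floor(decile * n)` with a minimum of 3; ties
#'   in the ratio are broken by smaller K, then input order.  Samples with
#'   `Si == 0` cannot be ranked by ratio and are excluded from selection
#'   with a warning.  The regression includes an intercept; only the slope
#'   is used downstream, the intercept is reported for audit.
#' @export
estimate_soil_k_slope <- function(K, Si, decile = 0.10) {
  if (length(K) != length(Si)) stop("K and Si must have equal length")
  if (length(K) < 10) stop("need at least 10 samples")
  if (decile <= 0 || decile > 1) stop("decile must be in (0, 1]")
  usable <- is.finite(K) & is.finite(Si) & Si != 0
  if (any(!usable & is.finite(K) & is.finite(Si)))
    warning(sum(Si == 0, na.rm = TRUE),
            " sample(s) with Si = 0 excluded from ratio ranking")
  idx <- which(usable)
  m <- floor(decile * length(K))
  if (m < 3) m <- 3L
  if (length(idx) < m)
    stop("fewer than ", m, " selectable samples (minimum 3) for the soil-K fit")
  ratio <- K[idx] / Si[idx]
  sel <- idx[order(ratio, K[idx])][seq_len(m)]
  fit <- stats::lm(K[sel] ~ Si[sel])
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope)) stop("soil-K slope is not finite (degenerate Si subset)")
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 decile = decile, n_used = m),
            class = "soil_k_adjustment")
}

#' @export
print.soil_k_adjustment <- function(x, ...) {
  cat(sprintf("Soil-K adjustment: K_w = K - %.4f * Si (lowest %.0f%% K/Si ratio, n = %d)\n",
              x$slope, 100 * x$decile, x$n_used))
  invisible(x)
}

#' Apply the soil-adjusted potassium transformation
#'
#' Computes `K_w = K - slope * Si` elementwise.  Negative values are
#' retained (the downstream z-scoring is location invariant; truncation
#' would bias the PCA) and their count is reported via a message.
#'
#' @param K,Si concentration vectors of equal length.
#' @param adj a [estimate_soil_k_slope()] result, or a bare numeric slope.
#' @return The adjusted potassium vector `K_w`.
#' @export
apply_soil_adjustment <- function(K, Si, adj) {
  if (length(K) != length(Si)) stop("K and Si must have equal length")
  slope <- if (inherits(adj, "soil_k_adjustment")) adj$slope else as.numeric(adj)
  kw <- K - slope * Si
  nneg <- sum(kw < 0, na.rm = TRUE)
  if (nneg > 0)
    message(nneg, " negative K_w value(s) retained after soil adjustment")
  kw
}

#' Complete-case filter with an exclusion report
#'
#' Drops rows with any missing value in the required columns, mirroring the
#' complete-case design of pooled-cohort analyses (no imputation).
#'
#' @param table a data frame.
#' @param required_columns columns that must be non-missing.
#' @return A list with `table` (the filtered data frame) and `report`
#'   (class `exclusion_report`): per-column missing counts, rows excluded,
#'   and the retention fraction.
#' @export
complete_case_filter <- function(table, required_columns) {
  missing_cols <- setdiff(required_columns, names(table))
  if (length(missing_cols))
    stop("required columns absent from table: ",
         paste(missing_cols, collapse = ", "))
  sub <- table[required_columns]
  miss <- vapply(sub, function(x) sum(is.na(x)), integer(1))
  drop <- !stats::complete.cases(sub)
  if (all(drop)) stop("complete-case filter excluded every row")
  report <- structure(list(n_input = nrow(table),
                           n_retained = sum(!drop),
                           n_excluded = sum(drop),
                           retention = sum(!drop) / nrow(table),
                           per_column_missing = miss),
                      class = "exclusion_report")
  list(table = table[!drop, , drop = FALSE], report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("Complete-case filter: %d of %d rows retained (%.1f%%)\n",
              x$n_retained, x$n_input, 100 * x$retention))
  nz <- x$per_column_missing[x$per_column_missing > 0]
  if (length(nz))
    cat("  missing per column:",
        paste(sprintf("%s=%d", names(nz), nz), collapse = ", "), "\n")
  invisible(x)
}

#' Write an exclusion report as JSON
#' @param report an `exclusion_report`.
#' @param path output file path.
#' @export
write_exclusion_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
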