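# Projection of a fitted APCA model onto individual-level exposures.

#' Project an APCA model onto individual exposure estimates
#'
#' Converts individual pollutant exposures to absolute principal component
#' scores using the monitoring-campaign standardization and scoring weights
#' (never refit on the cohort), and multiplies by the mass-regression slopes
#' to obtain per-participant source-specific PM2.5.  Soil-adjusted potassium
#' is recomputed from participant K and Si with the campaign's stored slope.
#' Negative projected masses are retained; their cell fraction is reported.
#'
#' @param exposures data frame with an optional `id` column and the model's
#'   pollutant columns, in the same units as the monitoring campaign.
#' @param model an [fit_apca()] model.
#' @param quiet suppress the negative-fraction message.
#' @return A `source_contributions` object (per-participant source masses
#'   plus the unapportioned intercept).
#' @export
project_exposures <- function(exposures, model, quiet = FALSE) {
  stopifnot(inherits(model, "apca_model"))
  if (is.null(model$mass_coefficients))
    stop("model carries no mass coefficients; fit the apportionment first")
  apcs <- absolute_scores(exposures, model)
  b <- model$mass_coefficients$slope
  contrib <- sweep(apcs, 2, b, "*")
  colnames(contrib) <- model$source_labels
  ids <- if ("id" %in% names(exposures)) exposures$id else exposures$site_id
  out <- .source_contributions(contrib, model$intercept, ids = ids,
                               mass_coefficients = model$mass_coefficients,
                               intercept_se = model$intercept_se)
  if (!quiet && out$negative_fraction > 0)
    message(sprintf("%.1f%% of projected source-mass cells are negative",
                    100 * out$negative_fraction))
  out
}

#' Distribution summary of source-specific exposures
#'
#' Quantiles (P5, P25, P50, P75, P95; linear-interpolation convention) and
#' the interquartile range per source, optionally within groups.  The IQR
#' convention matters because hazard ratios are reported per IQR increment.
#'
#' @param contributions a `source_contributions` object, or a data frame of
#'   per-source exposure columns.
#' @param grouping optional grouping vector (e.g. subcohort).
#' @return Data frame with columns `group`, `source`, `p5`, `p25`, `p50`,
#'   `p75`, `p95`, `iqr`.
#' @export
summarize_exposures <- function(contributions, grouping = NULL) {
  x <- if (inherits(contributions, "source_contributions"))
    contributions$contributions else as.data.frame(contributions)
  if (nrow(x) == 0) stop("no records to summarize")
  g <- if (is.null(grouping)) rep("all", nrow(x)) else as.character(grouping)
  out <- NULL
  for (grp in unique(g)) {
    sub <- x[g == grp, , drop = FALSE]
    if (nrow(sub) == 0) stop("empty group: ", grp)
    for (src in names(sub)) {
      q <- stats::quantile(sub[[src]], c(0.05, 0.25, 0.50, 0.75, 0.95),
                           names = FALSE, type = 7)
      out <- rbind(out, data.frame(group = grp, source = src,
                                   p5 = q[1], p25 = q[2], p50 = q[3],
                                   p75 = q[4], p95 = q[5],
                                   iqr = q[4] - q[2], row.names = NULL))
    }
  }
  out
}
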