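# Orchestration: one call runs generate -> preprocess -> apportion ->
# project -> fit -> report.  The apportionment stage never reads outcome
# columns and the health stage never reads raw monitoring data, mirroring
# the two-phase design of receptor-model epidemiology.

#' Pipeline configuration
#'
#' @param seed integer seed governing every random stage.
#' @param n_factors retained components (default 5).
#' @param rotation `"promax"` or `"varimax"`.
#' @param kappa Promax power.
#' @param include_sulfur include S in the source-identification PCA.
#' @param adjust_k apply the soil-potassium adjustment.
#' @param kfold folds for the robustness evaluation (default 5).
#' @param model_level confounder model level for the health stage (1-3).
#' @param increments `"iqr"` (hazard ratios per interquartile range) or
#'   `"unit"` (per 1 microgram per cubic metre).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_factors = 5,
                            rotation = c("promax", "varimax"), kappa = 1.6,
                            include_sulfur = FALSE, adjust_k = TRUE,
                            kfold = 5, model_level = 3,
                            increments = c("iqr", "unit")) {
  rotation <- match.arg(rotation)
  increments <- match.arg(increments)
  if (n_factors < 1) stop("n_factors must be positive")
  if (kfold < 2) stop("kfold must be at least 2")
  if (!model_level %in% 1:3) stop("model_level must be 1, 2 or 3")
  structure(list(seed = as.integer(seed), n_factors = n_factors,
                 rotation = rotation, kappa = kappa,
                 include_sulfur = include_sulfur, adjust_k = adjust_k,
                 kfold = kfold, model_level = as.integer(model_level),
                 increments = increments),
            class = "pipeline_config")
}

# FNV-1a hash of the serialized configuration, carried on output objects so
# a rerun under the same configuration is recognizably identical.
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s)) %% 256
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- (h - low + bitwXor(as.integer(low), as.integer(b)))
    h <- (h * 16777619) %% 4294967296
  }
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}

#' Run the apportionment stage end to end
#'
#' Fits the APCA model on a monitoring table, runs the stratified k-fold
#' robustness evaluation, and returns the model, training contributions,
#' source profiles and the robustness report, stamped with the
#' configuration hash and seed.
#'
#' @param table monitoring table (or a path to its CSV).
#' @param config a [pipeline_config()].
#' @return A list of class `apportionment_result`.
#' @export
run_apportionment <- function(table, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(table)) table <- utils::read.csv(table)
  need <- c(pca_pollutants(adjust_k = FALSE), "PM2.5")
  missing <- setdiff(need, names(table))
  if (length(missing))
    stop("apportionment stage: monitoring table lacks column(s): ",
         paste(missing, collapse = ", "))
  model <- fit_apca(table, n_factors = config$n_factors,
                    rotation = config$rotation, kappa = config$kappa,
                    adjust_k = config$adjust_k,
                    include_sulfur = config$include_sulfur)
  robustness <- kfold_robustness(table, k = config$kfold, seed = config$seed,
                                 n_factors = config$n_factors,
                                 rotation = config$rotation,
                                 kappa = config$kappa,
                                 adjust_k = config$adjust_k,
                                 include_sulfur = config$include_sulfur)
  structure(list(model = model,
                 contributions = model$contributions,
                 profiles = model$profiles,
                 robustness = robustness$report,
                 config = config,
                 config_hash = config_hash(config)),
            class = "apportionment_result")
}

#' Run the health-association stage
#'
#' Projects the fitted apportionment onto the cohort's pollutant exposures,
#' then fits single-source and multisource stratified Cox models at the
#' configured confounder level, reports hazard ratios per IQR and per unit,
#' and computes the cumulative risk index at the chosen increments.
#'
#' @param cohort cohort table (or a path to its CSV) with pollutant
#'   exposure columns, covariates and the survival outcome.
#' @param model a fitted [fit_apca()] model.
#' @param config a [pipeline_config()].
#' @return A list of class `health_result`: `exposure_summary`, tidy
#'   `results` (one row per exposure x model type), `single`, `multi`,
#'   `cri`, `config_hash`.
#' @export
run_health_analysis <- function(cohort, model, config = pipeline_config()) {
  stopifnot(inherits(model, "apca_model"), inherits(config, "pipeline_config"))
  if (is.character(cohort)) cohort <- utils::read.csv(cohort)
  spec <- cox_model_spec(config$model_level)
  missing <- setdiff(.spec_columns(spec), names(cohort))
  if (length(missing))
    stop("health stage: cohort lacks required column(s): ",
         paste(missing, collapse = ", "))
  proj <- project_exposures(cohort, model, quiet = TRUE)
  src_cols <- paste0("pm25_", names(proj$contributions))
  expo <- proj$contributions
  names(expo) <- src_cols
  cohort <- cbind(cohort, expo)
  cc <- complete_case_filter(cohort, c(src_cols, .spec_columns(spec)))
  cohort <- cc$table

  single <- lapply(src_cols, function(s) fit_cox(cohort, s, spec))
  names(single) <- src_cols
  multi <- fit_cox(cohort, src_cols, spec)
  x <- if (config$increments == "iqr")
    stats::setNames(multi$table$iqr, src_cols)
  else stats::setNames(rep(1, length(src_cols)), src_cols)
  cri <- cumulative_risk_index(multi, x)

  tidy <- rbind(
    do.call(rbind, lapply(single, function(f)
      cbind(model_type = "single-source", f$table))),
    cbind(model_type = "multisource", multi$table))
  rownames(tidy) <- NULL
  structure(list(exposure_summary = summarize_exposures(proj),
                 exclusion_report = cc$report,
                 results = tidy, single = single, multi = multi, cri = cri,
                 config = config, config_hash = config_hash(config)),
            class = "health_result")
}

#' Serialize a fitted APCA model as JSON
#'
#' Matrices are written row-major with labelled axes so the file is
#' self-describing; [read_apca_model()] restores an equivalent model.
#'
#' @param model an [fit_apca()] model.
#' @param path output path.
#' @export
write_apca_model <- function(model, path) {
  stopifnot(inherits(model, "apca_model"))
  mat <- function(m) list(rows = rownames(m), cols = colnames(m),
                          values = apply(unname(m), 1, as.numeric,
                                         simplify = FALSE))
  obj <- list(
    pollutants = model$standardization$pollutants,
    mean = as.list(model$standardization$mean),
    sd = as.list(model$standardization$sd),
    rotation = model$solution$rotation,
    kappa = model$solution$kappa,
    n_factors = model$solution$n_factors,
    pattern = mat(model$solution$pattern),
    factor_correlation = mat(model$solution$factor_correlation),
    eigenvalues = model$solution$eigenvalues,
    cumulative_variance = model$solution$cumulative_variance,
    score_coefficients = mat(model$score_coefficients),
    zero_sample_scores = as.list(model$zero_sample_scores),
    soil_k = if (is.null(model$soil_k)) NULL else unclass(model$soil_k),
    source_labels = model$source_labels,
    mass_coefficients = model$mass_coefficients,
    intercept = model$intercept,
    sulfur_coefficients = model$sulfur_coefficients)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Restore an APCA model written by [write_apca_model()]
#' @param path JSON path.
#' @return An `apca_model` usable for projection (training contributions
#'   and profiles are not stored in the file).
#' @export
read_apca_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mat <- function(m) {
    v <- if (is.list(m$values)) do.call(rbind, m$values) else as.matrix(m$values)
    dimnames(v) <- list(m$rows, m$cols)
    v
  }
  sol <- structure(list(n_factors = obj$n_factors,
                        pattern = mat(obj$pattern),
                        factor_correlation = mat(obj$factor_correlation),
                        eigenvalues = obj$eigenvalues,
                        cumulative_variance = obj$cumulative_variance,
                        rotation = obj$rotation, kappa = obj$kappa),
                   class = "rotated_solution")
  soil_k <- if (is.null(obj$soil_k)) NULL else
    structure(obj$soil_k, class = "soil_k_adjustment")
  structure(list(
    standardization = list(mean = unlist(obj$mean), sd = unlist(obj$sd),
                           pollutants = obj$pollutants),
    solution = sol,
    score_coefficients = mat(obj$score_coefficients),
    zero_sample_scores = unlist(obj$zero_sample_scores),
    soil_k = soil_k,
    source_labels = obj$source_labels,
    mass_coefficients = obj$mass_coefficients,
    intercept = obj$intercept,
    sulfur_coefficients = obj$sulfur_coefficients),
    class = "apca_model")
}

#' Serialize source contributions as CSV
#' @param contributions a `source_contributions` object.
#' @param path output path.
#' @param prefix column-name prefix for the per-source masses.
#' @export
write_contributions <- function(contributions, path, prefix = "pm25_") {
  stopifnot(inherits(contributions, "source_contributions"))
  df <- contributions$contributions
  names(df) <- paste0(prefix, names(df))
  df$unapportioned <- contributions$intercept
  if (!is.null(contributions$ids)) df <- cbind(id = contributions$ids, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
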