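#' Serialize a fitted model to JSON
#'
#' Stores coefficients, penalty specification, group structure,
#' standardization, the Breslow baseline and the full feature-space metadata
#' (including any training reference matrix) at full numeric precision, so
#' a re-loaded model reproduces predictions bit-identically.
#'
#' @param model A `penalized_cox_model`.
#' @param path Output JSON path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "penalized_cox_model"))
  fs <- model$feature_space
  obj <- list(
    coefficients = as.list(model$coefficients),
    lambda = model$lambda,
    penalty_kind = model$penalty_kind,
    groups = if (!is.null(model$groups)) list(
      groups = model$groups$groups,
      weights = model$groups$weights,
      weight_rule = model$groups$weight_rule),
    standardization = model$standardization,
    baseline = model$baseline,
    feature_ids = model$feature_ids,
    feature_space = if (!is.null(fs)) list(
      kind = fs$kind, method = fs$method, params = fs$params,
      config_name = fs$config_name, sets = fs$sets,
      sets_source = fs$sets_source,
      scoring_reference = serialize_reference(fs$scoring_reference),
      reference_expr = serialize_matrix(fs$reference_expr),
      seed = fs$seed),
    cv = model$cv)
  # digits = I(17): exact IEEE round-trip, so re-loaded models predict
  # bit-identically
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

serialize_matrix <- function(m) {
  if (is.null(m)) return(NULL)
  list(values = unclass(as.matrix(m)), gene_ids = rownames(m),
       sample_ids = colnames(m))
}

deserialize_matrix <- function(x) {
  if (is.null(x)) return(NULL)
  vals <- do.call(rbind, lapply(x$values, unlist))
  expression_matrix(vals, unlist(x$gene_ids), unlist(x$sample_ids))
}

serialize_reference <- function(ref) {
  if (is.null(ref)) return(NULL)
  if (!is.null(ref$expr)) list(expr = serialize_matrix(ref$expr))
  else ref
}

deserialize_reference <- function(ref) {
  if (is.null(ref)) return(NULL)
  if (!is.null(ref$expr)) list(expr = deserialize_matrix(ref$expr))
  else ref
}

#' Load a model serialized by [write_model()]
#'
#' @param path JSON path.
#' @return A `penalized_cox_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  coef <- vapply(obj$coefficients, as.numeric, numeric(1))
  p <- length(coef)
  groups <- NULL
  if (!is.null(obj$groups)) {
    glist <- lapply(obj$groups$groups, function(g) as.integer(unlist(g)))
    groups <- group_structure(glist, p,
                              weight_rule = obj$groups$weight_rule,
                              weights = as.numeric(unlist(obj$groups$weights)))
  }
  fs <- NULL
  if (!is.null(obj$feature_space)) {
    f <- obj$feature_space
    fs <- list(kind = f$kind, method = f$method,
               params = lapply(f$params, function(v) if (is.list(v)) unlist(v) else v),
               config_name = f$config_name,
               sets = lapply(f$sets, function(s) as.character(unlist(s))),
               sets_source = f$sets_source,
               scoring_reference = deserialize_reference(f$scoring_reference),
               reference_expr = deserialize_matrix(f$reference_expr),
               seed = f$seed)
  }
  structure(list(
    coefficients = coef,
    lambda = as.numeric(obj$lambda),
    penalty_kind = obj$penalty_kind,
    groups = groups,
    standardization = lapply(obj$standardization, function(v) as.numeric(unlist(v))),
    baseline = lapply(obj$baseline, function(v) as.numeric(unlist(v))),
    feature_ids = as.character(unlist(obj$feature_ids)),
    feature_space = fs,
    cv = if (!is.null(obj$cv)) lapply(obj$cv, function(v) as.numeric(unlist(v)))
  ), class = "penalized_cox_model")
}

#' Structured model report
#'
#' Collects the elements a transparent prediction-model report needs: data
#' provenance, feature space, selected features and pathways with
#' coefficients, the penalty and its cross-validation curve, validation
#' metrics when supplied, the missing-data policy, software versions and
#' seeds. Returned as a list; [write_report()] renders it to JSON and a
#' human-readable text file.
#'
#' @param model A model from [fit_prognostic_model()].
#' @param validation Optional `validation_report` or list of metric results
#'   to embed.
#' @param data_description Free-text provenance of the training data.
#' @return List of class `model_report`.
#' @export
model_report <- function(model, validation = NULL,
                         data_description = "unspecified training cohort") {
  fs <- model$feature_space
  nz <- model$coefficients[model$coefficients != 0]
  selected_groups <- character(0)
  if (!is.null(model$groups)) {
    gs <- model$groups
    nz_groups <- vapply(gs$groups, function(idx) {
      any(model$coefficients[idx] != 0)
    }, logical(1))
    selected_groups <- names(gs$groups)[nz_groups]
  }
  structure(list(
    title = "Pathway-informed penalized Cox prognostic model",
    data = data_description,
    outcome = "overall survival (months)",
    feature_space = list(kind = fs$kind %||% "custom", method = fs$method,
                         params = fs$params,
                         n_features = length(model$coefficients),
                         n_pathways = if (!is.null(fs$sets)) length(fs$sets)),
    model = list(penalty = model$penalty_kind, lambda = model$lambda,
                 n_selected_features = length(nz),
                 selected_features = as.list(nz),
                 n_selected_pathways = if (!is.null(model$groups)) length(selected_groups),
                 selected_pathways = as.list(selected_groups),
                 cv_lambda_grid = model$cv$lambda_grid,
                 cv_deviance = model$cv$cv_deviance),
    validation = if (inherits(validation, "validation_report")) {
      list(n_repeats = validation$n_repeats, train_frac = validation$train_frac,
           summary = validation$summary)
    } else validation,
    missing_data_policy = paste(
      "New samples with missing genes are imputed by distance-weighted",
      "K-nearest-gene averaging (K = 10) against the stored training",
      "reference; at most 5% missing values are allowed."),
    software = list(package = "pathsurv",
                    version = as.character(utils::packageVersion("pathsurv")),
                    r_version = paste(R.version$major, R.version$minor, sep = ".")),
    seed = fs$seed
  ), class = "model_report")
}

#' Write a model report to JSON and plain text
#'
#' @param report A [model_report()].
#' @param path Output path without extension; `<path>.json` and
#'   `<path>.txt` are written.
#' @return Invisibly, the two paths.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "model_report"))
  json_path <- paste0(path, ".json")
  txt_path <- paste0(path, ".txt")
  jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  lines <- c(
    report$title,
    strrep("=", nchar(report$title)),
    paste("Training data:", report$data),
    paste("Outcome:", report$outcome),
    sprintf("Feature space: %s%s (%d features)",
            report$feature_space$kind,
            if (!is.null(report$feature_space$method))
              paste0(" / ", report$feature_space$method) else "",
            report$feature_space$n_features),
    sprintf("Penalty: %s, lambda = %.6g", report$model$penalty, report$model$lambda),
    sprintf("Selected features: %d", report$model$n_selected_features),
    if (!is.null(report$model$n_selected_pathways))
      sprintf("Selected pathways: %d", report$model$n_selected_pathways),
    paste("Missing data:", report$missing_data_policy),
    sprintf("Software: %s %s (R %s)", report$software$package,
            report$software$version, report$software$r_version),
    if (!is.null(report$seed)) paste("Seed:", report$seed))
  writeLines(lines, txt_path)
  invisible(c(json = json_path, txt = txt_path))
}
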