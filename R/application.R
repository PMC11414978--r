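#' Describe one model configuration
#'
#' A configuration fully specifies feature construction and penalty:
#' gene-level lasso (`feature_space = "genes"`), pathway-score lasso
#' (`"pathway_scores"` plus a scoring method and gene-set collection), or
#' group lasso over pathway-grouped genes (`"grouped_genes"`).
#'
#' @param name Label used in reports.
#' @param feature_space `"genes"`, `"pathway_scores"`, or `"grouped_genes"`.
#' @param sets `GeneSetCollection` (required unless `feature_space = "genes"`).
#' @param method Scoring method for pathway scores (`"ssgsea"`, `"gsva"`,
#'   `"zscore"`).
#' @param penalty `"lasso"` or `"group"` (grouped genes default to `"group"`).
#' @param n_select Reduce the collection to its `n_select` most distinct
#'   pathways before use (`NULL` = use all).
#' @param min_size,max_size Gene-set size filter after universe restriction.
#' @param params Extra scoring parameters (`alpha`, `tau`, `denominator`, ...).
#' @return An object of class `model_config`.
#' @export
model_config <- function(name, feature_space = c("genes", "pathway_scores", "grouped_genes"),
                         sets = NULL, method = NULL, penalty = NULL,
                         n_select = NULL, min_size = 5, max_size = 500,
                         params = list()) {
  feature_space <- match.arg(feature_space)
  if (feature_space != "genes") {
    if (is.null(sets)) stop("config '", name, "' needs a gene-set collection")
    stopifnot(inherits(sets, "GeneSetCollection"))
  }
  if (feature_space == "pathway_scores") {
    if (is.null(method)) stop("config '", name, "' needs a scoring method")
    method <- match.arg(method, c("ssgsea", "gsva", "zscore"))
  }
  if (is.null(penalty)) {
    penalty <- if (feature_space == "grouped_genes") "group" else "lasso"
  }
  penalty <- match.arg(penalty, c("lasso", "group"))
  structure(list(name = name, feature_space = feature_space, sets = sets,
                 method = method, penalty = penalty, n_select = n_select,
                 min_size = min_size, max_size = max_size, params = params),
            class = "model_config")
}

prepare_sets <- function(config, universe) {
  sets <- restrict_to_universe(config$sets, universe,
                               min_size = config$min_size,
                               max_size = config$max_size)
  if (!is.null(config$n_select)) sets <- select_distinct_pathways(sets, config$n_select)
  sets
}

#' Construct model features from training data (and optionally new data)
#'
#' All feature construction that depends on background samples — gene-set
#' restriction and selection, z-score standardization, the GSVA kernel CDF,
#' the ssGSEA normalization constant — is computed on the training matrix
#' only and replayed on the new matrix, so each new sample's features depend
#' only on its own values plus training statistics (no leakage).
#'
#' @param config A [model_config()].
#' @param train_expr Training expression matrix.
#' @param new_expr Optional new-sample expression matrix on the same genes.
#' @return List with `x_train`, `x_new` (or `NULL`), `groups`, `sets_used`,
#'   and `reference` (the stored statistics needed at prediction time).
#' @export
construct_features <- function(config, train_expr, new_expr = NULL) {
  stopifnot(inherits(config, "model_config"))
  if (config$feature_space == "genes") {
    x_new <- if (!is.null(new_expr)) new_expr[rownames(train_expr), , drop = FALSE]
    return(list(x_train = train_expr, x_new = x_new, groups = NULL,
                sets_used = NULL, reference = NULL))
  }
  sets <- prepare_sets(config, rownames(train_expr))
  if (config$feature_space == "grouped_genes") {
    gf <- grouped_gene_features(train_expr, sets)
    x_new <- if (!is.null(new_expr)) new_expr[rownames(gf$x), , drop = FALSE]
    return(list(x_train = gf$x, x_new = x_new, groups = gf$groups,
                sets_used = sets, reference = NULL))
  }
  # pathway scores
  m <- config$method
  args <- config$params
  x_train <- do.call(score_pathways,
                     c(list(expr = train_expr, sets = sets, method = m), args))
  reference <- switch(m,
    ssgsea = list(norm_range = attr(x_train, "method_params")$norm_range),
    list(expr = train_expr))
  x_new <- NULL
  if (!is.null(new_expr)) {
    x_new <- score_new_samples(new_expr, sets, m, reference, args)
  }
  list(x_train = x_train, x_new = x_new, groups = NULL,
       sets_used = sets, reference = reference)
}

score_new_samples <- function(new_expr, sets, method, reference, params) {
  if (method == "ssgsea") {
    do.call(ssgsea_scores,
            c(list(expr = new_expr, sets = sets,
                   norm_range = reference$norm_range), params))
  } else {
    if (is.null(reference$expr)) {
      stop(method, " scoring of new samples requires the stored training ",
           "reference cohort (background-dependent method)")
    }
    ref <- reference$expr[rownames(new_expr), , drop = FALSE]
    do.call(score_pathways,
            c(list(expr = new_expr, sets = sets, method = method,
                   reference = ref), params))
  }
}

#' Fit a prognostic model from a configuration
#'
#' Builds the configured feature space on the training data, selects the
#' penalty by cross-validation ([cv_lambda()]) and fits the final model on
#' the full training data. The fitted model stores everything needed to
#' score new patients: coefficients, the Breslow baseline, the gene-set
#' collection actually used, and the training reference (full training
#' expression, required by background-dependent scoring methods, batch
#' alignment and imputation).
#'
#' @param expr Training expression matrix (genes x samples, complete).
#' @param surv Survival table for the training samples.
#' @param config A [model_config()].
#' @param seed Integer seed (cross-validation folds).
#' @param n_folds,n_lambda,lambda_min_ratio,tol,max_iter Passed to
#'   [cv_lambda()] / [fit_penalized_cox()].
#' @param keep_reference Store the training expression matrix in the model
#'   (default `TRUE`; required for alignment/imputation of new patients).
#' @return A `penalized_cox_model` with populated `feature_space` metadata
#'   and the `cv` curve attached.
#' @export
fit_prognostic_model <- function(expr, surv, config, seed = NULL, n_folds = 10,
                                 n_lambda = 100, lambda_min_ratio = 0.01,
                                 tol = 1e-7, max_iter = 1e5,
                                 keep_reference = TRUE) {
  if (anyNA(expr)) stop("training expression contains missing values")
  feats <- construct_features(config, expr)
  cv <- cv_lambda(feats$x_train, surv, penalty_kind = config$penalty,
                  groups = feats$groups, n_folds = n_folds,
                  n_lambda = n_lambda, lambda_min_ratio = lambda_min_ratio,
                  seed = seed, tol = tol, max_iter = max_iter)
  model <- fit_penalized_cox(feats$x_train, surv, penalty_kind = config$penalty,
                             lambda = cv$lambda, groups = feats$groups,
                             tol = tol, max_iter = max_iter)
  model$feature_space <- list(
    kind = config$feature_space,
    method = config$method,
    params = config$params,
    config_name = config$name,
    sets = if (!is.null(feats$sets_used)) feats$sets_used$sets,
    sets_source = if (!is.null(feats$sets_used)) feats$sets_used$source_name,
    scoring_reference = feats$reference,
    reference_expr = if (keep_reference) expr,
    seed = seed)
  model$cv <- list(lambda = cv$lambda, lambda_grid = cv$lambda_grid,
                   cv_deviance = cv$cv_deviance)
  model
}

#' Score new patients in a fitted model's feature space
#'
#' Replays the model's feature construction on new expression data using the
#' statistics stored at training time, then returns the linear predictor.
#'
#' @param model A model from [fit_prognostic_model()].
#' @param expr_new New expression matrix (genes x samples, complete; impute
#'   missing values first with [knn_impute_new_samples()]).
#' @return Named vector of risk scores (linear predictors).
#' @export
predict_for_model <- function(model, expr_new) {
  x <- features_for_model(model, expr_new)
  predict_risk(model, x)
}

#' Feature matrix for new samples in a fitted model's space
#'
#' The matrix [predict_risk()] would consume: gene rows aligned to the model
#' for gene-level models, or pathway scores computed with the stored training
#' statistics for pathway-score models.
#'
#' @param model A model from [fit_prognostic_model()].
#' @param expr_new New expression matrix (complete).
#' @return Features x samples matrix.
#' @export
features_for_model <- function(model, expr_new) {
  fs <- model$feature_space
  if (is.null(fs) || is.null(fs$kind)) stop("model lacks feature-space metadata")
  if (anyNA(expr_new)) stop("new expression contains missing values; impute first")
  if (fs$kind %in% c("genes", "grouped_genes")) {
    missing_feat <- setdiff(model$feature_ids, rownames(expr_new))
    if (length(missing_feat) > 0) {
      stop("genes missing from new data: ",
           paste(utils::head(missing_feat, 5), collapse = ", "))
    }
    return(expr_new[model$feature_ids, , drop = FALSE])
  }
  sets <- gene_set_collection(fs$sets, fs$sets_source %||% "stored")
  score_new_samples(expr_new, sets, fs$method, fs$scoring_reference, fs$params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a fitted model on an external cohort
#'
#' Optionally aligns the new expression to the training reference
#' ([reference_align()]), replays feature construction with stored training
#' statistics, and reports the concordance index and (optionally) the
#' integrated Brier score with percentile bootstrap confidence intervals.
#' When the IBS is requested a note is emitted: transporting the Breslow
#' baseline hazard assumes the baseline hazard is consistent between the
#' training and external populations.
#'
#' @param model A model from [fit_prognostic_model()].
#' @param expr_new External expression matrix.
#' @param surv_new External survival table.
#' @param align Location/scale-align new genes to the training reference.
#' @param metrics Any of `"cindex"`, `"ibs"`.
#' @param B Bootstrap resamples for confidence intervals (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return Named list of metric results (estimate + CI).
#' @export
external_validation <- function(model, expr_new, surv_new, align = FALSE,
                                metrics = c("cindex", "ibs"), B = 1000,
                                seed = NULL) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (align) {
    ref <- model$feature_space$reference_expr
    if (is.null(ref)) stop("model stores no reference cohort; cannot align")
    expr_new <- reference_align(expr_new, ref)
  }
  surv_new <- align_surv(expr_new, surv_new)
  x <- features_for_model(model, expr_new)
  risk <- predict_risk(model, x)
  out <- list()
  if ("cindex" %in% metrics) {
    out$cindex <- bootstrap_metric_ci(
      function(v, s) concordance_index(v, s)$estimate, risk, surv_new,
      B = B, seed = seed)
  }
  if ("ibs" %in% metrics) {
    message("IBS on external data assumes a consistent baseline hazard ",
            "between training and external populations; interpret with care")
    t_max <- max(surv_new$time[surv_new$event == 1])
    grid <- ibs_time_grid(surv_new, t_max)
    pi_mat <- suppressWarnings(predict_survival_probability(model, x, grid))
    out$ibs <- bootstrap_metric_ci(
      function(v, s) suppressWarnings(
        integrated_brier_score(v, surv = s, times = grid,
                               t_max = max(s$time[s$event == 1]))),
      pi_mat, surv_new, B = B, seed = seed)
  }
  out
}

#' Location/scale alignment of a new batch to a reference cohort
#'
#' Per gene, the new batch is rescaled so its mean and standard deviation
#' match the reference cohort's (zero-variance genes in the new batch are
#' shifted to the reference mean only). A deliberately simple batch
#' adjustment with an exact per-gene moment contract; it ignores the
#' covariance structure that empirical-Bayes batch correction models.
#'
#' @param expr_new New expression matrix (>= 2 samples).
#' @param reference Reference (training) expression matrix sharing genes.
#' @return Aligned matrix over the shared gene universe.
#' @export
reference_align <- function(expr_new, reference) {
  if (ncol(expr_new) < 2) stop("alignment needs >= 2 new samples")
  shared <- intersect(rownames(expr_new), rownames(reference))
  if (length(shared) == 0) stop("no shared genes with the reference")
  x <- expr_new[shared, , drop = FALSE]
  r <- reference[shared, , drop = FALSE]
  mx <- rowMeans(x); sx <- apply(x, 1, stats::sd)
  mr <- rowMeans(r); sr <- apply(r, 1, stats::sd)
  scl <- ifelse(sx > 0, sr / sx, 0)
  out <- (x - mx) * scl + mr
  dimnames(out) <- dimnames(x)
  out
}

#' Distance-weighted K-nearest-gene imputation for new samples
#'
#' For each missing gene in a new sample, the K nearest reference genes
#' (Euclidean distance over the reference cohort) that are observed in that
#' sample vote with weights `1 / (d + eps)`; the imputed value is their
#' weighted average. When fewer than K observed neighbours exist, all
#' observed genes are used. Samples whose missing fraction exceeds
#' `warn_frac` trigger a warning (imputation beyond that level is unreliable).
#'
#' @param expr_new Expression matrix with `NA` entries (genes x samples).
#' @param reference Complete reference (training) expression matrix.
#' @param K Number of neighbour genes (default 10).
#' @param eps Distance offset in the inverse-distance weights (default 1e-6).
#' @param warn_frac Missing-fraction warning threshold (default 0.05).
#' @return Completed expression matrix.
#' @export
knn_impute_new_samples <- function(expr_new, reference, K = 10, eps = 1e-6,
                                   warn_frac = 0.05) {
  if (anyNA(reference)) stop("reference must be complete")
  if (!anyNA(expr_new)) return(expr_new)
  miss_frac <- colMeans(is.na(expr_new))
  if (any(miss_frac == 1)) {
    stop("sample(s) with no observed genes: ",
         paste(colnames(expr_new)[miss_frac == 1], collapse = ", "))
  }
  if (any(miss_frac > warn_frac)) {
    warning(sum(miss_frac > warn_frac), " sample(s) exceed the ",
            sprintf("%.0f%%", 100 * warn_frac), " missing-value allowance")
  }
  miss_genes <- rownames(expr_new)[rowSums(is.na(expr_new)) > 0]
  absent <- setdiff(miss_genes, rownames(reference))
  if (length(absent) > 0) {
    stop("missing gene(s) absent from the reference: ",
         paste(utils::head(absent, 5), collapse = ", "))
  }
  # candidate neighbours: reference genes that are also rows of the new data
  cand <- intersect(rownames(reference), rownames(expr_new))
  refc <- reference[cand, , drop = FALSE]
  out <- expr_new
  # squared distances from every missing gene to all candidates in one
  # BLAS-backed cross product (masking experiments touch most genes)
  ref_sq <- rowSums(refc^2)
  Mm <- reference[miss_genes, , drop = FALSE]
  cross <- Mm %*% t(refc)
  m_sq <- rowSums(Mm^2)
  for (m in miss_genes) {
    d2 <- pmax(ref_sq - 2 * cross[m, ] + m_sq[m], 0)
    d <- sqrt(d2)
    names(d) <- cand
    d <- d[names(d) != m]
    ord <- names(d)[order(d, names(d))]
    for (j in which(is.na(expr_new[m, ]))) {
      obs <- ord[!is.na(expr_new[ord, j])]
      nb <- utils::head(obs, K)
      if (length(nb) == 0) stop("no observed neighbour genes for '", m, "'")
      w <- 1 / (d[nb] + eps)
      out[m, j] <- sum(w * expr_new[nb, j]) / sum(w)
    }
  }
  out
}

#' Mask random genes as missing
#'
#' Draws `floor(fraction * G)` genes without replacement and sets them
#' missing — a fresh draw per sample by default, or one shared draw for all
#' samples (`shared_mask = TRUE`).
#'
#' @param expr Complete expression matrix.
#' @param fraction Missing fraction in `[0, 1)`.
#' @param seed Integer seed.
#' @param shared_mask Mask the same genes in every sample.
#' @return List with `expr` (masked matrix) and `mask` (logical genes x
#'   samples matrix of masked positions).
#' @export
mask_random_genes <- function(expr, fraction, seed = NULL, shared_mask = FALSE) {
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  n_mask <- floor(fraction * nrow(expr))
  mask <- matrix(FALSE, nrow(expr), ncol(expr), dimnames = dimnames(expr))
  if (n_mask > 0) {
    with_seed(seed, {
      if (shared_mask) {
        idx <- sample.int(nrow(expr), n_mask)
        mask[idx, ] <- TRUE
      } else {
        for (j in seq_len(ncol(expr))) {
          mask[sample.int(nrow(expr), n_mask), j] <- TRUE
        }
      }
    })
  }
  masked <- expr
  masked[mask] <- NA_real_
  list(expr = masked, mask = mask)
}

#' Missing-value robustness experiment
#'
#' Repeatedly masks a fraction of genes in the test data, imputes them with
#' [knn_impute_new_samples()] against the model's stored training reference,
#' predicts, and records the concordance index — quantifying how prediction
#' degrades with increasing missingness.
#'
#' @param model A model from [fit_prognostic_model()] with a stored reference.
#' @param expr_test Complete test expression matrix.
#' @param surv_test Test survival table.
#' @param fractions Missing fractions (default 1%, 2%, 5%, 10%, 20%, 30%).
#' @param n_reps Replicates per fraction (default 20).
#' @param seed Integer master seed.
#' @param K Imputation neighbours (default 10).
#' @return List with `baseline` (no-missing C-index), `records` (per
#'   fraction x rep), and `summary` (mean and sd per fraction).
#' @export
missing_robustness_experiment <- function(model, expr_test, surv_test,
                                          fractions = c(0.01, 0.02, 0.05, 0.10, 0.20, 0.30),
                                          n_reps = 20, seed = NULL, K = 10) {
  reference <- model$feature_space$reference_expr
  if (is.null(reference)) stop("model stores no reference cohort for imputation")
  surv_test <- align_surv(expr_test, surv_test)
  baseline <- concordance_index(predict_for_model(model, expr_test), surv_test)$estimate
  seeds <- with_seed(seed, matrix(sample.int(.Machine$integer.max - 1,
                                             length(fractions) * n_reps),
                                  length(fractions), n_reps))
  records <- do.call(rbind, lapply(seq_along(fractions), function(fi) {
    f <- fractions[fi]
    ci <- vapply(seq_len(n_reps), function(r) {
      if (f == 0) return(baseline)
      masked <- mask_random_genes(expr_test, f, seed = seeds[fi, r])
      imputed <- suppressWarnings(
        knn_impute_new_samples(masked$expr, reference, K = K))
      concordance_index(predict_for_model(model, imputed), surv_test)$estimate
    }, numeric(1))
    data.frame(fraction = f, rep = seq_len(n_reps), cindex = ci)
  }))
  summary <- do.call(rbind, lapply(split(records, records$fraction), function(d) {
    data.frame(fraction = d$fraction[1], mean_cindex = mean(d$cindex),
               sd_cindex = stats::sd(d$cindex))
  }))
  rownames(summary) <- NULL
  list(baseline = baseline, records = records, summary = summary)
}

#' Internal validation by repeated random train/test splits
#'
#' Repeats `n_repeats` times: split the cohort (stratified by the event
#' indicator) into a `train_frac` training part and the remaining validation
#' part; for every configuration, construct features and select the penalty
#' on the training split only, then evaluate the concordance index and
#' integrated Brier score on the validation split. Background-dependent
#' statistics (z-score standardization, GSVA kernel CDF, ssGSEA
#' normalization constant, pathway selection, predictor standardization) are
#' all estimated on the training split and replayed on the validation split.
#' Configurations are compared pairwise with the corrected resampled t-test
#' at the split ratio used.
#'
#' @param expr Expression matrix (genes x samples, complete).
#' @param surv Survival table.
#' @param configs List of [model_config()]s (names taken from the configs).
#' @param n_repeats Number of random splits (default 100).
#' @param train_frac Training fraction (default 0.7).
#' @param seed Integer master seed.
#' @param n_folds,n_lambda,lambda_min_ratio Cross-validation controls.
#' @param compute_ibs Also compute the IBS per repeat (default `TRUE`).
#' @return A `validation_report`: `records` (per repeat x config),
#'   `summary` (mean and SE per config), and `pairwise` corrected
#'   resampled t-test p-values for each metric.
#' @export
internal_validation <- function(expr, surv, configs, n_repeats = 100,
                                train_frac = 0.7, seed = NULL, n_folds = 10,
                                n_lambda = 100, lambda_min_ratio = 0.01,
                                compute_ibs = TRUE) {
  stopifnot(length(configs) >= 1)
  for (cfg in configs) stopifnot(inherits(cfg, "model_config"))
  cfg_names <- vapply(configs, `[[`, character(1), "name")
  if (anyDuplicated(cfg_names)) stop("config names must be unique")
  surv <- align_surv(expr, surv)
  n <- ncol(expr)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1, 2 * n_repeats))
  records <- list()
  for (r in seq_len(n_repeats)) {
    split <- with_seed(seeds[r], {
      idx_ev <- which(surv$event == 1)
      idx_cn <- which(surv$event == 0)
      c(sample(idx_ev, round(train_frac * length(idx_ev))),
        sample(idx_cn, round(train_frac * length(idx_cn))))
    })
    tr <- sort(split)
    te <- setdiff(seq_len(n), tr)
    expr_tr <- expr[, tr, drop = FALSE]
    expr_te <- expr[, te, drop = FALSE]
    surv_tr <- surv[tr, , drop = FALSE]
    surv_te <- surv[te, , drop = FALSE]
    for (cfg in configs) {
      feats <- construct_features(cfg, expr_tr, expr_te)
      cv <- cv_lambda(feats$x_train, surv_tr, penalty_kind = cfg$penalty,
                      groups = feats$groups, n_folds = n_folds,
                      n_lambda = n_lambda, lambda_min_ratio = lambda_min_ratio,
                      seed = seeds[n_repeats + r])
      model <- fit_penalized_cox(feats$x_train, surv_tr,
                                 penalty_kind = cfg$penalty, lambda = cv$lambda,
                                 groups = feats$groups)
      risk <- predict_risk(model, feats$x_new)
      ci <- concordance_index(risk, surv_te)$estimate
      ibs <- NA_real_
      if (compute_ibs) {
        t_max <- max(surv_te$time[surv_te$event == 1])
        grid <- ibs_time_grid(surv_te, t_max)
        pi_mat <- suppressWarnings(
          predict_survival_probability(model, feats$x_new, grid))
        ibs <- suppressWarnings(
          integrated_brier_score(pi_mat, surv = surv_te, times = grid,
                                 t_max = t_max))
      }
      records[[length(records) + 1]] <-
        data.frame(repeat_id = r, seed = seeds[r], config = cfg$name,
                   lambda = cv$lambda, cindex = ci, ibs = ibs)
    }
  }
  records <- do.call(rbind, records)
  summary <- do.call(rbind, lapply(cfg_names, function(nm) {
    d <- records[records$config == nm, ]
    data.frame(config = nm,
               mean_cindex = mean(d$cindex),
               se_cindex = stats::sd(d$cindex) / sqrt(nrow(d)),
               mean_ibs = mean(d$ibs),
               se_ibs = if (all(is.na(d$ibs))) NA_real_ else
                 stats::sd(d$ibs) / sqrt(nrow(d)))
  }))
  n_train <- length(tr)
  n_test <- length(te)
  pairwise <- lapply(c(cindex = "cindex", ibs = "ibs"), function(metric) {
    if (metric == "ibs" && !compute_ibs) return(NULL)
    P <- matrix(NA_real_, length(cfg_names), length(cfg_names),
                dimnames = list(cfg_names, cfg_names))
    for (a in seq_along(cfg_names)) for (b in seq_along(cfg_names)) {
      if (a < b) {
        da <- records[records$config == cfg_names[a], metric]
        db <- records[records$config == cfg_names[b], metric]
        P[a, b] <- P[b, a] <-
          corrected_resampled_ttest(da - db, n_train, n_test)$p_value
      }
    }
    P
  })
  structure(list(records = records, summary = summary, pairwise = pairwise,
                 n_repeats = n_repeats, train_frac = train_frac,
                 n_train = n_train, n_test = n_test, seed = seed),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("internal validation: %d repeats, %.0f/%.0f split\n",
              x$n_repeats, 100 * x$train_frac, 100 * (1 - x$train_frac)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
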