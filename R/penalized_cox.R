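#' Define a group structure over predictors
#'
#' Groups must partition the predictor index set (no overlaps, no gaps).
#' The per-group penalty multiplier `m_g` defaults to the square root of the
#' group cardinality (`weight_rule = "sqrt"`); `"cardinality"` uses `T_g`
#' itself and `"one"` reduces the group penalty to an ordinary lasso when all
#' groups are singletons.
#'
#' @param groups Named list mapping group id to integer predictor indices.
#' @param p Total number of predictors.
#' @param weight_rule `"sqrt"` (default), `"cardinality"`, or `"one"`.
#' @param weights Optional explicit positive multipliers, overriding the rule.
#' @return An object of class `GroupStructure`.
#' @export
group_structure <- function(groups, p, weight_rule = c("sqrt", "cardinality", "one"),
                            weights = NULL) {
  weight_rule <- match.arg(weight_rule)
  idx <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(idx)) stop("groups overlap: predictor indices must partition")
  if (!setequal(idx, seq_len(p))) stop("groups must cover all ", p, " predictors")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  if (is.null(weights)) {
    weights <- switch(weight_rule,
                      sqrt = sqrt(lengths(groups)),
                      cardinality = lengths(groups),
                      one = rep(1, length(groups)))
  }
  weights <- as.numeric(weights)
  if (length(weights) != length(groups) || any(weights <= 0)) {
    stop("need one positive weight per group")
  }
  structure(list(groups = groups, weights = weights, weight_rule = weight_rule),
            class = "GroupStructure")
}

#' Build grouped gene-level features from a gene-set collection
#'
#' Constructs the design for a group-lasso model whose groups are pathways:
#' the features are the member genes of the (restricted) sets and each gene
#' is assigned to exactly one group. Genes shared by several pathways are
#' assigned to the lexicographically first set containing them, so the
#' groups form the partition the penalty requires; selecting distinct
#' pathways beforehand ([select_distinct_pathways()]) keeps such clashes rare.
#'
#' @param expr Expression matrix (genes x samples).
#' @param sets A `GeneSetCollection` restricted to the expression universe.
#' @param weight_rule Passed to [group_structure()].
#' @return List with `x` (features x samples) and `groups` (`GroupStructure`).
#' @export
grouped_gene_features <- function(expr, sets, weight_rule = "sqrt") {
  stopifnot(inherits(sets, "GeneSetCollection"))
  set_names <- sort(names(sets$sets))
  assigned <- list()
  seen <- character(0)
  for (nm in set_names) {
    g <- intersect(sets$sets[[nm]], rownames(expr))
    g <- setdiff(g, seen)
    if (length(g) > 0) {
      assigned[[nm]] <- sort(g)
      seen <- c(seen, g)
    }
  }
  if (length(assigned) == 0) stop("no set genes present in the expression matrix")
  feat <- unlist(assigned, use.names = FALSE)
  x <- expr[feat, , drop = FALSE]
  idx <- split(seq_along(feat), rep(names(assigned), lengths(assigned)))
  idx <- idx[names(assigned)]  # preserve set order
  list(x = x, groups = group_structure(idx, length(feat), weight_rule = weight_rule))
}

align_surv <- function(X, surv) {
  if (is.null(colnames(X))) stop("X must carry sample ids as column names")
  if (!setequal(colnames(X), surv$sample_id)) {
    stop("sample ids of X and the survival table differ")
  }
  surv[match(colnames(X), surv$sample_id), , drop = FALSE]
}

standardize_rows <- function(X) {
  ctr <- rowMeans(X)
  scl <- apply(X, 1, stats::sd)
  scl[scl == 0] <- 1
  list(x = (X - ctr) / scl, center = ctr, scale = scl)
}

penalty_codes <- function(penalty_kind, groups, p) {
  if (penalty_kind == "group") {
    if (is.null(groups)) stop("group penalty requires a GroupStructure")
    stopifnot(inherits(groups, "GroupStructure"))
    grp <- integer(p)
    for (g in seq_along(groups$groups)) grp[groups$groups[[g]]] <- g - 1L
    list(pen = 1L, grp = grp, gmult = groups$weights)
  } else {
    list(pen = 0L, grp = integer(p), gmult = numeric(1))
  }
}

#' Smallest penalty giving the all-zero solution
#'
#' Computed in closed form from the null-model gradient `g = (1/n) X' dL`:
#' `max_j |g_j|` for the lasso, `max_g ||g_g||_2 / m_g` for the group lasso.
#'
#' @param X Predictors x samples matrix (standardized internally as in the fit).
#' @param surv Survival table aligned to the columns of `X`.
#' @param penalty_kind `"lasso"` or `"group"`.
#' @param groups `GroupStructure` for the group penalty.
#' @param standardize Standardize predictors as the fit does (default `TRUE`).
#' @return The critical penalty value `lambda_max`.
#' @export
lambda_max <- function(X, surv, penalty_kind = c("lasso", "group"),
                       groups = NULL, standardize = TRUE) {
  penalty_kind <- match.arg(penalty_kind)
  surv <- align_surv(X, surv)
  std <- if (standardize) standardize_rows(X) else list(x = X)
  g0 <- .cox_obj_grad_eta(rep(0, ncol(X)), surv$time, surv$event)$grad
  gb <- as.numeric(std$x %*% g0)
  if (penalty_kind == "lasso") return(max(abs(gb)))
  max(vapply(seq_along(groups$groups), function(g) {
    sqrt(sum(gb[groups$groups[[g]]]^2)) / groups$weights[g]
  }, numeric(1)))
}

#' Fit a lasso or group-lasso penalized Cox model
#'
#' Minimizes `(1/n) * (negative log partial likelihood, Breslow ties)` plus
#' `lambda * sum(|beta_j|)` (lasso) or `lambda * sum_g m_g ||beta_g||_2`
#' (group lasso) by accelerated proximal gradient descent with backtracking
#' line search, converging when the relative objective change drops below
#' `tol`. Predictors are standardized internally and coefficients returned
#' on the original scale; the Breslow cumulative baseline hazard is fitted
#' on the training data and stored so absolute survival probabilities can be
#' predicted.
#'
#' @param X Predictors x samples matrix with feature row names and sample
#'   column names.
#' @param surv Survival table ([survival_table()]) covering the samples.
#' @param penalty_kind `"lasso"` or `"group"`.
#' @param lambda Non-negative penalty.
#' @param groups `GroupStructure` (group penalty only).
#' @param standardize Standardize predictors internally (default `TRUE`).
#' @param tol Relative objective-change convergence threshold (default 1e-7).
#' @param max_iter Iteration cap (default 1e5).
#' @param beta_init Optional warm start (original scale).
#' @param feature_space Optional metadata describing how features were built
#'   (attached verbatim; used by the validation/prediction harnesses).
#' @return An object of class `penalized_cox_model`.
#' @export
fit_penalized_cox <- function(X, surv, penalty_kind = c("lasso", "group"),
                              lambda, groups = NULL, standardize = TRUE,
                              tol = 1e-7, max_iter = 1e5, beta_init = NULL,
                              feature_space = NULL) {
  penalty_kind <- match.arg(penalty_kind)
  X <- as.matrix(X)
  if (anyNA(X)) stop("missing values in predictors; impute first")
  if (lambda < 0) stop("lambda must be non-negative")
  surv <- align_surv(X, surv)
  if (sum(surv$event) < 1) stop("at least one event is required")
  p <- nrow(X)
  std <- if (standardize) standardize_rows(X) else
    list(x = X, center = rep(0, p), scale = rep(1, p))
  pc <- penalty_codes(penalty_kind, groups, p)
  init <- if (is.null(beta_init)) rep(0, p) else beta_init * std$scale
  fit <- .solve_penalized(t(std$x), surv$time, surv$event, 0L, lambda,
                          pc$pen, pc$grp, pc$gmult, tol, as.integer(max_iter),
                          init, TRUE)
  if (!fit$converged) {
    stop(sprintf("solver did not converge in %d iterations (gradient norm %.3e)",
                 as.integer(max_iter), fit$grad_norm))
  }
  beta <- as.numeric(fit$beta) / std$scale
  names(beta) <- rownames(X)
  lp <- as.numeric(crossprod(X, beta))
  structure(list(
    coefficients = beta,
    lambda = lambda,
    penalty_kind = penalty_kind,
    groups = groups,
    standardization = list(center = std$center, scale = std$scale),
    baseline = breslow_baseline(lp, surv$time, surv$event),
    feature_ids = rownames(X),
    feature_space = feature_space,
    solver = list(iterations = fit$iterations, objective = fit$objective,
                  obj_path = as.numeric(fit$obj_path))
  ), class = "penalized_cox_model")
}

#' @export
print.penalized_cox_model <- function(x, ...) {
  cat(sprintf("penalized Cox model (%s penalty, lambda = %.4g): %d/%d non-zero coefficients\n",
              x$penalty_kind, x$lambda, sum(x$coefficients != 0),
              length(x$coefficients)))
  invisible(x)
}

#' Breslow cumulative baseline hazard
#'
#' @param lp Linear predictors of the training samples.
#' @param time Observed times.
#' @param event Event indicators.
#' @return List with `time` (distinct event times) and `hazard` (cumulative
#'   baseline hazard, non-decreasing, 0 before the first event).
#' @export
breslow_baseline <- function(lp, time, event) {
  ee <- exp(lp - mean(lp))
  et <- sort(unique(time[event == 1]))
  haz <- vapply(et, function(t) {
    sum(event == 1 & time == t) / sum(ee[time >= t])
  }, numeric(1))
  list(time = et, hazard = cumsum(haz) * exp(-mean(lp)))
}

#' Linear predictor (risk score) for new samples
#'
#' @param model A `penalized_cox_model`.
#' @param X_new Predictors x samples matrix in the model's feature space.
#' @return Named numeric vector of per-sample linear predictors.
#' @export
predict_risk <- function(model, X_new) {
  missing_feat <- setdiff(model$feature_ids, rownames(X_new))
  if (length(missing_feat) > 0) {
    stop("features missing from new data: ",
         paste(utils::head(missing_feat, 5), collapse = ", "),
         if (length(missing_feat) > 5) sprintf(" (+%d more)", length(missing_feat) - 5))
  }
  x <- X_new[model$feature_ids, , drop = FALSE]
  lp <- as.numeric(crossprod(x, model$coefficients))
  names(lp) <- colnames(X_new)
  lp
}

#' Predicted survival probabilities
#'
#' `pi(x, t) = exp(-H0(t) * exp(lp(x)))` with `H0` the stored Breslow
#' cumulative baseline hazard (right-continuous step function, 0 before the
#' first training event time). Times beyond the last training event time are
#' extrapolated flat with a warning, since transporting the baseline hazard
#' beyond the training follow-up assumes it stays constant.
#'
#' @param model A `penalized_cox_model`.
#' @param X_new Predictors x samples matrix.
#' @param times Non-negative evaluation times.
#' @return Samples x times matrix of survival probabilities.
#' @export
predict_survival_probability <- function(model, X_new, times) {
  if (any(times < 0)) stop("times must be non-negative")
  if (length(model$baseline$time) == 0) stop("model has no baseline hazard")
  tmax <- max(model$baseline$time)
  if (any(times > tmax)) {
    warning("times beyond the last training event time (", tmax,
            "); baseline hazard extrapolated flat")
  }
  lp <- predict_risk(model, X_new)
  H0 <- stats::stepfun(model$baseline$time, c(0, model$baseline$hazard))(times)
  out <- exp(-outer(exp(lp), H0))
  dimnames(out) <- list(names(lp), as.character(times))
  out
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stratified_folds <- function(event, n_folds) {
  fold <- integer(length(event))
  for (lvl in unique(event)) {
    idx <- which(event == lvl)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  fold
}

cox_log_pl <- function(X, beta, surv) {
  eta <- as.numeric(crossprod(X, beta))
  -.cox_obj_grad_eta(eta, surv$time, surv$event)$nll * length(eta)
}

#' Select the penalty by 10-fold cross-validation
#'
#' The grid defaults to 100 log-spaced values from `lambda_max` down to
#' `0.01 * lambda_max`. Folds are stratified by the event indicator. The CV
#' criterion is the Verweij-van Houwelingen cross-validated partial-
#' likelihood deviance: for fold k,
#' `-2 * (logPL_all(beta_(-k)) - logPL_train(beta_(-k)))`, summed over folds.
#' The returned `lambda` minimizes the total CV deviance. Fits are warm-
#' started along the decreasing grid.
#'
#' @param X Predictors x samples matrix.
#' @param surv Survival table.
#' @param penalty_kind `"lasso"` or `"group"`.
#' @param groups `GroupStructure` for the group penalty.
#' @param n_folds Number of folds (default 10).
#' @param lambda_grid Optional explicit penalty grid.
#' @param n_lambda Grid length when the grid is generated (default 100).
#' @param lambda_min_ratio Smallest grid value as a fraction of
#'   `lambda_max` (default 0.01).
#' @param seed Integer seed controlling fold assignment.
#' @param tol,max_iter Solver controls (see [fit_penalized_cox()]).
#' @return List of class `cv_penalized_cox` with the chosen `lambda`, the
#'   grid, the CV deviance curve, and the fold assignment.
#' @export
cv_lambda <- function(X, surv, penalty_kind = c("lasso", "group"), groups = NULL,
                      n_folds = 10, lambda_grid = NULL, n_lambda = 100,
                      lambda_min_ratio = 0.01, seed = NULL, tol = 1e-7,
                      max_iter = 1e5) {
  penalty_kind <- match.arg(penalty_kind)
  if (n_folds < 2) stop("n_folds must be >= 2")
  surv <- align_surv(X, surv)
  if (sum(surv$event) < n_folds) {
    stop("too few events to give every fold at least one event")
  }
  if (is.null(lambda_grid)) {
    lmax <- lambda_max(X, surv, penalty_kind, groups)
    lambda_grid <- exp(seq(log(lmax), log(lambda_min_ratio * lmax),
                           length.out = n_lambda))
  }
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  fold <- with_seed(seed, stratified_folds(surv$event, n_folds))
  if (any(tapply(surv$event, fold, sum) == 0)) {
    stop("a fold has zero events despite stratification")
  }
  dev <- matrix(NA_real_, length(lambda_grid), n_folds)
  for (k in seq_len(n_folds)) {
    tr <- fold != k
    X_tr <- X[, tr, drop = FALSE]
    surv_tr <- surv[tr, , drop = FALSE]
    beta_warm <- NULL
    for (l in seq_along(lambda_grid)) {
      fit <- fit_penalized_cox(X_tr, surv_tr, penalty_kind, lambda_grid[l],
                               groups = groups, tol = tol, max_iter = max_iter,
                               beta_init = beta_warm)
      beta_warm <- fit$coefficients
      dev[l, k] <- -2 * (cox_log_pl(X, fit$coefficients, surv) -
                           cox_log_pl(X_tr, fit$coefficients, surv_tr))
    }
  }
  cv_curve <- rowSums(dev)
  best <- which.min(cv_curve)
  structure(list(lambda = lambda_grid[best],
                 lambda_grid = lambda_grid,
                 cv_deviance = cv_curve,
                 cv_folds = dev,
                 fold = fold,
                 penalty_kind = penalty_kind),
            class = "cv_penalized_cox")
}

#' Fit the squared-error analogue (continuous outcomes)
#'
#' The literal least-squares objective
#' `(1/(2n)) * sum_i (y_i - beta0 - x_i' beta)^2` plus the same lasso /
#' group-lasso penalties, for continuous outcomes. The intercept `beta0` is
#' handled by centering and is returned unpenalized.
#'
#' @param X Predictors x samples matrix.
#' @param y Continuous response aligned to the columns of `X`.
#' @inheritParams fit_penalized_cox
#' @return List with `coefficients`, `intercept`, `lambda`, `penalty_kind`.
#' @export
fit_penalized_lm <- function(X, y, penalty_kind = c("lasso", "group"), lambda,
                             groups = NULL, standardize = TRUE, tol = 1e-7,
                             max_iter = 1e5) {
  penalty_kind <- match.arg(penalty_kind)
  X <- as.matrix(X)
  stopifnot(length(y) == ncol(X))
  p <- nrow(X)
  std <- if (standardize) standardize_rows(X) else
    list(x = X, center = rep(0, p), scale = rep(1, p))
  yc <- y - mean(y)
  pc <- penalty_codes(penalty_kind, groups, p)
  fit <- .solve_penalized(t(std$x), yc, rep(0, length(y)), 1L, lambda,
                          pc$pen, pc$grp, pc$gmult, tol, as.integer(max_iter),
                          rep(0, p), FALSE)
  if (!fit$converged) {
    stop(sprintf("solver did not converge (gradient norm %.3e)", fit$grad_norm))
  }
  beta <- as.numeric(fit$beta) / std$scale
  names(beta) <- rownames(X)
  list(coefficients = beta,
       intercept = mean(y) - sum(beta * rowMeans(X)),
       lambda = lambda, penalty_kind = penalty_kind)
}
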