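#' Kaplan-Meier estimator as a step function
#'
#' Thin wrapper around [survival::survfit()] returning the product-limit
#' estimate in a form convenient for evaluation (right-continuous, with left
#' limits available).
#'
#' @param times Non-negative observed times.
#' @param indicators Event indicators (1 = event).
#' @return Object of class `km_fit` with `time` and `surv` components.
#' @export
km_estimator <- function(times, indicators) {
  if (length(times) == 0) stop("empty input")
  if (any(times < 0)) stop("times must be non-negative")
  fit <- survival::survfit(survival::Surv(times, indicators) ~ 1)
  structure(list(time = fit$time, surv = fit$surv, n = length(times)),
            class = "km_fit")
}

#' Evaluate a Kaplan-Meier step function
#'
#' @param fit A `km_fit`.
#' @param t Evaluation times.
#' @param left Evaluate the left limit `S(t-)` instead of `S(t)`.
#' @return Survival probabilities at `t`.
#' @export
eval_km <- function(fit, t, left = FALSE) {
  sf <- stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)
  if (left) {
    # S(t-): value just before t; step occurs at t itself
    vapply(t, function(tt) {
      idx <- fit$time < tt
      if (!any(idx)) 1 else fit$surv[max(which(idx))]
    }, numeric(1))
  } else {
    sf(t)
  }
}

#' Censoring distribution estimate for IPCW
#'
#' Kaplan-Meier estimate of the censoring distribution `G(t) = P(C > t)`,
#' obtained by swapping the roles of events and censorings.
#'
#' @param surv Survival table.
#' @return A `km_fit` for the censoring distribution.
#' @export
censoring_model <- function(surv) {
  km_estimator(surv$time, 1 - surv$event)
}

#' Censoring-weighted Brier score at a time point
#'
#' `BS(t*) = (1/n) * sum_i W_i * (I(T_i > t*) - pi_i)^2` with IPCW weights:
#' subjects with an observed event at or before `t*` get `1 / G(T_i-)`,
#' subjects still under observation past `t*` get `1 / G(t*)`, and subjects
#' censored at or before `t*` get weight 0. `G` is the Kaplan-Meier estimate
#' of the censoring distribution on the evaluation set; the left limit
#' `G(T_i-)` avoids weighting a subject by its own censoring step (set
#' `left_limit = FALSE` for the plain `G(T_i)` convention).
#'
#' @param pi Predicted survival probabilities at `t_star`, in `[0, 1]`.
#' @param surv Survival table aligned with `pi`.
#' @param t_star Evaluation time.
#' @param cens Optional precomputed [censoring_model()].
#' @param left_limit Use `G(T_i-)` for event weights (default `TRUE`).
#' @return The weighted Brier score.
#' @export
brier_score_ipcw <- function(pi, surv, t_star, cens = NULL, left_limit = TRUE) {
  stopifnot(length(pi) == nrow(surv))
  if (any(pi < 0 | pi > 1)) stop("predicted probabilities must lie in [0, 1]")
  if (is.null(cens)) cens <- censoring_model(surv)
  w <- numeric(nrow(surv))
  ev <- surv$event == 1 & surv$time <= t_star
  alive <- surv$time > t_star
  if (any(ev)) {
    g_ev <- eval_km(cens, surv$time[ev], left = left_limit)
    if (any(g_ev <= 0)) {
      stop("censoring survival G is 0 at an event time; use a smaller t*")
    }
    w[ev] <- 1 / g_ev
  }
  if (any(alive)) {
    g_t <- eval_km(cens, t_star)
    if (g_t <= 0) stop("censoring survival G(t*) is 0; use a smaller t*")
    w[alive] <- 1 / g_t
  }
  mean(w * (as.numeric(surv$time > t_star) - pi)^2)
}

ibs_time_grid <- function(surv, t_max) {
  et <- sort(unique(surv$time[surv$event == 1]))
  et <- et[et > 0 & et <= t_max]
  unique(c(0, et, t_max))
}

#' Integrated Brier score
#'
#' `IBS = (1/t_max) * integral of BS(t) over (0, t_max]`, trapezoidal rule
#' over the unique evaluation-set event times plus `t_max`. By default
#' `t_max` is the largest observed event time in the evaluation set.
#'
#' Supply either a fitted model plus new-data predictors, or a precomputed
#' matrix of survival probabilities with its evaluation `times`.
#'
#' @param object A `penalized_cox_model`, or a samples x times matrix of
#'   survival probabilities.
#' @param X_new Predictors x samples matrix (model interface).
#' @param surv Survival table for the evaluation samples.
#' @param t_max Upper end of the integration range.
#' @param times Evaluation times matching the columns of a probability
#'   matrix (matrix interface; must cover the grid).
#' @param cens Optional precomputed [censoring_model()].
#' @return The integrated Brier score.
#' @export
integrated_brier_score <- function(object, X_new = NULL, surv, t_max = NULL,
                                   times = NULL, cens = NULL) {
  if (is.null(t_max)) {
    if (sum(surv$event) == 0) stop("no events in the evaluation set")
    t_max <- max(surv$time[surv$event == 1])
  }
  grid <- ibs_time_grid(surv, t_max)
  if (length(grid) < 2) stop("empty integration grid; no event times in (0, t_max]")
  if (inherits(object, "penalized_cox_model")) {
    pi_mat <- predict_survival_probability(object, X_new, grid)
  } else {
    pi_mat <- as.matrix(object)
    if (is.null(times)) stop("matrix interface requires the evaluation times")
    idx <- match(grid, times)
    if (anyNA(idx)) stop("probability matrix does not cover the IBS grid")
    pi_mat <- pi_mat[, idx, drop = FALSE]
  }
  if (is.null(cens)) cens <- censoring_model(surv)
  bs <- vapply(seq_along(grid), function(i) {
    brier_score_ipcw(pi_mat[, i], surv, grid[i], cens = cens)
  }, numeric(1))
  sum(diff(grid) * (utils::head(bs, -1) + utils::tail(bs, -1)) / 2) / t_max
}

#' Concordance index with censoring-aware pair exclusion
#'
#' Estimates `P(Risk(i) > Risk(j) | T_i < T_j)` over all subject pairs whose
#' survival order is established: a pair is usable iff the smaller observed
#' time belongs to an event (pairs where both are censored, or where the
#' earlier subject is censored, are excluded; a subject censored at the same
#' time as another's event counts as surviving longer). Pairs of events with
#' identical times are excluded because their order is unknown. Risk ties
#' among usable pairs contribute 0.5.
#'
#' @param risk Per-sample risk scores (higher = worse prognosis).
#' @param surv Survival table aligned with `risk`.
#' @return List with `estimate`, `n_pairs` (usable pairs), `concordant`,
#'   `tied_risk`.
#' @export
concordance_index <- function(risk, surv) {
  stopifnot(length(risk) == nrow(surv))
  tm <- surv$time
  dl <- surv$event
  # ordered pairs (i, j): i is the reference whose event fixes the order
  earlier <- outer(tm, tm, `<`) & (dl == 1)
  tied_time <- outer(tm, tm, `==`) & outer(dl == 1, dl == 0, `&`)
  usable <- earlier | tied_time
  if (!any(usable)) stop("no usable pairs (censoring leaves no ordered pair)")
  rgt <- outer(risk, risk, `>`)
  req <- outer(risk, risk, `==`)
  concordant <- sum(rgt & usable)
  ties <- sum(req & usable)
  list(estimate = (concordant + 0.5 * ties) / sum(usable),
       n_pairs = sum(usable), concordant = concordant, tied_risk = ties)
}

#' Corrected resampled t-test for repeated train/test comparisons
#'
#' For J paired metric differences from repeated random train/test splits,
#' `t = mean(d) / sqrt((1/J + n_test/n_train) * var(d))` with the unbiased
#' sample variance, referred to a Student t distribution with J - 1 degrees
#' of freedom. The variance inflation accounts for the overlap between
#' resampled training sets, which makes the naive resampled t-test badly
#' anti-conservative.
#'
#' @param diffs Per-repeat paired metric differences (length J >= 2).
#' @param n_train,n_test Split sizes.
#' @return List with `t`, `p_value`, `df`, `mean_diff`.
#' @export
corrected_resampled_ttest <- function(diffs, n_train, n_test) {
  J <- length(diffs)
  if (J < 2) stop("need at least two repeats")
  if (n_train <= 0 || n_test <= 0) stop("split sizes must be positive")
  v <- stats::var(diffs)
  m <- mean(diffs)
  if (v == 0) {
    if (m == 0) return(list(t = 0, p_value = 1, df = J - 1, mean_diff = 0))
    warning("zero variance with non-zero mean difference")
    return(list(t = sign(m) * Inf, p_value = 0, df = J - 1, mean_diff = m))
  }
  t_stat <- m / sqrt((1 / J + n_test / n_train) * v)
  list(t = t_stat, p_value = 2 * stats::pt(-abs(t_stat), df = J - 1),
       df = J - 1, mean_diff = m)
}

#' Percentile bootstrap confidence interval for an evaluation metric
#'
#' Resamples evaluation subjects with replacement `B` times, recomputes the
#' metric on each resample, and reports the percentile interval. Resamples
#' on which the metric is undefined (e.g. no usable pairs) are redrawn and
#' counted.
#'
#' @param metric_fun Function `(values, surv) -> scalar`, e.g. a wrapper
#'   around [concordance_index()].
#' @param values Per-sample risk vector, or a samples x times matrix of
#'   predictions (rows are resampled).
#' @param surv Survival table aligned with `values`.
#' @param B Number of bootstrap resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed for reproducibility.
#' @return List with `estimate`, `ci_lower`, `ci_upper`, `level`, `B`,
#'   `n_redrawn`.
#' @export
bootstrap_metric_ci <- function(metric_fun, values, surv, B = 1000,
                                level = 0.95, seed = NULL) {
  if (B < 2) stop("B must be >= 2")
  n <- nrow(surv)
  take <- function(v, idx) if (is.matrix(v)) v[idx, , drop = FALSE] else v[idx]
  est <- metric_fun(values, surv)
  boot <- with_seed(seed, {
    out <- numeric(B)
    redrawn <- 0L
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        val <- tryCatch(metric_fun(take(values, idx), surv[idx, , drop = FALSE]),
                        error = function(e) NULL)
        if (!is.null(val)) break
        redrawn <- redrawn + 1L
        if (redrawn > 10 * B) stop("metric undefined on almost all resamples")
      }
      out[b] <- val
    }
    list(values = out, redrawn = redrawn)
  })
  alpha <- (1 - level) / 2
  qs <- stats::quantile(boot$values, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(estimate = est, ci_lower = qs[1], ci_upper = qs[2], level = level,
       B = B, n_redrawn = boot$redrawn)
}

#' Median split into high- and low-risk groups
#'
#' Labels samples with risk above the median as high risk (`> median`; the
#' median sample itself goes to the low-risk group) and, when a survival
#' table is supplied, attaches per-group Kaplan-Meier curves.
#'
#' @param risk Per-sample risk scores (length >= 2).
#' @param surv Optional survival table aligned with `risk`.
#' @return List with `group` (factor high/low), `cutoff`, and optionally
#'   `km` (per-group `km_fit`s).
#' @export
risk_group_split <- function(risk, surv = NULL) {
  if (length(risk) < 2) stop("need at least two samples")
  if (length(unique(risk)) == 1) stop("all risks identical; no split possible")
  cutoff <- stats::median(risk)
  group <- factor(ifelse(risk > cutoff, "high", "low"), levels = c("low", "high"))
  out <- list(group = group, cutoff = cutoff)
  if (!is.null(surv)) {
    out$km <- lapply(split(seq_along(risk), group), function(idx) {
      km_estimator(surv$time[idx], surv$event[idx])
    })
  }
  out
}
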