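#' Simulate overlapping gene sets
#'
#' Draws `n_pathways` sets with sizes uniform in `size_range`. A fraction
#' `overlap_frac` of each set's genes is drawn from genes already used by
#' earlier sets (creating the between-pathway overlap that motivates
#' distinct-pathway selection); the remainder comes from unused genes while
#' any remain.
#'
#' @param n_genes Universe size (genes are named `g0001`, ...).
#' @param n_pathways Number of sets.
#' @param size_range Integer set-size range, within `[2, n_genes]`.
#' @param overlap_frac Fraction of each set drawn from previously used genes.
#' @param seed Integer seed.
#' @return A `GeneSetCollection`.
#' @export
simulate_gene_sets <- function(n_genes, n_pathways, size_range = c(10, 40),
                               overlap_frac = 0.2, seed = NULL) {
  if (size_range[1] < 2 || size_range[2] > n_genes) {
    stop("size_range must lie within [2, n_genes]")
  }
  genes <- sprintf("g%0*d", nchar(n_genes), seq_len(n_genes))
  with_seed(seed, {
    used <- character(0)
    sets <- list()
    for (k in seq_len(n_pathways)) {
      size <- sample(seq(size_range[1], size_range[2]), 1)
      n_old <- min(round(overlap_frac * size), length(used))
      old <- if (n_old > 0) sample(used, n_old) else character(0)
      pool <- setdiff(genes, c(used, old))
      n_new <- size - n_old
      if (length(pool) < n_new) {
        # unused genes exhausted: top up from used genes
        extra <- sample(setdiff(used, old), n_new - length(pool))
        new <- c(pool, extra)
      } else {
        new <- sample(pool, n_new)
      }
      members <- sort(c(old, new))
      sets[[sprintf("pw%03d", k)]] <- members
      used <- union(used, members)
    }
    gene_set_collection(sets, "synthetic")
  })
}

#' Simulate a pathway-structured survival cohort
#'
#' Latent pathway activities `A_p ~ N(0, 1)` per sample drive both
#' expression and survival: member genes load on their pathways
#' (`x_gj = mu_g + sum_p loading_gp * A_pj + noise`, baseline
#' `mu_g ~ N(8, 2)` on a log2-microarray-like scale) and the first
#' `n_active` pathways carry survival effects `gamma_p` of magnitude
#' `effect_size` (alternating sign) on the Cox linear predictor. Event
#' times are Weibull via inverse transform,
#' `T = (-log U / (kappa * exp(lp)))^(1/rho)`, with the scale chosen so the
#' baseline median survival is `median_survival` months. Independent uniform
#' censoring `C ~ U(0, c_max)` has `c_max` calibrated by bisection so the
#' realized event rate is within `rate_tol` of `target_event_rate`.
#'
#' @param sets `GeneSetCollection` defining the pathways.
#' @param n_samples Cohort size.
#' @param n_active Number of survival-active pathways.
#' @param effect_size Magnitude of each active pathway's log-hazard effect.
#' @param noise_sd Residual expression noise SD (default 1).
#' @param target_event_rate Fraction of subjects with an observed event
#'   (default 0.44).
#' @param rate_tol Calibration tolerance on the realized event rate
#'   (default 0.03).
#' @param shape Weibull shape `rho` (default 1.5).
#' @param median_survival Baseline median survival in months (default 90).
#' @param universe Optional full gene universe (character vector containing
#'   all set genes); genes outside every set get zero loadings, emulating the
#'   bulk of a microarray that carries no pathway signal.
#' @param seed Integer seed; fully determines the cohort.
#' @return List with `expr` (genes x samples), `surv`, and `truth`
#'   (active pathways with effects, loadings, Weibull parameters, latent
#'   activities, true linear predictor, seed).
#' @export
simulate_cohort <- function(sets, n_samples, n_active = 3, effect_size = 1,
                            noise_sd = 1, target_event_rate = 0.44,
                            rate_tol = 0.03, shape = 1.5, median_survival = 90,
                            universe = NULL, seed = NULL) {
  stopifnot(inherits(sets, "GeneSetCollection"))
  if (n_active > length(sets$sets)) stop("n_active exceeds the number of sets")
  genes <- sort(unique(unlist(sets$sets, use.names = FALSE)))
  if (!is.null(universe)) {
    if (!all(genes %in% universe)) stop("universe must contain all set genes")
    genes <- sort(unique(universe))
  }
  P <- length(sets$sets)
  with_seed(seed, {
    A <- matrix(stats::rnorm(P * n_samples), P, n_samples,
                dimnames = list(names(sets$sets),
                                sprintf("s%0*d", nchar(n_samples), seq_len(n_samples))))
    loadings <- matrix(0, length(genes), P, dimnames = list(genes, names(sets$sets)))
    for (p in seq_len(P)) {
      members <- sets$sets[[p]]
      loadings[members, p] <- stats::rnorm(length(members), 1, 0.2)
    }
    mu <- stats::rnorm(length(genes), 8, 2)
    expr <- mu + loadings %*% A +
      matrix(stats::rnorm(length(genes) * n_samples, 0, noise_sd),
             length(genes), n_samples)
    dimnames(expr) <- list(genes, colnames(A))
    active <- names(sets$sets)[seq_len(n_active)]
    gamma <- effect_size * rep_len(c(1, -1), n_active)
    names(gamma) <- active
    lp <- as.numeric(gamma %*% A[active, , drop = FALSE])
    kappa <- log(2) / median_survival^shape
    u <- stats::runif(n_samples)
    t_event <- (-log(u) / (kappa * exp(lp)))^(1 / shape)
    u_cens <- stats::runif(n_samples)
    # bisect the censoring upper bound to hit the target event rate
    rate_at <- function(cmax) mean(t_event <= cmax * u_cens)
    lo <- 0; hi <- max(t_event) / min(u_cens) * 2
    cmax <- NA_real_
    for (it in seq_len(200)) {
      mid <- (lo + hi) / 2
      r <- rate_at(mid)
      if (abs(r - target_event_rate) <= min(rate_tol, 0.005) ||
          (hi - lo) < 1e-9 * max(1, hi)) { cmax <- mid; break }
      if (r < target_event_rate) lo <- mid else hi <- mid
    }
    if (is.na(cmax)) {
      cmax <- (lo + hi) / 2
      if (abs(rate_at(cmax) - target_event_rate) > rate_tol) {
        stop("censoring calibration failed to reach the target event rate")
      }
    }
    cens <- cmax * u_cens
    time <- pmin(t_event, cens)
    event <- as.numeric(t_event <= cens)
    surv <- survival_table(colnames(expr), time, event)
    truth <- structure(list(active_pathways = gamma, loadings = loadings,
                            baseline_shape = shape, baseline_scale = kappa,
                            target_event_rate = target_event_rate,
                            latent = A, true_lp = stats::setNames(lp, colnames(expr)),
                            censoring_max = cmax, seed = seed),
                       class = "synthetic_truth")
    list(expr = expression_matrix(expr), surv = surv, truth = truth)
  })
}

#' Preset parameters for the synthetic fixtures
#'
#' `tiny` (50 genes x 30 samples x 6 sets) supports fast unit tests;
#' `default` (2000 genes x 400 samples x 60 sets, 3 active pathways with
#' effect magnitude 1) supports the parameter-recovery and robustness
#' experiments.
#'
#' @param preset `"tiny"` or `"default"`.
#' @return List of generator arguments.
#' @export
synthetic_preset <- function(preset = c("tiny", "default")) {
  preset <- match.arg(preset)
  switch(preset,
         tiny = list(n_genes = 50, n_samples = 30, n_pathways = 6,
                     size_range = c(4, 8), overlap_frac = 0.2, n_active = 2,
                     effect_size = 1),
         default = list(n_genes = 2000, n_samples = 400, n_pathways = 60,
                        size_range = c(10, 40), overlap_frac = 0.2,
                        n_active = 3, effect_size = 1))
}

#' Simulate a preset cohort
#'
#' Convenience wrapper combining [simulate_gene_sets()] and
#' [simulate_cohort()] under one seed.
#'
#' @param preset `"tiny"` or `"default"` (see [synthetic_preset()]).
#' @param seed Integer seed.
#' @param ... Overrides for individual preset parameters.
#' @return List with `expr`, `surv`, `sets`, `truth`.
#' @export
simulate_preset_cohort <- function(preset = c("tiny", "default"), seed = 1, ...) {
  pars <- utils::modifyList(synthetic_preset(preset), list(...))
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1, 2))
  sets <- simulate_gene_sets(pars$n_genes, pars$n_pathways, pars$size_range,
                             pars$overlap_frac, seed = seeds[1])
  universe <- sprintf("g%0*d", nchar(pars$n_genes), seq_len(pars$n_genes))
  cohort <- simulate_cohort(sets, pars$n_samples, n_active = pars$n_active,
                            effect_size = pars$effect_size,
                            universe = universe, seed = seeds[2])
  c(cohort, list(sets = sets))
}

#' Write a synthetic fixture bundle to disk
#'
#' Writes `expr.tsv`, `surv.tsv`, `sets.gmt` and `truth.json` for a preset
#' cohort; the recorded seed reproduces the bundle exactly.
#'
#' @param out_dir Output directory (created if needed).
#' @param preset `"tiny"` or `"default"`.
#' @param seed Integer seed.
#' @return Invisibly, the list of file paths.
#' @export
write_fixture_bundle <- function(out_dir, preset = c("tiny", "default"), seed = 1) {
  preset <- match.arg(preset)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_preset_cohort(preset, seed = seed)
  paths <- list(expr = file.path(out_dir, "expr.tsv"),
                surv = file.path(out_dir, "surv.tsv"),
                sets = file.path(out_dir, "sets.gmt"),
                truth = file.path(out_dir, "truth.json"))
  write_expression_table(sim$expr, paths$expr)
  write_survival_table(sim$surv, paths$surv)
  write_gmt(sim$sets, paths$sets)
  truth <- sim$truth
  jsonlite::write_json(list(preset = preset, seed = seed,
                            active_pathways = as.list(truth$active_pathways),
                            baseline_shape = truth$baseline_shape,
                            baseline_scale = truth$baseline_scale,
                            target_event_rate = truth$target_event_rate,
                            censoring_max = truth$censoring_max),
                       paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
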