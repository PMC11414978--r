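test_that("feature construction uses training statistics only (no leakage)", {
  sim <- tiny_cohort()
  tr <- colnames(sim$expr)[1:20]
  te <- colnames(sim$expr)[21:30]
  cfg <- model_config("z", "pathway_scores", sets = sim$sets,
                      method = "zscore", min_size = 2)
  feats <- suppressMessages(construct_features(cfg, sim$expr[, tr], sim$expr[, te]))
  # deliberately leaked version: validation samples standardized by their own
  # statistics differs from the shipped construction
  sets <- suppressMessages(restrict_to_universe(cfg$sets, rownames(sim$expr),
                                                min_size = 2))
  leaked <- zscore_scores(sim$expr[, te], sets)
  expect_gt(max(abs(feats$x_new - leaked)), 1e-6)
  # each held-out sample's features are independent of its companions
  solo <- suppressMessages(
    construct_features(cfg, sim$expr[, tr], sim$expr[, te[3], drop = FALSE]))
  expect_equal(solo$x_new[, 1], feats$x_new[, 3], tolerance = 1e-12)
  # ssGSEA construction stores and reuses the training normalization range
  cfg_ss <- model_config("ss", "pathway_scores", sets = sim$sets,
                         method = "ssgsea", min_size = 2)
  f_ss <- suppressMessages(construct_features(cfg_ss, sim$expr[, tr], sim$expr[, te]))
  solo_ss <- suppressMessages(
    construct_features(cfg_ss, sim$expr[, tr], sim$expr[, te[1], drop = FALSE]))
  expect_equal(solo_ss$x_new[, 1], f_ss$x_new[, 1], tolerance = 1e-15)
})

test_that("internal validation is seed-reproducible and identical configs tie", {
  sim <- tiny_cohort()
  cfg1 <- model_config("m1", "pathway_scores", sets = sim$sets,
                       method = "zscore", min_size = 2)
  cfg2 <- model_config("m2", "pathway_scores", sets = sim$sets,
                       method = "zscore", min_size = 2)
  rep1 <- suppressMessages(
    internal_validation(sim$expr, sim$surv, list(cfg1, cfg2), n_repeats = 3,
                        seed = 77, n_folds = 3, n_lambda = 12,
                        compute_ibs = TRUE))
  rep2 <- suppressMessages(
    internal_validation(sim$expr, sim$surv, list(cfg1, cfg2), n_repeats = 3,
                        seed = 77, n_folds = 3, n_lambda = 12,
                        compute_ibs = TRUE))
  expect_identical(rep1$records, rep2$records)
  m1 <- rep1$records[rep1$records$config == "m1", ]
  m2 <- rep1$records[rep1$records$config == "m2", ]
  expect_equal(m1$cindex, m2$cindex)
  expect_equal(rep1$pairwise$cindex["m1", "m2"], 1)
  # summary means equal the mean of the records
  expect_equal(rep1$summary$mean_cindex[1], mean(m1$cindex), tolerance = 1e-12)
  # split sizes respect the 70/30 design
  expect_equal(rep1$n_train + rep1$n_test, ncol(sim$expr))
  expect_equal(rep1$n_train, 21)
})

test_that("external validation on the training set reproduces in-sample metrics", {
  sim <- tiny_cohort()
  cfg <- model_config("ss", "pathway_scores", sets = sim$sets,
                      method = "ssgsea", min_size = 2)
  model <- suppressMessages(
    fit_prognostic_model(sim$expr, sim$surv, cfg, seed = 5, n_folds = 3,
                         n_lambda = 12))
  risk_in <- predict_for_model(model, sim$expr)
  res <- suppressMessages(
    external_validation(model, sim$expr, sim$surv, B = 50, seed = 9))
  expect_equal(res$cindex$estimate,
               concordance_index(risk_in, sim$surv)$estimate, tolerance = 1e-12)
  expect_true(res$ibs$estimate >= 0 && res$ibs$estimate <= 1)
})

test_that("background-dependent models demand a stored reference for new samples", {
  sim <- tiny_cohort()
  cfg <- model_config("z", "pathway_scores", sets = sim$sets,
                      method = "zscore", min_size = 2)
  model <- suppressMessages(
    fit_prognostic_model(sim$expr, sim$surv, cfg, seed = 5, n_folds = 3,
                         n_lambda = 12))
  one <- sim$expr[, 1, drop = FALSE]
  expect_silent(r <- predict_for_model(model, one))
  model$feature_space$scoring_reference <- NULL
  expect_error(predict_for_model(model, one), "reference")
  # ssGSEA scores single samples with no reference at all
  cfg_ss <- model_config("ss", "pathway_scores", sets = sim$sets,
                         method = "ssgsea", min_size = 2)
  model_ss <- suppressMessages(
    fit_prognostic_model(sim$expr, sim$surv, cfg_ss, seed = 5, n_folds = 3,
                         n_lambda = 12))
  expect_length(predict_for_model(model_ss, one), 1)
})

test_that("reference alignment matches per-gene moments exactly", {
  ref <- random_expr(20, 15, seed = 8)
  new <- random_expr(20, 10, seed = 9) * 1.7 + 3
  aligned <- reference_align(new, ref)
  expect_equal(rowMeans(aligned), rowMeans(ref), tolerance = 1e-10)
  expect_equal(apply(aligned, 1, sd), apply(ref, 1, sd), tolerance = 1e-10)
  # already-aligned input is unchanged
  expect_equal(reference_align(aligned, ref), aligned, tolerance = 1e-12)
  # global shift is removed entirely
  shifted <- ref + 3
  colnames(shifted) <- paste0("n", seq_len(ncol(shifted)))
  expect_equal(unname(reference_align(shifted, ref)), unname(unclass(ref)),
               tolerance = 1e-10)
  expect_error(reference_align(ref[, 1, drop = FALSE], ref), ">= 2")
})

test_that("KNN imputation reproduces hand-computed weighted averages", {
  ref <- expression_matrix(matrix(c(1, 1, 1,
                                    1, 1, 2,
                                    5, 5, 5), 3, byrow = TRUE,
                                  dimnames = list(c("gA", "gB", "gC"),
                                                  c("r1", "r2", "r3"))))
  new <- expression_matrix(matrix(c(NA, 2, 10), 3,
                                  dimnames = list(c("gA", "gB", "gC"), "n1")),
                           allow_missing = TRUE)
  out <- suppressWarnings(knn_impute_new_samples(new, ref, K = 10))
  dAB <- 1   # euclidean over reference rows
  dAC <- sqrt(48)
  w <- 1 / (c(dAB, dAC) + 1e-6)
  expect_equal(out["gA", 1], sum(w * c(2, 10)) / sum(w), tolerance = 1e-12)
  # K = 1 keeps only the nearest observed neighbour
  out1 <- suppressWarnings(knn_impute_new_samples(new, ref, K = 1))
  expect_equal(out1["gA", 1], 2, tolerance = 1e-12)
  # observed entries never change; no-missing input returns unchanged
  expect_equal(out["gB", 1], 2)
  complete <- new; complete["gA", 1] <- 0
  expect_identical(knn_impute_new_samples(complete, ref), complete)
})

test_that("KNN imputation enforces its preconditions and the 5% allowance", {
  ref <- random_expr(30, 10, seed = 10)
  new <- random_expr(30, 4, seed = 11)
  masked <- mask_random_genes(new, 0.1, seed = 12)
  expect_warning(knn_impute_new_samples(masked$expr, ref), "5% missing")
  small <- mask_random_genes(new, 0.03, seed = 13)
  expect_silent(knn_impute_new_samples(small$expr, ref))
  # a missing gene absent from the reference is an error
  bad <- new
  bad[1, 1] <- NA
  expect_error(knn_impute_new_samples(bad, ref[-1, ]), "absent from the reference")
  # an all-missing sample is an error
  allna <- new
  allna[, 2] <- NA
  expect_error(suppressWarnings(knn_impute_new_samples(allna, ref)),
               "no observed genes")
})

test_that("gene masking respects counts, seeds and the shared-mask switch", {
  expr <- random_expr(100, 5, seed = 14)
  m0 <- mask_random_genes(expr, 0, seed = 1)
  expect_identical(m0$expr, expr)
  m <- mask_random_genes(expr, 0.3, seed = 2)
  expect_true(all(colSums(is.na(m$expr)) == 30))
  expect_identical(mask_random_genes(expr, 0.3, seed = 2)$mask, m$mask)
  shared <- mask_random_genes(expr, 0.2, seed = 3, shared_mask = TRUE)
  miss_rows <- which(rowSums(shared$mask) > 0)
  expect_equal(length(miss_rows), 20)
  expect_true(all(shared$mask[miss_rows, ]))
  expect_error(mask_random_genes(expr, 1), "fraction")
})

test_that("the robustness experiment keys off the baseline at fraction zero", {
  sim <- tiny_cohort()
  cfg <- model_config("ss", "pathway_scores", sets = sim$sets,
                      method = "ssgsea", min_size = 2)
  model <- suppressMessages(
    fit_prognostic_model(sim$expr, sim$surv, cfg, seed = 5, n_folds = 3,
                         n_lambda = 12))
  res <- suppressWarnings(missing_robustness_experiment(
    model, sim$expr, sim$surv, fractions = c(0, 0.1), n_reps = 2, seed = 21))
  expect_equal(res$records$cindex[res$records$fraction == 0],
               rep(res$baseline, 2))
  expect_equal(nrow(res$records), 4)
  expect_true(all(res$summary$mean_cindex >= 0 & res$summary$mean_cindex <= 1))
})

test_that("models round-trip through JSON with bit-identical predictions", {
  sim <- tiny_cohort()
  cfg <- model_config("z", "pathway_scores", sets = sim$sets,
                      method = "zscore", min_size = 2)
  model <- suppressMessages(
    fit_prognostic_model(sim$expr, sim$surv, cfg, seed = 5, n_folds = 3,
                         n_lambda = 12))
  path <- withr::local_tempfile(fileext = ".json")
  write_model(model, path)
  back <- read_model(path)
  expect_identical(predict_for_model(back, sim$expr),
                   predict_for_model(model, sim$expr))
  pi1 <- predict_survival_probability(model, construct_features(cfg, sim$expr)$x_train,
                                      c(10, 50))
  pi2 <- predict_survival_probability(back, construct_features(cfg, sim$expr)$x_train,
                                      c(10, 50))
  expect_identical(pi1, pi2)
})

test_that("model reports expose selected features, pathways and policies", {
  sim <- tiny_cohort()
  cfg <- model_config("grp", "grouped_genes", sets = sim$sets, min_size = 2)
  model <- suppressMessages(
    fit_prognostic_model(sim$expr, sim$surv, cfg, seed = 5, n_folds = 3,
                         n_lambda = 12))
  rep <- model_report(model, data_description = "tiny synthetic cohort")
  nz_groups <- sum(vapply(model$groups$groups, function(i)
    any(model$coefficients[i] != 0), logical(1)))
  expect_equal(rep$model$n_selected_pathways, nz_groups)
  expect_equal(rep$model$n_selected_features, sum(model$coefficients != 0))
  expect_match(rep$missing_data_policy, "5%")
  dir <- withr::local_tempdir()
  paths <- write_report(rep, file.path(dir, "report"))
  expect_true(file.exists(paths["json"]))
  parsed <- jsonlite::read_json(paths["json"])
  expect_equal(parsed$model$n_selected_features, sum(model$coefficients != 0))

  # an all-zero model reports zero selected features
  d <- random_surv_data(40, 4, seed = 90)
  fit0 <- fit_penalized_cox(d$X, d$surv, "lasso",
                            lambda = 2 * lambda_max(d$X, d$surv, "lasso"))
  fit0$feature_space <- list(kind = "genes")
  rep0 <- model_report(fit0)
  expect_equal(rep0$model$n_selected_features, 0)
})

test_that("the full pipeline is bitwise-reproducible under a fixed seed", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  suppressMessages(suppressWarnings(run_pipeline(dir1, seed = 33)))
  suppressMessages(suppressWarnings(run_pipeline(dir2, seed = 33)))
  files1 <- sort(list.files(dir1, recursive = TRUE))
  files2 <- sort(list.files(dir2, recursive = TRUE))
  expect_identical(files1, files2)
  for (f in files1) {
    expect_identical(readLines(file.path(dir1, f), warn = FALSE),
                     readLines(file.path(dir2, f), warn = FALSE))
  }
})
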