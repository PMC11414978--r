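test_that("group structures must partition the predictors with positive weights", {
  expect_error(group_structure(list(1:3, 3:5), 5), "overlap")
  expect_error(group_structure(list(1:3), 5), "cover")
  gs <- group_structure(list(a = 1:3, b = 4:5), 5)
  expect_equal(gs$weights, sqrt(c(3, 2)))
  gs1 <- group_structure(list(a = 1:3, b = 4:5), 5, weight_rule = "cardinality")
  expect_equal(gs1$weights, c(3, 2))
})

test_that("penalty above lambda_max yields the exact all-zero model", {
  d <- random_surv_data(80, 10, beta = c(0.5, rep(0, 9)), seed = 3)
  lm_l <- lambda_max(d$X, d$surv, "lasso")
  fit <- fit_penalized_cox(d$X, d$surv, "lasso", lambda = lm_l * 1.000001)
  expect_true(all(fit$coefficients == 0))
  # just below lambda_max at least one coefficient enters
  fit2 <- fit_penalized_cox(d$X, d$surv, "lasso", lambda = lm_l * 0.95)
  expect_gt(sum(fit2$coefficients != 0), 0)

  gs <- group_structure(split(1:10, rep(1:5, each = 2)), 10)
  lm_g <- lambda_max(d$X, d$surv, "group", groups = gs)
  fitg <- fit_penalized_cox(d$X, d$surv, "group", lambda = lm_g * 1.000001,
                            groups = gs)
  expect_true(all(fitg$coefficients == 0))
})

test_that("the unpenalized fit matches an independent Newton-Raphson Cox solver", {
  d <- random_surv_data(200, 5, beta = c(0.8, -0.5, 0.3, 0, 0), seed = 11)
  fit <- fit_penalized_cox(d$X, d$surv, "lasso", lambda = 0)
  beta_newton <- oracle_newton_cox(d$X, d$surv$time, d$surv$event)
  expect_equal(unname(fit$coefficients), beta_newton, tolerance = 1e-3)
  # and agrees with survival::coxph (Breslow ties)
  cox <- survival::coxph(survival::Surv(d$surv$time, d$surv$event) ~ t(d$X),
                         ties = "breslow")
  expect_equal(unname(fit$coefficients), unname(coef(cox)), tolerance = 1e-3)
})

test_that("singleton groups with unit weights reduce the group lasso to the lasso", {
  d <- random_surv_data(100, 20, beta = c(1, -1, rep(0, 18)), seed = 5)
  gs <- group_structure(as.list(1:20), 20, weight_rule = "one")
  lam <- 0.5 * lambda_max(d$X, d$surv, "lasso")
  fit_l <- fit_penalized_cox(d$X, d$surv, "lasso", lambda = lam)
  fit_g <- fit_penalized_cox(d$X, d$surv, "group", lambda = lam, groups = gs)
  expect_equal(fit_g$coefficients, fit_l$coefficients, tolerance = 1e-4)
})

test_that("lasso coefficients agree with glmnet at a matched penalty", {
  d <- random_surv_data(150, 8, beta = c(0.9, -0.6, rep(0, 6)), seed = 13)
  lam <- 0.3 * lambda_max(d$X, d$surv, "lasso", standardize = FALSE)
  fit <- fit_penalized_cox(d$X, d$surv, "lasso", lambda = lam,
                           standardize = FALSE)
  g <- glmnet::glmnet(t(d$X), survival::Surv(d$surv$time, d$surv$event),
                      family = "cox", lambda = lam, standardize = FALSE,
                      thresh = 1e-12)
  expect_equal(unname(fit$coefficients), as.numeric(coef(g)), tolerance = 1e-3)
})

test_that("the solver objective decreases monotonically", {
  d <- random_surv_data(60, 15, beta = c(rep(0.4, 3), rep(0, 12)), seed = 17)
  fit <- fit_penalized_cox(d$X, d$surv, "lasso",
                           lambda = 0.1 * lambda_max(d$X, d$surv, "lasso"))
  expect_true(all(diff(fit$solver$obj_path) <= 1e-12))
})

test_that("coefficients are invariant to sample permutation", {
  d <- random_surv_data(70, 6, beta = c(0.7, rep(0, 5)), seed = 19)
  perm <- sample(70)
  fit1 <- fit_penalized_cox(d$X, d$surv, "lasso", lambda = 0.05)
  fit2 <- fit_penalized_cox(d$X[, perm], d$surv[perm, ], "lasso", lambda = 0.05)
  expect_equal(fit1$coefficients, fit2$coefficients, tolerance = 1e-8)
})

test_that("group sparsity is all-in/all-out and KKT conditions hold at zero coefficients", {
  d <- random_surv_data(120, 12, beta = c(rep(0.6, 3), rep(0, 9)), seed = 23)
  gs <- group_structure(split(1:12, rep(1:4, each = 3)), 12)
  lam <- 0.4 * lambda_max(d$X, d$surv, "group", groups = gs)
  fit <- fit_penalized_cox(d$X, d$surv, "group", lambda = lam, groups = gs)
  for (g in gs$groups) {
    blk <- fit$coefficients[g]
    expect_true(all(blk == 0) || sqrt(sum(blk^2)) > 0)
  }
  # lasso KKT: |gradient_j| <= lambda + tol wherever beta_j = 0
  lam_l <- 0.4 * lambda_max(d$X, d$surv, "lasso")
  fit_l <- fit_penalized_cox(d$X, d$surv, "lasso", lambda = lam_l)
  std <- (d$X - rowMeans(d$X)) / apply(d$X, 1, sd)
  eta <- as.numeric(crossprod(d$X, fit_l$coefficients))
  gb <- as.numeric(std %*% pathsurv:::.cox_obj_grad_eta(eta, d$surv$time,
                                                        d$surv$event)$grad)
  zero <- fit_l$coefficients == 0
  expect_true(all(abs(gb[zero]) <= lam_l + 1e-4))
})

test_that("cross-validation is deterministic, stratified, and finds real signal", {
  d <- random_surv_data(150, 10, beta = c(1.5, rep(0, 9)), seed = 29)
  cv1 <- cv_lambda(d$X, d$surv, "lasso", n_folds = 5, n_lambda = 30, seed = 31)
  cv2 <- cv_lambda(d$X, d$surv, "lasso", n_folds = 5, n_lambda = 30, seed = 31)
  expect_identical(cv1$fold, cv2$fold)
  expect_identical(cv1$lambda, cv2$lambda)
  expect_true(all(tapply(d$surv$event, cv1$fold, sum) >= 1))
  fit <- fit_penalized_cox(d$X, d$surv, "lasso", lambda = cv1$lambda)
  expect_true(fit$coefficients["f01"] != 0)
})

test_that("cross-validation on pure noise keeps the model near-empty in most seeds", {
  n_small <- 0
  for (s in 1:8) {
    d <- random_surv_data(100, 15, seed = 400 + s)
    cv <- cv_lambda(d$X, d$surv, "lasso", n_folds = 5, n_lambda = 25, seed = s)
    fit <- fit_penalized_cox(d$X, d$surv, "lasso", lambda = cv$lambda)
    if (sum(fit$coefficients != 0) <= 3) n_small <- n_small + 1
  }
  expect_gte(n_small, 6)
})

test_that("risk prediction is a plain linear predictor over aligned features", {
  d <- random_surv_data(50, 4, beta = c(0.5, -0.5, 0, 0), seed = 37)
  fit <- fit_penalized_cox(d$X, d$surv, "lasso", lambda = 0.05)
  X_new <- matrix(c(1, 2, 3, 4, 0, 0, 0, 0), 4,
                  dimnames = list(rownames(d$X), c("n1", "n2")))
  lp <- predict_risk(fit, X_new)
  expect_equal(unname(lp), as.numeric(crossprod(X_new, fit$coefficients)))
  # reordered features align by name
  lp2 <- predict_risk(fit, X_new[c(3, 1, 4, 2), ])
  expect_equal(lp, lp2)
  expect_error(predict_risk(fit, X_new[1:2, ]), "missing")
  fit0 <- fit_penalized_cox(d$X, d$surv, "lasso",
                            lambda = 2 * lambda_max(d$X, d$surv, "lasso"))
  expect_equal(unname(predict_risk(fit0, X_new)), c(0, 0))
})

test_that("survival probabilities follow the Breslow baseline contract", {
  d <- random_surv_data(80, 3, beta = c(0.8, 0, 0), seed = 41)
  fit <- fit_penalized_cox(d$X, d$surv, "lasso", lambda = 0.01)
  times <- c(0, sort(sample(d$surv$time, 5)))
  pi_mat <- predict_survival_probability(fit, d$X[, 1:4], times)
  expect_equal(unname(pi_mat[, 1]), rep(1, 4))              # pi(x, 0) = 1
  expect_true(all(diff(t(pi_mat)) <= 1e-12))                # non-increasing in t
  expect_true(all(pi_mat > 0 & pi_mat <= 1))
  expect_warning(predict_survival_probability(fit, d$X[, 1:2],
                                              max(d$surv$time) + 10),
                 "extrapolated")
  # very negative linear predictor pushes survival towards 1
  X_low <- matrix(c(-50, 0, 0), 3, dimnames = list(rownames(d$X), "low"))
  pi_low <- predict_survival_probability(fit, X_low, max(fit$baseline$time))
  expect_gt(pi_low[1, 1], 0.999)
})

test_that("the squared-error variant solves the penalized least-squares problem", {
  set.seed(43)
  X <- matrix(rnorm(300), 3, 100, dimnames = list(c("a", "b", "c"), NULL))
  colnames(X) <- sprintf("s%03d", 1:100)
  y <- 2 + 1.5 * X["a", ] - 0.7 * X["b", ] + rnorm(100, 0, 0.3)
  fit <- fit_penalized_lm(X, y, "lasso", lambda = 0, tol = 1e-12)
  ls <- lm(y ~ t(X))
  expect_equal(unname(fit$coefficients), unname(coef(ls)[-1]), tolerance = 1e-5)
  expect_equal(fit$intercept, unname(coef(ls)[1]), tolerance = 1e-5)
  # strong penalty empties the model
  fit0 <- fit_penalized_lm(X, y, "lasso", lambda = 100)
  expect_true(all(fit0$coefficients == 0))
})

test_that("fitting requires events and complete predictors", {
  d <- random_surv_data(20, 3, seed = 47)
  surv0 <- d$surv
  surv0$event <- 0
  expect_error(fit_penalized_cox(d$X, surv0, "lasso", lambda = 0.1),
               "at least one event")
  Xna <- d$X
  Xna[1, 1] <- NA
  expect_error(fit_penalized_cox(Xna, d$surv, "lasso", lambda = 0.1), "missing")
})
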