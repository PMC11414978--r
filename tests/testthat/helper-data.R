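# Shared small fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

tiny_cohort <- function() {
  if (is.null(.fixture_env$tiny)) {
    .fixture_env$tiny <- simulate_preset_cohort("tiny", seed = 42)
  }
  .fixture_env$tiny
}

# small random survival data with controllable signal
random_surv_data <- function(n, p, beta = rep(0, p), cens_max = 3, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(p * n), p, n,
              dimnames = list(sprintf("f%02d", seq_len(p)),
                              sprintf("s%03d", seq_len(n))))
  lp <- as.numeric(crossprod(X, beta))
  tt <- rexp(n, exp(lp))
  cc <- runif(n, 0, cens_max)
  list(X = X,
       surv = survival_table(colnames(X), pmin(tt, cc), as.numeric(tt <= cc)))
}

random_expr <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  expression_matrix(matrix(rnorm(n_genes * n_samples, 8, 2), n_genes,
                           dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                           sprintf("s%02d", seq_len(n_samples)))))
}
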