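strip_score_attrs <- function(x) {
  attributes(x) <- attributes(x)[c("dim", "dimnames")]
  x
}

# Independent literal-formula oracles used to validate the optimized
# implementations. Deliberately written as plain loops that follow the
# method definitions step by step; they share no code with the package.

oracle_zscore <- function(expr, sets, denominator = "sqrt") {
  z <- expr
  for (g in seq_len(nrow(expr))) {
    z[g, ] <- (expr[g, ] - mean(expr[g, ])) / sd(expr[g, ])
  }
  out <- matrix(NA_real_, length(sets), ncol(expr),
                dimnames = list(names(sets), colnames(expr)))
  for (k in seq_along(sets)) {
    J <- intersect(sets[[k]], rownames(expr))
    for (i in seq_len(ncol(expr))) {
      s <- 0
      for (g in J) s <- s + z[g, i]
      D <- if (denominator == "sqrt") sqrt(length(J)) else length(J)
      out[k, i] <- s / D
    }
  }
  out
}

oracle_ssgsea <- function(expr, sets, alpha = 0.25, normalize = TRUE) {
  N <- nrow(expr)
  genes <- rownames(expr)
  out <- matrix(NA_real_, length(sets), ncol(expr),
                dimnames = list(names(sets), colnames(expr)))
  for (i in seq_len(ncol(expr))) {
    ord <- order(-expr[, i], genes)   # descending, ties by gene id
    ranked <- genes[ord]
    s <- (N - seq_len(N) + 1)^alpha   # rank score at each position
    for (k in seq_along(sets)) {
      J <- sets[[k]]
      denom_in <- sum(s[ranked %in% J])
      n_out <- N - sum(ranked %in% J)
      es <- 0; cum_in <- 0; cum_out <- 0
      for (pos in seq_len(N)) {
        if (ranked[pos] %in% J) cum_in <- cum_in + s[pos]
        else cum_out <- cum_out + 1
        es <- es + (cum_in / denom_in - cum_out / n_out)
      }
      out[k, i] <- es
    }
  }
  if (normalize) out <- out / (max(out) - min(out))
  out
}

oracle_gsva <- function(expr, sets, tau = 1, es_mode = "max_diff") {
  N <- nrow(expr)
  n <- ncol(expr)
  genes <- rownames(expr)
  # step 1: Gaussian kernel CDF per gene, bandwidth sd/4
  khat <- matrix(NA_real_, N, n, dimnames = dimnames(expr))
  for (g in seq_len(N)) {
    h <- sd(expr[g, ]) / 4
    for (j in seq_len(n)) {
      if (h == 0) khat[g, j] <- 0.5
      else khat[g, j] <- mean(pnorm((expr[g, j] - expr[g, ]) / h))
    }
  }
  out <- matrix(NA_real_, length(sets), n,
                dimnames = list(names(sets), colnames(expr)))
  for (j in seq_len(n)) {
    # step 2: rank by khat descending (ties by gene id), symmetrize
    ord <- order(-khat[, j], genes)
    rho <- integer(N); rho[ord] <- seq_len(N)
    r <- abs(N / 2 - rho)
    for (k in seq_along(sets)) {
      J <- sets[[k]]
      inset <- genes %in% J
      denom <- sum(r[inset]^tau)
      # step 3: KS-like walk down the ranked list
      walk <- numeric(N); acc <- 0
      for (pos in seq_len(N)) {
        g <- ord[pos]
        if (inset[g]) acc <- acc + r[g]^tau / denom
        else acc <- acc - 1 / (N - sum(inset))
        walk[pos] <- acc
      }
      if (es_mode == "max_diff") {
        out[k, j] <- max(c(0, walk)) + min(c(0, walk))
      } else {
        out[k, j] <- walk[which.max(abs(walk))]
      }
    }
  }
  out
}

# exhaustive pair enumeration with the censoring-aware usability rules
oracle_cindex <- function(risk, time, event) {
  num <- 0; den <- 0
  n <- length(risk)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    usable <- (time[i] < time[j] && event[i] == 1) ||
      (time[i] == time[j] && event[i] == 1 && event[j] == 0)
    if (!usable) next
    den <- den + 1
    if (risk[i] > risk[j]) num <- num + 1
    else if (risk[i] == risk[j]) num <- num + 0.5
  }
  if (den == 0) return(NA_real_)
  num / den
}

# literal product-limit estimator
oracle_km <- function(times, ind, t_eval, left = FALSE) {
  ut <- sort(unique(times))
  s <- 1
  for (u in ut) {
    if ((left && u < t_eval) || (!left && u <= t_eval)) {
      n_at_risk <- sum(times >= u)
      d <- sum(times == u & ind == 1)
      s <- s * (1 - d / n_at_risk)
    }
  }
  s
}

# term-by-term IPCW Brier score with G from the literal censoring KM
oracle_brier <- function(pi, time, event, t_star) {
  n <- length(pi)
  total <- 0
  for (i in seq_len(n)) {
    if (event[i] == 1 && time[i] <= t_star) {
      g <- oracle_km(time, 1 - event, time[i], left = TRUE)
      w <- 1 / g
    } else if (time[i] > t_star) {
      g <- oracle_km(time, 1 - event, t_star)
      w <- 1 / g
    } else {
      w <- 0
    }
    total <- total + w * (as.numeric(time[i] > t_star) - pi[i])^2
  }
  total / n
}

# unpenalized Cox fit by plain Newton-Raphson (Breslow ties)
oracle_newton_cox <- function(X, time, event, iter = 50) {
  p <- nrow(X)
  beta <- rep(0, p)
  for (it in seq_len(iter)) {
    eta <- as.numeric(crossprod(X, beta))
    ee <- exp(eta)
    grad <- rep(0, p); hess <- matrix(0, p, p)
    for (u in sort(unique(time[event == 1]))) {
      at_risk <- which(time >= u)
      d <- sum(time == u & event == 1)
      s0 <- sum(ee[at_risk])
      s1 <- as.numeric(X[, at_risk, drop = FALSE] %*% ee[at_risk])
      s2 <- matrix(0, p, p)
      for (k in at_risk) s2 <- s2 + ee[k] * tcrossprod(X[, k])
      ev_idx <- which(time == u & event == 1)
      grad <- grad + rowSums(X[, ev_idx, drop = FALSE]) - d * s1 / s0
      hess <- hess + d * (s2 / s0 - tcrossprod(s1 / s0))
    }
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(step)) < 1e-10) break
  }
  beta
}
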