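#' Restrict gene sets to a measured gene universe
#'
#' Each set is intersected with the measured genes; sets whose post-
#' intersection size falls outside `[min_size, max_size]` are dropped with a
#' message reporting the count.
#'
#' @param sets A `GeneSetCollection`.
#' @param genes Character vector of measured gene ids.
#' @param min_size,max_size Size bounds after intersection (defaults 5, 500).
#' @return A restricted `GeneSetCollection`.
#' @export
restrict_to_universe <- function(sets, genes, min_size = 5, max_size = 500) {
  stopifnot(inherits(sets, "GeneSetCollection"), min_size >= 1)
  restricted <- lapply(sets$sets, function(s) intersect(s, genes))
  ok <- lengths(restricted) >= min_size & lengths(restricted) <= max_size
  if (!all(ok)) {
    message(sum(!ok), " of ", length(ok),
            " gene sets dropped by universe restriction/size filter")
  }
  if (!any(ok)) stop("all gene sets dropped after universe restriction")
  gene_set_collection(restricted[ok], sets$source_name)
}

new_pathway_scores <- function(scores, method, method_params) {
  if (!all(is.finite(scores))) stop("pathway scores must be finite")
  structure(scores, method = method, method_params = method_params,
            class = c("pathway_scores", class(scores)))
}

#' @export
print.pathway_scores <- function(x, ...) {
  cat(sprintf("pathway scores (%s): %d pathways x %d samples\n",
              attr(x, "method"), nrow(x), ncol(x)))
  invisible(x)
}

# Per-sample gene positions for rank-based methods: expression descending,
# ties broken by lexicographic gene id so results are platform-independent.
rank_positions <- function(values, ids) {
  ord <- order(-values, ids, method = "radix")
  pos <- integer(length(values))
  pos[ord] <- seq_along(values)
  pos
}

#' Z-score pathway scores
#'
#' Each gene is standardized across samples (mean 0, sd 1) to `z_ij`; the
#' score of sample *i* for set *J* is `sum(z_ij, j in J) / D` with
#' `D = sqrt(|J|)` (default, the combined z-score convention) or `D = |J|`
#' (a mean). Zero-variance genes carry no sample-distribution information and
#' are dropped from all sets with a warning.
#'
#' Standardization relies on the background samples. When scoring new samples
#' against a trained model, pass the training matrix as `reference` so the
#' training means and standard deviations are reused (no leakage; single new
#' samples become scoreable).
#'
#' @param expr Complete expression matrix (genes x samples).
#' @param sets A `GeneSetCollection` (already restricted to the universe).
#' @param denominator `"sqrt"` (default) or `"count"`.
#' @param reference Optional training expression matrix supplying the
#'   per-gene standardization statistics.
#' @return A pathways x samples score matrix with method metadata.
#' @export
zscore_scores <- function(expr, sets, denominator = c("sqrt", "count"),
                          reference = NULL) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(sets, "GeneSetCollection"))
  if (anyNA(expr)) stop("expression contains missing values; impute first")
  bg <- if (is.null(reference)) expr else reference
  if (ncol(bg) < 2) {
    stop("z-score standardization needs >= 2 background samples; ",
         "supply a training reference to score fewer")
  }
  mu <- rowMeans(bg)
  sdev <- apply(bg, 1, stats::sd)
  usable <- names(mu)[sdev > 0]
  if (length(usable) < nrow(bg)) {
    warning(nrow(bg) - length(usable), " zero-variance genes dropped from all sets")
  }
  restricted <- lapply(sets$sets, function(s) {
    s <- intersect(s, rownames(expr))
    dropped <- s[!(s %in% usable)]
    setdiff(s, dropped)
  })
  dead <- lengths(restricted) == 0
  if (any(dead)) {
    stop("set(s) with only zero-variance genes: ",
         paste(names(restricted)[dead], collapse = ", "))
  }
  z <- (expr[usable, , drop = FALSE] - mu[usable]) / sdev[usable]
  scores <- matrix(NA_real_, length(restricted), ncol(expr),
                   dimnames = list(names(restricted), colnames(expr)))
  for (k in seq_along(restricted)) {
    s <- restricted[[k]]
    d <- if (denominator == "sqrt") sqrt(length(s)) else length(s)
    scores[k, ] <- colSums(z[s, , drop = FALSE]) / d
  }
  new_pathway_scores(scores, "zscore",
                     list(denominator = denominator,
                          reference = !is.null(reference)))
}

#' ssGSEA pathway scores
#'
#' Single-sample gene-set enrichment. Within each sample, genes are ranked
#' by expression (descending, ties broken by gene id) and assigned the rank
#' score `s_g = N - position + 1`. Walking down the ranked list, the
#' enrichment score for set *J* is the sum over positions of
#' `P_in(i) - P_out(i)`, where `P_in` accumulates `s_g^alpha` over in-set
#' genes (normalized by the in-set total) and `P_out` accumulates the
#' uniform out-of-set step `1/(N - |J|)`. Scores depend only on within-sample
#' gene ranks, so no background cohort is required.
#'
#' @param expr Complete expression matrix.
#' @param sets A `GeneSetCollection`.
#' @param alpha Rank-weighting exponent (default 0.25).
#' @param normalize Divide all scores by the matrix-wide `max - min`
#'   (default `TRUE`).
#' @param norm_range Optional fixed normalization constant (the training
#'   matrix's score range). When scoring new samples for a trained model this
#'   keeps each sample's score a function of that sample alone.
#' @return A pathways x samples score matrix with method metadata.
#' @export
ssgsea_scores <- function(expr, sets, alpha = 0.25, normalize = TRUE,
                          norm_range = NULL) {
  stopifnot(inherits(sets, "GeneSetCollection"))
  if (anyNA(expr)) stop("expression contains missing values; impute first")
  if (alpha < 0) stop("alpha must be non-negative")
  genes <- rownames(expr)
  N <- length(genes)
  full <- vapply(sets$sets, function(s) length(intersect(s, genes)) == N, logical(1))
  if (any(full)) {
    stop("set(s) equal to the full gene universe (no out-of-set genes): ",
         paste(names(sets$sets)[full], collapse = ", "))
  }
  member <- lapply(sets$sets, function(s) rownames(expr) %in% s)
  scores <- matrix(0, length(sets$sets), ncol(expr),
                   dimnames = list(names(sets$sets), colnames(expr)))
  for (j in seq_len(ncol(expr))) {
    ord <- order(-expr[, j], genes, method = "radix")
    s_rank <- (N - seq_len(N) + 1)^alpha  # rank score at each position
    for (k in seq_along(member)) {
      inset <- member[[k]][ord]
      win <- s_rank * inset
      p_in <- cumsum(win) / sum(win)
      p_out <- cumsum(!inset) / (N - sum(inset))
      scores[k, j] <- sum(p_in - p_out)
    }
  }
  rng <- NULL
  if (normalize) {
    rng <- if (is.null(norm_range)) max(scores) - min(scores) else norm_range
    if (rng > 0) scores <- scores / rng
  }
  new_pathway_scores(scores, "ssgsea",
                     list(alpha = alpha, normalize = normalize,
                          norm_range = rng))
}

# Kernel CDF matrix for GSVA: khat[g, j] = mean_k Phi((x_gj - x_ref_gk)/h_g)
# with h_g = sd of gene g in the reference / 4; zero-variance genes get 0.5.
gsva_kcdf <- function(expr, reference) {
  h <- apply(reference, 1, stats::sd) / 4
  khat <- matrix(0.5, nrow(expr), ncol(expr), dimnames = dimnames(expr))
  for (g in seq_len(nrow(expr))) {
    if (h[g] > 0) {
      khat[g, ] <- colMeans(stats::pnorm(outer(reference[g, ], expr[g, ], function(r, x) (x - r) / h[g])))
    }
  }
  khat
}

#' GSVA pathway scores
#'
#' Gene-set variation analysis. Each gene's expression is transformed to an
#' empirical kernel CDF over the background samples (Gaussian kernel,
#' bandwidth `sd/4`); per sample, genes are ranked by the CDF value
#' (descending, ties by gene id) and the rank is symmetrized to
#' `r_g = |N/2 - rank_g|`. A Kolmogorov-Smirnov-like random walk down the
#' ranked list (in-set steps weighted `r_g^tau`, out-of-set steps uniform)
#' yields the enrichment score: the sum of the largest positive and largest
#' negative deviations (`es_mode = "max_diff"`, default) or the signed
#' maximum-magnitude deviation (`"max_abs"`). Scores lie in (-1, 1).
#'
#' The kernel CDF depends on the background cohort. Pass the training matrix
#' as `reference` to score new samples against the training distribution.
#'
#' @param expr Complete expression matrix.
#' @param sets A `GeneSetCollection`.
#' @param tau Rank-weighting exponent (default 1).
#' @param es_mode `"max_diff"` or `"max_abs"`.
#' @param reference Optional training expression matrix used as the kernel
#'   CDF background (>= 3 samples).
#' @return A pathways x samples score matrix with method metadata.
#' @export
gsva_scores <- function(expr, sets, tau = 1, es_mode = c("max_diff", "max_abs"),
                        reference = NULL) {
  es_mode <- match.arg(es_mode)
  stopifnot(inherits(sets, "GeneSetCollection"))
  if (anyNA(expr)) stop("expression contains missing values; impute first")
  if (tau < 0) stop("tau must be non-negative")
  bg <- if (is.null(reference)) expr else reference
  if (ncol(bg) < 3) {
    stop("GSVA needs >= 3 background samples for the kernel CDF; ",
         "supply a training reference to score fewer")
  }
  if (!is.null(reference) && !identical(rownames(reference), rownames(expr))) {
    bg <- reference[rownames(expr), , drop = FALSE]
  }
  genes <- rownames(expr)
  N <- length(genes)
  khat <- gsva_kcdf(expr, bg)
  member <- lapply(sets$sets, function(s) genes %in% s)
  scores <- matrix(0, length(sets$sets), ncol(expr),
                   dimnames = list(names(sets$sets), colnames(expr)))
  for (j in seq_len(ncol(expr))) {
    pos <- rank_positions(khat[, j], genes)
    r <- abs(N / 2 - pos)
    ord <- order(pos)
    r_ord <- r[ord]^tau
    for (k in seq_along(member)) {
      inset <- member[[k]][ord]
      nin <- sum(inset)
      if (nin == 0 || nin == N) stop("set '", names(member)[k],
                                     "' empty or equal to the universe")
      walk <- cumsum(ifelse(inset, r_ord / sum(r_ord[inset]),
                            -1 / (N - nin)))
      if (es_mode == "max_diff") {
        scores[k, j] <- max(c(0, walk)) + min(c(0, walk))
      } else {
        scores[k, j] <- walk[which.max(abs(walk))]
      }
    }
  }
  new_pathway_scores(scores, "gsva",
                     list(tau = tau, es_mode = es_mode,
                          bandwidth = "sd/4", reference = !is.null(reference)))
}

#' Score pathways by a named method
#'
#' Dispatch wrapper over [ssgsea_scores()], [gsva_scores()] and
#' [zscore_scores()] used by the validation harnesses and the command line.
#'
#' @param expr Expression matrix.
#' @param sets A `GeneSetCollection`.
#' @param method One of `"ssgsea"`, `"gsva"`, `"zscore"`.
#' @param reference Optional training reference for background-dependent
#'   methods (ignored by ssGSEA).
#' @param ... Method parameters (`alpha`, `tau`, `denominator`, ...).
#' @return A pathways x samples score matrix.
#' @export
score_pathways <- function(expr, sets, method = c("ssgsea", "gsva", "zscore"),
                           reference = NULL, ...) {
  method <- match.arg(method)
  switch(method,
         ssgsea = ssgsea_scores(expr, sets, ...),
         gsva = gsva_scores(expr, sets, reference = reference, ...),
         zscore = zscore_scores(expr, sets, reference = reference, ...))
}
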