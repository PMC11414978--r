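#' Pairwise Jaccard distances between gene sets
#'
#' `d(A, B) = 1 - |A intersect B| / |A union B|` on gene membership.
#'
#' @param sets A `GeneSetCollection` with at least two non-empty sets.
#' @return A symmetric distance matrix with zero diagonal.
#' @export
pathway_distance_matrix <- function(sets) {
  stopifnot(inherits(sets, "GeneSetCollection"))
  if (length(sets$sets) < 2) stop("need at least two gene sets")
  if (any(lengths(sets$sets) == 0)) stop("empty gene set")
  universe <- unique(unlist(sets$sets, use.names = FALSE))
  # binary membership matrix -> |intersections| by crossprod
  M <- vapply(sets$sets, function(s) universe %in% s, logical(length(universe)))
  inter <- crossprod(M * 1)
  sizes <- lengths(sets$sets)
  uni <- outer(sizes, sizes, `+`) - inter
  d <- 1 - inter / uni
  diag(d) <- 0
  dimnames(d) <- list(names(sets$sets), names(sets$sets))
  d
}

#' Select the most distinct pathways by hierarchical clustering
#'
#' Collections larger than `n_select` are reduced by average-linkage
#' hierarchical clustering on the Jaccard distance matrix: the tree is cut
#' into `n_select` clusters and each cluster contributes its medoid (the
#' member with the smallest summed distance to the rest of its cluster, ties
#' broken by lexicographic name). Collections with at most `n_select` sets
#' are returned unchanged, so small databases (e.g. the 50 hallmark sets)
#' are used in full.
#'
#' @param sets A `GeneSetCollection`.
#' @param n_select Number of representatives to keep (default 100).
#' @return A `GeneSetCollection` that is a subset of the input.
#' @export
select_distinct_pathways <- function(sets, n_select = 100) {
  stopifnot(inherits(sets, "GeneSetCollection"), n_select >= 1)
  if (length(sets$sets) <= n_select) return(sets)
  d <- pathway_distance_matrix(sets)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  cl <- stats::cutree(hc, k = n_select)
  reps <- vapply(split(names(cl), cl), function(members) {
    if (length(members) == 1) return(members)
    sub <- d[members, members, drop = FALSE]
    tot <- rowSums(sub)
    members[order(tot, members)][1]
  }, character(1))
  keep <- names(sets$sets)[names(sets$sets) %in% reps]
  gene_set_collection(sets$sets[keep], sets$source_name)
}
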