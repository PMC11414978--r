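#' Construct a validated expression matrix
#'
#' An expression matrix is a plain numeric matrix with genes in rows and
#' samples in columns, both uniquely named. Values are continuous log2-scale
#' expression. `NA` entries are only permitted when `allow_missing = TRUE`
#' (prediction-time inputs); training-path functions reject missing values.
#'
#' @param values Numeric matrix, genes x samples.
#' @param gene_ids Character vector of row names (defaults to `rownames(values)`).
#' @param sample_ids Character vector of column names (defaults to `colnames(values)`).
#' @param allow_missing Logical; permit `NA` entries.
#' @return A numeric matrix with validated dimnames.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              allow_missing = FALSE) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("gene_ids and sample_ids are required")
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values)) stop("gene_ids do not match row count")
  if (length(sample_ids) != ncol(values)) stop("sample_ids do not match column count")
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids: ", paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ", paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (!allow_missing && anyNA(values)) {
    stop("missing values are not allowed in this expression matrix")
  }
  if (any(!is.finite(values) & !is.na(values))) {
    stop("expression values must be finite or NA")
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  if (!all(is.na(values)) && max(values, na.rm = TRUE) > 30) {
    warning("expression maximum exceeds 30; values may not be log2-scale")
  }
  values
}

#' Construct a gene-set collection
#'
#' A thin container for named gene sets (pathways): a named list of unique
#' gene-symbol character vectors plus the name of the source database.
#'
#' @param sets Named list of character vectors.
#' @param source_name Label for the source collection (e.g. "Hallmark").
#' @return An object of class `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, source_name = "custom") {
  if (is.null(names(sets)) || any(names(sets) == "")) stop("all sets must be named")
  if (anyDuplicated(names(sets))) {
    stop("duplicate set names: ", paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  }
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0)) {
    stop("empty gene sets: ", paste(names(sets)[lengths(sets) == 0], collapse = ", "))
  }
  structure(list(sets = sets, source_name = source_name),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection '%s': %d sets, sizes %d-%d\n",
              x$source_name, length(x$sets),
              min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' @export
length.GeneSetCollection <- function(x) length(x$sets)

#' Construct a validated survival table
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param time Non-negative observed follow-up times in months
#'   (`min(T_i, C_i)`).
#' @param event Event indicator, 1 = event observed, 0 = censored.
#' @return A `data.frame` with columns `sample_id`, `time`, `event`.
#' @export
survival_table <- function(sample_id, time, event) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicate sample ids in survival table")
  time <- as.numeric(time)
  if (anyNA(time) || any(time < 0)) stop("survival times must be non-negative and non-missing")
  event <- as.numeric(event)
  if (anyNA(event) || !all(event %in% c(0, 1))) stop("event indicator must be 0 or 1")
  data.frame(sample_id = sample_id, time = time, event = event,
             stringsAsFactors = FALSE)
}

#' Read a GMT gene-set file
#'
#' Parses the tab-separated MSigDB dialect: set name, description (ignored),
#' then member genes. Duplicate genes within a line are dropped with a
#' warning; duplicate set names are an error.
#'
#' @param path Path to a GMT file.
#' @param source_name Collection label; defaults to the file name.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, source_name = NULL) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("GMT file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("GMT line ", which(nf < 3)[1], " has fewer than 3 tab-separated fields")
  }
  nms <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(nms)) {
    dup <- nms[duplicated(nms)][1]
    stop("duplicate set name '", dup, "' at line ", which(nms == dup)[2])
  }
  sets <- lapply(fields, function(f) {
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("duplicate genes within set '", f[[1]], "' deduplicated")
      genes <- unique(genes)
    }
    genes
  })
  names(sets) <- nms
  if (is.null(source_name)) source_name <- sub("\\.gmt$", "", basename(path))
  gene_set_collection(sets, source_name)
}

#' Write a gene-set collection to GMT
#'
#' @param sets A `GeneSetCollection`.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(inherits(sets, "GeneSetCollection"))
  lines <- vapply(names(sets$sets), function(nm) {
    paste(c(nm, "na", sets$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a tab-separated expression table
#'
#' First column holds gene ids, header row holds sample ids. Cells equal to
#' `missing_token` become `NA` (allowed only when `allow_missing = TRUE`);
#' any other non-numeric cell is an error reported with its coordinates.
#'
#' @param path Path to a TSV file.
#' @param missing_token String marking missing cells (default "NA").
#' @param allow_missing Permit missing cells (prediction-time input).
#' @return An [expression_matrix()].
#' @export
read_expression_table <- function(path, missing_token = "NA",
                                  allow_missing = FALSE) {
  if (!file.exists(path)) stop("expression table not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "", comment.char = "")
  gene_ids <- tab[[1]]
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene id in expression table: ",
         gene_ids[duplicated(gene_ids)][1])
  }
  cells <- as.matrix(tab[, -1, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  miss <- is.na(cells)  # read.table already maps literal "NA"
  miss[!miss] <- cells[!miss] == missing_token
  bad <- is.na(vals) & !miss
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell '%s' at gene '%s', sample '%s'",
                 cells[idx[1], idx[2]], gene_ids[idx[1]], colnames(cells)[idx[2]]))
  }
  vals[miss] <- NA_real_
  expression_matrix(vals, gene_ids, colnames(cells), allow_missing = allow_missing)
}

#' Write an expression matrix as TSV
#'
#' @param expr Expression matrix (genes x samples).
#' @param path Output path.
#' @param missing_token String written for `NA` cells.
#' @export
write_expression_table <- function(expr, path, missing_token = "NA") {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = missing_token)
  invisible(path)
}

#' Read a survival table
#'
#' Expects tab-separated columns `sample_id`, `time` (months), `event` (0/1).
#'
#' @param path Path to a TSV file.
#' @return A validated survival `data.frame`.
#' @export
read_survival_table <- function(path) {
  if (!file.exists(path)) stop("survival table not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(tab))) {
    stop("survival table must have columns: ", paste(need, collapse = ", "))
  }
  survival_table(tab$sample_id, tab$time, tab$event)
}

#' Write a survival table as TSV
#'
#' @param surv Survival `data.frame`.
#' @param path Output path.
#' @export
write_survival_table <- function(surv, path) {
  utils::write.table(surv, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse probe-level expression to gene level
#'
#' Probes mapping to zero or to multiple gene symbols are removed. When
#' several remaining probes target the same gene, the probe with the highest
#' mean expression across samples represents that gene.
#'
#' @param probe_expr Probe-level expression matrix (probes x samples).
#' @param probe_map Data frame with columns `probe` and `symbol`; a probe
#'   maps to multiple symbols via multiple rows (or a symbol string
#'   containing `///`), and to zero symbols via an empty/NA symbol.
#' @return Gene-level [expression_matrix()].
#' @export
collapse_probes <- function(probe_expr, probe_map) {
  stopifnot(is.matrix(probe_expr), all(c("probe", "symbol") %in% names(probe_map)))
  sym <- as.character(probe_map$symbol)
  sym[is.na(sym)] <- ""
  # expand multi-symbol strings so "A///B" counts as two targets
  n_targets <- vapply(seq_along(sym), function(i) {
    s <- trimws(strsplit(sym[i], "///", fixed = TRUE)[[1]])
    length(unique(s[nzchar(s)]))
  }, integer(1))
  per_probe <- tapply(seq_len(nrow(probe_map)), probe_map$probe, function(idx) {
    syms <- unlist(lapply(sym[idx], function(s) {
      s <- trimws(strsplit(s, "///", fixed = TRUE)[[1]])
      s[nzchar(s)]
    }))
    unique(syms)
  })
  keep <- names(per_probe)[lengths(per_probe) == 1]
  keep <- intersect(keep, rownames(probe_expr))
  if (length(keep) == 0) stop("no probes map uniquely to a gene symbol")
  gene_of <- vapply(per_probe[keep], `[[`, character(1), 1)
  means <- rowMeans(probe_expr[keep, , drop = FALSE])
  ord <- order(gene_of, -means, keep)  # per gene, highest-mean probe first
  first <- !duplicated(gene_of[ord])
  chosen <- keep[ord][first]
  out <- probe_expr[chosen, , drop = FALSE]
  rownames(out) <- gene_of[ord][first]
  expression_matrix(out[order(rownames(out)), , drop = FALSE])
}

#' Restrict expression matrices to their common gene universe
#'
#' All matrices are subset to the lexicographically sorted intersection of
#' their gene ids, so that model coefficients are portable across datasets.
#'
#' @param matrices List of at least two expression matrices.
#' @return List of matrices over the identical, sorted gene universe.
#' @export
intersect_gene_universe <- function(matrices) {
  if (length(matrices) < 2) stop("need at least two matrices")
  common <- Reduce(intersect, lapply(matrices, rownames))
  if (length(common) == 0) stop("gene universes are disjoint")
  common <- sort(common)
  lapply(matrices, function(m) m[common, , drop = FALSE])
}
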