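#' Run the full pipeline: simulate, score, fit, validate, report
#'
#' A deterministic end-to-end run used for smoke-testing and reproducibility
#' checks: writes a synthetic fixture bundle, re-reads it through the
#' standard readers, computes pathway scores, fits a cross-validated
#' pathway-score model and a grouped-gene model, runs a short internal
#' validation, and writes the serialized model and the structured report.
#' Every file written is a deterministic function of `seed`.
#'
#' @param out_dir Output directory.
#' @param seed Integer master seed.
#' @param preset Synthetic preset (default `"tiny"`).
#' @param method Scoring method for the pathway-score model.
#' @param n_repeats Internal-validation repeats (default 2).
#' @param n_folds,n_lambda Cross-validation controls (reduced defaults for a
#'   fast run; raise for real use).
#' @return Invisibly, a named vector of the files written.
#' @export
run_pipeline <- function(out_dir, seed = 1, preset = "tiny", method = "zscore",
                         n_repeats = 2, n_folds = 5, n_lambda = 20) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fixdir <- file.path(out_dir, "fixtures")
  write_fixture_bundle(fixdir, preset, seed = seed)
  expr <- read_expression_table(file.path(fixdir, "expr.tsv"))
  surv <- read_survival_table(file.path(fixdir, "surv.tsv"))
  sets <- read_gmt(file.path(fixdir, "sets.gmt"))

  scores <- score_pathways(expr, restrict_to_universe(sets, rownames(expr),
                                                      min_size = 2),
                           method = method)
  utils::write.table(data.frame(pathway = rownames(scores), unclass(scores),
                                check.names = FALSE),
                     file.path(out_dir, "scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  cfg_score <- model_config("pathway_score_model", "pathway_scores",
                            sets = sets, method = method, min_size = 2)
  cfg_group <- model_config("group_lasso_model", "grouped_genes",
                            sets = sets, min_size = 2)
  model <- fit_prognostic_model(expr, surv, cfg_score, seed = seed,
                                n_folds = n_folds, n_lambda = n_lambda)
  write_model(model, file.path(out_dir, "model.json"))

  report <- suppressWarnings(
    internal_validation(expr, surv, list(cfg_score, cfg_group),
                        n_repeats = n_repeats, seed = seed,
                        n_folds = n_folds, n_lambda = n_lambda,
                        compute_ibs = TRUE))
  utils::write.table(report$records, file.path(out_dir, "validation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  rep <- model_report(model, validation = report,
                      data_description = sprintf("synthetic %s cohort, seed %d",
                                                 preset, seed))
  write_report(rep, file.path(out_dir, "report"))
  files <- c(list.files(fixdir, full.names = TRUE),
             file.path(out_dir, c("scores.tsv", "model.json",
                                  "validation.tsv", "report.json", "report.txt")))
  invisible(files)
}
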