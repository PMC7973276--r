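## End-to-end orchestration of the analysis sequence: single-analyte
## biomarker table on the long/short contrast, multidimensional biomarker,
## trend tests across the full ordered cohort, correlation matrices, and
## the expression-quartile survival screen. Each stage writes a plain-text
## report; a JSON manifest records inputs, seed and per-stage wall time.

#' Run the full analysis pipeline
#'
#' Executes, in order: (1) restriction to the long/short groups and the
#' per-analyte threshold-biomarker table; (2) top-k ranking, power-set
#' subset search and hyperparameter grid search for the multidimensional
#' biomarker, with ROC; (3) per-analyte trend tests across the full ordered
#' cohort plus the total-immune vs PFS rank correlation; (4) gene x gene
#' and gene x cell correlation matrices; (5) a per-analyte top-vs-bottom
#' expression-quartile log-rank survival screen. Any stage failure aborts
#' with a stage-tagged error.
#'
#' @param x An `immune_cohort`, or `NULL` to read one from the three paths.
#' @param matrix_path,meta_path,kinds_path Input TSVs (used when `x` is
#'   `NULL`); see [read_cohort()].
#' @param outdir Output directory for the report files.
#' @param seed Master seed for the stochastic stages.
#' @param top_k Candidates entering the subset search.
#' @param endpoint Survival endpoint for the quartile screen.
#' @param use_alt_months Use maintenance-adjusted months where recorded.
#' @param quartile_n Optional per-arm size for the quartile screen.
#' @param defaults,grid Forest hyperparameters, as in
#'   [multidim_biomarker()].
#' @return Invisibly, the manifest (also written as `manifest.json`).
#' @export
run_pipeline <- function(x = NULL, matrix_path = NULL, meta_path = NULL,
                         kinds_path = NULL, outdir, seed = 1, top_k = 5,
                         endpoint = c("pfs", "os"), use_alt_months = FALSE,
                         quartile_n = NULL, defaults = forest_params(),
                         grid = NULL) {
  endpoint <- match.arg(endpoint)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, endpoint = endpoint,
                   use_alt_months = use_alt_months, top_k = top_k,
                   package_version = as.character(utils::packageVersion("immunomark")),
                   stages = list())
  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
    manifest$stages[[name]] <<- list(seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }

  x <- stage("load", function() {
    if (!is.null(x)) return(x)
    for (p in c(matrix_path, meta_path, kinds_path)) {
      if (is.null(p) || !file.exists(p)) {
        stop("missing input file: ", if (is.null(p)) "(unset path)" else p)
      }
    }
    manifest$inputs <<- list(
      matrix = unname(tools::md5sum(matrix_path)),
      metadata = unname(tools::md5sum(meta_path)),
      kinds = unname(tools::md5sum(kinds_path)))
    read_cohort(matrix_path, meta_path, kinds_path)
  })

  reports <- stage("analyte_table", function() {
    tab <- analyte_table(x)
    write_analyte_table(tab, file.path(outdir, "analyte_table.tsv"))
    tab
  })

  bm <- stage("multidim_biomarker", function() {
    bm <- multidim_biomarker(x, top_k = top_k, defaults = defaults,
                             grid = grid, seed = seed, reports = reports)
    m <- bm$model$metrics
    rep_json <- list(
      ranking = bm$ranking$top,
      loo_errors = as.list(bm$search$loo_errors),
      chosen_subset = bm$search$chosen,
      params = bm$model$params[c("n_trees", "features_per_split",
                                 "min_leaf", "max_depth")],
      scores = as.list(bm$model$scores),
      classes = as.list(as.character(bm$model$classes)),
      confusion = as.list(m$counts),
      metrics = list(accuracy = m$accuracy, ppv = m$ppv, npv = m$npv,
                     sensitivity = m$sensitivity,
                     specificity = m$specificity),
      auc = bm$roc$auc
    )
    rep_json$params$max_depth <-
      if (is.finite(rep_json$params$max_depth %||% Inf))
        rep_json$params$max_depth else "unlimited"
    jsonlite::write_json(rep_json, file.path(outdir, "biomarker_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.table(bm$roc$points, file.path(outdir, "roc_points.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    bm
  })

  trend <- stage("trend", function() {
    tr <- trend_table(x)
    utils::write.table(tr, file.path(outdir, "trend.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ## total immune infiltrate vs PFS across the whole cohort
    ti <- vapply(x$records$sample_id, function(id)
      total_immune(x, id, intersect(immune_cell_subsets(), colnames(x$matrix))),
      numeric(1))
    cp <- spearman_corr(ti, x$records$pfs_months)
    manifest$total_immune_vs_pfs <<- list(r = cp$r, p = cp$p, n = cp$n)
    tr
  })

  stage("correlations", function() {
    kinds <- x$kinds[colnames(x$matrix)]
    genes <- names(kinds)[kinds == "gene_tpm"]
    cells <- names(kinds)[kinds == "cell_percent"]
    long_fmt <- function(cm) {
      data.frame(row = rep(rownames(cm$r), times = ncol(cm$r)),
                 col = rep(colnames(cm$r), each = nrow(cm$r)),
                 r = as.vector(cm$r), p = as.vector(cm$p),
                 n = as.vector(cm$n), stringsAsFactors = FALSE)
    }
    out <- long_fmt(correlation_matrix(x, genes, genes))
    if (length(cells)) {
      out <- rbind(out, long_fmt(correlation_matrix(x, genes, cells)))
    }
    utils::write.table(out, file.path(outdir, "correlations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out
  })

  stage("survival", function() {
    st <- survival_table(x, endpoint = endpoint, n_per_group = quartile_n,
                         use_alt_months = use_alt_months)
    utils::write.table(st, file.path(outdir, "survival.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    st
  })

  manifest$chosen_subset <- bm$search$chosen
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
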