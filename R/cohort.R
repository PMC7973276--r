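#' @keywords internal
"_PACKAGE"

## Canonical immune cell subsets modeled by the assay; their infiltration
## percentages sum to the "total immune" fraction of a sample.
.CELL_SUBSETS <- c(
  "T_reg cells", "CD8+ T cells", "M2 macrophages", "CD4+ T cells",
  "M1 macrophages", "CD14+ monocytes", "CD19+ B cells", "CD56+ NK cells"
)

#' Names of the modeled immune cell subsets
#'
#' The eight immune cell populations whose tumor-infiltration percentages are
#' quantified alongside gene transcript abundances. Their per-sample sum is
#' the "total immune" fraction.
#'
#' @return Character vector of length 8.
#' @export
immune_cell_subsets <- function() .CELL_SUBSETS

#' Parse a censoring-aware survival field
#'
#' Clinical survival columns use a compact grammar:
#' `NUMBER [ "(" NUMBER ")" ] [ "+" ]`. The leading number is the
#' progression-free or overall survival in months; an optional parenthetical
#' records an alternative clock (months recomputed from the end of maintenance
#' bevacizumab); a trailing `+` marks the value as censored (no event observed
#' by last follow-up).
#'
#' @param text Character scalar, e.g. `"90+"`, `"62 (51)"`, `"6"`.
#' @return A list with components `months` (numeric), `censored` (logical)
#'   and `alt_months` (numeric, `NA` when no parenthetical is present).
#' @examples
#' parse_survival_field("76 (64)+")
#' @export
parse_survival_field <- function(text) {
  if (length(text) != 1L || !is.character(text)) {
    stop("parse_survival_field() expects a single character string")
  }
  txt <- trimws(text)
  num <- "[0-9]+(?:\\.[0-9]+)?"
  pat <- sprintf("^(%s)(?:\\s*\\(\\s*(%s)\\s*\\))?\\s*(\\+)?$", num, num)
  m <- regmatches(txt, regexec(pat, txt, perl = TRUE))[[1]]
  if (length(m) == 0L) {
    stop(sprintf("malformed survival field: '%s'", text))
  }
  list(
    months    = as.numeric(m[2]),
    censored  = m[4] == "+",
    alt_months = if (nzchar(m[3])) as.numeric(m[3]) else NA_real_
  )
}

## Vectorised parse for readers: returns a data.frame months/censored/alt.
.parse_survival_vec <- function(x, field = "pfs") {
  parsed <- lapply(x, function(v) {
    tryCatch(parse_survival_field(v),
             error = function(e) stop(sprintf("column '%s': %s",
                                              field, conditionMessage(e))))
  })
  data.frame(
    months   = vapply(parsed, `[[`, numeric(1), "months"),
    censored = vapply(parsed, `[[`, logical(1), "censored"),
    alt      = vapply(parsed, `[[`, numeric(1), "alt_months")
  )
}

.format_survival_field <- function(months, censored, alt) {
  out <- as.character(months)
  has_alt <- !is.na(alt)
  out[has_alt] <- paste0(out[has_alt], " (", as.character(alt[has_alt]), ")")
  out[censored] <- paste0(out[censored], "+")
  out
}

.GROUP_LEVELS <- c("long", "intermediate", "short")

#' Construct and validate a cohort object
#'
#' A cohort bundles per-sample clinical records with a samples x analytes
#' measurement matrix. Gene analytes carry TPM values (non-negative); cell
#' analytes carry infiltration percentages (0 to 100).
#'
#' @param records Data frame with at least `sample_id`; typically also
#'   `group`, `pfs_months`, `pfs_censored`, `pfs_alt`, `os_months`,
#'   `os_censored`, `os_alt`, `maint_bev` and free-form covariate columns.
#' @param matrix Numeric matrix, rows named by sample id, columns by analyte.
#' @param kinds Named character vector mapping each analyte to
#'   `"gene_tpm"` or `"cell_percent"`.
#' @return An object of class `immune_cohort`.
#' @export
cohort <- function(records, matrix, kinds) {
  stopifnot(is.data.frame(records), "sample_id" %in% names(records))
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  obj <- structure(
    list(records = records, matrix = matrix, kinds = kinds),
    class = "immune_cohort"
  )
  validate_cohort(obj)
  obj
}

#' @rdname cohort
#' @param x An `immune_cohort` object.
#' @export
validate_cohort <- function(x) {
  records <- x$records; mat <- x$matrix; kinds <- x$kinds
  ids <- records$sample_id
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("cohort matrix must have sample row names and analyte column names")
  }
  orphans_meta <- setdiff(ids, rownames(mat))
  orphans_mat  <- setdiff(rownames(mat), ids)
  if (length(orphans_meta) || length(orphans_mat)) {
    stop("sample id mismatch between metadata and matrix; orphans: ",
         paste(c(orphans_meta, orphans_mat), collapse = ", "))
  }
  if (!identical(rownames(mat), ids)) {
    stop("matrix rows must be ordered as the metadata records")
  }
  missing_kind <- setdiff(colnames(mat), names(kinds))
  if (length(missing_kind)) {
    stop("analytes with no declared kind: ",
         paste(missing_kind, collapse = ", "))
  }
  bad_kind <- setdiff(unique(kinds), c("gene_tpm", "cell_percent"))
  if (length(bad_kind)) {
    stop("unknown analyte kind: ", paste(bad_kind, collapse = ", "))
  }
  if ("group" %in% names(records)) {
    gr <- as.character(records$group)
    bad <- setdiff(stats::na.omit(gr[gr != ""]), .GROUP_LEVELS)
    if (length(bad)) {
      stop("unknown outcome group token: ", paste(unique(bad), collapse = ", "))
    }
  }
  .check_cell <- function(analyte) {
    v <- mat[, analyte]
    bad <- which(!is.na(v) & (v < 0 | v > 100))
    if (length(bad)) {
      stop(sprintf("cell_percent analyte '%s' outside [0,100] at sample(s): %s",
                   analyte, paste(rownames(mat)[bad], collapse = ", ")))
    }
  }
  .check_gene <- function(analyte) {
    v <- mat[, analyte]
    bad <- which(!is.na(v) & v < 0)
    if (length(bad)) {
      stop(sprintf("negative TPM for analyte '%s' at sample(s): %s",
                   analyte, paste(rownames(mat)[bad], collapse = ", ")))
    }
  }
  for (a in colnames(mat)) {
    if (kinds[[a]] == "cell_percent") .check_cell(a) else .check_gene(a)
  }
  invisible(x)
}

#' @export
print.immune_cohort <- function(x, ...) {
  kinds <- x$kinds[colnames(x$matrix)]
  cat(sprintf("immune cohort: %d samples, %d analytes (%d gene_tpm, %d cell_percent)\n",
              nrow(x$matrix), ncol(x$matrix),
              sum(kinds == "gene_tpm"), sum(kinds == "cell_percent")))
  if ("group" %in% names(x$records)) {
    tab <- table(factor(x$records$group, levels = .GROUP_LEVELS))
    cat("groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a cohort from TSV files
#'
#' Loads a samples x analytes measurement matrix, clinical metadata with
#' censoring-aware survival fields, and an analyte-kind map, and returns a
#' validated [cohort()].
#'
#' @param matrix_path TSV, first column `sample_id`, remaining columns one
#'   per analyte (dot decimal separator).
#' @param meta_path TSV with columns `sample_id, group, pfs, os, maint_bev,
#'   age_band, ca125_band, debulking`; `pfs`/`os` use the grammar of
#'   [parse_survival_field()].
#' @param kinds_path Two-column TSV `analyte, kind` with kind
#'   `gene_tpm` or `cell_percent`.
#' @return An `immune_cohort` object.
#' @export
read_cohort <- function(matrix_path, meta_path, kinds_path) {
  for (p in c(matrix_path, meta_path, kinds_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  mat_df <- utils::read.delim(matrix_path, check.names = FALSE,
                              stringsAsFactors = FALSE)
  if (nrow(mat_df) == 0L || ncol(mat_df) < 2L) {
    stop("empty or malformed analyte matrix: ", matrix_path)
  }
  if (names(mat_df)[1] != "sample_id") {
    stop("matrix first column must be 'sample_id', got: ", names(mat_df)[1])
  }
  mat <- as.matrix(mat_df[, -1, drop = FALSE])
  rownames(mat) <- mat_df$sample_id
  storage.mode(mat) <- "double"

  meta <- utils::read.delim(meta_path, check.names = FALSE,
                            stringsAsFactors = FALSE,
                            colClasses = "character")
  req <- c("sample_id", "group", "pfs", "os")
  miss <- setdiff(req, names(meta))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  pfs <- .parse_survival_vec(meta$pfs, "pfs")
  os  <- .parse_survival_vec(meta$os, "os")
  records <- data.frame(
    sample_id    = meta$sample_id,
    group        = meta$group,
    pfs_months   = pfs$months, pfs_censored = pfs$censored, pfs_alt = pfs$alt,
    os_months    = os$months,  os_censored  = os$censored,  os_alt  = os$alt,
    maint_bev    = if ("maint_bev" %in% names(meta))
                     tolower(meta$maint_bev) %in% c("yes", "true", "1")
                   else NA,
    stringsAsFactors = FALSE
  )
  for (cov in setdiff(names(meta), c(req, "maint_bev"))) {
    records[[cov]] <- meta[[cov]]
  }

  kinds_df <- utils::read.delim(kinds_path, stringsAsFactors = FALSE,
                                check.names = FALSE)
  if (!all(c("analyte", "kind") %in% names(kinds_df))) {
    stop("kinds file must have columns 'analyte' and 'kind'")
  }
  kinds <- stats::setNames(kinds_df$kind, kinds_df$analyte)

  ## align matrix rows to metadata order, reporting orphans first
  orphans <- c(setdiff(records$sample_id, rownames(mat)),
               setdiff(rownames(mat), records$sample_id))
  if (length(orphans)) {
    stop("sample id mismatch between metadata and matrix; orphans: ",
         paste(orphans, collapse = ", "))
  }
  mat <- mat[records$sample_id, , drop = FALSE]
  obj <- cohort(records, mat, kinds)
  message(sprintf("read cohort: %d samples, %d gene_tpm + %d cell_percent analytes",
                  nrow(mat), sum(kinds[colnames(mat)] == "gene_tpm"),
                  sum(kinds[colnames(mat)] == "cell_percent")))
  obj
}

#' Write a cohort to TSV files
#'
#' Inverse of [read_cohort()]: values with finite decimal representations
#' round-trip bit-identically.
#'
#' @inheritParams read_cohort
#' @param x An `immune_cohort` object.
#' @return Invisibly, the three paths written.
#' @export
write_cohort <- function(x, matrix_path, meta_path, kinds_path) {
  stopifnot(inherits(x, "immune_cohort"))
  mat_df <- data.frame(sample_id = rownames(x$matrix),
                       as.data.frame(x$matrix, check.names = FALSE),
                       check.names = FALSE)
  utils::write.table(mat_df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  r <- x$records
  meta <- data.frame(
    sample_id = r$sample_id,
    group = r$group,
    pfs = .format_survival_field(r$pfs_months, r$pfs_censored, r$pfs_alt),
    os  = .format_survival_field(r$os_months,  r$os_censored,  r$os_alt),
    maint_bev = ifelse(is.na(r$maint_bev), "NA", ifelse(r$maint_bev, "yes", "no")),
    stringsAsFactors = FALSE
  )
  for (cov in setdiff(names(r), c("sample_id", "group", "pfs_months",
                                  "pfs_censored", "pfs_alt", "os_months",
                                  "os_censored", "os_alt", "maint_bev"))) {
    meta[[cov]] <- r[[cov]]
  }
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  kinds_df <- data.frame(analyte = colnames(x$matrix),
                         kind = unname(x$kinds[colnames(x$matrix)]))
  utils::write.table(kinds_df, kinds_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix_path, meta_path, kinds_path))
}

#' Total immune infiltration of a sample
#'
#' Sums the infiltration percentages of the eight modeled immune cell
#' subsets for one sample. The total immune fraction is taken to be this sum
#' (the subsets partition the modeled immune compartment).
#'
#' @param x An `immune_cohort`.
#' @param sample_id Sample identifier.
#' @param subsets Cell subset analytes to sum; defaults to
#'   [immune_cell_subsets()].
#' @return Numeric percentage.
#' @export
total_immune <- function(x, sample_id, subsets = immune_cell_subsets()) {
  stopifnot(inherits(x, "immune_cohort"))
  if (!sample_id %in% rownames(x$matrix)) {
    stop("unknown sample id: ", sample_id)
  }
  missing <- setdiff(subsets, colnames(x$matrix))
  if (length(missing)) {
    stop("missing cell subset analyte(s): ", paste(missing, collapse = ", "))
  }
  sum(x$matrix[sample_id, subsets])
}

#' Median of a group of values
#'
#' Plain sample median (mean of the central pair for even n). Censoring
#' marks are deliberately ignored: summary medians of survival columns are
#' computed on the recorded months as plain numbers, matching how clinical
#' summary tables print them. Proper censoring-aware analysis lives in the
#' survival functions.
#'
#' @param values Non-empty numeric vector.
#' @return The median.
#' @export
group_median <- function(values) {
  if (length(values) == 0L) stop("group_median() of an empty vector")
  stats::median(as.numeric(values))
}

#' Restrict a cohort to selected outcome groups
#'
#' @param x An `immune_cohort`.
#' @param groups Character vector of group labels to keep.
#' @return A new `immune_cohort` with only the matching samples.
#' @export
subset_groups <- function(x, groups) {
  stopifnot(inherits(x, "immune_cohort"))
  keep <- x$records$group %in% groups
  if (!any(keep)) stop("no samples in group(s): ", paste(groups, collapse = ", "))
  cohort(x$records[keep, , drop = FALSE],
         x$matrix[keep, , drop = FALSE],
         x$kinds)
}

#' Path to the bundled reference cohort tables
#'
#' The package ships two small reference tables transcribed from a published
#' 26-patient high grade serous ovarian cancer immune-profiling study:
#' `"clinical"` (per-patient outcome group, censored PFS/OS in months, and
#' covariates) and `"analytes"` (per-analyte group medians, thresholds,
#' p-values and leave-one-out classification metrics for the 40-analyte
#' immune panel).
#'
#' @param which `"clinical"` or `"analytes"`.
#' @return File path.
#' @export
wihri_reference_path <- function(which = c("clinical", "analytes")) {
  which <- match.arg(which)
  fname <- switch(which,
                  clinical = "wihri_clinical.tsv",
                  analytes = "wihri_analyte_table.tsv")
  system.file("extdata", fname, package = "immunomark", mustWork = TRUE)
}

#' Load the bundled reference tables
#'
#' @inheritParams wihri_reference_path
#' @return A data frame.
#' @export
wihri_reference <- function(which = c("clinical", "analytes")) {
  which <- match.arg(which)
  utils::read.delim(wihri_reference_path(which), check.names = FALSE,
                    stringsAsFactors = FALSE)
}
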