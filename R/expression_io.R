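#' Construct and validate an expression matrix object
#'
#' An `expr_set` bundles a genes-by-samples matrix of normalized,
#' non-negative expression values with optional per-sample annotation:
#' a condition label (`"tumor"` / `"normal"`) and a patient identifier
#' that allows tumor/matched-normal pairing.
#'
#' @param values Numeric matrix, genes in rows and samples in columns, with
#'   unique row and column names. All entries must be finite and `>= 0`.
#' @param condition Optional character vector of per-sample labels, each
#'   `"tumor"` or `"normal"`, in column order (or named by sample id).
#' @param patient_id Optional character vector of per-sample patient
#'   identifiers, in column order (or named by sample id).
#'
#' @return An object of class `expr_set`: a list with elements `values`,
#'   `condition` and `patient_id`.
#' @export
expression_matrix <- function(values, condition = NULL, patient_id = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (genes x samples)")
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("expression matrix is empty")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene row names and sample column names")
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g))
    stop("duplicated gene ids: ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicated sample ids: ", paste(dup_s, collapse = ", "))
  if (any(!is.finite(values)))
    stop("expression values must be finite (missing values are not permitted)")
  if (any(values < 0)) {
    bad <- rownames(values)[apply(values < 0, 1L, any)]
    stop("negative expression values in gene(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  condition <- match_sample_annotation(condition, colnames(values), "condition")
  if (!is.null(condition)) {
    if (!all(condition %in% c("tumor", "normal")))
      stop("condition labels must be 'tumor' or 'normal'")
  }
  patient_id <- match_sample_annotation(patient_id, colnames(values), "patient_id")
  structure(list(values = values, condition = condition,
                 patient_id = patient_id),
            class = "expr_set")
}

# Recycle/reorder a per-sample annotation vector against sample ids.
match_sample_annotation <- function(x, sample_ids, what) {
  if (is.null(x)) return(NULL)
  x <- as.character(x)
  if (!is.null(names(x))) {
    missing <- setdiff(sample_ids, names(x))
    if (length(missing))
      stop(what, " missing for sample(s): ", paste(missing, collapse = ", "))
    x <- unname(x[sample_ids])
  } else if (length(x) != length(sample_ids)) {
    stop(what, " must have one entry per sample")
  }
  x
}

#' @export
print.expr_set <- function(x, ...) {
  cat("<expr_set> ", nrow(x$values), " genes x ", ncol(x$values), " samples\n",
      sep = "")
  if (!is.null(x$condition)) {
    tab <- table(x$condition)
    cat("  conditions:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  if (!is.null(x$patient_id))
    cat("  patients:", length(unique(x$patient_id)), "\n")
  invisible(x)
}

#' Number of genes / samples in an expression set
#' @param em An `expr_set`.
#' @return Integer count.
#' @export
n_genes <- function(em) nrow(em$values)

#' @rdname n_genes
#' @export
n_samples <- function(em) ncol(em$values)

#' Read an expression matrix from a delimited text file
#'
#' The first row must hold sample ids and the first column gene ids.
#' Genes with any non-numeric entry are rejected, as are duplicated ids,
#' negative or missing values.
#'
#' @param path Path to a TSV or CSV file.
#' @param sep Field separator; `NULL` (default) guesses from the file
#'   extension (`.csv` gives comma, anything else tab).
#' @param sample_sheet Optional path to a sample-annotation table with
#'   columns `sample_id`, `patient_id`, `condition` (read with the same
#'   separator rules).
#' @return An [expression_matrix()] object.
#' @export
read_expression <- function(path, sep = NULL, sample_sheet = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           check.names = FALSE, colClasses = "character",
                           row.names = NULL, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(raw) < 2L) stop("expression table needs gene ids plus >= 1 sample column")
  gene_ids <- raw[[1L]]
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup)) stop("duplicated gene ids: ", paste(dup, collapse = ", "))
  num <- as.matrix(raw[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(num) <- "double")
  bad <- gene_ids[apply(is.na(num), 1L, any)]
  if (length(bad))
    stop("non-numeric or missing entries in gene(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  rownames(num) <- gene_ids
  condition <- NULL
  patient <- NULL
  if (!is.null(sample_sheet)) {
    sheet <- read_sample_sheet(sample_sheet)
    condition <- stats::setNames(sheet$condition, sheet$sample_id)
    patient <- stats::setNames(sheet$patient_id, sheet$sample_id)
  }
  expression_matrix(num, condition = condition, patient_id = patient)
}

#' Read a sample sheet (sample_id, patient_id, condition)
#' @param path Path to a delimited file with columns `sample_id`,
#'   `patient_id`, `condition`.
#' @param sep Field separator; guessed from the extension when `NULL`.
#' @return A data.frame with the three columns, one row per sample.
#' @export
read_sample_sheet <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  sheet <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample_id", "patient_id", "condition")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id)) stop("sample sheet has duplicated sample ids")
  sheet[need]
}

#' Read a clinical table (patient_id, time_days, event)
#'
#' @param path Path to a delimited file with columns `patient_id`,
#'   `time_days` (follow-up, days, `>= 0`) and `event` (0/1 or TRUE/FALSE;
#'   1 = death observed). Extra columns (e.g. subgroup labels) are kept.
#' @param sep Field separator; guessed from the extension when `NULL`.
#' @return A data.frame with at least `patient_id`, `time_days`, `event`.
#' @export
read_clinical <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  cl <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("patient_id", "time_days", "event")
  miss <- setdiff(need, names(cl))
  if (length(miss)) stop("clinical table lacks column(s): ", paste(miss, collapse = ", "))
  validate_clinical(cl)
}

validate_clinical <- function(cl) {
  if (anyDuplicated(cl$patient_id)) stop("clinical table has duplicated patient ids")
  cl$time_days <- as.numeric(cl$time_days)
  if (any(!is.finite(cl$time_days)) || any(cl$time_days < 0))
    stop("follow-up times must be finite and >= 0")
  ev <- cl$event
  if (is.character(ev)) ev <- as.numeric(ev)
  if (!all(ev %in% c(0, 1, FALSE, TRUE)))
    stop("event flags must be 0/1")
  cl$event <- as.integer(ev)
  cl
}

#' Filter genes by minimum expression
#'
#' Keeps genes whose expression is at least `min_value` in at least a
#' `min_fraction` share of samples (boundary inclusive on both counts).
#'
#' @param em An `expr_set`.
#' @param min_value Expression floor (same units as the matrix).
#' @param min_fraction Required fraction of samples in `[0, 1]`.
#' @return A filtered `expr_set`.
#' @export
filter_low_expression <- function(em, min_value, min_fraction = 0.5) {
  stopifnot(inherits(em, "expr_set"))
  if (min_fraction < 0 || min_fraction > 1)
    stop("`min_fraction` must lie in [0, 1]")
  frac <- rowMeans(em$values >= min_value)
  keep <- frac >= min_fraction
  if (!any(keep))
    stop("all genes removed by the expression filter; lower `min_value` or `min_fraction`")
  expression_matrix(em$values[keep, , drop = FALSE],
                    condition = em$condition, patient_id = em$patient_id)
}

#' Select differentially expressed genes by mean-ratio log2 fold change
#'
#' For each gene, `log2fc = log2((mean_tumor + eps) / (mean_normal + eps))`
#' over unpaired condition means; a gene is selected when
#' `|log2fc| >= log2fc_threshold`.
#'
#' @param em An `expr_set` carrying a `condition` annotation with both
#'   `"tumor"` and `"normal"` present (>= 2 samples each).
#' @param log2fc_threshold Absolute log2 fold-change cutoff (default 1,
#'   i.e. a two-fold change).
#' @param eps Pseudocount guarding against zero means (default 0.05).
#' @return A data.frame with columns `gene`, `mean_tumor`, `mean_normal`,
#'   `log2fc`, `selected`.
#' @export
select_differential <- function(em, log2fc_threshold = 1, eps = 0.05) {
  stopifnot(inherits(em, "expr_set"))
  if (is.null(em$condition))
    stop("expression set has no condition annotation")
  for (cond in c("tumor", "normal"))
    if (sum(em$condition == cond) < 2L)
      stop("need >= 2 '", cond, "' samples for differential selection")
  mt <- rowMeans(em$values[, em$condition == "tumor", drop = FALSE])
  mn <- rowMeans(em$values[, em$condition == "normal", drop = FALSE])
  lfc <- log2((mt + eps) / (mn + eps))
  data.frame(gene = rownames(em$values),
             mean_tumor = unname(mt), mean_normal = unname(mn),
             log2fc = unname(lfc),
             selected = unname(abs(lfc) >= log2fc_threshold),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Subset an expression set to a gene list or sample set
#' @param em An `expr_set`.
#' @param genes Optional character vector of gene ids to keep.
#' @param samples Optional character vector of sample ids to keep.
#' @return The subsetted `expr_set`.
#' @export
subset_expression <- function(em, genes = NULL, samples = NULL) {
  stopifnot(inherits(em, "expr_set"))
  v <- em$values
  cond <- em$condition
  pat <- em$patient_id
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(v))
    if (length(miss)) stop("unknown gene(s): ", paste(utils::head(miss, 5L), collapse = ", "))
    v <- v[genes, , drop = FALSE]
  }
  if (!is.null(samples)) {
    idx <- match(samples, colnames(v))
    if (anyNA(idx)) stop("unknown sample(s): ",
                         paste(samples[is.na(idx)], collapse = ", "))
    v <- v[, idx, drop = FALSE]
    if (!is.null(cond)) cond <- cond[idx]
    if (!is.null(pat)) pat <- pat[idx]
  }
  expression_matrix(v, condition = cond, patient_id = pat)
}

#' Write an expression set to a TSV file
#' @param em An `expr_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(em, path) {
  df <- data.frame(gene = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
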