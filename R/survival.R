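#' Stratify patients into low/high expression cohorts for one gene
#'
#' Patients are split on the quartiles of the gene's tumor-sample
#' expression: the low cohort holds patients strictly below the lower
#' quantile, the high cohort strictly above the upper quantile; patients
#' in between (including exact ties with the quantiles) are excluded.
#'
#' @param em An `expr_set`. When a `condition` annotation is present only
#'   tumor samples are used; `patient_id` maps samples to patients (one
#'   tumor sample per patient expected).
#' @param clinical Clinical data.frame with `patient_id`, `time_days`,
#'   `event` (see [read_clinical()]).
#' @param gene Gene id present in the matrix.
#' @param low_q,high_q Quantile cut points (defaults 0.25 and 0.75).
#' @return A data.frame (`patient_id`, `time`, `event`, `group`) with
#'   `group` in `{"low", "high"}`, or `NULL` with a warning when either
#'   cohort is empty.
#' @export
stratify_by_expression <- function(em, clinical, gene,
                                   low_q = 0.25, high_q = 0.75) {
  stopifnot(inherits(em, "expr_set"))
  if (!gene %in% rownames(em$values)) stop("unknown gene: ", gene)
  clinical <- validate_clinical(clinical)
  keep <- rep(TRUE, n_samples(em))
  if (!is.null(em$condition)) keep <- em$condition == "tumor"
  if (is.null(em$patient_id))
    stop("expression set needs a patient_id annotation for survival analysis")
  expr <- em$values[gene, keep]
  patients <- em$patient_id[keep]
  expr <- tapply(expr, patients, mean)  # one value per patient
  common <- intersect(names(expr), clinical$patient_id)
  if (!length(common)) stop("no patients shared between expression and clinical data")
  expr <- expr[common]
  qs <- stats::quantile(expr, c(low_q, high_q), names = FALSE)
  group <- ifelse(expr < qs[1L], "low", ifelse(expr > qs[2L], "high", NA))
  df <- data.frame(patient_id = common, group = group,
                   stringsAsFactors = FALSE)
  df <- df[!is.na(df$group), , drop = FALSE]
  if (!nrow(df) || length(unique(df$group)) < 2L) {
    warning("gene ", gene, " skipped: empty low or high cohort")
    return(NULL)
  }
  idx <- match(df$patient_id, clinical$patient_id)
  data.frame(patient_id = df$patient_id,
             time = clinical$time_days[idx],
             event = clinical$event[idx],
             group = df$group,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Kaplan-Meier product-limit estimate for one cohort
#'
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over distinct event times
#' `t_i`, with `d_i` deaths and `n_i` at risk. Computed with
#' [survival::survfit()].
#'
#' @param cohort Data.frame with `time` and `event` columns (as returned
#'   by [stratify_by_expression()] for one group).
#' @return A data.frame with `time`, `n_risk`, `n_event`, `surv`
#'   (non-increasing, starting from 1).
#' @export
km_estimate <- function(cohort) {
  if (is.null(cohort) || !nrow(cohort)) stop("cohort is empty")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = cohort)
  data.frame(time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, surv = fit$surv,
             row.names = NULL)
}

#' Two-group log-rank test
#'
#' Standard unweighted log-rank statistic (observed vs expected events
#' summed over distinct event times), computed with
#' [survival::survdiff()]; p-value from a chi-square with 1 df.
#'
#' @param a,b Cohort data.frames with `time` and `event` columns.
#' @return A list with `chi_square`, `p_value`, `n_events`.
#' @export
logrank_test <- function(a, b) {
  if (is.null(a) || is.null(b) || !nrow(a) || !nrow(b))
    stop("both cohorts must be non-empty")
  dat <- rbind(data.frame(time = a$time, event = a$event, grp = 0L),
               data.frame(time = b$time, event = b$event, grp = 1L))
  if (sum(dat$event) == 0L) {
    warning("no events in either cohort; log-rank undefined, p set to 1")
    return(list(chi_square = 0, p_value = 1, n_events = 0L))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp, data = dat)
  chi <- unname(sd$chisq)
  list(chi_square = chi,
       p_value = stats::pchisq(chi, df = 1L, lower.tail = FALSE),
       n_events = sum(dat$event))
}

#' Rank switch genes by prognostic separation
#'
#' For each switch gene, patients are stratified into low/high expression
#' cohorts and a log-rank test compares their survival; genes are sorted
#' by increasing p-value so the best separators of the two prognosis
#' groups come first. A Benjamini-Hochberg column is added for reference
#' but the ordering uses the raw p-values.
#'
#' @param em,clinical See [stratify_by_expression()].
#' @param switch_genes Non-empty character vector of gene ids.
#' @param low_q,high_q Quantile cut points for stratification.
#' @param max_followup_days Optional right-truncation of follow-up:
#'   observations beyond this horizon are censored there (default `Inf`,
#'   i.e. off).
#' @return A data.frame (`gene`, `chi_square`, `p`, `q`, `n_low`,
#'   `n_high`) sorted by ascending p; genes skipped for degenerate
#'   stratification are listed in attribute `"skipped"`.
#' @export
rank_switch_genes_by_survival <- function(em, clinical, switch_genes,
                                          low_q = 0.25, high_q = 0.75,
                                          max_followup_days = Inf) {
  if (!length(switch_genes)) stop("`switch_genes` must be non-empty")
  rows <- list()
  skipped <- character()
  for (gene in switch_genes) {
    rec <- withCallingHandlers(
      stratify_by_expression(em, clinical, gene, low_q, high_q),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(rec)) { skipped <- c(skipped, gene); next }
    if (is.finite(max_followup_days)) {
      over <- rec$time > max_followup_days
      rec$event[over] <- 0L
      rec$time[over] <- max_followup_days
    }
    lo <- rec[rec$group == "low", ]
    hi <- rec[rec$group == "high", ]
    lr <- withCallingHandlers(logrank_test(lo, hi),
                              warning = function(w) invokeRestart("muffleWarning"))
    rows[[gene]] <- data.frame(gene = gene, chi_square = lr$chi_square,
                               p = lr$p_value, n_low = nrow(lo),
                               n_high = nrow(hi), stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    res <- data.frame(gene = character(), chi_square = numeric(),
                      p = numeric(), q = numeric(),
                      n_low = integer(), n_high = integer())
  } else {
    res <- do.call(rbind, rows)
    res$q <- stats::p.adjust(res$p, method = "BH")
    res <- res[order(res$p, res$gene), c("gene", "chi_square", "p", "q",
                                         "n_low", "n_high")]
    rownames(res) <- NULL
  }
  attr(res, "skipped") <- skipped
  res
}
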