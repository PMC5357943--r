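#' Generate modular expression data with planted switch genes
#'
#' Factor model: each module m draws an independent latent factor
#' `f_m ~ N(0, 1)` per sample; a member gene of module m is
#' `baseline + sqrt(intra_corr) * f_m + noise_sd * eps`. Each planted
#' switch gene is assigned a home module and tracks the *negated*,
#' unit-variance average of the latent factors of `n_foreign` other
#' modules: `baseline - switch_strength * u + noise_sd * eps` with
#' `u = sum(f_targets) / sqrt(n_foreign)`, so `switch_strength` is the
#' loading on a unit-variance repressive signal whatever `n_foreign`. In a
#' thresholded correlation network this gives switch genes edges almost
#' exclusively into foreign modules with negative correlations: high
#' clusterphobic coefficient, low global within-module degree and negative
#' APCC. At zero noise the switch-to-target-member correlation has the
#' closed form `-1 / sqrt(n_foreign)`.
#'
#' @param n_modules Number of modules (>= 3 when switches are planted, so
#'   each switch can track >= 2 foreign modules).
#' @param genes_per_module Member genes per module.
#' @param n_samples Number of samples.
#' @param intra_corr Squared factor loading of member genes in (0, 1]:
#'   the noise-free correlation between two members of one module is 1 and
#'   the member-factor correlation is `sqrt(intra_corr)` (default 0.8).
#' @param n_switch Number of planted switch genes (default 0).
#' @param switch_strength Loading of switch genes on their foreign-module
#'   factors, in (0, 1] (default 0.8).
#' @param noise_sd Gene-level Gaussian noise sd (default 0.3).
#' @param n_foreign Number of foreign modules each switch tracks
#'   (default 2).
#' @param baseline Additive offset keeping values positive (default 10);
#'   Pearson correlations are unaffected.
#' @param seed Integer seed (mandatory).
#' @return A list with `em` (an `expr_set`) and `truth`: a data.frame
#'   (`gene`, `module`, `is_switch`, `targets` — semicolon-joined foreign
#'   modules for switch genes) plus the generator parameters in attribute
#'   `"params"`.
#' @export
generate_modular_expression <- function(n_modules, genes_per_module,
                                        n_samples, intra_corr = 0.8,
                                        n_switch = 0L,
                                        switch_strength = 0.8,
                                        noise_sd = 0.3, n_foreign = 2L,
                                        baseline = 10, seed) {
  stopifnot(n_modules >= 1L, genes_per_module >= 1L, n_samples >= 3L,
            intra_corr > 0, intra_corr <= 1,
            switch_strength > 0, switch_strength <= 1, noise_sd >= 0)
  if (n_switch > 0L) {
    if (n_modules < n_foreign + 1L)
      stop("planting switches needs n_modules >= n_foreign + 1")
    if (n_switch > n_modules * genes_per_module)
      stop("n_switch exceeds capacity (n_modules * genes_per_module)")
  }
  if (n_samples <= n_modules + 1L)
    stop("need n_samples > n_modules + 1 for in-sample orthonormal factors")
  with_seed(seed, {
    # latent factors, centred and orthonormalized in-sample (unit sample
    # variance, zero sample correlation) so planted correlations are exact
    # at the zero-noise limit
    raw <- matrix(stats::rnorm(n_samples * n_modules), n_samples, n_modules)
    q <- qr.Q(qr(cbind(1, raw)))
    factors <- q[, -1L, drop = FALSE] * sqrt(n_samples - 1L)
    member_genes <- paste0("M", rep(seq_len(n_modules), each = genes_per_module),
                           "_G", sprintf("%03d", rep(seq_len(genes_per_module),
                                                     times = n_modules)))
    member_module <- rep(seq_len(n_modules), each = genes_per_module)
    vals <- baseline +
      sqrt(intra_corr) * t(factors[, member_module, drop = FALSE]) +
      noise_sd * matrix(stats::rnorm(length(member_genes) * n_samples),
                        length(member_genes), n_samples)
    sw_targets <- character(0)
    if (n_switch > 0L) {
      sw_genes <- paste0("SW", sprintf("%02d", seq_len(n_switch)))
      sw_home <- rep_len(seq_len(n_modules), n_switch)
      sw_rows <- matrix(NA_real_, n_switch, n_samples)
      sw_targets <- character(n_switch)
      for (i in seq_len(n_switch)) {
        targets <- sample(setdiff(seq_len(n_modules), sw_home[i]), n_foreign)
        sw_targets[i] <- paste(sort(targets), collapse = ";")
        u <- rowSums(factors[, targets, drop = FALSE]) / sqrt(n_foreign)
        sw_rows[i, ] <- baseline - switch_strength * u +
          noise_sd * stats::rnorm(n_samples)
      }
      vals <- rbind(vals, sw_rows)
      genes <- c(member_genes, sw_genes)
      modules <- c(member_module, sw_home)
      is_switch <- c(rep(FALSE, length(member_genes)), rep(TRUE, n_switch))
      targets_all <- c(rep(NA_character_, length(member_genes)), sw_targets)
    } else {
      genes <- member_genes
      modules <- member_module
      is_switch <- rep(FALSE, length(member_genes))
      targets_all <- rep(NA_character_, length(member_genes))
    }
    rownames(vals) <- genes
    colnames(vals) <- paste0("S", sprintf("%03d", seq_len(n_samples)))
    truth <- data.frame(gene = genes, module = modules,
                        is_switch = is_switch, targets = targets_all,
                        stringsAsFactors = FALSE)
    attr(truth, "params") <- list(n_modules = n_modules,
                                  genes_per_module = genes_per_module,
                                  n_samples = n_samples,
                                  intra_corr = intra_corr,
                                  n_switch = n_switch,
                                  switch_strength = switch_strength,
                                  noise_sd = noise_sd,
                                  n_foreign = n_foreign,
                                  baseline = baseline, seed = seed)
    list(em = expression_matrix(vals), truth = truth)
  })
}

#' Derive a paired tumor/normal expression set from a base matrix
#'
#' The base matrix supplies one normal sample per patient; the tumor
#' sample of each patient is the normal profile with the selected genes
#' scaled by `2^log2fc`, plus multiplicative log-normal noise. Sample ids
#' become `<patient>_N` / `<patient>_T` and condition and pairing
#' annotations are recorded.
#'
#' @param base An `expr_set` whose columns are taken as patients' normal
#'   samples.
#' @param de_genes Genes (subset of the matrix) to perturb in tumors.
#' @param log2fc Log2 fold change applied to `de_genes` in tumors.
#' @param noise_sd Sd of the Gaussian noise added on the log2 scale to
#'   every tumor entry (default 0, i.e. noiseless).
#' @param seed Integer seed.
#' @return An `expr_set` with `condition` and `patient_id` set.
#' @export
generate_paired_tumor_normal <- function(base, de_genes, log2fc,
                                         noise_sd = 0, seed) {
  stopifnot(inherits(base, "expr_set"))
  miss <- setdiff(de_genes, rownames(base$values))
  if (length(miss)) stop("de_genes not in matrix: ",
                         paste(utils::head(miss, 5L), collapse = ", "))
  with_seed(seed, {
    patients <- colnames(base$values)
    normal <- base$values
    tumor <- normal
    tumor[de_genes, ] <- tumor[de_genes, , drop = FALSE] * 2^log2fc
    if (noise_sd > 0)
      tumor <- tumor * 2^matrix(stats::rnorm(length(tumor), sd = noise_sd),
                                nrow(tumor), ncol(tumor))
    vals <- cbind(normal, tumor)
    colnames(vals) <- c(paste0(patients, "_N"), paste0(patients, "_T"))
    expression_matrix(vals,
                      condition = rep(c("normal", "tumor"),
                                      each = length(patients)),
                      patient_id = rep(patients, 2L))
  })
}

#' Simulate survival times driven by a gene's expression
#'
#' Event times are exponential with rate
#' `baseline_rate * exp(beta * z)` where `z` is the patient's
#' standardized tumor expression of the driver gene; censoring times are
#' independent exponentials with rate `censor_rate` (no censoring when
#' `censor_rate = 0`). `beta = 0` gives a null relationship.
#'
#' @param em An `expr_set`; tumor samples are used when a condition
#'   annotation is present, and `patient_id` (or the sample ids, as a
#'   fallback) identify patients.
#' @param driver_gene Gene id driving the hazard.
#' @param beta Log-hazard per sd of expression.
#' @param baseline_rate Baseline event rate per day (default 1/1000).
#' @param censor_rate Censoring rate per day (default 1/2000).
#' @param seed Integer seed.
#' @return A clinical data.frame (`patient_id`, `time_days`, `event`).
#' @export
generate_survival <- function(em, driver_gene, beta,
                              baseline_rate = 1e-3, censor_rate = 5e-4,
                              seed) {
  stopifnot(inherits(em, "expr_set"))
  if (!driver_gene %in% rownames(em$values)) stop("unknown gene: ", driver_gene)
  keep <- if (!is.null(em$condition)) em$condition == "tumor" else
    rep(TRUE, n_samples(em))
  expr <- em$values[driver_gene, keep]
  patients <- if (!is.null(em$patient_id)) em$patient_id[keep] else
    colnames(em$values)[keep]
  expr <- tapply(expr, patients, mean)
  z <- as.numeric(scale(as.numeric(expr)))
  with_seed(seed, {
    n <- length(z)
    event_time <- stats::rexp(n, rate = baseline_rate * exp(beta * z))
    censor_time <- if (censor_rate > 0) stats::rexp(n, rate = censor_rate)
      else rep(Inf, n)
    data.frame(patient_id = names(expr),
               time_days = pmin(event_time, censor_time),
               event = as.integer(event_time <= censor_time),
               stringsAsFactors = FALSE, row.names = NULL)
  })
}
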