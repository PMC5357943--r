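# small deterministic clinical fixture
toy_clinical <- function(patients, times, events) {
  data.frame(patient_id = patients, time_days = times, event = events,
             stringsAsFactors = FALSE)
}

test_that("stratification keeps only the expression quartile tails", {
  vals <- matrix(c(1:8, rep(5, 8)), nrow = 2, byrow = TRUE,
                 dimnames = list(c("gA", "gB"), paste0("P", 1:8)))
  em <- expression_matrix(vals, patient_id = paste0("P", 1:8))
  clin <- toy_clinical(paste0("P", 1:8), 100 * (1:8), rep(1L, 8))

  rec <- stratify_by_expression(em, clin, "gA")
  expect_setequal(rec$patient_id[rec$group == "low"], c("P1", "P2"))
  expect_setequal(rec$patient_id[rec$group == "high"], c("P7", "P8"))
  expect_equal(nrow(rec), 4L)

  # constant expression: both cohorts empty, gene skipped
  expect_warning(rec_b <- stratify_by_expression(em, clin, "gB"), "skipped")
  expect_null(rec_b)

  # ties exactly at the quantile are excluded (strict inequalities)
  vals2 <- matrix(c(1, 2, 2, 3, 3, 4, 4, 5), nrow = 1,
                  dimnames = list("gC", paste0("P", 1:8)))
  em2 <- expression_matrix(vals2, patient_id = paste0("P", 1:8))
  rec2 <- stratify_by_expression(em2, clin, "gC")
  q <- stats::quantile(c(1, 2, 2, 3, 3, 4, 4, 5), c(0.25, 0.75), names = FALSE)
  expect_true(all(rec2$patient_id %in%
                    paste0("P", which(c(1, 2, 2, 3, 3, 4, 4, 5) < q[1] |
                                      c(1, 2, 2, 3, 3, 4, 4, 5) > q[2]))))
})

test_that("stratification uses tumor samples when conditions are annotated", {
  em <- toy_paired(n_genes = 3L, n_patients = 8L, log2fc = 3, de = "gA")
  clin <- toy_clinical(paste0("P", 1:8), 100 * (1:8), rep(1L, 8))
  rec <- stratify_by_expression(em, clin, "gA")
  tumor_expr <- em$values["gA", em$condition == "tumor"]
  names(tumor_expr) <- em$patient_id[em$condition == "tumor"]
  q <- stats::quantile(tumor_expr, c(0.25, 0.75), names = FALSE)
  expect_setequal(rec$patient_id[rec$group == "low"],
                  names(tumor_expr)[tumor_expr < q[1]])
})

test_that("KM estimate equals the hand product-limit table", {
  # no events: survival stays at 1
  none <- data.frame(time = c(5, 8, 12), event = c(0, 0, 0))
  expect_true(all(km_estimate(none)$surv == 1))

  # two events among two subjects: S = 0.5 then 0
  both <- data.frame(time = c(1, 2), event = c(1, 1))
  km <- km_estimate(both)
  expect_equal(km$surv, c(0.5, 0))

  # 6-record mixed censoring vs hand oracle
  mixed <- data.frame(time = c(2, 3, 3, 5, 8, 9),
                      event = c(1, 1, 0, 1, 0, 1))
  km2 <- km_estimate(mixed)
  hand <- oracle_km(mixed$time, mixed$event)
  expect_equal(km2$surv[km2$n_event > 0], hand$surv)
  expect_true(all(diff(km2$surv) <= 0))
  expect_true(all(km2$surv >= 0 & km2$surv <= 1))
})

test_that("log-rank statistic matches first-principles computation and is symmetric", {
  set.seed(42)
  a <- data.frame(time = round(rexp(15, 1 / 300)) + 1, event = rbinom(15, 1, 0.8))
  b <- data.frame(time = round(rexp(15, 1 / 600)) + 1, event = rbinom(15, 1, 0.8))
  lr <- logrank_test(a, b)
  chi_oracle <- oracle_logrank_chisq(c(a$time, b$time), c(a$event, b$event),
                                     rep(c(0L, 1L), c(15L, 15L)))
  expect_equal(lr$chi_square, chi_oracle, tolerance = 1e-9)
  expect_equal(lr$p_value, pchisq(chi_oracle, 1, lower.tail = FALSE))

  # identical cohorts: statistic 0, p = 1
  same <- data.frame(time = c(3, 6, 9), event = c(1, 1, 0))
  lr0 <- logrank_test(same, same)
  expect_equal(lr0$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1)

  # label swap leaves the statistic unchanged
  lr_swap <- logrank_test(b, a)
  expect_equal(lr_swap$chi_square, lr$chi_square, tolerance = 1e-12)

  # zero events -> warning and p = 1
  cens <- data.frame(time = c(5, 6), event = c(0, 0))
  expect_warning(lrz <- logrank_test(cens, cens), "no events")
  expect_equal(lrz$p_value, 1)
})

test_that("log-rank p agrees with a permutation oracle on a 40-patient toy", {
  set.seed(7)
  n <- 20L
  time <- c(round(rexp(n, 1 / 200)) + 1, round(rexp(n, 1 / 400)) + 1)
  event <- rbinom(2L * n, 1L, 0.85)
  grp <- rep(c(0L, 1L), each = n)
  a <- data.frame(time = time[grp == 0], event = event[grp == 0])
  b <- data.frame(time = time[grp == 1], event = event[grp == 1])
  p_chisq <- logrank_test(a, b)$p_value

  obs <- oracle_logrank_chisq(time, event, grp)
  B <- 2000L
  set.seed(99)
  exceed <- 0L
  for (i in seq_len(B)) {
    g_perm <- sample(grp)
    if (oracle_logrank_chisq(time, event, g_perm) >= obs - 1e-12)
      exceed <- exceed + 1L
  }
  p_perm <- (exceed + 1L) / (B + 1L)
  mc_sd <- sqrt(p_perm * (1 - p_perm) / B)
  # chi-square approximation should sit within Monte-Carlo error plus a
  # small approximation allowance at this sample size
  expect_lt(abs(p_chisq - p_perm), 3 * mc_sd + 0.02)
})

test_that("ranking orders genes by prognostic separation and is deterministic", {
  base <- generate_modular_expression(2L, 6L, 60L, intra_corr = 0.5,
                                      noise_sd = 1, seed = 31)$em
  em <- generate_paired_tumor_normal(base, de_genes = character(0),
                                     log2fc = 0, seed = 31)
  driver <- "M1_G001"
  clin <- generate_survival(em, driver, beta = 2, baseline_rate = 1e-3,
                            censor_rate = 1e-4, seed = 32)
  genes <- rownames(em$values)[1:6]
  rk <- rank_switch_genes_by_survival(em, clin, genes)
  expect_equal(rk$gene[1], driver)
  expect_true(!is.unsorted(rk$p))
  expect_identical(rk, rank_switch_genes_by_survival(em, clin, genes))

  single <- rank_switch_genes_by_survival(em, clin, driver)
  expect_equal(nrow(single), 1L)

  # pooled event count equals the sum over cohorts
  rec <- stratify_by_expression(em, clin, driver)
  lo <- rec[rec$group == "low", ]; hi <- rec[rec$group == "high", ]
  expect_equal(sum(km_estimate(rec)$n_event),
               sum(km_estimate(lo)$n_event) + sum(km_estimate(hi)$n_event))
})
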