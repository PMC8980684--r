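test_that("confusion matrix counts match a brute-force tally", {
  set.seed(42)
  pos <- runif(20) > 0.5
  isch <- runif(20) > 0.5
  cm <- confusion_matrix(pos, isch)
  expect_equal(cm$tp, sum(pos & isch))
  expect_equal(cm$fp, sum(pos & !isch))
  expect_equal(cm$tn, sum(!pos & !isch))
  expect_equal(cm$fn, sum(!pos & isch))

  all_pos <- confusion_matrix(rep(TRUE, 5), rep(TRUE, 5))
  expect_equal(all_pos$fp + all_pos$tn, 0)
  expect_error(confusion_matrix(logical(0), logical(0)), "nonempty")
})

test_that("diagnostic metrics reproduce the per-vessel worked example", {
  rep_ct <- diagnostic_metrics(table3_ctffr_cm())
  got <- setNames(rep_ct$value_pct, rep_ct$metric)
  expect_equal(got[["sensitivity"]], 89.9)
  expect_equal(got[["specificity"]], 87.8)
  expect_equal(got[["accuracy"]], 88.8)
  expect_equal(got[["npv"]], 91.1)

  rep_cta <- diagnostic_metrics(table3_cta_cm())
  got <- setNames(rep_cta$value_pct, rep_cta$metric)
  expect_equal(got[["specificity"]], 35.5)
  expect_equal(got[["accuracy"]], 60.4)
  expect_equal(got[["ppv"]], 54.3)
})

test_that("perfect classifier reports 100% with intervals capped at 100", {
  rep <- diagnostic_metrics(confusion_counts(tp = 30, fp = 0, tn = 25, fn = 0))
  expect_true(all(rep$value_pct == 100))
  expect_true(all(rep$ci_high_pct <= 100))
  expect_true(all(rep$ci_low_pct <= rep$value_raw_pct &
                  rep$value_raw_pct <= rep$ci_high_pct))
})

test_that("zero-denominator metrics are flagged undefined, not fabricated", {
  rep <- diagnostic_metrics(confusion_counts(tp = 0, fp = 0, tn = 10, fn = 5))
  expect_true(is.na(rep$value_pct[rep$metric == "ppv"]))
  expect_false(is.na(rep$value_pct[rep$metric == "npv"]))
})

test_that("accuracy identity holds for arbitrary confusion matrices", {
  set.seed(7)
  for (i in 1:20) {
    cts <- rmultinom(1, 200, runif(4, 0.05, 1))
    cm <- confusion_counts(cts[1], cts[2], cts[3], cts[4])
    rep <- diagnostic_metrics(cm)
    v <- setNames(rep$value_raw_pct, rep$metric)
    P <- cm$tp + cm$fn; N <- cm$tn + cm$fp
    expect_equal(v[["accuracy"]],
                 (v[["sensitivity"]] * P + v[["specificity"]] * N) / (P + N),
                 tolerance = 1e-10)
  }
})

test_that("Wilson interval contains the point estimate and stays in [0,1]", {
  for (x in c(0, 1, 7, 50)) {
    ci <- wilson_ci(x, 50)
    p <- x / 50
    expect_true(ci[1] >= 0 && ci[2] <= 1)
    expect_true(ci[1] <= p && p <= ci[2])
  }
})

test_that("AUC equals all-pairs concordance enumeration", {
  expect_equal(auc_mann_whitney(c(0.5, 0.6, 0.9, 0.95),
                                c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(auc_mann_whitney(rep(0.8, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)

  set.seed(11)
  scores <- round(runif(12, 0.4, 1), 2)   # induce ties
  isch <- c(rep(TRUE, 5), rep(FALSE, 7))
  res <- auc_mann_whitney(scores, isch)
  expect_equal(res$auc, auc_brute_force(scores, isch), tolerance = 1e-12)
  expect_true(res$ci[1] <= res$auc && res$auc <= res$ci[2])
  expect_error(auc_mann_whitney(1:5, rep(TRUE, 5)), "both classes")
})

test_that("binary-score AUC equals (sensitivity+specificity)/2", {
  set.seed(3)
  isch <- runif(200) < 0.45
  cta_pos <- runif(200) < ifelse(isch, 0.85, 0.5)
  res <- auc_mann_whitney(-as.numeric(cta_pos), isch)  # lower = more diseased
  cm <- confusion_matrix(cta_pos, isch)
  se <- cm$tp / (cm$tp + cm$fn)
  sp <- cm$tn / (cm$tn + cm$fp)
  expect_equal(res$auc, (se + sp) / 2, tolerance = 1e-12)
  expect_equal(res$auc, auc_brute_force(-as.numeric(cta_pos), isch),
               tolerance = 1e-12)
})

test_that("Bland-Altman returns mean, SD, limits, and CI of the mean", {
  same <- bland_altman(c(0.8, 0.7, 0.9), c(0.8, 0.7, 0.9))
  expect_equal(same$mean_difference, 0)
  expect_equal(same$sd, 0)

  off <- bland_altman(c(0.8, 0.7, 0.9), c(0.85, 0.75, 0.95))
  expect_equal(off$mean_difference, 0.05, tolerance = 1e-12)
  expect_equal(off$sd, 0, tolerance = 1e-12)

  x <- c(0.70, 0.75, 0.80, 0.85, 0.90)
  y <- c(0.72, 0.74, 0.83, 0.84, 0.93)
  ba <- bland_altman(x, y)
  d <- y - x
  expect_equal(ba$mean_difference, mean(d), tolerance = 1e-12)
  expect_equal(ba$sd, sd(d), tolerance = 1e-12)
  expect_equal(ba$loa_high, mean(d) + 1.96 * sd(d), tolerance = 1e-12)
  expect_error(bland_altman(1, 1), ">= 2")
})

test_that("Pearson correlation matches its definition", {
  x <- c(0.6, 0.7, 0.75, 0.8, 0.85, 0.95)
  expect_equal(pearson_r(x, x)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  set.seed(2)
  y <- x + rnorm(6, 0, 0.05)
  r_def <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y)$r, r_def, tolerance = 1e-12)
  expect_true(pearson_r(x, rep(1, 6))$undefined)
})

test_that("per-bin accuracy equals a group-by tally", {
  set.seed(13)
  n <- 200
  measured <- runif(n, 0.5, 1)
  ct <- pmin(pmax(measured + rnorm(n, 0, 0.05), 0.01), 1)
  cohort <- data.frame(measured_ffr = measured, ct_ffr = ct,
                       cta_percent_stenosis = 50)
  tab <- accuracy_by_ffr_bin(cohort)
  agree <- (ct <= 0.8) == (measured < 0.8)
  bins <- cut(measured, c(-Inf, 0.655, 0.705, 0.755, 0.805, 0.855, 0.905, Inf))
  oracle <- tapply(agree, bins, mean)
  for (i in seq_len(nrow(tab))) {
    if (tab$n[i] > 0)
      expect_equal(tab$accuracy_pct[i],
                   floor(100 * oracle[[i]] * 10 + 0.5) / 10)
  }
  # perfect agreement: every nonempty bin 100%
  perfect <- accuracy_by_ffr_bin(data.frame(
    measured_ffr = measured, ct_ffr = measured, cta_percent_stenosis = 50))
  expect_true(all(perfect$accuracy_pct[perfect$n > 0] == 100))
})

test_that("stratified misdiagnosis rates reproduce the worked example", {
  tab <- misdiagnosis_rates(cohort_from_strata())
  got <- setNames(tab$rate_pct, tab$stratum)
  expect_equal(got[["FFR<0.76"]], 5.9)     # 7 of 119
  expect_equal(got[["gray zone"]], 20.0)   # 10 of 50
  expect_equal(got[["FFR>0.8"]], 10.7)     # 21 of 197
  acc <- setNames(tab$accuracy_pct, tab$stratum)
  expect_equal(acc[["gray zone"]], 80.0)
  expect_equal(tab$n, c(119, 50, 197))
})

test_that("group comparison: Mann-Whitney U matches pair enumeration", {
  x <- c(1.2, 3.4, 2.2)
  y <- c(0.8, 2.9, 5.1)
  res <- group_compare(c(x, y), rep(c("a", "b"), each = 3), "continuous")
  expect_equal(unname(res$U), u_brute_force(x, y))
  expect_equal(res$groups$median, c(median(x), median(y)))

  # identical multisets: U at its null mean, p near 1
  v <- c(1, 2, 3, 4)
  same <- group_compare(c(v, v), rep(c("a", "b"), each = 4), "continuous")
  expect_equal(unname(same$U), length(v)^2 / 2)
  expect_gte(same$p, 0.99)
})

test_that("categorical comparison takes the Fisher path on sparse tables", {
  vals <- c(rep(TRUE, 6), rep(FALSE, 1), rep(TRUE, 1), rep(FALSE, 7))
  grp <- rep(c("a", "b"), c(7, 8))
  res <- group_compare(vals, grp, "categorical")
  expect_identical(res$test, "fisher")
  expect_equal(res$p, fisher_brute_force(table(factor(vals), grp)),
               tolerance = 1e-9)
})

test_that("univariate logistic OR on a binary covariate equals ad/bc", {
  # 2x2: exposed/unexposed x outcome
  a <- 12; b <- 30; c <- 5; d <- 40   # outcome|exposed, no-outcome|exposed, ...
  cov <- c(rep(1, a + b), rep(0, c + d))
  out <- c(rep(TRUE, a), rep(FALSE, b), rep(TRUE, c), rep(FALSE, d))
  res <- univariate_logistic_or(cov, out)
  expect_true(res$estimable)
  expect_equal(res$or, (a * d) / (b * c), tolerance = 1e-6)
  expect_true(res$ci[1] <= res$or && res$or <= res$ci[2])

  const <- univariate_logistic_or(rep(2, 20), rep(c(TRUE, FALSE), 10))
  expect_false(const$estimable)

  sep <- univariate_logistic_or(c(rep(0, 10), rep(1, 10)),
                                c(rep(FALSE, 10), rep(TRUE, 10)))
  expect_false(sep$estimable)
})

test_that("null logistic OR is near 1 on a large independent sample", {
  set.seed(19)
  cov <- rnorm(5000)
  out <- runif(5000) < 0.3
  res <- univariate_logistic_or(cov, out)
  expect_true(res$or > 0.9 && res$or < 1.1)
})

test_that("paired McNemar comparison equals the exact binomial sum", {
  isch <- rep(TRUE, 40)
  a_pos <- c(rep(TRUE, 25), rep(FALSE, 15))
  b_pos <- a_pos
  expect_equal(paired_metric_compare(isch, a_pos, b_pos, "sensitivity")$p, 1)

  # discordant counts (12, 3)
  isch <- rep(TRUE, 30)
  a_pos <- c(rep(TRUE, 12), rep(FALSE, 3), rep(TRUE, 15))
  b_pos <- c(rep(FALSE, 12), rep(TRUE, 3), rep(TRUE, 15))
  res <- paired_metric_compare(isch, a_pos, b_pos, "sensitivity")
  expect_equal(unname(res$discordant["a_only"]), 12)
  expect_equal(res$p, binom_two_sided_brute(12, 15), tolerance = 1e-12)

  # symmetric discordance: p = 1
  a_pos <- c(rep(TRUE, 5), rep(FALSE, 5), rep(TRUE, 20))
  b_pos <- c(rep(FALSE, 5), rep(TRUE, 5), rep(TRUE, 20))
  expect_equal(paired_metric_compare(isch, a_pos, b_pos, "sensitivity")$p, 1)
})

test_that("full evaluation is perfect when CT-FFR equals measured FFR", {
  set.seed(23)
  n <- 300
  measured <- runif(n, 0.45, 1)
  cohort <- data.frame(measured_ffr = measured, ct_ffr = measured,
                       cta_percent_stenosis = runif(n, 20, 95),
                       calcium_score = rlnorm(n, 3, 1),
                       plaque_burden = runif(n, 30, 70))
  ev <- evaluate_cohort(cohort)
  v <- setNames(ev$metrics$ct_ffr$value_pct, ev$metrics$ct_ffr$metric)
  expect_true(all(v == 100))
  expect_true(all(ev$bin_accuracy$accuracy_pct[ev$bin_accuracy$n > 0] == 100))
  expect_equal(ev$auc$ct_ffr$auc, 1)
  expect_equal(ev$pearson$r, 1)
  expect_equal(ev$bland_altman$all$mean_difference, 0)
})
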