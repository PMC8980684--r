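# Diagnostic-performance analysis of a CT-FFR trial cohort: confusion-matrix
# metrics with Wilson intervals, rank-based AUC with DeLong variance,
# agreement and correlation, per-FFR-bin accuracy, gray-zone stratification,
# group comparisons, and univariate logistic risk-factor screening.

#' Round half-up, as clinical tables print
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Classification thresholds of the trial
#'
#' Ischemia is defined by invasive FFR below `ischemia_threshold`; the
#' CT-FFR test is positive at or below `index_threshold`; CTA is positive at
#' or above `cta_threshold` percent stenosis.  The gray zone (FFR near the
#' decision threshold) is treated as ischemic.
#'
#' @param ischemia_threshold FFR ischemia cut-off (exclusive), default 0.80.
#' @param index_threshold CT-FFR positivity cut-off (inclusive), default 0.80.
#' @param cta_threshold CTA positivity cut-off in percent stenosis, default 50.
#' @param gray_zone Gray-zone FFR interval, default `c(0.76, 0.80)`.
#' @return A list of class `threshold_policy`.
#' @export
threshold_policy <- function(ischemia_threshold = 0.80, index_threshold = 0.80,
                             cta_threshold = 50, gray_zone = c(0.76, 0.80)) {
  stopifnot(ischemia_threshold > 0, ischemia_threshold < 1,
            index_threshold > 0, index_threshold < 1,
            cta_threshold > 0, cta_threshold < 100,
            gray_zone[1] < gray_zone[2])
  structure(list(ischemia_threshold = ischemia_threshold,
                 index_threshold = index_threshold,
                 cta_threshold = cta_threshold, gray_zone = gray_zone),
            class = "threshold_policy")
}

#' 2x2 confusion matrix from paired flags
#'
#' @param index_positive Logical vector: test positive.
#' @param ischemic Logical vector: reference positive (same length).
#' @return A list of class `confusion_matrix` with counts `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
confusion_matrix <- function(index_positive, ischemic) {
  if (!length(index_positive) || length(index_positive) != length(ischemic))
    stop("flags must be nonempty and of equal length", call. = FALSE)
  index_positive <- as.logical(index_positive)
  ischemic <- as.logical(ischemic)
  confusion_counts(tp = sum(index_positive & ischemic),
                   fp = sum(index_positive & !ischemic),
                   tn = sum(!index_positive & !ischemic),
                   fn = sum(!index_positive & ischemic))
}

#' 2x2 confusion matrix from counts
#'
#' @param tp,fp,tn,fn Cell counts (>= 0, total > 0).
#' @return A `confusion_matrix`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (sum(counts) == 0) stop("confusion matrix must have total > 0", call. = FALSE)
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(test = c("positive", "negative"),
                              reference = c("ischemic", "non-ischemic")))
  print(m)
  invisible(x)
}

#' Wilson score confidence interval for a proportion
#'
#' @param x Successes; `n` trials; `conf` confidence level.
#' @return `c(lower, upper)` on the proportion scale.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  if (n <= 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  # clamp against floating-point loss so the interval always contains p
  c(min(max(0, centre - half), p), max(min(1, centre + half), p))
}

#' Diagnostic metrics with confidence intervals
#'
#' Sensitivity, specificity, accuracy, PPV and NPV as percentages (rounded
#' half-up to one decimal, as printed in clinical tables, with full-precision
#' values alongside) and 95% intervals, Wilson score by default.  A metric
#' with a zero denominator is reported as `NA`, never fabricated.
#'
#' @param cm A [confusion_matrix()].
#' @param ci_method `"wilson"` (default) or `"normal"`.
#' @param conf Confidence level.
#' @return A data.frame of class `diagnostic_report`: one row per metric with
#'   `value_pct` (rounded), `value_raw_pct`, `ci_low_pct`, `ci_high_pct`,
#'   `numerator`, `denominator`.
#' @examples
#' diagnostic_metrics(confusion_counts(tp = 152, fp = 24, tn = 173, fn = 17))
#' @export
diagnostic_metrics <- function(cm, ci_method = c("wilson", "normal"),
                               conf = 0.95) {
  stopifnot(inherits(cm, "confusion_matrix"))
  ci_method <- match.arg(ci_method)
  total <- cm$tp + cm$fp + cm$tn + cm$fn
  num <- c(sensitivity = cm$tp, specificity = cm$tn,
           accuracy = cm$tp + cm$tn, ppv = cm$tp, npv = cm$tn)
  den <- c(sensitivity = cm$tp + cm$fn, specificity = cm$tn + cm$fp,
           accuracy = total, ppv = cm$tp + cm$fp, npv = cm$tn + cm$fn)
  rows <- lapply(names(num), function(m) {
    if (den[m] == 0)
      return(data.frame(metric = m, value_pct = NA_real_,
                        value_raw_pct = NA_real_, ci_low_pct = NA_real_,
                        ci_high_pct = NA_real_, numerator = num[[m]],
                        denominator = den[[m]]))
    p <- num[[m]] / den[[m]]
    ci <- if (ci_method == "wilson") wilson_ci(num[[m]], den[[m]], conf)
          else {
            z <- stats::qnorm(1 - (1 - conf) / 2)
            half <- z * sqrt(p * (1 - p) / den[[m]])
            c(max(0, p - half), min(1, p + half))
          }
    data.frame(metric = m, value_pct = round_half_up(100 * p, 1),
               value_raw_pct = 100 * p,
               ci_low_pct = 100 * ci[1], ci_high_pct = 100 * ci[2],
               numerator = num[[m]], denominator = den[[m]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("diagnostic_report", "data.frame")
  out
}

#' Rank-based AUC with DeLong variance
#'
#' Concordance AUC for a continuous index oriented so that lower values
#' indicate more disease (as FFR-like indices are), ties counted 1/2, with a
#' DeLong-style placement variance for the confidence interval.
#'
#' @param scores Continuous index values (lower = more diseased).
#' @param ischemic Logical reference flags; both classes must be present.
#' @param conf Confidence level.
#' @return List with `auc`, `ci` (length 2), `se`, `n_pos`, `n_neg`.
#' @export
auc_mann_whitney <- function(scores, ischemic, conf = 0.95) {
  ischemic <- as.logical(ischemic)
  if (length(scores) != length(ischemic))
    stop("scores and flags must have equal length", call. = FALSE)
  x <- scores[ischemic]    # diseased: expected lower
  y <- scores[!ischemic]
  if (!length(x) || !length(y))
    stop("both classes must be present to compute an AUC", call. = FALSE)
  # placements: psi(x_i, y_j) = 1 if y_j > x_i, 1/2 if tied
  psi <- outer(x, y, function(a, b) (b > a) + 0.5 * (b == a))
  auc <- mean(psi)
  v10 <- rowMeans(psi)     # per-diseased placements
  v01 <- colMeans(psi)
  se <- sqrt(stats::var(v10) / length(x) + stats::var(v01) / length(y))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- c(max(0, auc - z * se), min(1, auc + z * se))
  list(auc = auc, ci = ci, se = se, n_pos = length(x), n_neg = length(y))
}

#' Bland-Altman agreement of paired measurements
#'
#' Differences `d = y - x`: mean difference, SD, 95% limits of agreement
#' `mean +/- 1.96 SD`, and the t-based 95% CI of the mean difference (both
#' interval types are reported).
#'
#' @param x,y Paired measurement vectors (>= 2 pairs).
#' @param conf Confidence level for the CI of the mean difference.
#' @return List with `mean_difference`, `sd`, `loa_low`, `loa_high`,
#'   `ci_mean`, `n`.
#' @export
bland_altman <- function(x, y, conf = 0.95) {
  if (length(x) != length(y) || length(x) < 2)
    stop("need >= 2 complete pairs", call. = FALSE)
  d <- y - x
  m <- mean(d)
  s <- stats::sd(d)
  n <- length(d)
  half <- stats::qt(1 - (1 - conf) / 2, n - 1) * s / sqrt(n)
  list(mean_difference = m, sd = s,
       loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
       ci_mean = c(m - half, m + half), n = n)
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y Paired vectors (>= 3 pairs, nonzero variance).
#' @return List with `r`, `p`, `n`, `undefined` flag (zero variance).
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need >= 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(x), undefined = TRUE))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       undefined = FALSE)
}

#' @keywords internal
default_ffr_bins <- function() {
  data.frame(label = c("<0.66", "0.66-0.70", "0.71-0.75", "0.76-0.80",
                       "0.81-0.85", "0.86-0.90", ">0.90"),
             lo = c(-Inf, 0.655, 0.705, 0.755, 0.805, 0.855, 0.905),
             hi = c(0.655, 0.705, 0.755, 0.805, 0.855, 0.905, Inf),
             stringsAsFactors = FALSE)
}

#' Diagnostic accuracy of CT-FFR per invasive-FFR bin
#'
#' Per-bin fraction of vessels where the CT-FFR classification (at or below
#' the index threshold) agrees with the FFR classification (below the
#' ischemia threshold).  Default bins follow the printed two-decimal
#' convention <0.66, 0.66-0.70, ..., >0.90 (a value belongs to the bin its
#' two-decimal rounding falls in).
#'
#' @param cohort Data.frame with `measured_ffr` and `ct_ffr` columns.
#' @param policy A [threshold_policy()].
#' @param bins Data.frame with `label`, `lo`, `hi` (bin is `(lo, hi]`).
#' @return Data.frame of `bin`, `n`, `accuracy_pct` (`NA` for empty bins).
#' @export
accuracy_by_ffr_bin <- function(cohort, policy = threshold_policy(),
                                bins = default_ffr_bins()) {
  agree <- (cohort$ct_ffr <= policy$index_threshold) ==
           (cohort$measured_ffr < policy$ischemia_threshold)
  rows <- lapply(seq_len(nrow(bins)), function(i) {
    sel <- cohort$measured_ffr > bins$lo[i] & cohort$measured_ffr <= bins$hi[i]
    n <- sum(sel)
    data.frame(bin = bins$label[i], n = n,
               accuracy_pct = if (n) round_half_up(100 * mean(agree[sel]), 1)
                              else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @keywords internal
ffr_stratum <- function(measured_ffr, policy) {
  gz <- policy$gray_zone
  ifelse(measured_ffr < gz[1], "FFR<0.76",
         ifelse(measured_ffr <= gz[2], "gray zone", "FFR>0.8"))
}

#' Misdiagnosis rates by FFR stratum
#'
#' Strata below / inside / above the gray zone.  In the two ischemic strata
#' (gray zone counted ischemic) the false-negative rate is the fraction with
#' CT-FFR above the index threshold; in the non-ischemic stratum the
#' false-positive rate is the fraction at or below it.  Stratum accuracy is
#' the complement.
#'
#' @inheritParams accuracy_by_ffr_bin
#' @return Data.frame of `stratum`, `n`, `misdiagnosed`, `rate_pct`,
#'   `accuracy_pct`, `error_type`.
#' @export
misdiagnosis_rates <- function(cohort, policy = threshold_policy()) {
  strat <- ffr_stratum(cohort$measured_ffr, policy)
  pos <- cohort$ct_ffr <= policy$index_threshold
  levels <- c("FFR<0.76", "gray zone", "FFR>0.8")
  rows <- lapply(levels, function(s) {
    sel <- strat == s
    n <- sum(sel)
    miss <- if (s == "FFR>0.8") sum(pos[sel]) else sum(!pos[sel])
    data.frame(stratum = s, n = n, misdiagnosed = miss,
               rate_pct = if (n) round_half_up(100 * miss / n, 1) else NA_real_,
               accuracy_pct = if (n) round_half_up(100 * (1 - miss / n), 1)
                              else NA_real_,
               error_type = if (s == "FFR>0.8") "FP" else "FN",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-group comparison, continuous or categorical
#'
#' Continuous data: Mann-Whitney U with normal approximation (tie-corrected,
#' no continuity correction) plus per-group median and IQR.  Categorical
#' data: chi-square test, switching to Fisher's exact test whenever an
#' expected cell is below 5.
#'
#' @param values Numeric (continuous) or logical/factor (categorical) vector.
#' @param group Two-level grouping vector, same length.
#' @param kind `"continuous"` or `"categorical"`.
#' @return List with `p`, and for continuous data `U` plus a `groups`
#'   summary data.frame, or for categorical data the `table` and the `test`
#'   used.
#' @export
group_compare <- function(values, group, kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  group <- as.factor(as.character(group))
  if (nlevels(group) != 2 || any(table(group) == 0))
    stop("`group` must define two nonempty groups", call. = FALSE)
  g1 <- levels(group)[1]; g2 <- levels(group)[2]
  if (kind == "continuous") {
    x <- values[group == g1]; y <- values[group == g2]
    wt <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
    qs <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    q1 <- qs(x); q2 <- qs(y)
    list(U = unname(wt$statistic), p = wt$p.value,
         groups = data.frame(group = c(g1, g2), n = c(length(x), length(y)),
                             median = c(q1[2], q2[2]),
                             iqr_low = c(q1[1], q2[1]),
                             iqr_high = c(q1[3], q2[3]),
                             stringsAsFactors = FALSE))
  } else {
    tab <- table(factor(values), group)
    if (nrow(tab) < 2)
      stop("categorical values are constant; nothing to compare", call. = FALSE)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      ft <- stats::fisher.test(tab)
      list(p = ft$p.value, test = "fisher", table = tab)
    } else {
      ct <- stats::chisq.test(tab, correct = FALSE)
      list(p = ct$p.value, statistic = unname(ct$statistic),
           test = "chi-square", table = tab)
    }
  }
}

#' Univariate logistic regression odds ratio
#'
#' Single-covariate logistic fit (IRLS via `glm`); odds ratio per unit of
#' the covariate with Wald CI and p-value.  Complete separation or a
#' constant covariate is flagged non-estimable rather than silently
#' diverging.
#'
#' @param covariate Numeric (or logical) per-vessel covariate.
#' @param outcome Logical misdiagnosis flags; both classes required.
#' @param conf Confidence level.
#' @return List with `or`, `ci`, `p`, `slope`, `estimable`.
#' @export
univariate_logistic_or <- function(covariate, outcome, conf = 0.95) {
  outcome <- as.logical(outcome)
  if (length(unique(outcome)) < 2)
    stop("outcome must contain both classes", call. = FALSE)
  covariate <- as.numeric(covariate)
  not_estimable <- list(or = NA_real_, ci = c(NA_real_, NA_real_),
                        p = NA_real_, slope = NA_real_, estimable = FALSE)
  if (stats::sd(covariate) == 0) return(not_estimable)
  fit <- suppressWarnings(
    stats::glm(outcome ~ covariate, family = stats::binomial()))
  sm <- summary(fit)$coefficients
  slope <- sm["covariate", "Estimate"]
  se <- sm["covariate", "Std. Error"]
  # complete separation drives the slope to the iteration cap with an
  # exploding Wald SE; flag instead of reporting a divergent estimate
  if (!fit$converged || abs(slope) > 15 || se > 50) return(not_estimable)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(or = exp(slope), ci = exp(slope + c(-z, z) * se),
       p = sm["covariate", "Pr(>|z|)"], slope = slope, estimable = TRUE)
}

#' Paired comparison of two classifiers on one metric
#'
#' Exact McNemar test on the discordant pairs within the relevant truth
#' stratum: ischemic vessels for sensitivity, non-ischemic for specificity
#' (two-sided exact binomial at 1/2).
#'
#' @param ischemic Logical reference flags.
#' @param positive_a,positive_b Positivity flags of the two classifiers on
#'   the same vessels.
#' @param on `"sensitivity"` or `"specificity"`.
#' @return List with `p`, `discordant` (counts `c(a_only, b_only)`), `n`.
#' @export
paired_metric_compare <- function(ischemic, positive_a, positive_b,
                                  on = c("sensitivity", "specificity")) {
  on <- match.arg(on)
  ischemic <- as.logical(ischemic)
  sel <- if (on == "sensitivity") ischemic else !ischemic
  a <- as.logical(positive_a)[sel]
  b <- as.logical(positive_b)[sel]
  if (on == "specificity") { a <- !a; b <- !b }  # correctness flags
  n_a <- sum(a & !b)
  n_b <- sum(!a & b)
  p <- if (n_a + n_b == 0) 1
       else stats::binom.test(n_a, n_a + n_b, 0.5)$p.value
  list(p = p, discordant = c(a_only = n_a, b_only = n_b), n = sum(sel))
}

#' Full trial evaluation of a cohort table
#'
#' Assembles the complete diagnostic-performance analysis: CT-FFR and CTA
#' confusion matrices and metric tables, AUCs, Pearson correlation,
#' Bland-Altman agreement (overall and per FFR stratum), per-FFR-bin
#' accuracy, stratified misdiagnosis rates, paired McNemar comparisons, and
#' univariate logistic screening of plaque covariates against misdiagnosis
#' within each stratum.  No multiple-testing adjustment is applied (noted in
#' the output).
#'
#' @param cohort Data.frame with columns `measured_ffr`, `ct_ffr`,
#'   `cta_percent_stenosis` and (optionally) the plaque covariates.
#' @param policy A [threshold_policy()].
#' @return A list of class `trial_evaluation`.
#' @export
evaluate_cohort <- function(cohort, policy = threshold_policy()) {
  need <- c("measured_ffr", "ct_ffr", "cta_percent_stenosis")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop(sprintf("cohort is missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  ok <- stats::complete.cases(cohort[need])
  cohort <- cohort[ok, , drop = FALSE]
  ischemic <- cohort$measured_ffr < policy$ischemia_threshold
  pos_ct <- cohort$ct_ffr <= policy$index_threshold
  pos_cta <- cohort$cta_percent_stenosis >= policy$cta_threshold
  cm_ct <- confusion_matrix(pos_ct, ischemic)
  cm_cta <- confusion_matrix(pos_cta, ischemic)
  strat <- ffr_stratum(cohort$measured_ffr, policy)

  ba_stratum <- lapply(split(seq_len(nrow(cohort)), strat), function(idx)
    if (length(idx) >= 2)
      bland_altman(cohort$ct_ffr[idx], cohort$measured_ffr[idx]) else NULL)

  covs <- intersect(c("calcium_score", "plaque_burden", "calcified_volume",
                      "lesion_length", "lumen_area", "lumen_diameter"),
                    names(cohort))
  or_screen <- list()
  for (s in unique(strat)) {
    sel <- strat == s
    miss_flag <- if (s == "FFR>0.8") pos_ct[sel] else !pos_ct[sel]
    if (length(unique(miss_flag)) < 2) next
    or_screen[[s]] <- do.call(rbind, lapply(covs, function(cv) {
      res <- univariate_logistic_or(cohort[[cv]][sel], miss_flag)
      data.frame(stratum = s, covariate = cv, or = res$or,
                 ci_low = res$ci[1], ci_high = res$ci[2], p = res$p,
                 estimable = res$estimable, stringsAsFactors = FALSE)
    }))
  }

  structure(list(
    n_vessels = nrow(cohort),
    confusion = list(ct_ffr = cm_ct, cta = cm_cta),
    metrics = list(ct_ffr = diagnostic_metrics(cm_ct),
                   cta = diagnostic_metrics(cm_cta)),
    auc = list(ct_ffr = auc_mann_whitney(cohort$ct_ffr, ischemic),
               cta = auc_mann_whitney(-cohort$cta_percent_stenosis, ischemic)),
    pearson = pearson_r(cohort$ct_ffr, cohort$measured_ffr),
    bland_altman = c(list(all = bland_altman(cohort$ct_ffr, cohort$measured_ffr)),
                     ba_stratum),
    bin_accuracy = accuracy_by_ffr_bin(cohort, policy),
    misdiagnosis = misdiagnosis_rates(cohort, policy),
    mcnemar = list(
      sensitivity = paired_metric_compare(ischemic, pos_cta, pos_ct, "sensitivity"),
      specificity = paired_metric_compare(ischemic, pos_cta, pos_ct, "specificity")),
    or_screen = if (length(or_screen)) do.call(rbind, unname(or_screen)) else NULL,
    policy = policy,
    note = "p-values are unadjusted for multiple testing"),
    class = "trial_evaluation")
}

#' @export
print.trial_evaluation <- function(x, ...) {
  cat(sprintf("Trial evaluation: %d vessels\n", x$n_vessels))
  cat("\nCT-FFR diagnostic metrics (%):\n")
  print(x$metrics$ct_ffr[c("metric", "value_pct", "ci_low_pct", "ci_high_pct")],
        digits = 3)
  cat("\nCTA diagnostic metrics (%):\n")
  print(x$metrics$cta[c("metric", "value_pct", "ci_low_pct", "ci_high_pct")],
        digits = 3)
  cat(sprintf("\nAUC: CT-FFR %.3f [%.3f, %.3f], CTA %.3f [%.3f, %.3f]\n",
              x$auc$ct_ffr$auc, x$auc$ct_ffr$ci[1], x$auc$ct_ffr$ci[2],
              x$auc$cta$auc, x$auc$cta$ci[1], x$auc$cta$ci[2]))
  cat(sprintf("Pearson r (CT-FFR vs FFR): %.3f\n", x$pearson$r))
  cat("\nAccuracy by FFR bin (%):\n")
  print(x$bin_accuracy)
  cat("\nMisdiagnosis by stratum:\n")
  print(x$misdiagnosis)
  cat(sprintf("\n(%s)\n", x$note))
  invisible(x)
}
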