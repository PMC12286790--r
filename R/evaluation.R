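#' ROC analysis with DeLong confidence interval and Youden threshold
#'
#' Computes the area under the ROC curve by the midrank (Mann-Whitney)
#' formula, the full ROC curve enumerated at every unique score, a 95%
#' DeLong confidence interval, and the operating threshold maximising the
#' Youden index J = sensitivity + specificity - 1. Scores greater than or
#' equal to the threshold are called positive.
#'
#' @param scores Numeric vector of continuous scores (higher = more
#'   positive).
#' @param labels Binary vector (0/1, logical, or 2-level factor); 1 is the
#'   positive class.
#' @return An object of class `roc_result` with elements `auc`, `auc_ci95`,
#'   `z` and `p` (DeLong test of AUC = 0.5), `threshold_star`, `youden`,
#'   and `curve` (data.frame of threshold, fpr, tpr).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  if (anyNA(scores) || anyNA(labels)) stop("NA in scores or labels")
  m <- sum(labels == 1); n <- sum(labels == 0)
  if (m == 0 || n == 0) stop("both classes must be present for ROC analysis")
  r <- rank(scores)           # midranks handle ties
  auc <- (sum(r[labels == 1]) - m * (m + 1) / 2) / (m * n)

  thr <- sort(unique(scores), decreasing = TRUE)
  thr <- c(Inf, thr)          # empty-positive operating point first
  tp <- vapply(thr, function(t) sum(scores >= t & labels == 1), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & labels == 0), numeric(1))
  curve <- data.frame(threshold = thr, fpr = fp / n, tpr = tp / m)

  v <- delong_components(scores, labels)
  se <- if (m >= 2 && n >= 2) {
    sqrt(stats::var(v$v10) / m + stats::var(v$v01) / n)
  } else NA_real_
  zstat <- if (isTRUE(se > 0)) (auc - 0.5) / se
           else if (isTRUE(se == 0)) Inf else NA_real_
  ci <- if (is.na(se)) c(NA_real_, NA_real_)
        else pmin(pmax(auc + c(-1, 1) * 1.96 * se, 0), 1)

  yt <- youden_threshold(curve)
  structure(list(auc = auc, auc_ci95 = ci, se = se, z = zstat,
                 p = if (is.na(zstat)) NA_real_
                     else 2 * stats::pnorm(-abs(zstat)),
                 threshold_star = yt$threshold, youden = yt$J,
                 curve = curve, n_pos = m, n_neg = n),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f (95%% CI %.3f-%.3f), threshold* %.4g, J %.3f\n",
              x$auc, x$auc_ci95[1], x$auc_ci95[2], x$threshold_star,
              x$youden))
  invisible(x)
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  labels
}

#' Youden-optimal threshold from an ROC curve
#'
#' Scans every operating point and returns the threshold maximising
#' J = tpr - fpr. Ties are broken toward the lowest threshold (the more
#' sensitive operating point).
#'
#' @param curve data.frame with columns `threshold`, `fpr`, `tpr` as
#'   produced by [roc_auc()].
#' @return List with `threshold` and `J`.
#' @export
youden_threshold <- function(curve) {
  if (!NROW(curve)) stop("empty ROC curve")
  j <- curve$tpr - curve$fpr
  best <- which(j >= max(j) - 1e-12)
  pick <- best[which.min(curve$threshold[best])]
  list(threshold = curve$threshold[pick], J = j[pick])
}

#' Confusion metrics from integer counts
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return A `confusion_metrics` list: counts plus sensitivity, specificity,
#'   accuracy, npv, ppv, precision, recall, youden, f1. The identities
#'   `youden = sensitivity + specificity - 1`, `precision = ppv` and
#'   `recall = sensitivity` hold by construction and are asserted.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  acc <- (tp + tn) / sum(counts)
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  f1 <- if (isTRUE(2 * tp + fp + fn > 0)) 2 * tp / (2 * tp + fp + fn)
        else NA_real_
  out <- list(counts = counts, sensitivity = sens, specificity = spec,
              accuracy = acc, npv = npv, ppv = ppv, precision = ppv,
              recall = sens, youden = sens + spec - 1, f1 = f1)
  stopifnot(identical(out$precision, out$ppv),
            identical(out$recall, out$sensitivity),
            abs(out$youden - (sens + spec - 1)) < 1e-12)
  class(out) <- "confusion_metrics"
  out
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf(paste0("confusion: TP %d FP %d TN %d FN %d | sens %.3f spec ",
                     "%.3f acc %.3f ppv %.3f npv %.3f J %.3f\n"),
              x$counts["tp"], x$counts["fp"], x$counts["tn"], x$counts["fn"],
              x$sensitivity, x$specificity, x$accuracy, x$ppv, x$npv,
              x$youden))
  invisible(x)
}

#' Reconstruct confusion metrics from a printed operating point
#'
#' Published reports usually print sensitivity and specificity at an
#' operating threshold together with the cohort split. Because the
#' underlying confusion matrix holds integer counts, the remaining metrics
#' are fully determined: TP = round(sens * n_pos), TN = round(spec * n_neg),
#' complements for FP/FN, and every derived metric recomputed from counts.
#'
#' @param sens,spec Fractions in \[0, 1\].
#' @param n_pos,n_neg Class sizes (positive integers).
#' @return A `confusion_metrics` object.
#' @export
confusion_from_operating_point <- function(sens, spec, n_pos, n_neg) {
  stopifnot(sens >= 0, sens <= 1, spec >= 0, spec <= 1,
            n_pos >= 1, n_neg >= 1)
  tp <- round(sens * n_pos)
  tn <- round(spec * n_neg)
  confusion_metrics(tp = tp, fp = n_neg - tn, tn = tn, fn = n_pos - tp)
}

# DeLong structural components: v10[i] = mean_j psi(x_i, y_j) over negatives,
# v01[j] = mean_i psi(x_i, y_j) over positives; psi = 1, 1/2, 0 for >, =, <.
delong_components <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  x <- scores[labels == 1]; y <- scores[labels == 0]
  m <- length(x); n <- length(y)
  # midrank trick: psi sums follow from ranks within the pooled vector
  r_all <- rank(c(x, y))
  r_x <- rank(x); r_y <- rank(y)
  v10 <- (r_all[seq_len(m)] - r_x) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_y) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong test for two correlated AUCs
#'
#' Nonparametric comparison of two ROC curves built from paired scores on
#' the same patients, via the structural-components covariance estimate.
#'
#' @param scores1,scores2 Paired numeric score vectors.
#' @param labels Shared binary labels.
#' @param conf_level Confidence level for the difference CI.
#' @return A `delong_comparison` list: `auc1`, `auc2`, `diff`, `ci`, `z`,
#'   `p`. Swapping the two models negates `diff` and `z` and leaves `p`
#'   unchanged.
#' @export
delong_test <- function(scores1, scores2, labels, conf_level = 0.95) {
  if (length(scores1) != length(scores2)) {
    stop("scores1 and scores2 must be paired (equal length)")
  }
  labels <- as_binary_labels(labels)
  m <- sum(labels == 1); n <- sum(labels == 0)
  if (m == 0 || n == 0) stop("both classes must be present")
  c1 <- delong_components(scores1, labels)
  c2 <- delong_components(scores2, labels)
  s10 <- stats::cov(cbind(c1$v10, c2$v10))
  s01 <- stats::cov(cbind(c1$v01, c2$v01))
  s <- s10 / m + s01 / n
  d <- c1$auc - c2$auc
  var_d <- s[1, 1] + s[2, 2] - 2 * s[1, 2]
  se <- sqrt(max(var_d, 0))
  z <- if (se > 0) d / se else 0
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(auc1 = c1$auc, auc2 = c2$auc, diff = d,
                 ci = c(d - q * se, d + q * se), se = se, z = z,
                 p = if (se > 0) 2 * stats::pnorm(-abs(z)) else 1),
            class = "delong_comparison")
}

#' @export
print.delong_comparison <- function(x, ...) {
  cat(sprintf("DeLong: AUC %.3f vs %.3f, diff %.3f (%.3f, %.3f), z %.2f, p %.3g\n",
              x$auc1, x$auc2, x$diff, x$ci[1], x$ci[2], x$z, x$p))
  invisible(x)
}

#' Two-rater reliability: ICC(2,1) and Bland-Altman
#'
#' Intraclass correlation under a two-way random-effects model, absolute
#' agreement, single measurement (ICC(A,1) in McGraw-Wong notation), with
#' an F-based 95% confidence interval, plus Bland-Altman bias and limits
#' of agreement (bias +/- 1.96 SD of paired differences).
#'
#' @param x1,x2 Paired measurement vectors (one per rater), n >= 3.
#' @return A `reliability_report` list with `icc`, `icc_ci95`,
#'   `bland_altman` (bias, loa_lower, loa_upper), and the ANOVA mean
#'   squares.
#' @export
icc_two_rater <- function(x1, x2) {
  if (length(x1) != length(x2)) stop("paired vectors required")
  n <- length(x1)
  if (n < 3) stop("need at least 3 paired measurements")
  mat <- cbind(x1, x2)
  if (stats::var(as.numeric(mat)) == 0) {
    stop("zero total variance: ICC undefined")
  }
  k <- 2
  g <- mean(mat)
  row_m <- rowMeans(mat); col_m <- colMeans(mat)
  ssr <- k * sum((row_m - g)^2)
  ssc <- n * sum((col_m - g)^2)
  sst <- sum((mat - g)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  # McGraw & Wong (1996) CI for ICC(A,1)
  alpha <- 0.05
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f1 <- stats::qf(1 - alpha / 2, n - 1, v)
  f2 <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (msr - f1 * mse) /
    (f1 * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (f2 * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f2 * msr)

  d <- x1 - x2
  bias <- mean(d); sd_d <- stats::sd(d)
  structure(list(icc = icc, icc_ci95 = c(lo, hi),
                 bland_altman = list(bias = bias,
                                     loa_lower = bias - 1.96 * sd_d,
                                     loa_upper = bias + 1.96 * sd_d),
                 ms = c(msr = msr, msc = msc, mse = mse), n = n),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("ICC(2,1) %.3f (95%% CI %.3f-%.3f); Bland-Altman bias %.4g, LoA [%.4g, %.4g]\n",
              x$icc, x$icc_ci95[1], x$icc_ci95[2], x$bland_altman$bias,
              x$bland_altman$loa_lower, x$bland_altman$loa_upper))
  invisible(x)
}

#' Group comparison table (baseline-characteristics style)
#'
#' Continuous variables are summarised as median (IQR) per group and
#' compared with the Mann-Whitney U test (exact when both groups have
#' <= 8 observations and no ties, normal approximation with tie and
#' continuity correction otherwise). Categorical variables (factor,
#' logical, or integer-coded with <= 4 distinct values) are summarised as
#' counts (%) and compared with the chi-square test.
#'
#' @param table data.frame of covariates (one row per patient).
#' @param labels Binary group labels.
#' @param chisq_correct Apply Yates continuity correction (default FALSE).
#' @return data.frame with one row per variable: summaries per group, test
#'   name and p value.
#' @export
group_tests <- function(table, labels, chisq_correct = FALSE) {
  labels <- as_binary_labels(labels)
  if (NROW(table) != length(labels)) stop("table/labels mismatch")
  rows <- lapply(names(table), function(v) {
    x <- table[[v]]
    is_cat <- is.factor(x) || is.logical(x) ||
      (length(unique(x[!is.na(x)])) <= 4 && all(x == round(x), na.rm = TRUE))
    if (is_cat) {
      x <- factor(x)
      tab <- base::table(x, labels)
      p <- tryCatch(
        suppressWarnings(
          stats::chisq.test(tab, correct = chisq_correct)$p.value),
        error = function(e) NA_real_)
      summ0 <- paste(sprintf("%s:%d (%.1f%%)", rownames(tab), tab[, "0"],
                             100 * tab[, "0"] / sum(tab[, "0"])),
                     collapse = "; ")
      summ1 <- paste(sprintf("%s:%d (%.1f%%)", rownames(tab), tab[, "1"],
                             100 * tab[, "1"] / sum(tab[, "1"])),
                     collapse = "; ")
      data.frame(variable = v, type = "categorical", group0 = summ0,
                 group1 = summ1, test = "chi-square", p = p,
                 stringsAsFactors = FALSE)
    } else {
      x0 <- x[labels == 0]; x1 <- x[labels == 1]
      use_exact <- length(x0) <= 8 && length(x1) <= 8 &&
        !any(duplicated(c(x0, x1)))
      p <- suppressWarnings(
        stats::wilcox.test(x1, x0, exact = use_exact,
                           correct = TRUE)$p.value)
      fmt <- function(z) sprintf("%.2f (%.2f, %.2f)", stats::median(z),
                                 stats::quantile(z, 0.25),
                                 stats::quantile(z, 0.75))
      data.frame(variable = v, type = "continuous", group0 = fmt(x0),
                 group1 = fmt(x1), test = "Mann-Whitney U", p = p,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
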