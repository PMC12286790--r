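#' Stratified fold assignment
#'
#' Assigns every patient to exactly one fold, balancing the class split
#' across folds. The assignment is a pure function of (ids, labels, seed):
#' patients are ordered by `ids` (or by position when absent) within each
#' class, shuffled with the seeded RNG, and dealt out cyclically.
#'
#' @param labels Binary labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @param ids Optional patient identifiers for order-invariance.
#' @return Integer fold id (1..k) per patient.
#' @export
stratified_folds <- function(labels, k, seed = 1L, ids = NULL) {
  labels <- as_binary_labels(labels)
  n <- length(labels)
  if (min(table(labels)) < k) {
    stop("need at least ", k, " patients per class for ", k, " folds")
  }
  ord <- if (is.null(ids)) seq_len(n) else order(ids)
  fold <- integer(n)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  for (cls in c(0L, 1L)) {
    idx <- ord[labels[ord] == cls]
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Model specification
#'
#' The three models of interest: `clinical_radiological` (CA125 + tumor
#' size), `aptw_h3` (the radiomic score alone), and `combined` (all
#' three).
#'
#' @param name One of "clinical_radiological", "aptw_h3", "combined".
#' @param predictors Character vector of column names; defaults follow the
#'   model name with columns `ca125`, `tumor_size`, `aptw_h3`.
#' @return A `model_spec` list.
#' @export
model_spec <- function(name = c("clinical_radiological", "aptw_h3",
                                "combined"),
                       predictors = NULL) {
  name <- match.arg(name)
  if (is.null(predictors)) {
    predictors <- switch(name,
                         clinical_radiological = c("ca125", "tumor_size"),
                         aptw_h3 = "aptw_h3",
                         combined = c("ca125", "tumor_size", "aptw_h3"))
  }
  structure(list(name = name, predictors = predictors),
            class = "model_spec")
}

# Ridge-logistic fit with inner-CV-tuned penalty; returns a predict
# function for new rows. Predictors are z-scored on the training rows.
fit_tuned_logistic <- function(x, y, inner_folds = 5L, seed = 1L,
                               lambda_grid = c(1e-4, 1e-3, 1e-2, 1e-1, 1)) {
  x <- as.matrix(x)
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0] <- 1
  xz <- sweep(sweep(x, 2, center), 2, scale, "/")
  inner_folds <- max(2L, min(inner_folds, min(table(y))))
  foldid <- stratified_folds(y, inner_folds, seed)
  if (ncol(xz) == 1) xz2 <- cbind(xz, 0) else xz2 <- xz  # glmnet needs p>=2
  cv <- glmnet::cv.glmnet(xz2, y, family = "binomial", alpha = 0,
                          lambda = sort(lambda_grid, decreasing = TRUE),
                          foldid = foldid, standardize = FALSE,
                          type.measure = "deviance")
  fit <- glmnet::glmnet(xz2, y, family = "binomial", alpha = 0,
                        lambda = cv$lambda.min, standardize = FALSE)
  list(lambda = cv$lambda.min,
       coefficients = as.matrix(stats::coef(fit))[, 1],
       predict = function(newx) {
         nz <- sweep(sweep(as.matrix(newx), 2, center), 2, scale, "/")
         if (ncol(nz) == 1) nz <- cbind(nz, 0)
         as.numeric(stats::predict(fit, nz, type = "response"))
       })
}

#' Stratified k-fold cross-validation of a logistic model
#'
#' Outer stratified folds; within each outer training fold an inner
#' stratified CV tunes the L2 penalty of a logistic model over a small
#' grid (including an effectively-unpenalised value); scaling is fit on
#' the outer-training rows only. Out-of-fold probabilities are pooled so
#' every patient is predicted exactly once.
#'
#' @param spec A [model_spec()].
#' @param cohort_table data.frame containing the predictor columns.
#' @param labels Binary labels.
#' @param folds Outer folds (default 5).
#' @param seed Integer seed.
#' @param ids Optional patient ids (fold assignment order-invariance).
#' @return A `cv_result`: `per_fold` (data.frame of fold, auc, accuracy,
#'   f1), `mean_auc`, `mean_accuracy`, `mean_f1`, `oof_prob` (pooled
#'   out-of-fold probabilities in input row order), `fold` assignment,
#'   `pooled_roc` (ROC of pooled OOF predictions).
#' @export
fit_cv <- function(spec, cohort_table, labels, folds = 5L, seed = 1L,
                   ids = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  labels <- as_binary_labels(labels)
  miss <- setdiff(spec$predictors, names(cohort_table))
  if (length(miss)) stop("missing predictors: ", paste(miss, collapse = ", "))
  x <- as.matrix(cohort_table[, spec$predictors, drop = FALSE])
  fold <- stratified_folds(labels, folds, seed, ids)
  oof <- rep(NA_real_, length(labels))
  per_fold <- data.frame(fold = seq_len(folds), auc = NA_real_,
                         accuracy = NA_real_, f1 = NA_real_)
  for (f in seq_len(folds)) {
    tr <- fold != f; va <- fold == f
    if (length(unique(labels[tr])) < 2 || length(unique(labels[va])) < 2) {
      stop("degenerate fold encountered; too few patients per class")
    }
    fit <- fit_tuned_logistic(x[tr, , drop = FALSE], labels[tr],
                              seed = seed + f)
    pv <- fit$predict(x[va, , drop = FALSE])
    oof[va] <- pv
    pred <- as.integer(pv >= 0.5)
    tp <- sum(pred == 1 & labels[va] == 1)
    fp <- sum(pred == 1 & labels[va] == 0)
    fn <- sum(pred == 0 & labels[va] == 1)
    per_fold$auc[f] <- roc_auc(pv, labels[va])$auc
    per_fold$accuracy[f] <- mean(pred == labels[va])
    per_fold$f1[f] <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn)
                      else NA_real_
  }
  structure(list(spec = spec, per_fold = per_fold,
                 mean_auc = mean(per_fold$auc),
                 mean_accuracy = mean(per_fold$accuracy),
                 mean_f1 = mean(per_fold$f1, na.rm = TRUE),
                 oof_prob = oof, fold = fold,
                 pooled_roc = roc_auc(oof, labels)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("CV [%s]: mean AUC %.3f, accuracy %.3f, F1 %.3f; pooled-OOF AUC %.3f\n",
              x$spec$name, x$mean_auc, x$mean_accuracy, x$mean_f1,
              x$pooled_roc$auc))
  invisible(x)
}

#' Univariable and multivariable logistic association analysis
#'
#' Each candidate variable is fit alone against the outcome by maximum
#' likelihood; variables with univariable Wald p < `p_enter` then enter a
#' single multivariable model. Odds ratios are exponentiated coefficients
#' with Wald 95% confidence intervals.
#'
#' @param table data.frame of covariates.
#' @param labels Binary outcome.
#' @param variables Columns to analyse (default: all).
#' @param p_enter Threshold for entering the multivariable model.
#' @return An `association_report`: `univariable` and `multivariable`
#'   data.frames (variable, or, ci_lo, ci_hi, p, converged).
#' @export
association_analysis <- function(table, labels, variables = names(table),
                                 p_enter = 0.05) {
  labels <- as_binary_labels(labels)
  uni <- lapply(variables, function(v) {
    d <- data.frame(y = labels, x = as.numeric(table[[v]]))
    fit <- suppressWarnings(stats::glm(y ~ x, data = d, family = stats::binomial()))
    s <- summary(fit)$coefficients
    ok <- fit$converged && "x" %in% rownames(s)
    if (ok) {
      b <- s["x", "Estimate"]; se <- s["x", "Std. Error"]
      data.frame(variable = v, or = exp(b), ci_lo = exp(b - 1.96 * se),
                 ci_hi = exp(b + 1.96 * se), p = s["x", "Pr(>|z|)"],
                 converged = TRUE, stringsAsFactors = FALSE)
    } else {
      data.frame(variable = v, or = NA_real_, ci_lo = NA_real_,
                 ci_hi = NA_real_, p = NA_real_, converged = FALSE,
                 stringsAsFactors = FALSE)
    }
  })
  uni <- do.call(rbind, uni)
  sig <- uni$variable[!is.na(uni$p) & uni$p < p_enter]
  multi <- NULL
  if (length(sig)) {
    d <- data.frame(y = labels, table[, sig, drop = FALSE])
    fit <- suppressWarnings(stats::glm(y ~ ., data = d, family = stats::binomial()))
    s <- summary(fit)$coefficients
    rows <- intersect(rownames(s), make.names(sig))
    multi <- data.frame(variable = sig,
                        or = exp(s[rows, "Estimate"]),
                        ci_lo = exp(s[rows, "Estimate"] -
                                      1.96 * s[rows, "Std. Error"]),
                        ci_hi = exp(s[rows, "Estimate"] +
                                      1.96 * s[rows, "Std. Error"]),
                        p = s[rows, "Pr(>|z|)"],
                        converged = fit$converged,
                        stringsAsFactors = FALSE, row.names = NULL)
  }
  structure(list(univariable = uni, multivariable = multi,
                 entered = sig),
            class = "association_report")
}

#' @export
print.association_report <- function(x, ...) {
  cat("univariable:\n")
  print(x$univariable, digits = 3)
  if (!is.null(x$multivariable)) {
    cat("multivariable (", paste(x$entered, collapse = ", "), "):\n",
        sep = "")
    print(x$multivariable, digits = 3)
  }
  invisible(x)
}
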