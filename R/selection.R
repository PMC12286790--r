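#' Selection-cascade configuration
#'
#' @param icc_min Minimum two-rater ICC to retain a feature (default 0.85).
#' @param p_max Welch t-test significance threshold (default 0.05).
#' @param corr_max Pearson correlation pruning threshold (default 0.9).
#' @param mrmr_k Number of features kept by mRMR pre-selection (default 30).
#' @param lasso_folds Cross-validation folds for the LASSO (default 10).
#' @param seed Integer seed (drives CV fold assignment).
#' @return A `selection_config` list.
#' @export
selection_config <- function(icc_min = 0.85, p_max = 0.05, corr_max = 0.9,
                             mrmr_k = 30L, lasso_folds = 10L, seed = 1L) {
  stopifnot(icc_min > 0, icc_min <= 1, p_max > 0, p_max < 1,
            lasso_folds >= 2)
  structure(list(icc_min = icc_min, p_max = p_max, corr_max = corr_max,
                 mrmr_k = as.integer(mrmr_k),
                 lasso_folds = as.integer(lasso_folds),
                 seed = as.integer(seed)),
            class = "selection_config")
}

feature_matrix <- function(table) {
  if (inherits(table, "data.frame")) {
    num <- table[, setdiff(names(table), "patient_id"), drop = FALSE]
    as.matrix(num)
  } else as.matrix(table)
}

# Vectorised ICC(2,1) for two rater matrices with identical columns.
icc_columns <- function(m1, m2) {
  n <- nrow(m1); k <- 2
  g <- (colMeans(m1) + colMeans(m2)) / 2
  rm_ <- (m1 + m2) / 2
  ssr <- k * colSums(sweep(rm_, 2, g)^2)
  ssc <- n * ((colMeans(m1) - g)^2 + (colMeans(m2) - g)^2)
  sst <- colSums(sweep(m1, 2, g)^2) + colSums(sweep(m2, 2, g)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc; mse <- sse / (n - 1)
  (msr - mse) / (msr + mse + k * (msc - mse) / n)
}

#' ICC reliability filter
#'
#' Keeps features whose two-rater ICC (two-way random effects, absolute
#' agreement, single measurement) meets `icc_min`. Features with zero
#' variance across both raters have an undefined ICC and are dropped with
#' a warning.
#'
#' @param table_reader1,table_reader2 Feature tables (same rows/columns)
#'   from two independent segmentations/readers.
#' @param icc_min ICC threshold (default 0.85).
#' @return List with `kept` (column names), `icc` (named vector),
#'   `dropped_degenerate`.
#' @export
icc_filter <- function(table_reader1, table_reader2, icc_min = 0.85) {
  m1 <- feature_matrix(table_reader1)
  m2 <- feature_matrix(table_reader2)
  if (!identical(dim(m1), dim(m2)) ||
      !identical(colnames(m1), colnames(m2))) {
    stop("reader tables must have identical rows and columns")
  }
  tot_var <- apply(rbind(m1, m2), 2, stats::var)
  degen <- tot_var == 0 | !is.finite(tot_var)
  if (any(degen)) {
    warning(sum(degen), " zero-variance feature(s) dropped (ICC undefined)")
  }
  icc <- rep(NA_real_, ncol(m1))
  icc[!degen] <- icc_columns(m1[, !degen, drop = FALSE],
                             m2[, !degen, drop = FALSE])
  names(icc) <- colnames(m1)
  kept <- colnames(m1)[!degen & icc >= icc_min]
  list(kept = kept, icc = icc, dropped_degenerate = colnames(m1)[degen])
}

# Vectorised Welch t-test per column; returns t, df, p.
welch_columns <- function(m, labels) {
  labels <- as_binary_labels(labels)
  m1 <- m[labels == 1, , drop = FALSE]
  m0 <- m[labels == 0, , drop = FALSE]
  n1 <- nrow(m1); n0 <- nrow(m0)
  if (n1 < 2 || n0 < 2) stop("each class needs at least 2 members")
  v1 <- apply(m1, 2, stats::var) / n1
  v0 <- apply(m0, 2, stats::var) / n0
  t <- (colMeans(m1) - colMeans(m0)) / sqrt(v1 + v0)
  df <- (v1 + v0)^2 / (v1^2 / (n1 - 1) + v0^2 / (n0 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  p[!is.finite(t)] <- 1        # zero-variance degenerate columns
  list(t = t, df = df, p = p)
}

#' Welch t-test relevance filter
#'
#' @param table Feature table.
#' @param labels Binary labels.
#' @param p_max Keep features with p < `p_max`.
#' @return List with `kept`, `p` (named vector), `t`.
#' @export
ttest_filter <- function(table, labels, p_max = 0.05) {
  m <- feature_matrix(table)
  w <- welch_columns(m, labels)
  names(w$p) <- names(w$t) <- colnames(m)
  list(kept = colnames(m)[w$p < p_max & !is.na(w$p)], p = w$p, t = w$t)
}

#' Greedy correlation pruning
#'
#' Repeatedly locates the most-correlated feature pair with |r| above
#' `corr_max` and drops the member with the weaker class association
#' (larger Welch p; ties drop the lexicographically later name), until no
#' pair exceeds the threshold.
#'
#' @param table Feature table.
#' @param labels Binary labels (used for the keep/drop decision).
#' @param corr_max Absolute Pearson threshold (default 0.9).
#' @return List with `kept` and `dropped`.
#' @export
correlation_prune <- function(table, labels, corr_max = 0.9) {
  m <- feature_matrix(table)
  if (ncol(m) < 2) return(list(kept = colnames(m), dropped = character(0)))
  p <- welch_columns(m, labels)$p
  names(p) <- colnames(m)
  r <- abs(suppressWarnings(stats::cor(m)))
  r[!is.finite(r)] <- 0
  diag(r) <- 0
  alive <- colnames(m)
  dropped <- character(0)
  repeat {
    sub <- r[alive, alive, drop = FALSE]
    mx <- max(sub)
    if (mx <= corr_max) break
    hit <- which(sub == mx, arr.ind = TRUE)[1, ]
    a <- alive[hit[1]]; b <- alive[hit[2]]
    drop <- if (p[a] > p[b]) a
            else if (p[b] > p[a]) b
            else max(a, b)           # lexicographically later
    alive <- setdiff(alive, drop)
    dropped <- c(dropped, drop)
  }
  list(kept = alive, dropped = dropped)
}

#' Minimum-redundancy maximum-relevance selection
#'
#' Greedy forward selection maximising the difference criterion
#' relevance - mean redundancy. Relevance is the one-way ANOVA
#' F-statistic against the binary label, rescaled to its correlation-ratio
#' form F / (F + df2) (the eta-squared of the grouping) so that it lives
#' on the same unit interval as the redundancy term, the mean absolute
#' Pearson correlation with already-selected features; with the raw F the
#' redundancy penalty would be numerically irrelevant and duplicated
#' features would never be demoted.
#'
#' @param table Feature table.
#' @param labels Binary labels.
#' @param k Number of features to select.
#' @return Character vector of selected feature names, in selection order.
#' @export
mrmr_select <- function(table, labels, k) {
  if (k <= 0) stop("k must be positive")
  m <- feature_matrix(table)
  labels <- as_binary_labels(labels)
  k <- min(k, ncol(m))
  # one-way ANOVA F for a binary grouping, on the correlation-ratio scale
  f_stat <- apply(m, 2, function(x) {
    x1 <- x[labels == 1]; x0 <- x[labels == 0]
    n1 <- length(x1); n0 <- length(x0); n <- n1 + n0
    ssb <- n1 * (mean(x1) - mean(x))^2 + n0 * (mean(x0) - mean(x))^2
    ssw <- sum((x1 - mean(x1))^2) + sum((x0 - mean(x0))^2)
    f <- if (ssw == 0) Inf else (ssb / 1) / (ssw / (n - 2))
    if (is.infinite(f)) 1 else f / (f + n - 2)
  })
  names(f_stat) <- colnames(m)
  cors <- abs(suppressWarnings(stats::cor(m)))
  cors[!is.finite(cors)] <- 0
  selected <- character(0)
  remaining <- colnames(m)
  for (step in seq_len(k)) {
    score <- if (!length(selected)) f_stat[remaining]
             else f_stat[remaining] -
               rowMeans(cors[remaining, selected, drop = FALSE])
    best <- remaining[score >= max(score) - 1e-12]
    pick <- min(best)      # deterministic lexicographic tie-break
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  selected
}

#' LASSO regression and the linear radiomic score
#'
#' L1-penalised logistic regression over a geometric lambda grid, with the
#' penalty chosen by stratified k-fold cross-validated deviance (lambda at
#' the CV optimum, not the 1-SE rule). Features entering here are assumed
#' already z-scored; the nonzero-coefficient features define the radiomic
#' score as the linear predictor.
#'
#' @param table Feature table (z-scored columns).
#' @param labels Binary labels.
#' @param folds CV folds (default 10).
#' @param lambda_grid Optional numeric lambda grid; defaults to 100 values
#'   spanning \[lambda_max * 1e-4, lambda_max\].
#' @param family `"binomial"` (default) for the logistic radiomic score;
#'   `"gaussian"` exposes the plain linear-regression LASSO (used e.g. to
#'   verify the soft-threshold solution on orthonormal designs).
#' @param seed Seed for the fold assignment.
#' @return List with `features` (names), `coefficients`, `intercept`,
#'   `lambda`, `score` (per-patient linear predictor), `empty` (TRUE when
#'   all coefficients vanish at the optimum).
#' @export
lasso_score <- function(table, labels, folds = 10L, lambda_grid = NULL,
                        seed = 1L, family = c("binomial", "gaussian")) {
  family <- match.arg(family)
  m <- feature_matrix(table)
  if (family == "binomial") {
    labels <- as_binary_labels(labels)
    if (min(table(labels)) < folds) {
      folds <- max(2L, min(table(labels)))
    }
    foldid <- stratified_folds(labels, folds, seed)
  } else {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           globalenv()))
    set.seed(seed)
    foldid <- sample(rep_len(seq_len(folds), length(labels)))
  }
  m_fit <- if (ncol(m) == 1) {
    cbind(m, `.pad.` = 0)       # glmnet requires >= 2 columns
  } else m
  cvfit <- glmnet::cv.glmnet(m_fit, labels, family = family,
                             alpha = 1, standardize = FALSE,
                             lambda = lambda_grid, nlambda = 100,
                             lambda.min.ratio = 1e-4, thresh = 1e-10,
                             foldid = foldid, type.measure = "deviance")
  co <- as.matrix(stats::coef(cvfit, s = "lambda.min"))
  co <- co[rownames(co) != ".pad.", , drop = FALSE]
  nz <- rownames(co)[co[, 1] != 0 & rownames(co) != "(Intercept)"]
  coefs <- co[nz, 1]
  intercept <- co["(Intercept)", 1]
  score <- as.numeric(intercept +
                        m[, nz, drop = FALSE] %*% matrix(coefs, ncol = 1))
  list(features = nz, coefficients = coefs, intercept = intercept,
       lambda = cvfit$lambda.min, score = score, empty = length(nz) == 0,
       cv_fit = cvfit)
}

#' Compare selected features between groups
#'
#' Per-feature class means and Welch t-test for the final selection.
#'
#' @param table Feature table.
#' @param labels Binary labels.
#' @param final_features Character vector of feature names.
#' @return data.frame: feature, mean_neg, mean_pos, t, p.
#' @export
compare_selected_features <- function(table, labels, final_features) {
  if (!length(final_features)) stop("empty selection")
  m <- feature_matrix(table)[, final_features, drop = FALSE]
  labels <- as_binary_labels(labels)
  w <- welch_columns(m, labels)
  data.frame(feature = final_features,
             mean_neg = colMeans(m[labels == 0, , drop = FALSE]),
             mean_pos = colMeans(m[labels == 1, , drop = FALSE]),
             t = w$t, p = w$p, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Run the full feature-selection cascade
#'
#' ICC filter (when a second reader table is available) -> z-scoring ->
#' Welch t-test -> greedy correlation pruning -> mRMR -> LASSO. All
#' statistics (including the z-score centres/scales) are fit on the rows
#' passed in, so calling this on training rows only gives a leakage-free
#' selection whose `scale` can be applied to held-out patients via
#' [apply_radiomic_score()].
#'
#' @param table Feature table (training rows).
#' @param labels Binary labels (training rows).
#' @param table_reader2 Optional second-reader feature table for the ICC
#'   stage (same rows/columns as `table`).
#' @param config A [selection_config()].
#' @return A `selection_report`: `surviving_per_stage` (named counts),
#'   `stage_features`, `final_features`, `coefficients`, `intercept`,
#'   `center`/`scale` (z-score parameters of the final features),
#'   `score` (training-row radiomic score), `empty`.
#' @export
run_selection_cascade <- function(table, labels, table_reader2 = NULL,
                                  config = selection_config()) {
  m <- feature_matrix(table)
  labels <- as_binary_labels(labels)
  stages <- list()
  feats <- colnames(m)
  stages[["input"]] <- feats

  # drop non-finite / missing columns up front
  ok <- apply(m, 2, function(x) all(is.finite(x)))
  feats <- feats[ok]
  stages[["finite"]] <- feats

  if (!is.null(table_reader2)) {
    m2 <- feature_matrix(table_reader2)
    common <- intersect(feats, colnames(m2))
    ic <- icc_filter(m[, common, drop = FALSE], m2[, common, drop = FALSE],
                     config$icc_min)
    feats <- ic$kept
  }
  stages[["icc"]] <- feats
  if (!length(feats)) stop("no features survived the ICC filter")

  # z-score on the rows provided (training only in CV use)
  center <- colMeans(m[, feats, drop = FALSE])
  scale <- apply(m[, feats, drop = FALSE], 2, stats::sd)
  nonzero <- scale > 0
  feats <- feats[nonzero]
  center <- center[feats]; scale <- scale[feats]
  mz <- sweep(sweep(m[, feats, drop = FALSE], 2, center), 2, scale, "/")

  tt <- ttest_filter(mz, labels, config$p_max)
  feats <- tt$kept
  if (!length(feats)) {
    # null-data degradation: nothing is "significant", so fall back to a
    # pure p-value ranking; the LASSO downstream still shrinks freely
    warning("no features passed the t-test filter; falling back to the ",
            config$mrmr_k, " smallest-p features")
    feats <- names(sort(tt$p))[seq_len(min(config$mrmr_k, length(tt$p)))]
  }
  stages[["ttest"]] <- feats

  cp <- correlation_prune(mz[, feats, drop = FALSE], labels,
                          config$corr_max)
  feats <- cp$kept
  stages[["correlation"]] <- feats

  feats <- mrmr_select(mz[, feats, drop = FALSE], labels,
                       min(config$mrmr_k, length(feats)))
  stages[["mrmr"]] <- feats

  las <- lasso_score(mz[, feats, drop = FALSE], labels,
                     folds = config$lasso_folds, seed = config$seed)
  stages[["lasso"]] <- las$features

  counts <- vapply(stages, length, integer(1))
  if (any(diff(counts) > 0)) {
    stop("internal error: cascade stage grew in feature count")
  }
  structure(list(surviving_per_stage = counts, stage_features = stages,
                 final_features = las$features,
                 coefficients = las$coefficients,
                 intercept = las$intercept, lambda = las$lambda,
                 center = center[las$features],
                 scale = scale[las$features],
                 score = las$score, empty = las$empty,
                 config = config),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("selection cascade:",
      paste(sprintf("%s=%d", names(x$surviving_per_stage),
                    x$surviving_per_stage), collapse = " -> "), "\n")
  if (x$empty) cat("  ! empty selection at lambda_opt\n")
  invisible(x)
}

#' Apply a fitted radiomic score to new patients
#'
#' Evaluates intercept + sum(coef_i * z-scored feature_i) using the
#' z-score parameters stored in the report (fit on training rows).
#'
#' @param report A `selection_report`.
#' @param table Feature table containing the report's final features.
#' @return Numeric score per row.
#' @export
apply_radiomic_score <- function(report, table) {
  if (report$empty) {
    stop("selection is empty: no radiomic score is defined")
  }
  m <- feature_matrix(table)
  miss <- setdiff(report$final_features, colnames(m))
  if (length(miss)) stop("missing features: ", paste(miss, collapse = ", "))
  mz <- sweep(sweep(m[, report$final_features, drop = FALSE], 2,
                    report$center), 2, report$scale, "/")
  as.numeric(report$intercept +
               mz %*% matrix(report$coefficients, ncol = 1))
}
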