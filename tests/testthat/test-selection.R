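test_that("ICC filter: identity keeps all, heavy noise drops, manual ANOVA", {
  set.seed(101)
  m1 <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  r <- icc_filter(m1, m1, icc_min = 0.85)
  expect_setequal(r$kept, c("a", "b", "c"))
  expect_true(all(abs(r$icc - 1) < 1e-12))

  m2 <- m1 + matrix(rnorm(60, 0, 20), 20, 3)
  r2 <- icc_filter(m1, m2, icc_min = 0.85)
  expect_length(r2$kept, 0)

  # 6-patient toy column against the hand-computed ANOVA formula
  x1 <- c(9, 6, 8, 7, 10, 6); x2 <- c(2, 1, 4, 1, 5, 2)
  r3 <- icc_filter(matrix(x1, dimnames = list(NULL, "f")),
                   matrix(x2, dimnames = list(NULL, "f")), icc_min = 0)
  expect_equal(unname(r3$icc["f"]), manual_icc21(x1, x2), tolerance = 1e-12)

  const <- matrix(1, 6, 1, dimnames = list(NULL, "z"))
  expect_warning(icc_filter(const, const), "zero-variance")
})

test_that("t-test filter matches manual Welch computation and null rate", {
  x <- c(1.1, 2.3, 1.9, 2.8); y <- c(4.2, 5.1, 4.8, 5.9)
  tab <- matrix(c(x, y), ncol = 1, dimnames = list(NULL, "f"))
  lab <- rep(c(0, 1), each = 4)
  r <- ttest_filter(tab, lab, p_max = 0.05)
  manual <- t.test(y, x)        # Welch by default
  expect_equal(unname(r$t["f"]), unname(manual$statistic), tolerance = 1e-12)
  expect_equal(unname(r$p["f"]), manual$p.value, tolerance = 1e-12)
  expect_equal(r$kept, "f")

  # under the null the survival fraction approximates p_max
  set.seed(102)
  mnull <- matrix(rnorm(100 * 400), 100, 400,
                  dimnames = list(NULL, sprintf("n%03d", 1:400)))
  lab2 <- rep(c(0, 1), each = 50)
  rn <- ttest_filter(mnull, lab2, p_max = 0.05)
  expect_lt(abs(length(rn$kept) / 400 - 0.05), 0.03)

  # a perfect separator is always kept
  sep <- matrix(lab2 + rnorm(100, 0, 1e-3), ncol = 1,
                dimnames = list(NULL, "s"))
  expect_equal(ttest_filter(sep, lab2)$kept, "s")
})

test_that("correlation pruning replays the greedy rule exactly", {
  set.seed(103)
  base <- rnorm(40)
  lab <- rep(c(0, 1), each = 20)
  m <- cbind(f1 = base + lab * 2,
             f2 = base + lab * 2 + rnorm(40, 0, 1e-6),  # near-duplicate
             f3 = rnorm(40),
             f4 = base * 0.5 + rnorm(40, 0, 0.8),
             f5 = rnorm(40) + lab)
  r <- correlation_prune(m, lab, corr_max = 0.9)
  # exhaustive replay of the documented rule
  p <- sapply(colnames(m), function(cn) t.test(m[lab == 1, cn],
                                               m[lab == 0, cn])$p.value)
  alive <- colnames(m)
  repeat {
    cc <- abs(cor(m[, alive, drop = FALSE])); diag(cc) <- 0
    if (max(cc) <= 0.9) break
    hit <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    a <- alive[hit[1]]; b <- alive[hit[2]]
    drop <- if (p[a] > p[b]) a else if (p[b] > p[a]) b else max(a, b)
    alive <- setdiff(alive, drop)
  }
  expect_setequal(r$kept, alive)

  # exact duplicate: exactly one copy survives
  md <- cbind(a = base, b = base)
  rd <- correlation_prune(md, lab, corr_max = 0.9)
  expect_length(rd$kept, 1)

  # nothing above the threshold: no-op
  set.seed(104)
  mi <- matrix(rnorm(40 * 4), 40, 4, dimnames = list(NULL, letters[1:4]))
  expect_setequal(correlation_prune(mi, lab, corr_max = 0.95)$kept,
                  letters[1:4])
})

test_that("mRMR ranks the generating signal first and replays greedily", {
  set.seed(105)
  lab <- rep(c(0, 1), each = 30)
  sig <- lab + rnorm(60, 0, 0.3)
  m <- cbind(sig = sig, n1 = rnorm(60), n2 = rnorm(60), n3 = rnorm(60))
  expect_equal(mrmr_select(m, lab, 1), "sig")

  # duplicated informative feature is penalised at step 2
  m2 <- cbind(sig = sig, dup = sig + rnorm(60, 0, 1e-4),
              weak = lab + rnorm(60, 0, 1.6))
  sel <- mrmr_select(m2, lab, 2)
  expect_equal(sel[1], "sig")
  expect_equal(sel[2], "weak")

  # <= 6 features: full greedy trace equals an independent replay
  set.seed(106)
  m3 <- matrix(rnorm(60 * 6), 60, 6, dimnames = list(NULL, letters[1:6]))
  m3[, 2] <- m3[, 2] + lab; m3[, 5] <- m3[, 5] + 0.6 * lab
  sel3 <- mrmr_select(m3, lab, 6)
  f_or <- sapply(colnames(m3), function(cn) {
    f <- summary(aov(m3[, cn] ~ factor(lab)))[[1]][1, "F value"]
    f / (f + length(lab) - 2)    # documented correlation-ratio scale
  })
  cors <- abs(cor(m3))
  chosen <- character(0); rem <- colnames(m3)
  for (s in 1:6) {
    sc <- if (!length(chosen)) f_or[rem]
          else f_or[rem] - rowMeans(cors[rem, chosen, drop = FALSE])
    pick <- rem[which.max(sc)]
    chosen <- c(chosen, pick); rem <- setdiff(rem, pick)
  }
  expect_equal(sel3, chosen)
  expect_error(mrmr_select(m3, lab, 0), "positive")
})

test_that("LASSO: penalty limit and soft-threshold oracle", {
  set.seed(107)
  lab <- rep(c(0, 1), each = 20)
  m <- matrix(rnorm(40 * 5), 40, 5, dimnames = list(NULL, letters[1:5]))
  m[, 1] <- m[, 1] + 2 * lab
  big <- lasso_score(m, lab, folds = 5, lambda_grid = c(1e3, 9e2), seed = 1)
  expect_true(big$empty)
  expect_length(big$features, 0)

  # orthonormal design, gaussian mode: soft-thresholded OLS coefficients
  n <- 64
  # orthonormal AND mean-zero columns (glmnet centres predictors, so the
  # soft-threshold identity is exact only for a centred design)
  q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 4), n, 4))))[, 2:5] * sqrt(n)
  colnames(q) <- paste0("x", 1:4)
  beta <- c(2, -1, 0.5, 0)
  set.seed(108)
  y <- as.numeric(q %*% beta + rnorm(n, 0, 0.3))
  fit <- lasso_score(q, y, folds = 5, seed = 2, family = "gaussian")
  b_ols <- as.numeric(crossprod(q, y) / n)
  soft <- sign(b_ols) * pmax(abs(b_ols) - fit$lambda, 0)
  names(soft) <- colnames(q)
  got <- setNames(rep(0, 4), colnames(q))
  got[fit$features] <- fit$coefficients
  expect_equal(unname(got), unname(soft), tolerance = 5e-3)
})

test_that("the full cascade is monotone, deterministic and scoreable", {
  set.seed(109)
  n <- 40
  lab <- rep(c(0, 1), each = 20)
  base <- rnorm(n)
  m <- cbind(matrix(rnorm(n * 30), n, 30), base + 2 * lab,
             base + 2 * lab + rnorm(n, 0, 1e-4), lab + rnorm(n, 0, 0.5))
  colnames(m) <- sprintf("f%02d", seq_len(ncol(m)))
  m2 <- m + matrix(rnorm(length(m), 0, 0.05), nrow(m))
  cfg <- selection_config(mrmr_k = 10, lasso_folds = 5, seed = 3)
  rep1 <- run_selection_cascade(m, lab, table_reader2 = m2, config = cfg)
  expect_true(all(diff(rep1$surviving_per_stage) <= 0))
  expect_false(rep1$empty)
  rep2 <- run_selection_cascade(m, lab, table_reader2 = m2, config = cfg)
  expect_identical(rep1$final_features, rep2$final_features)
  expect_identical(rep1$coefficients, rep2$coefficients)

  sc <- apply_radiomic_score(rep1, m)
  expect_equal(sc, rep1$score, tolerance = 1e-10)
  cmp <- compare_selected_features(m, lab, rep1$final_features)
  expect_equal(nrow(cmp), length(rep1$final_features))
  expect_true(all(is.finite(cmp$p)))
  expect_error(compare_selected_features(m, lab, character(0)), "empty")
})
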