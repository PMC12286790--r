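test_that("ROC/AUC reference points and pair-counting oracle", {
  lab <- rep(c(0, 1), each = 10)
  perfect <- c(rnorm(10, 0, 0.1), rnorm(10, 10, 0.1))
  r <- roc_auc(perfect, lab)
  expect_equal(r$auc, 1)
  expect_gt(r$threshold_star, max(perfect[lab == 0]))
  expect_equal(r$youden, 1)

  ties <- rep(1, 20)
  expect_equal(roc_auc(ties, lab)$auc, 0.5)

  set.seed(201)
  for (rep in 1:5) {
    sc <- sample(round(rnorm(30), 1))   # ensure some ties
    lb <- sample(c(rep(1, 12), rep(0, 18)))
    expect_equal(roc_auc(sc, lb)$auc, pair_count_auc(sc, lb))
  }
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("AUC identities: complement and monotone-transform invariance", {
  set.seed(202)
  sc <- rnorm(50); lb <- rbinom(50, 1, 0.4)
  lb[1:2] <- c(0, 1)
  a1 <- roc_auc(sc, lb)$auc
  expect_equal(a1 + roc_auc(-sc, lb)$auc, 1)
  expect_equal(roc_auc(exp(sc) + 3, lb)$auc, a1)
})

test_that("Youden threshold: table-row identity and brute-force scan", {
  # printed operating point: sens 0.740 / spec 0.878 -> J = 0.618
  expect_equal(round(0.740 + 0.878 - 1, 3), 0.618)

  set.seed(203)
  sc <- rnorm(60); lb <- rbinom(60, 1, 0.5); lb[1:2] <- c(0, 1)
  r <- roc_auc(sc, lb)
  yt <- youden_threshold(r$curve)
  brute <- sapply(unique(sc), function(t) {
    mean(sc[lb == 1] >= t) - mean(sc[lb == 0] >= t)
  })
  expect_equal(yt$J, max(brute), tolerance = 1e-12)
  expect_error(youden_threshold(data.frame()), "empty")
})

test_that("confusion metrics satisfy their identities on random points", {
  set.seed(204)
  for (rep in 1:20) {
    sens <- runif(1); spec <- runif(1)
    npos <- sample(10:80, 1); nneg <- sample(10:80, 1)
    cm <- confusion_from_operating_point(sens, spec, npos, nneg)
    tp <- cm$counts["tp"]; tn <- cm$counts["tn"]
    fp <- cm$counts["fp"]; fn <- cm$counts["fn"]
    expect_equal(unname(tp), round(sens * npos))
    expect_equal(unname(cm$accuracy), unname((tp + tn) / (npos + nneg)))
    expect_equal(cm$youden, cm$sensitivity + cm$specificity - 1)
    expect_identical(cm$precision, cm$ppv)
    expect_identical(cm$recall, cm$sensitivity)
  }
  cm1 <- confusion_from_operating_point(1, 1, 10, 10)
  expect_equal(cm1$youden, 1)
  expect_equal(cm1$accuracy, 1)
})

test_that("DeLong test: identity, antisymmetry, permutation agreement", {
  set.seed(205)
  lb <- rbinom(40, 1, 0.5); lb[1:2] <- c(0, 1)
  s1 <- rnorm(40) + lb; s2 <- rnorm(40) + 0.5 * lb
  d0 <- delong_test(s1, s1, lb)
  expect_equal(d0$diff, 0)
  expect_equal(d0$p, 1)

  d12 <- delong_test(s1, s2, lb)
  d21 <- delong_test(s2, s1, lb)
  expect_equal(d12$diff, -d21$diff)
  expect_equal(d12$z, -d21$z)
  expect_equal(d12$p, d21$p)
  expect_error(delong_test(s1, s2[-1], lb), "paired")

  # small-n agreement with a label-permutation AUC-difference test
  set.seed(206)
  lbs <- rep(c(0, 1), each = 12)
  x1 <- rnorm(24) + 0.8 * lbs; x2 <- rnorm(24)
  dl <- delong_test(x1, x2, lbs)
  obs <- abs(roc_auc(x1, lbs)$auc - roc_auc(x2, lbs)$auc)
  perm <- replicate(600, {
    pl <- sample(lbs)
    abs(roc_auc(x1, pl)$auc - roc_auc(x2, pl)$auc)
  })
  p_perm <- mean(perm >= obs - 1e-12)
  expect_lt(abs(dl$p - p_perm), 0.12)
})

test_that("two-rater reliability: identity, closed form, manual ANOVA", {
  x <- c(3.1, 4.2, 5.0, 6.3, 7.7, 8.1)
  r_id <- icc_two_rater(x, x)
  expect_equal(r_id$icc, 1)
  expect_equal(r_id$bland_altman$bias, 0)
  expect_equal(r_id$bland_altman$loa_lower, 0)

  # known variance components: ICC -> sb2 / (sb2 + se2)
  set.seed(207)
  subj <- rnorm(800, 0, sqrt(4))
  e1 <- rnorm(800, 0, 1); e2 <- rnorm(800, 0, 1)
  r_vc <- icc_two_rater(subj + e1, subj + e2)
  expect_lt(abs(r_vc$icc - 4 / 5), 0.04)

  # 5-pair toy table against the textbook formula
  a <- c(10, 12, 14, 16, 20); b <- c(11, 13, 13, 17, 19)
  r5 <- icc_two_rater(a, b)
  expect_equal(r5$icc, manual_icc21(a, b), tolerance = 1e-12)
  expect_true(r5$icc_ci95[1] < r5$icc && r5$icc < r5$icc_ci95[2])
  expect_error(icc_two_rater(rep(1, 5), rep(1, 5)), "zero total variance")
})

test_that("group tests match manual rank-sum and chi-square computations", {
  tab <- data.frame(cont = c(1.2, 3.4, 2.2, 5.1, 6.7, 4.4, 8.0, 7.2),
                    cat = factor(c("a", "a", "b", "a", "b", "b", "b", "b")))
  lab <- c(0, 0, 0, 0, 1, 1, 1, 1)
  out <- group_tests(tab, lab)
  manual_w <- wilcox.test(tab$cont[lab == 1], tab$cont[lab == 0],
                          exact = TRUE)
  expect_equal(out$p[out$variable == "cont"], manual_w$p.value)

  t2x2 <- table(tab$cat, lab)
  manual_chi <- suppressWarnings(chisq.test(t2x2, correct = FALSE))
  expect_equal(out$p[out$variable == "cat"], manual_chi$p.value)

  # identical groups: p is 1 (or the maximal attainable value)
  tab2 <- data.frame(v = rep(c(1, 2, 3, 4), 2))
  out2 <- group_tests(tab2, rep(c(0, 1), each = 4))
  expect_gt(out2$p, 0.95)
})
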