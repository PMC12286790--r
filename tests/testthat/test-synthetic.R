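test_that("cohort generation is deterministic and validates its config", {
  cfg <- tiny_cohort_config(seed = 5, n = 6)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  expect_error(cohort_config(n_patients = 2), "n_patients")
  expect_error(cohort_config(prevalence_pos = 1.2), "prevalence")
  expect_error(cohort_config(grid_shape = c(8, 20, 20)), "grid_shape")
  expect_error(cohort_config(noise_sd = -1), "noise")
})

test_that("phantom invariants hold for every patient", {
  coh <- generate_cohort(tiny_cohort_config(seed = 6, n = 10))
  lab <- vapply(coh, `[[`, integer(1), "lvsi_label")
  expect_equal(sum(lab), round(10 * 0.4))
  for (p in coh) {
    msk <- as.numeric(p$mask) > 0
    expect_gt(sum(msk), 0)
    hl <- as.integer(p$true_habitat_map)
    expect_true(all(hl[msk] %in% 1:3))
    expect_true(all(hl[!msk] == 0))
    expect_identical(dim(p$volume_aptw), dim(p$volume_adc))
    expect_gte(p$clinical$tumor_size, 10)
    expect_true(all(unlist(p$clinical[c("age", "bmi", "ca125",
                                        "tumor_size")]) > 0))
  }
  # ADC anti-correlated with APTw within tumors
  cors <- vapply(coh, function(p) {
    msk <- as.numeric(p$mask) > 0
    cor(p$volume_aptw[msk], p$volume_adc[msk])
  }, numeric(1))
  expect_true(all(cors < -0.5))
})

test_that("whole-tumor APTw class means hit the published anchors", {
  coh <- generate_cohort(cohort_config(seed = 42))
  lab <- vapply(coh, `[[`, integer(1), "lvsi_label")
  wm <- vapply(coh, function(p) {
    mean(p$volume_aptw[as.numeric(p$mask) > 0])
  }, numeric(1))
  expect_lt(abs(mean(wm[lab == 0]) - 2.31), 0.5)
  expect_lt(abs(mean(wm[lab == 1]) - 4.36), 0.5)
})

test_that("clinical medians converge to the configured targets", {
  coh <- generate_cohort(cohort_config(n_patients = 400, seed = 31))
  cl <- cohort_clinical_table(coh)
  expect_lt(abs(median(cl$ca125) - 22.5), 22.5 * 3 / sqrt(400))
  expect_lt(abs(median(cl$bmi) - 25), 25 * 2 / sqrt(400))
  expect_lt(abs(median(cl$age) - 50), 50 * 2.5 / sqrt(400))
  # tumor size carries a +/- one-voxel (2 mm) discretization granularity
  expect_lt(abs(median(cl$tumor_size) - 34), 2 + 34 * 2 / sqrt(400))
  # positive class has elevated CA125 and tumor size
  expect_gt(median(cl$ca125[cl$lvsi == 1]), median(cl$ca125[cl$lvsi == 0]))
  expect_gt(median(cl$tumor_size[cl$lvsi == 1]),
            median(cl$tumor_size[cl$lvsi == 0]))
})

test_that("null configuration severs the label from every channel", {
  cfg <- cohort_config(n_patients = 200, seed = 8,
                       grid_shape = c(24L, 24L, 16L),
                       effect_size_aptw = 0,
                       label_coefs = c(f_high = 0, log_ca125 = 0,
                                       tumor_size = 0))
  coh <- generate_cohort(cfg)
  lab <- vapply(coh, `[[`, integer(1), "lvsi_label")
  cl <- cohort_clinical_table(coh)
  wm <- vapply(coh, function(p) mean(p$volume_aptw[as.numeric(p$mask) > 0]),
               numeric(1))
  tab <- data.frame(ca125 = cl$ca125, tumor_size = cl$tumor_size,
                    aptw_h3 = wm)
  cv <- fit_cv(model_spec("combined"), tab, lab, seed = 2)
  expect_gt(cv$pooled_roc$auc, 0.4)
  expect_lt(cv$pooled_roc$auc, 0.6)
})

test_that("z-spectrum synthesis is consistent with the planted APTw field", {
  coh <- generate_cohort(tiny_cohort_config(seed = 9, n = 4))
  p <- coh[[1]]
  z <- synth_zspectrum(p$volume_aptw)
  m <- compute_aptw_map(z, p$mask)
  msk <- as.numeric(p$mask) > 0
  expect_equal(m$values[msk], p$volume_aptw[msk], tolerance = 0.01)
})

test_that("two readers: noiseless identity and calibrated agreement", {
  coh <- generate_cohort(tiny_cohort_config(seed = 10, n = 6))
  r0 <- simulate_two_readers(coh[[1]], reader_noise_sd = 0, seed = 3)
  expect_identical(r0$reader1$per_roi_means, r0$reader2$per_roi_means)
  expect_equal(icc_two_rater(c(r0$reader1$summary_mean, 1:5),
                             c(r0$reader2$summary_mean, 1:5))$icc, 1)

  # closed-form target: with known between/within variance the two-reader
  # ICC of the summary means approaches sb2 / (sb2 + se2 / 3)
  coh2 <- generate_cohort(cohort_config(n_patients = 60, seed = 11,
                                        grid_shape = c(24L, 24L, 16L)))
  rr <- lapply(seq_along(coh2), function(i) {
    simulate_two_readers(coh2[[i]], reader_noise_sd = 0.25, seed = 100 + i)
  })
  m1 <- vapply(rr, function(r) r$reader1$summary_mean, numeric(1))
  m2 <- vapply(rr, function(r) r$reader2$summary_mean, numeric(1))
  icc <- icc_two_rater(m1, m2)$icc
  sb2 <- var((m1 + m2) / 2)
  expected <- sb2 / (sb2 + 0.25^2 / 3)
  expect_lt(abs(icc - expected), 0.08)
  expect_gt(icc, 0.85)   # "good" agreement at default calibration

  # heavy reader noise destroys agreement
  rr_bad <- lapply(seq_along(coh2[1:30]), function(i) {
    simulate_two_readers(coh2[[i]], reader_noise_sd = 8, seed = 300 + i)
  })
  b1 <- vapply(rr_bad, function(r) r$reader1$summary_mean, numeric(1))
  b2 <- vapply(rr_bad, function(r) r$reader2$summary_mean, numeric(1))
  expect_lt(icc_two_rater(b1, b2)$icc, 0.5)
})

test_that("mask perturbation keeps a plausible second segmentation", {
  coh <- generate_cohort(tiny_cohort_config(seed = 12, n = 4))
  p <- coh[[2]]
  m2 <- perturb_mask(p$mask, seed = 7)
  a <- as.numeric(p$mask) > 0; b <- as.numeric(m2) > 0
  dice <- 2 * sum(a & b) / (sum(a) + sum(b))
  expect_gt(dice, 0.8)
  expect_lt(dice, 1)
  expect_identical(as.numeric(perturb_mask(p$mask, seed = 7)),
                   as.numeric(m2))
})
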