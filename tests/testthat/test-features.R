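test_that("shape features: unit voxel, cube geometry, ball sphericity", {
  single <- array(0, c(5, 5, 5)); single[3, 3, 3] <- 1
  s1 <- shape_features(volume(single, spacing = c(1, 1, 1)))
  expect_equal(unname(s1["VoxelVolume"]), 1)

  cube <- array(0, c(14, 14, 14)); cube[3:12, 3:12, 3:12] <- 1
  sc <- shape_features(volume(cube))
  expect_equal(unname(sc["VoxelVolume"]), 1000)
  expect_equal(unname(sc["Maximum3DDiameter"]), sqrt(3 * 81))
  expect_equal(unname(sc["Elongation"]), 1, tolerance = 1e-8)
  expect_equal(unname(sc["Flatness"]), 1, tolerance = 1e-8)

  ball <- ball_mask(9, 23)
  sb <- shape_features(volume(array(as.numeric(ball), dim(ball))))
  expect_gt(unname(sb["Sphericity"]), 0.93)
  expect_lt(unname(sb["Sphericity"]), 1.07)
  expect_error(shape_features(volume(array(0, c(3, 3, 3)))), "empty")
})

test_that("shape features ignore intensity scale entirely", {
  set.seed(71)
  reg <- array(as.numeric(ball_mask(5, 13)), c(13, 13, 13))
  expect_identical(shape_features(volume(reg)),
                   shape_features(volume(reg * 1)))
})

test_that("first-order features: degenerate case and percentile convention", {
  f <- firstorder_features(rep(4.4, 50), bin_width = 0.1)
  expect_equal(unname(f["Variance"]), 0)
  expect_equal(unname(f["Entropy"]), 0)
  expect_equal(unname(f["Uniformity"]), 1)

  f2 <- firstorder_features(1:100, bin_width = 1)
  expect_equal(unname(f2["10Percentile"]), 10.9)
  expect_equal(unname(f2["90Percentile"]), 90.1)
})

test_that("first-order features equal a naive recomputation", {
  set.seed(72)
  x <- rnorm(321, 5, 2)
  f <- firstorder_features(x, bin_width = 0.25, voxel_volume = 8)
  mu <- mean(x); m2 <- mean((x - mu)^2)
  q <- quantile(x, c(0.1, 0.25, 0.75, 0.9), type = 7, names = FALSE)
  inr <- x[x >= q[1] & x <= q[4]]
  lv <- floor((x - min(x)) / 0.25) + 1
  p <- as.numeric(table(lv)) / length(x)
  expected <- c(mu, median(x), min(x), max(x), diff(range(x)), m2,
                mean((x - mu)^3) / m2^1.5, mean((x - mu)^4) / m2^2,
                sum(x^2), 8 * sum(x^2), -sum(p * log2(p)), sum(p^2),
                q[1], q[4], q[3] - q[2], mean(abs(x - mu)),
                mean(abs(inr - mean(inr))), sqrt(mean(x^2)))
  expect_equal(unname(f), expected, tolerance = 1e-12)

  # mean is equivariant to intensity shift
  f_shift <- firstorder_features(x + 3, bin_width = 0.25)
  expect_equal(unname(f_shift["Mean"]) - unname(f["Mean"]), 3)
})

test_that("texture features match a hand-built co-occurrence matrix", {
  # 3 x 3 x 1 region with 2 gray levels arranged in stripes
  a <- array(c(1, 2, 1,
               1, 2, 1,
               1, 2, 1), c(3, 3, 1))
  reg <- array(TRUE, c(3, 3, 1))
  tx <- suppressWarnings(texture_features(a, reg, n_levels = 2))
  # hand-built symmetric GLCM over the in-plane directions that exist in
  # a 3x3x1 grid: (1,0,0), (0,1,0), (1,1,0), (1,-1,0)
  # counts: same-level pairs and cross-level pairs enumerated by hand
  P <- matrix(0, 2, 2)
  lv <- a[, , 1]
  dirs <- rbind(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
  for (i in 1:3) for (j in 1:3) for (d in 1:4) {
    ii <- i + dirs[d, 1]; jj <- j + dirs[d, 2]
    if (ii < 1 || jj < 1 || ii > 3 || jj > 3) next
    P[lv[i, j], lv[ii, jj]] <- P[lv[i, j], lv[ii, jj]] + 1
    P[lv[ii, jj], lv[i, j]] <- P[lv[ii, jj], lv[i, j]] + 1
  }
  p <- P / sum(P)
  expect_equal(unname(tx["glcm_Contrast"]),
               sum(p * (row(p) - col(p))^2))
  expect_equal(unname(tx["glcm_JointEnergy"]), sum(p^2))
  expect_equal(unname(tx["glcm_MaximumProbability"]), max(p))

  # GLRLM by hand: vertical runs of length 3 (6 of them over +/-y), etc.
  expect_equal(length(tx), 75)
})

test_that("texture degenerate and extremal patterns behave as documented", {
  const <- array(5, c(3, 3, 2))
  reg <- array(TRUE, c(3, 3, 2))
  expect_warning(txc <- texture_features(const, reg, n_levels = 8),
                 "single gray level")
  expect_equal(unname(txc["ngtdm_Busyness"]), 0)

  # checkerboard has maximal contrast among 2-level images of equal size
  n <- 4
  idx <- array(seq_len(n^3), c(n, n, n))
  ai <- arrayInd(idx, c(n, n, n))
  checker <- array((rowSums(ai) %% 2) + 1, c(n, n, n))
  regn <- array(TRUE, c(n, n, n))
  tx_check <- texture_features(checker, regn, n_levels = 2)
  set.seed(81)
  for (rep in 1:5) {
    rnd <- array(sample(1:2, n^3, TRUE), c(n, n, n))
    tx_rnd <- suppressWarnings(texture_features(rnd, regn, n_levels = 2))
    expect_gte(tx_check[["glcm_Contrast"]], tx_rnd[["glcm_Contrast"]])
    expect_lte(tx_check[["glcm_Id"]], tx_rnd[["glcm_Id"]])
  }
})

test_that("feature table has the documented column structure", {
  cfg_id <- feature_bank_config(transforms = "original", n_habitats = 3L)
  expect_equal(per_habitat_ncol(cfg_id), 107)          # 14 + 93
  cfg_full <- feature_bank_config()
  expect_equal(length(cfg_full$transforms), 20)
  expect_equal(per_habitat_ncol(cfg_full), 1874)       # 14 + 20 * 93

  set.seed(91)
  coh <- generate_cohort(tiny_cohort_config(seed = 13, n = 4))
  maps <- lapply(coh, function(p) {
    fmap <- extract_voxel_features(p$volume_aptw, p$mask)
    select_habitats(fmap, p$volume_aptw, k_range = 3:4, seed = 3)
  })
  ft <- extract_feature_table(coh, maps, cfg_id)
  expect_equal(ncol(ft) - 1, 3 * 107)                  # 3 habitats
  expect_true(all(is.finite(as.matrix(ft[, -1]))))
  expect_true("original_firstorder_Mean_h3" %in% names(ft))
  expect_true("original_shape_Sphericity_h1" %in% names(ft))
})

test_that("transform bank members run and keep the grid", {
  set.seed(92)
  v <- volume(array(rnorm(10 * 10 * 8, 3, 1), c(10, 10, 8)),
              spacing = c(2, 2, 2))
  for (tr in default_transforms()) {
    out <- apply_transform(v, tr)
    expect_equal(dim(out), dim(v))
    expect_true(all(is.finite(out)))
  }
  # identity really is the identity
  expect_equal(as.numeric(apply_transform(v, "original")), as.numeric(v))
})
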