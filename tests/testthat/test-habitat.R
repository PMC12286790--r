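test_that("voxel features: constant field and hand-computed bright voxel", {
  v <- volume(array(3.5, c(5, 5, 5)))   # binary-exact constant
  m <- volume(array(1, c(5, 5, 5)))
  fm <- extract_voxel_features(v, m)
  expect_equal(unname(fm$features[, "mean"]), rep(3.5, nrow(fm$features)))
  expect_true(all(fm$features[, c("variance", "range", "entropy")] == 0))

  # single bright voxel at the window center of an otherwise-zero volume
  a <- array(0, c(5, 5, 5)); a[3, 3, 3] <- 27
  fm2 <- extract_voxel_features(volume(a), m)
  center <- which(fm2$index == 3 + 5 * (2 + 5 * 2))
  expect_equal(unname(fm2$features[center, "max"]), 27)
  expect_equal(unname(fm2$features[center, "mean"]), 1)   # 27 / 27
  expect_equal(unname(fm2$features[center, "energy"]), 27^2)
})

test_that("voxel features equal a naive nested-loop recomputation", {
  set.seed(21)
  a <- array(rnorm(9^3), c(9, 9, 9))
  full <- array(TRUE, c(9, 9, 9))
  fm <- extract_voxel_features(volume(a), volume(full * 1),
                               min_neighbors = 26L)
  oracle <- naive_window_features(a, full, 26L)
  expect_equal(fm$index, oracle$index)
  expect_equal(unname(fm$features), unname(oracle$features),
               tolerance = 1e-10)

  # the mask-restricted edge-window route must agree with the oracle too
  mask <- array(runif(9^3) > 0.15, c(9, 9, 9))
  fm8 <- extract_voxel_features(volume(a), volume(mask * 1),
                                min_neighbors = 8L)
  oracle8 <- naive_window_features(a, mask, 8L)
  expect_equal(fm8$index, oracle8$index)
  expect_equal(unname(fm8$features), unname(oracle8$features),
               tolerance = 1e-10)
})

test_that("k-means recovers separable clouds and matches brute force", {
  set.seed(31)
  x <- rbind(matrix(rnorm(60, 0, 0.2), 30, 2),
             matrix(rnorm(60, 8, 0.2), 30, 2))
  km <- kmeans_partition(x, 2, seed = 1)
  expect_equal(length(unique(km$cluster[1:30])), 1)
  expect_equal(length(unique(km$cluster[31:60])), 1)
  expect_true(km$cluster[1] != km$cluster[60])

  # 8 points, k = 2: exhaustive enumeration of all assignments
  set.seed(32)
  x8 <- matrix(rnorm(16), 8, 2)
  km8 <- kmeans_partition(x8, 2, seed = 3)
  z8 <- scale(x8)
  z8 <- sweep(sweep(x8, 2, colMeans(x8)), 2, apply(x8, 2, sd), "/")
  best <- Inf
  for (code in 1:(2^8 - 2)) {
    lab <- as.integer(intToBits(code))[1:8] + 1L
    if (length(unique(lab)) < 2) next
    w <- 0
    for (g in 1:2) {
      pts <- z8[lab == g, , drop = FALSE]
      w <- w + sum(sweep(pts, 2, colMeans(pts))^2)
    }
    best <- min(best, w)
  }
  expect_equal(km8$inertia, best, tolerance = 1e-8)

  # duplicated rows receive identical labels
  set.seed(33)
  xd <- matrix(rnorm(20), 10, 2)
  xdd <- rbind(xd, xd)
  kmd <- kmeans_partition(xdd, 3, seed = 2)
  expect_equal(kmd$cluster[1:10], kmd$cluster[11:20])

  expect_error(kmeans_partition(xd, 11, seed = 1), "exceeds")
})

test_that("Calinski-Harabasz matches a manual scatter computation", {
  x <- matrix(c(0, 0, 0.2, 0.1, 5, 5.1, 5.2, 4.9, 10.1, 10, 9.8, 10.2),
              ncol = 2, byrow = TRUE)
  lab <- c(1, 1, 2, 2, 3, 3)
  g <- colMeans(x)
  trb <- 0; trw <- 0
  for (j in 1:3) {
    xi <- x[lab == j, , drop = FALSE]
    trb <- trb + 2 * sum((colMeans(xi) - g)^2)
    trw <- trw + sum(sweep(xi, 2, colMeans(xi))^2)
  }
  manual <- (trb / 2) / (trw / 3)
  expect_equal(calinski_harabasz(x, lab), manual)
  expect_error(calinski_harabasz(x, rep(1, 6)), "2 clusters")

  # CH grows with squared separation for two tight clusters
  mk <- function(d) {
    rbind(matrix(rnorm(40, 0, 0.1), 20), matrix(rnorm(40, d, 0.1), 20))
  }
  set.seed(41)
  ch1 <- calinski_harabasz(mk(2), rep(1:2, each = 20))
  set.seed(41)
  ch2 <- calinski_harabasz(mk(8), rep(1:2, each = 20))
  expect_gt(ch2, ch1 * 4)

  # random labels on random data: CH concentrates near 1
  set.seed(42)
  vals <- replicate(40, {
    calinski_harabasz(matrix(rnorm(200), 100, 2),
                      sample(1:2, 100, TRUE))
  })
  expect_lt(abs(mean(vals) - 1), 0.35)
})

test_that("habitat selection orders by mean APTw and is order-invariant", {
  set.seed(51)
  cfg <- tiny_cohort_config(seed = 7, n = 4)
  p <- generate_cohort(cfg)[[2]]
  fmap <- extract_voxel_features(p$volume_aptw, p$mask)
  hm <- select_habitats(fmap, p$volume_aptw, seed = 9)
  expect_true(all(diff(hm$ordering_key) >= 0))
  expect_true(all(sort(unique(hm$cluster)) == seq_len(hm$k)))
  # labels partition the mask (0 outside, 1..k inside)
  lab <- as.integer(hm$labels)
  msk <- as.numeric(p$mask) > 0
  expect_true(all(lab[msk] >= 1 & lab[msk] <= hm$k))
  expect_true(all(lab[!msk] == 0))
  # deterministic rerun
  hm2 <- select_habitats(fmap, p$volume_aptw, seed = 9)
  expect_identical(hm$cluster, hm2$cluster)
  expect_identical(hm$ch_scores, hm2$ch_scores)
})

test_that("adjusted Rand index behaves at its reference points", {
  lab <- rep(1:3, each = 10)
  expect_equal(adjusted_rand_index(lab, lab), 1)
  perm <- c(3, 1, 2)[lab]
  expect_equal(adjusted_rand_index(lab, perm), 1)
  set.seed(61)
  rnd <- replicate(50, adjusted_rand_index(sample(lab), lab))
  expect_lt(abs(mean(rnd)), 0.1)
})
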