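make_stack <- function(dims = c(4, 4, 3), offsets = seq(-4, 4, by = 0.5),
                       fill = 1, s0 = 1) {
  sig <- array(fill * s0, c(dims, length(offsets)))
  zspectrum_stack(sig, offsets, array(s0, dims))
}

test_that("MTR asymmetry arithmetic matches the printed formula", {
  dims <- c(3, 3, 3)
  offsets <- c(-3.5, 0, 3.5)
  s0 <- array(200, dims)
  sig <- array(0, c(dims, 3))
  sig[, , , 1] <- 0.6 * 200   # S(-3.5)
  sig[, , , 2] <- 0.1 * 200
  sig[, , , 3] <- 0.5 * 200   # S(+3.5)
  z <- zspectrum_stack(sig, offsets, s0)
  mask <- array(1, dims)
  m <- compute_aptw_map(z, mask)
  expect_equal(unname(m$values[2, 2, 2]), 10.0)

  # perfectly symmetric spectrum -> 0 everywhere
  sig[, , , 1] <- sig[, , , 3]
  m0 <- compute_aptw_map(zspectrum_stack(sig, offsets, s0), mask)
  expect_true(all(abs(m0$values[!is.na(m0$values)]) < 1e-12))
})

test_that("APTw map equals an independent per-voxel recomputation", {
  set.seed(11)
  dims <- c(5, 5, 2)
  offsets <- c(-3.5, -1, 1, 3.5)
  sig <- array(runif(prod(dims) * 4, 0.3, 1), c(dims, 4))
  s0 <- array(runif(prod(dims), 0.8, 1.2), dims)
  mask <- array(runif(prod(dims)) > 0.3, dims)
  m <- compute_aptw_map(zspectrum_stack(sig, offsets, s0), mask * 1)
  for (i in which(mask)) {
    ai <- arrayInd(i, dims)
    expected <- (sig[ai[1], ai[2], ai[3], 1] - sig[ai[1], ai[2], ai[3], 4]) /
      s0[ai[1], ai[2], ai[3]] * 100
    expect_equal(unname(m$values[i]), expected)
  }
  expect_true(all(is.na(m$values[!mask])))
})

test_that("APTw invariances: scaling, mask-locality, amide monotonicity", {
  set.seed(12)
  dims <- c(4, 4, 4)
  offsets <- seq(-4, 4, 0.5)
  sig <- array(runif(prod(dims) * length(offsets), 0.4, 1), c(dims, length(offsets)))
  s0 <- array(1, dims)
  mask <- array(1, dims)
  m1 <- compute_aptw_map(zspectrum_stack(sig, offsets, s0), mask)
  m2 <- compute_aptw_map(zspectrum_stack(sig * 7, offsets, s0 * 7), mask)
  expect_equal(as.numeric(m1$values), as.numeric(m2$values))

  # voxels outside the mask never influence inside values
  sig_b <- sig
  sig_b[1, 1, 1, ] <- 99
  mask2 <- mask; mask2[1, 1, 1] <- 0
  ma <- compute_aptw_map(zspectrum_stack(sig, offsets, s0), mask2)
  mb <- compute_aptw_map(zspectrum_stack(sig_b, offsets, s0), mask2)
  expect_equal(as.numeric(ma$values)[-1], as.numeric(mb$values)[-1])

  # deepening the +3.5 ppm dip strictly increases APTw
  i_pos <- which(offsets == 3.5)
  sig_c <- sig
  sig_c[, , , i_pos] <- sig_c[, , , i_pos] - 0.1
  mc <- compute_aptw_map(zspectrum_stack(sig_c, offsets, s0), mask)
  expect_true(all(mc$values > m1$values))
})

test_that("offset and S0 validation behave as documented", {
  z <- make_stack(offsets = c(-3.5, 0, 2))
  expect_error(compute_aptw_map(z, array(1, c(4, 4, 3))), "available")
  z2 <- make_stack()
  z2$s0[1, 1, 1] <- 0
  expect_warning(m <- compute_aptw_map(z2, array(1, c(4, 4, 3))),
                 "S0 <= 0")
  expect_equal(unname(m$mask[1, 1, 1]), 0)
})

test_that("three-ROI measurement: constant field, determinism, errors", {
  dims <- c(24, 24, 5)
  mask <- array(0, dims)
  mask[4:21, 4:21, 3] <- 1
  vals <- array(7.5, dims)
  v <- volume(vals, spacing = c(1, 1, 4))
  r <- measure_three_roi_mean(v, volume(mask, spacing = c(1, 1, 4)),
                              roi_radius_mm = 2, seed = 5)
  expect_equal(r$summary_mean, 7.5)
  expect_equal(r$summary_mean, mean(r$per_roi_means))
  expect_equal(r$slice, 3)

  r2 <- measure_three_roi_mean(v, volume(mask, spacing = c(1, 1, 4)),
                               roi_radius_mm = 2, seed = 5)
  expect_identical(r$roi_centers, r2$roi_centers)

  expect_error(
    measure_three_roi_mean(v, volume(mask, spacing = c(1, 1, 4)),
                           roi_radius_mm = 50, seed = 1),
    "radius")
})

test_that("three-ROI means match analytically constructed circle values", {
  dims <- c(30, 30, 3)
  mask <- array(0, dims); mask[, , 2] <- 1
  vals <- array(0, dims)
  # three disjoint constant discs; ROI radius small enough to sit inside
  centers <- list(c(8, 8), c(8, 22), c(22, 15))
  levels <- c(2, 5, 11)
  for (t in 1:3) {
    for (i in 1:30) for (j in 1:30) {
      if ((i - centers[[t]][1])^2 + (j - centers[[t]][2])^2 <= 36) {
        vals[i, j, 2] <- levels[t]
      }
    }
  }
  v <- volume(vals)
  # restrict the tumor to the union of the three discs
  m <- array(0, dims)
  m[, , 2] <- (vals[, , 2] > 0) * 1
  r <- measure_three_roi_mean(v, volume(m), roi_radius_mm = 2, seed = 3)
  expect_setequal(round(sort(r$per_roi_means), 6), sort(levels))
  expect_equal(r$summary_mean, mean(levels))
})
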