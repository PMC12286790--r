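#' Construct a z-spectrum stack
#'
#' Per-voxel saturated signals over a list of frequency offsets, plus the
#' unsaturated reference signal S0. Offsets are in ppm relative to water
#' and must include both +3.5 and -3.5 ppm for APTw quantification.
#'
#' @param signals 4D array (x, y, z, offset), arbitrary units.
#' @param offsets Numeric vector of ppm offsets, length = dim(signals)[4].
#' @param s0 3D array of unsaturated signals, same grid.
#' @param spacing Voxel spacing in mm.
#' @return A `zspectrum_stack` object.
#' @export
zspectrum_stack <- function(signals, offsets, s0, spacing = c(1, 1, 1)) {
  signals <- as.array(signals)
  if (length(dim(signals)) != 4L) stop("signals must be 4D (x, y, z, offset)")
  if (dim(signals)[4] != length(offsets)) {
    stop("length(offsets) must equal the 4th dimension of signals")
  }
  s0 <- as.array(s0)
  if (!identical(dim(s0), dim(signals)[1:3])) {
    stop("s0 grid does not match signals grid")
  }
  structure(list(signals = signals, offsets = as.numeric(offsets), s0 = s0,
                 spacing = as.numeric(spacing)),
            class = "zspectrum_stack")
}

# Nearest-offset lookup with a ppm tolerance; errors list what is available.
match_offset <- function(offsets, target, tol = 0.05) {
  i <- which.min(abs(offsets - target))
  if (abs(offsets[i] - target) > tol) {
    stop(sprintf("no offset within %.2f ppm of %+.2f ppm; available: %s",
                 tol, target, paste(sprintf("%+.2f", sort(offsets)),
                                    collapse = ", ")))
  }
  i
}

#' Compute an APTw map from a z-spectrum stack
#'
#' APTw contrast is the magnetization transfer ratio asymmetry at
#' +/-3.5 ppm around water, in percent units:
#' \deqn{APTw\% = (S(-3.5\,ppm) - S(+3.5\,ppm)) / S_0 \times 100}
#' computed voxel-wise on the mask only. Voxels with S0 <= 0 cannot be
#' normalised; they are flagged invalid and removed from the output mask.
#'
#' @param z A [zspectrum_stack()].
#' @param mask Binary `volume` (or 3D array) on the same grid.
#' @param tol_ppm Offset matching tolerance (default 0.05 ppm).
#' @return An `aptw_map`: list with `values` (a `volume`, NA outside mask),
#'   `mask` (possibly shrunk by invalid-S0 voxels), and `n_invalid_s0`.
#' @export
compute_aptw_map <- function(z, mask, tol_ppm = 0.05) {
  stopifnot(inherits(z, "zspectrum_stack"))
  mask_arr <- vol_data(mask) > 0
  if (!identical(dim(mask_arr), dim(z$s0))) stop("mask grid mismatch")
  i_neg <- match_offset(z$offsets, -3.5, tol_ppm)
  i_pos <- match_offset(z$offsets, +3.5, tol_ppm)

  bad <- mask_arr & !(z$s0 > 0)
  n_bad <- sum(bad)
  if (n_bad > 0) {
    warning(n_bad, " in-mask voxel(s) with S0 <= 0 excluded from mask")
    mask_arr <- mask_arr & !bad
  }
  s_neg <- z$signals[, , , i_neg, drop = TRUE]
  s_pos <- z$signals[, , , i_pos, drop = TRUE]
  vals <- array(NA_real_, dim = dim(z$s0))
  vals[mask_arr] <- (s_neg[mask_arr] - s_pos[mask_arr]) / z$s0[mask_arr] * 100
  structure(list(values = volume(vals, spacing = z$spacing),
                 mask = volume(array(as.numeric(mask_arr),
                                     dim = dim(mask_arr)),
                               spacing = z$spacing),
                 n_invalid_s0 = n_bad),
            class = "aptw_map")
}

#' @export
print.aptw_map <- function(x, ...) {
  v <- x$values[vol_data(x$mask) > 0]
  cat(sprintf("<aptw_map: %d in-mask voxels, mean %.2f%%, range [%.2f, %.2f]%%>\n",
              length(v), mean(v), min(v), max(v)))
  invisible(x)
}

# Feasible circle centers on a 2D slice: all pixels of the disk must lie in
# the allowed region. Returns integer matrix of (i, j) centers and the
# in-plane clearance (mm) of every allowed pixel.
feasible_centers <- function(region2d, radius_mm, spacing2d) {
  idx <- which(region2d, arr.ind = TRUE)
  if (!nrow(idx)) return(list(centers = idx, clearance = numeric(0)))
  # clearance of a pixel = min mm distance to any pixel outside the region
  out <- which(!region2d, arr.ind = TRUE)
  d <- dim(region2d)
  clearance <- rep(Inf, nrow(idx))
  if (nrow(out)) {
    for (r in seq_len(nrow(idx))) {
      dx <- (idx[r, 1] - out[, 1]) * spacing2d[1]
      dy <- (idx[r, 2] - out[, 2]) * spacing2d[2]
      clearance[r] <- sqrt(min(dx * dx + dy * dy))
    }
  }
  # distance to image border also limits the disk
  bx <- pmin(idx[, 1] - 1, d[1] - idx[, 1]) * spacing2d[1]
  by <- pmin(idx[, 2] - 1, d[2] - idx[, 2]) * spacing2d[2]
  clearance <- pmin(clearance, bx + spacing2d[1], by + spacing2d[2])
  keep <- clearance >= radius_mm
  list(centers = idx[keep, , drop = FALSE], clearance = clearance,
       all_centers = idx)
}

#' Conventional three-ROI mean measurement
#'
#' Reproduces the conventional APTw reading protocol: on the axial slice of
#' maximum in-mask extent (ties broken toward the lowest slice index),
#' three disjoint circular ROIs are placed inside the tumor while avoiding
#' an exclusion region (vessels/necrosis), and the measurement is the
#' arithmetic mean of the three ROI means.
#'
#' Placement is greedy farthest-point and deterministic given `seed`: the
#' first center is drawn (seeded) among the deepest feasible candidates,
#' and each subsequent circle maximises its minimum center distance to the
#' circles already placed, subject to disjointness.
#'
#' @param map An `aptw_map`, or a plain `volume` of values.
#' @param mask Binary volume (defaults to the map's own mask).
#' @param exclusion_mask Optional binary volume of voxels to avoid.
#' @param roi_radius_mm Circle radius in mm (default 3).
#' @param seed Integer seed for the placement tie-breaks.
#' @return A `roi_measurement`: `roi_centers` (3 x 3 voxel coordinates),
#'   `roi_radius`, `per_roi_means` (length 3), `summary_mean`, `slice`.
#' @export
measure_three_roi_mean <- function(map, mask = NULL, exclusion_mask = NULL,
                                   roi_radius_mm = 3, seed = 1L) {
  if (inherits(map, "aptw_map")) {
    values <- map$values
    if (is.null(mask)) mask <- map$mask
  } else {
    values <- map
    if (is.null(mask)) stop("mask required when `map` is a plain volume")
  }
  sp <- vox_spacing(values)
  mask_arr <- vol_data(mask) > 0
  if (!any(mask_arr)) stop("empty mask")
  excl <- if (is.null(exclusion_mask)) array(FALSE, dim(mask_arr))
          else vol_data(exclusion_mask) > 0

  counts <- apply(mask_arr, 3, sum)
  slice <- which.max(counts)   # which.max takes the first (lowest) maximum
  region <- mask_arr[, , slice] & !excl[, , slice]

  fc <- feasible_centers(region, roi_radius_mm, sp[1:2])
  centers <- fc$centers
  if (nrow(centers) < 1) {
    stop(sprintf("cannot fit a circle of radius %.2f mm; achievable maximum radius is %.2f mm",
                 roi_radius_mm,
                 if (length(fc$clearance)) max(fc$clearance) else 0))
  }
  clear_ok <- fc$clearance[fc$clearance >= roi_radius_mm]

  mm <- function(a, b) sqrt(sum(((a - b) * sp[1:2])^2))
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  # first circle: seeded draw among the deepest third of feasible candidates
  ord <- order(-clear_ok, centers[, 1], centers[, 2])
  top <- ord[seq_len(max(1L, ceiling(length(ord) / 3)))]
  first <- withr_seed(top[sample.int(length(top), 1)])
  placed <- list(centers[first, ])

  for (k in 2:3) {
    ok <- vapply(seq_len(nrow(centers)), function(r) {
      all(vapply(placed, function(p) mm(centers[r, ], p) >= 2 * roi_radius_mm,
                 logical(1)))
    }, logical(1))
    if (!any(ok)) {
      stop(sprintf("cannot fit 3 disjoint circles of radius %.2f mm; try a smaller radius (max feasible single-circle radius %.2f mm)",
                   roi_radius_mm, max(clear_ok)))
    }
    cand <- which(ok)
    score <- vapply(cand, function(r) {
      min(vapply(placed, function(p) mm(centers[r, ], p), numeric(1)))
    }, numeric(1))
    best <- cand[score >= max(score) - 1e-9]
    best <- best[order(centers[best, 1], centers[best, 2])][1]
    placed[[k]] <- centers[best, ]
  }

  d2 <- dim(region)
  gx <- matrix(seq_len(d2[1]), d2[1], d2[2])
  gy <- matrix(seq_len(d2[2]), d2[1], d2[2], byrow = TRUE)
  vals2d <- values[, , slice]
  per_roi <- vapply(placed, function(p) {
    disk <- ((gx - p[1]) * sp[1])^2 + ((gy - p[2]) * sp[2])^2 <=
      roi_radius_mm^2
    mean(vals2d[disk & region])
  }, numeric(1))

  structure(list(roi_centers = cbind(do.call(rbind, placed), slice),
                 roi_radius = roi_radius_mm, per_roi_means = per_roi,
                 summary_mean = mean(per_roi), slice = slice),
            class = "roi_measurement")
}

#' @export
print.roi_measurement <- function(x, ...) {
  cat(sprintf("three-ROI measurement on slice %d: %s -> mean %.3f\n",
              x$slice, paste(sprintf("%.3f", x$per_roi_means),
                             collapse = ", "),
              x$summary_mean))
  invisible(x)
}
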