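#' Feature-bank configuration
#'
#' Controls the image-transform bank and the intensity discretization used
#' for texture matrices. The default bank has 20 members: the identity
#' ("original") image, 8 stationary Haar wavelet sub-bands (LLL..HHH),
#' Laplacian-of-Gaussian at 5 sigmas (1-5 mm), gradient magnitude, square,
#' square-root, logarithm, exponential, and a 6-neighbour 3D local binary
#' pattern map.
#'
#' Discretization: the original image uses a fixed bin width (`bin_width`,
#' intensity units; default 0.1, suited to APTw percent units). Filtered
#' images have arbitrary intensity scales, so they use a fixed bin count
#' (`gray_levels`, default 32). Either route is capped at `max_levels`
#' gray levels to keep texture matrices well-conditioned on small regions.
#'
#' @param transforms Character vector of transform names; must include
#'   "original".
#' @param bin_width Bin width for the original image (> 0).
#' @param gray_levels Bin count for transformed images.
#' @param max_levels Hard cap on gray levels (default 64).
#' @param n_habitats Number of habitats expected per tumor (default 3).
#' @return A `feature_bank_config` list.
#' @export
feature_bank_config <- function(transforms = default_transforms(),
                                bin_width = 0.1, gray_levels = 32L,
                                max_levels = 64L, n_habitats = 3L) {
  if (!"original" %in% transforms) {
    stop("the identity transform ('original') must be present")
  }
  if (bin_width <= 0) stop("bin_width must be > 0")
  unknown <- setdiff(transforms, default_transforms())
  if (length(unknown)) stop("unknown transforms: ", paste(unknown, collapse = ", "))
  structure(list(transforms = transforms, bin_width = bin_width,
                 gray_levels = as.integer(gray_levels),
                 max_levels = as.integer(max_levels),
                 n_habitats = as.integer(n_habitats)),
            class = "feature_bank_config")
}

#' @rdname feature_bank_config
#' @export
default_transforms <- function() {
  c("original",
    paste0("wavelet_", c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL",
                         "HHH")),
    paste0("log_sigma_", 1:5, "_0_mm_3D"),
    "gradient", "square", "squareroot", "logarithm", "exponential",
    "lbp_3D")
}

# ---------------------------------------------------------------------------
# Image transforms (whole-volume, intensity-only except the spatial filters)
# ---------------------------------------------------------------------------

# 1D convolution along an axis with edge replication.
conv_axis <- function(a, kernel, axis) {
  d <- dim(a)
  half <- (length(kernel) - 1) / 2
  out <- array(0, d)
  for (t in seq_along(kernel)) {
    shift <- t - 1 - half
    idx <- pmin(pmax(seq_len(d[axis]) + shift, 1), d[axis])
    sl <- switch(axis,
                 a[idx, , , drop = FALSE],
                 a[, idx, , drop = FALSE],
                 a[, , idx, drop = FALSE])
    out <- out + kernel[t] * sl
  }
  out
}

gaussian_kernel <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  half <- max(1L, ceiling(3 * sigma_vox))
  x <- -half:half
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Laplacian of Gaussian, sigma in mm, spacing-aware.
log_filter <- function(a, sigma_mm, spacing) {
  sm <- a
  for (ax in 1:3) {
    sm <- conv_axis(sm, gaussian_kernel(sigma_mm / spacing[ax]), ax)
  }
  lap <- array(0, dim(a))
  for (ax in 1:3) {
    lap <- lap + conv_axis(sm, c(1, -2, 1), ax) / spacing[ax]^2
  }
  lap
}

gradient_magnitude <- function(a, spacing) {
  g2 <- array(0, dim(a))
  for (ax in 1:3) {
    g <- conv_axis(a, c(0.5, 0, -0.5), ax) / spacing[ax]
    g2 <- g2 + g^2
  }
  sqrt(g2)
}

# Stationary (undecimated) single-level Haar sub-band; code like "LHH".
haar_band <- function(a, code) {
  out <- a
  for (ax in 1:3) {
    k <- if (substr(code, ax, ax) == "L") c(1, 1) / sqrt(2)
         else c(1, -1) / sqrt(2)
    # 2-tap kernel: pair each voxel with its +1 neighbour (edge replicated)
    d <- dim(out)
    idx <- pmin(seq_len(d[ax]) + 1, d[ax])
    nb <- switch(ax,
                 out[idx, , , drop = FALSE],
                 out[, idx, , drop = FALSE],
                 out[, , idx, drop = FALSE])
    out <- k[1] * out + k[2] * nb
  }
  out
}

# 6-neighbour 3D local binary pattern code (0..63), edge replicated.
lbp3d <- function(a) {
  d <- dim(a)
  code <- array(0, d)
  bit <- 1
  for (ax in 1:3) for (s in c(-1, 1)) {
    idx <- pmin(pmax(seq_len(d[ax]) + s, 1), d[ax])
    nb <- switch(ax,
                 a[idx, , , drop = FALSE],
                 a[, idx, , drop = FALSE],
                 a[, , idx, drop = FALSE])
    code <- code + bit * (nb > a)
    bit <- bit * 2
  }
  code
}

# Monotone intensity maps on shifted-positive intensities, scale-preserving.
intensity_map <- function(a, kind) {
  x <- a - min(a)
  mx <- max(x)
  if (mx == 0) return(x)
  switch(kind,
         square = x^2 / mx,
         squareroot = sqrt(x * mx),
         logarithm = log1p(x) * mx / log1p(mx),
         exponential = expm1(x / mx * log1p(mx)),
         stop("unknown intensity map: ", kind))
}

#' Apply a named transform from the feature bank
#'
#' @param vol A `volume`.
#' @param name A transform name from [default_transforms()].
#' @return A `volume` of transformed intensities on the same grid.
#' @export
apply_transform <- function(vol, name) {
  a <- vol_data(vol)
  sp <- vox_spacing(vol)
  out <-
    if (name == "original") a
    else if (grepl("^wavelet_", name)) haar_band(a, sub("^wavelet_", "", name))
    else if (grepl("^log_sigma_", name)) {
      sigma <- as.numeric(sub("^log_sigma_(\\d+)_(\\d+)_mm_3D$", "\\1.\\2",
                              name))
      log_filter(a, sigma, sp)
    }
    else if (name == "gradient") gradient_magnitude(a, sp)
    else if (name == "lbp_3D") lbp3d(a)
    else intensity_map(a, name)
  volume(out, spacing = sp)
}

# ---------------------------------------------------------------------------
# Shape features (geometry only; intensity-independent)
# ---------------------------------------------------------------------------

SHAPE_NAMES <- c("VoxelVolume", "SurfaceArea", "SurfaceVolumeRatio",
                 "Sphericity", "Compactness1", "Compactness2",
                 "SphericalDisproportion", "Maximum3DDiameter",
                 "Maximum2DDiameterSlice", "MajorAxisLength",
                 "MinorAxisLength", "LeastAxisLength", "Elongation",
                 "Flatness")

# Neighbour values along an axis, out-of-grid treated as background.
shift_bg <- function(reg, ax, s) {
  d <- dim(reg)
  out <- array(FALSE, d)
  n <- d[ax]
  src <- if (s == 1) 2:n else 1:(n - 1)
  dst <- if (s == 1) 1:(n - 1) else 2:n
  if (ax == 1) out[dst, , ] <- reg[src, , ]
  else if (ax == 2) out[, dst, ] <- reg[, src, ]
  else out[, , dst] <- reg[, , src]
  out
}

# Surface voxels: in-region voxels with at least one 6-neighbour outside.
surface_voxels <- function(reg) {
  all_in <- reg
  for (ax in 1:3) for (s in c(-1, 1)) {
    all_in <- all_in & shift_bg(reg, ax, s)
  }
  reg & !all_in
}

# Surface area by the coarea formula: smooth the binary indicator with a
# small Gaussian and integrate the gradient magnitude. Accurate to ~1% for
# smooth blob-like regions a few voxels across (tumors); underestimates
# sharp-cornered regions by up to ~15%. Avoids carrying a marching-cubes
# triangle table.
surface_area_coarea <- function(reg, spacing, sigma_mm = NULL) {
  if (is.null(sigma_mm)) sigma_mm <- 0.7 * min(spacing)
  pad <- ceiling(3 * sigma_mm / min(spacing)) + 1
  d <- dim(reg)
  big <- array(0, d + 2 * pad)
  big[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <-
    as.numeric(reg)
  sm <- big
  for (ax in 1:3) sm <- conv_axis(sm, gaussian_kernel(sigma_mm / spacing[ax]), ax)
  g2 <- array(0, dim(sm))
  for (ax in 1:3) {
    g <- conv_axis(sm, c(0.5, 0, -0.5), ax) / spacing[ax]
    g2 <- g2 + g^2
  }
  sum(sqrt(g2)) * prod(spacing)
}

#' Geometric shape features of a region
#'
#' 14 intensity-independent descriptors of a voxel region: voxel volume,
#' surface area (coarea-formula estimate on the smoothed indicator),
#' surface/volume ratio, sphericity, the two classical compactness
#' variants, spherical disproportion, maximum 3D diameter and maximum
#' in-plane (axial) diameter from surface voxels, the three PCA axis
#' lengths, elongation and flatness.
#'
#' @param mask_region Binary `volume` (or array with spacing) selecting the
#'   region.
#' @param spacing Voxel spacing in mm (taken from the volume if absent).
#' @return Named numeric vector of length 14.
#' @export
shape_features <- function(mask_region, spacing = NULL) {
  reg <- vol_data(mask_region) > 0
  if (!any(reg)) stop("empty region")
  if (is.null(spacing)) spacing <- vox_spacing(mask_region)
  n <- sum(reg)
  vol <- n * prod(spacing)
  sa <- surface_area_coarea(reg, spacing)
  spher <- pi^(1 / 3) * (6 * vol)^(2 / 3) / sa

  surf <- which(surface_voxels(reg), arr.ind = TRUE)
  pts <- sweep(surf, 2, spacing, "*")
  max3d <- if (nrow(pts) > 1) cpp_max_pairwise_dist(pts) else 0
  max2d <- 0
  for (sl in unique(surf[, 3])) {
    p2 <- pts[surf[, 3] == sl, 1:2, drop = FALSE]
    if (nrow(p2) > 1) {
      max2d <- max(max2d, cpp_max_pairwise_dist(cbind(p2, 0)))
    }
  }

  coords <- which(reg, arr.ind = TRUE)
  cm <- sweep(coords, 2, spacing, "*")
  ev <- if (nrow(cm) > 1) {
    sort(pmax(eigen(stats::cov(cm), symmetric = TRUE,
                    only.values = TRUE)$values, 0), decreasing = TRUE)
  } else c(0, 0, 0)
  axes <- 4 * sqrt(ev)
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1
  flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1

  out <- c(vol, sa, sa / vol, spher,
           vol / (sqrt(pi) * sa^1.5),
           36 * pi * vol^2 / sa^3,
           1 / spher, max3d, max2d, axes[1], axes[2], axes[3], elong, flat)
  names(out) <- SHAPE_NAMES
  out
}

# ---------------------------------------------------------------------------
# First-order features
# ---------------------------------------------------------------------------

FIRSTORDER_NAMES <- c("Mean", "Median", "Minimum", "Maximum", "Range",
                      "Variance", "Skewness", "Kurtosis", "Energy",
                      "TotalEnergy", "Entropy", "Uniformity",
                      "10Percentile", "90Percentile",
                      "InterquartileRange", "MeanAbsoluteDeviation",
                      "RobustMeanAbsoluteDeviation", "RootMeanSquared")

#' First-order intensity features
#'
#' 18 distribution descriptors of the in-region intensities. Moments use
#' the population convention (divide by N); kurtosis is non-excess (3 for
#' a normal distribution); percentiles interpolate linearly between
#' closest ranks; entropy and uniformity use a fixed-bin-width histogram.
#'
#' @param values Numeric vector of in-region intensities.
#' @param bin_width Histogram bin width for entropy/uniformity.
#' @param voxel_volume Voxel volume in mm^3 (for TotalEnergy; default 1).
#' @return Named numeric vector of length 18.
#' @export
firstorder_features <- function(values, bin_width = 0.1, voxel_volume = 1) {
  x <- as.numeric(values)
  if (!length(x)) stop("empty region")
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  sdv <- sqrt(m2)
  skew <- if (sdv > 0) mean((x - mu)^3) / sdv^3 else 0
  kurt <- if (m2 > 0) mean((x - mu)^4) / m2^2 else 0
  q <- stats::quantile(x, c(0.1, 0.25, 0.75, 0.9), type = 7, names = FALSE)
  inr <- x[x >= q[1] & x <= q[4]]
  rmad <- if (length(inr)) mean(abs(inr - mean(inr))) else 0
  lv <- discretize_fbw(x, bin_width)
  p <- tabulate(lv$levels) / n
  p <- p[p > 0]
  c(stats::setNames(
    c(mu, stats::median(x), min(x), max(x), max(x) - min(x), m2, skew, kurt,
      sum(x^2), voxel_volume * sum(x^2), -sum(p * log2(p)), sum(p^2),
      q[1], q[4], q[3] - q[2], mean(abs(x - mu)), rmad, sqrt(mean(x^2))),
    FIRSTORDER_NAMES))
}

# Fixed-bin-width discretization to levels 1..Ng, capped at max_levels.
discretize_fbw <- function(x, bin_width, max_levels = 64L) {
  rng <- max(x) - min(x)
  if (rng == 0) return(list(levels = rep(1L, length(x)), ng = 1L))
  ng_raw <- floor(rng / bin_width) + 1L
  if (ng_raw > max_levels) bin_width <- rng / (max_levels - 1L)
  lv <- as.integer(floor((x - min(x)) / bin_width)) + 1L
  list(levels = lv, ng = max(lv))
}

# Fixed-bin-count discretization.
discretize_fbn <- function(x, n_bins) {
  rng <- max(x) - min(x)
  if (rng == 0) return(list(levels = rep(1L, length(x)), ng = 1L))
  lv <- pmin(as.integer(floor((x - min(x)) / rng * n_bins)) + 1L, n_bins)
  list(levels = lv, ng = as.integer(n_bins))
}

# ---------------------------------------------------------------------------
# Texture features from count matrices
# ---------------------------------------------------------------------------

glcm_features <- function(P) {
  ng <- nrow(P)
  tot <- sum(P)
  nm <- paste0("glcm_", c("Autocorrelation", "JointAverage",
                          "ClusterProminence", "ClusterShade",
                          "ClusterTendency", "Contrast", "Correlation",
                          "DifferenceAverage", "DifferenceEntropy",
                          "DifferenceVariance", "JointEnergy",
                          "JointEntropy", "Imc1", "Imc2", "Idm", "Idmn",
                          "Id", "Idn", "InverseVariance",
                          "MaximumProbability", "SumAverage", "SumEntropy",
                          "SumSquares", "MCC"))
  if (tot == 0 || ng == 1) {
    out <- stats::setNames(rep(0, 24), nm)
    out["glcm_Correlation"] <- 1; out["glcm_JointEnergy"] <- 1
    out["glcm_Idm"] <- 1; out["glcm_Idmn"] <- 1; out["glcm_Id"] <- 1
    out["glcm_Idn"] <- 1; out["glcm_MaximumProbability"] <- 1
    out["glcm_MCC"] <- 1; out["glcm_Imc2"] <- 0
    out["glcm_JointAverage"] <- 1; out["glcm_SumAverage"] <- 2
    out["glcm_Autocorrelation"] <- 1
    return(out)
  }
  p <- P / tot
  i <- row(p); j <- col(p)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(i * p); muy <- sum(j * p)
  sx <- sqrt(sum((i - mux)^2 * p)); sy <- sqrt(sum((j - muy)^2 * p))
  # sum / difference distributions
  ks <- 2:(2 * ng)
  psum <- vapply(ks, function(k) sum(p[i + j == k]), numeric(1))
  kd <- 0:(ng - 1)
  pdiff <- vapply(kd, function(k) sum(p[abs(i - j) == k]), numeric(1))
  ent <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  hxy <- ent(p)
  pxpy <- outer(px, py)
  hxy1 <- -sum(p[pxpy > 0] * log2(pxpy[pxpy > 0]))
  hxy2 <- ent(pxpy)
  hx <- ent(px); hy <- ent(py)
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  da <- sum(kd * pdiff)
  off <- i != j
  # MCC: sqrt of the second-largest eigenvalue of
  # Q(i,j) = sum_k p(i,k) p(j,k) / (px(i) py(k))
  mcc <- tryCatch({
    Q <- matrix(0, ng, ng)
    for (kk in seq_len(ng)) {
      if (py[kk] > 0) {
        Q <- Q + outer(p[, kk] / ifelse(px > 0, px, 1), p[, kk] / py[kk])
      }
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, ev[min(2, length(ev))]))
  }, error = function(e) NA_real_)
  stats::setNames(c(
    sum(i * j * p), mux,
    sum((i + j - mux - muy)^4 * p), sum((i + j - mux - muy)^3 * p),
    sum((i + j - mux - muy)^2 * p), sum((i - j)^2 * p),
    if (sx > 0 && sy > 0) (sum(i * j * p) - mux * muy) / (sx * sy) else 1,
    da, ent(pdiff), sum((kd - da)^2 * pdiff),
    sum(p^2), hxy, imc1, imc2,
    sum(p / (1 + (i - j)^2)), sum(p / (1 + ((i - j) / ng)^2)),
    sum(p / (1 + abs(i - j))), sum(p / (1 + abs(i - j) / ng)),
    if (any(off)) sum(p[off] / (i[off] - j[off])^2) else 0,
    max(p), sum(ks * psum), ent(psum), sum((i - mux)^2 * p), mcc), nm)
}

# Shared algebra for run-length-style matrices P(g, s) with "size" s.
rl_style_features <- function(P, prefix, size_names) {
  g <- row(P); s <- col(P)
  nr <- sum(P)
  np_tot <- sum(P * s)
  p <- P / nr
  mu_g <- sum(g * p); mu_s <- sum(s * p)
  pe <- p[p > 0]
  vals <- c(
    sum(P / s^2) / nr,                 # small emphasis
    sum(P * s^2) / nr,                 # large emphasis
    sum(rowSums(P)^2) / nr,            # gray-level nonuniformity
    sum(rowSums(P)^2) / nr^2,          # GLN normalised
    sum(colSums(P)^2) / nr,            # size nonuniformity
    sum(colSums(P)^2) / nr^2,          # size nonuniformity normalised
    nr / np_tot,                       # percentage
    sum((g - mu_g)^2 * p),             # gray-level variance
    sum((s - mu_s)^2 * p),             # size variance
    -sum(pe * log2(pe)),               # entropy
    sum(P / g^2) / nr,                 # low gray-level emphasis
    sum(P * g^2) / nr,                 # high gray-level emphasis
    sum(P / (g^2 * s^2)) / nr,
    sum(P * g^2 / s^2) / nr,
    sum(P * s^2 / g^2) / nr,
    sum(P * g^2 * s^2) / nr)
  stats::setNames(vals, paste0(prefix, size_names))
}

glrlm_features <- function(P) {
  rl_style_features(P, "glrlm_",
    c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
      "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
      "RunLengthNonUniformityNormalized", "RunPercentage",
      "GrayLevelVariance", "RunVariance", "RunEntropy",
      "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
      "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
      "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis"))
}

glszm_features <- function(P) {
  rl_style_features(P, "glszm_",
    c("SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
      "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
      "SizeZoneNonUniformityNormalized", "ZonePercentage",
      "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
      "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
      "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
      "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis"))
}

gldm_features <- function(P) {
  # dependence size = dependent-neighbour count + 1 (so sizes start at 1)
  keep <- colSums(P) > 0
  last <- max(which(keep), 1)
  P <- P[, seq_len(last), drop = FALSE]
  f <- rl_style_features(P, "gldm_",
    c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
      "GrayLevelNonUniformity", "GLNN_drop", "DependenceNonUniformity",
      "DependenceNonUniformityNormalized", "Percentage_drop",
      "GrayLevelVariance", "DependenceVariance", "DependenceEntropy",
      "LowGrayLevelEmphasis", "HighGrayLevelEmphasis",
      "SmallDependenceLowGrayLevelEmphasis",
      "SmallDependenceHighGrayLevelEmphasis",
      "LargeDependenceLowGrayLevelEmphasis",
      "LargeDependenceHighGrayLevelEmphasis"))
  f[!grepl("_drop$", names(f))]   # GLDM defines 14 of the 16
}

ngtdm_features <- function(s, n) {
  nm <- paste0("ngtdm_", c("Coarseness", "Contrast", "Busyness",
                           "Complexity", "Strength"))
  ntot <- sum(n)
  p <- n / ntot
  act <- which(p > 0)
  ngp <- length(act)
  i <- seq_along(p)
  coarse <- { d <- sum(p * s); if (d > 0) 1 / d else 1e6 }
  contrast <- if (ngp > 1) {
    (sum(outer(p[act], p[act]) * outer(i[act], i[act], "-")^2) /
       (ngp * (ngp - 1))) * (sum(s) / ntot)
  } else 0
  busy <- {
    d <- sum(abs(outer(i[act] * p[act], i[act] * p[act], "-")))
    if (d > 0) sum(p * s) / d else 0
  }
  complexity <- if (ngp >= 1) {
    acc <- 0
    for (a in act) for (b in act) {
      acc <- acc + abs(a - b) * (p[a] * s[a] + p[b] * s[b]) / (p[a] + p[b])
    }
    acc / ntot
  } else 0
  strength <- {
    d <- sum(s)
    if (d > 0) {
      sum(vapply(act, function(a) sum((p[a] + p[act]) * (a - i[act])^2),
                 numeric(1))) / d
    } else 0
  }
  stats::setNames(c(coarse, contrast, busy, complexity, strength), nm)
}

#' Texture features of a discretized region
#'
#' Computes 75 texture descriptors from five matrix families: GLCM (24,
#' 13 symmetric directions merged), GLRLM (16, 13 directions merged),
#' GLSZM (16, 26-connected zones), GLDM (14, dependence alpha = 0), and
#' NGTDM (5). Definitions follow the IBSI reference formulations.
#'
#' @param region_volume Numeric 3D array of intensities with NA (or the
#'   `region` argument) marking out-of-region voxels.
#' @param region Binary array selecting the region.
#' @param n_levels Gray-level count for fixed-bin-count discretization, or
#'   NULL to use `bin_width`.
#' @param bin_width Fixed bin width (used when `n_levels` is NULL).
#' @return Named numeric vector of length 75.
#' @export
texture_features <- function(region_volume, region, n_levels = 32L,
                             bin_width = NULL) {
  a <- vol_data(region_volume)
  reg <- vol_data(region) > 0
  vals <- a[reg]
  if (length(vals) < 2) stop("region must contain at least 2 voxels")
  dsc <- if (is.null(n_levels)) discretize_fbw(vals, bin_width)
         else discretize_fbn(vals, n_levels)
  if (dsc$ng == 1) {
    warning("single gray level in region; texture features take limit values")
  }
  # crop to bounding box for speed
  idx <- which(reg, arr.ind = TRUE)
  rng <- apply(idx, 2, range)
  sub <- reg[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2], rng[1, 3]:rng[2, 3],
             drop = FALSE]
  # column-major in-region ordering is preserved under bounding-box cropping
  disc <- array(0L, dim(sub))
  disc[sub] <- dsc$levels
  dims <- as.integer(dim(sub))
  ng <- dsc$ng
  c(glcm_features(cpp_glcm(as.integer(disc), dims, ng)),
    glrlm_features(cpp_glrlm(as.integer(disc), dims, ng)),
    glszm_features(cpp_glszm(as.integer(disc), dims, ng)),
    gldm_features(cpp_gldm(as.integer(disc), dims, ng, 0L)),
    { r <- cpp_ngtdm(as.integer(disc), dims, ng); ngtdm_features(r$s, r$n) })
}

# ---------------------------------------------------------------------------
# Cohort-level feature table
# ---------------------------------------------------------------------------

#' Extract the per-habitat radiomic feature table for a cohort
#'
#' For every patient and every habitat: 14 shape features (computed once,
#' on geometry only) plus, per transform in the bank, 18 first-order and
#' 75 texture features. Column names encode transform, family, feature and
#' habitat as underscore-joined tokens, e.g.
#' `wavelet_LLL_firstorder_10Percentile_h3`. With the default 20-transform
#' bank this gives 14 + 20 x 93 = 1874 columns per habitat.
#'
#' @param cohort List of patients; each needs `patient_id`, `volume_aptw`.
#' @param habitat_maps List of `habitat_map`s aligned with `cohort`.
#' @param config A [feature_bank_config()].
#' @param progress Print per-patient progress (default FALSE).
#' @return A `feature_table`: data.frame with `patient_id` plus numeric
#'   feature columns; attribute `flagged` lists patients with missing
#'   habitats (their habitat columns are NA).
#' @export
extract_feature_table <- function(cohort, habitat_maps,
                                  config = feature_bank_config(),
                                  progress = FALSE) {
  stopifnot(length(cohort) == length(habitat_maps))
  rows <- vector("list", length(cohort))
  flagged <- character(0)
  for (pi in seq_along(cohort)) {
    pat <- cohort[[pi]]
    hm <- habitat_maps[[pi]]
    check_same_geometry(pat$volume_aptw, hm$labels, "volume and habitat map")
    tvols <- lapply(config$transforms, function(tr) {
      apply_transform(pat$volume_aptw, tr)
    })
    names(tvols) <- config$transforms
    lab <- vol_data(hm$labels)
    sp <- vox_spacing(pat$volume_aptw)
    feats <- list()
    for (h in seq_len(config$n_habitats)) {
      reg <- lab == h
      tag <- paste0("_h", h)
      if (sum(reg) < 2) {
        flagged <- c(flagged, pat$patient_id)
        feats[[length(feats) + 1]] <-
          stats::setNames(rep(NA_real_, per_habitat_ncol(config)),
                          habitat_colnames(config, h))
        next
      }
      sh <- shape_features(volume(array(as.numeric(reg), dim(reg)),
                                  spacing = sp))
      names(sh) <- paste0("original_shape_", names(sh), tag)
      block <- list(sh)
      for (tr in config$transforms) {
        v <- vol_data(tvols[[tr]])
        vals <- v[reg]
        fo <- if (tr == "original") {
          firstorder_features(vals, bin_width = config$bin_width,
                              voxel_volume = prod(sp))
        } else {
          rngv <- diff(range(vals))
          firstorder_features(vals,
                              bin_width = if (rngv > 0)
                                rngv / config$gray_levels else 1,
                              voxel_volume = prod(sp))
        }
        names(fo) <- paste0(tr, "_firstorder_", names(fo), tag)
        tx <- suppressWarnings(
          if (tr == "original") {
            texture_features(v, reg, n_levels = NULL,
                             bin_width = config$bin_width)
          } else {
            texture_features(v, reg, n_levels = config$gray_levels)
          })
        names(tx) <- paste0(tr, "_", names(tx), tag)
        block[[length(block) + 1]] <- c(fo, tx)
      }
      feats[[length(feats) + 1]] <- unlist(block)
    }
    rows[[pi]] <- unlist(feats)
    if (progress) {
      message(sprintf("features: patient %d/%d (%s)", pi, length(cohort),
                      pat$patient_id))
    }
  }
  mat <- do.call(rbind, rows)
  out <- data.frame(patient_id = vapply(cohort, `[[`, "", "patient_id"),
                    mat, check.names = FALSE, stringsAsFactors = FALSE)
  attr(out, "flagged") <- unique(flagged)
  class(out) <- c("feature_table", class(out))
  out
}

per_habitat_ncol <- function(config) {
  14L + length(config$transforms) * 93L
}

habitat_colnames <- function(config, h) {
  tag <- paste0("_h", h)
  shape <- paste0("original_shape_", SHAPE_NAMES, tag)
  per_tr <- unlist(lapply(config$transforms, function(tr) {
    fo <- paste0(tr, "_firstorder_", FIRSTORDER_NAMES, tag)
    tx <- paste0(tr, "_", texture_feature_names(), tag)
    c(fo, tx)
  }))
  c(shape, per_tr)
}

texture_feature_names <- function() {
  dummy_gl <- matrix(c(2, 1, 1, 2), 2, 2)
  dummy_sz <- matrix(c(1, 0, 0, 1), 2, 2)
  c(names(glcm_features(dummy_gl)), names(glrlm_features(dummy_sz)),
    names(glszm_features(dummy_sz)),
    names(gldm_features(matrix(1, 2, 3))),
    names(ngtdm_features(c(0.5, 0.5), c(2, 2))))
}
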