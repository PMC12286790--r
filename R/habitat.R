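VOXEL_FEATURE_NAMES <- c("mean", "variance", "skewness", "kurtosis", "min",
                         "max", "range", "energy", "entropy",
                         "glcm_contrast", "glcm_homogeneity",
                         "glcm_correlation", "glcm_energy")

#' Voxel-level local radiomic features
#'
#' Slides a 3x3x3 window over the tumor and computes 13 local descriptors
#' per in-mask voxel: 9 first-order (mean, variance, skewness, kurtosis,
#' min, max, range, energy, 8-bin Shannon entropy) and 4 co-occurrence
#' descriptors (contrast, homogeneity, correlation, energy) on the window
#' re-discretized to 8 gray levels. The window is restricted to the mask;
#' voxels with fewer than `min_neighbors` in-mask neighbours are excluded
#' so that poorly-supported edge estimates never enter the clustering.
#'
#' @param vol A `volume` of intensities (e.g. an APTw map).
#' @param mask Binary volume on the same grid.
#' @param min_neighbors Minimum in-mask neighbours required (default 26,
#'   i.e. full windows only; truncated edge windows bias the
#'   scale-dependent descriptors and contaminate the clustering, so edge
#'   voxels are labelled afterwards by spatial propagation in
#'   [select_habitats()]).
#' @return A `voxel_feature_map`: `index` (linear voxel indices into the
#'   grid), `features` (voxels x 13 matrix), `feature_names`, `dims`,
#'   `spacing`.
#' @export
extract_voxel_features <- function(vol, mask, min_neighbors = 26L) {
  mask_arr <- vol_data(mask) > 0
  check_same_geometry(vol, mask)
  if (!any(mask_arr)) stop("empty mask")
  if (any(dim(vol) < 3)) stop("each volume axis must be >= 3 for a 3x3x3 window")
  v <- vol_data(vol)
  v[!mask_arr] <- 0   # never read outside mask, but keep finite
  gmin <- min(v[mask_arr]); gmax <- max(v[mask_arr])
  res <- cpp_voxel_features(as.numeric(v), as.integer(mask_arr),
                            as.integer(dim(v)), as.integer(min_neighbors),
                            gmin, gmax)
  if (length(res$index) < 32L && min_neighbors > 8L) {
    # tiny or sheet-like masks admit too few full windows; fall back to
    # the mask-restricted windows so small tumors remain clusterable
    res <- cpp_voxel_features(as.numeric(v), as.integer(mask_arr),
                              as.integer(dim(v)), 8L, gmin, gmax)
  }
  colnames(res$features) <- VOXEL_FEATURE_NAMES
  structure(list(index = res$index, features = res$features,
                 feature_names = VOXEL_FEATURE_NAMES, dims = dim(v),
                 spacing = vox_spacing(vol), mask_index = which(mask_arr)),
            class = "voxel_feature_map")
}

#' @export
print.voxel_feature_map <- function(x, ...) {
  cat(sprintf("<voxel_feature_map: %d voxels x %d features>\n",
              nrow(x$features), ncol(x$features)))
  invisible(x)
}

# z-score columns; zero-variance columns become 0.
zscore_cols <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0] <- 1
  sweep(sweep(x, 2, mu), 2, sdv, "/")
}

# k-means++ initial centers (Arthur & Vassilvitskii); expects RNG to be set.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  i <- sample.int(n, 1)
  centers[1, ] <- x[i, ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  if (k > 1) for (j in 2:k) {
    if (all(d2 == 0)) i <- sample.int(n, 1)
    else i <- sample.int(n, 1, prob = d2)
    centers[j, ] <- x[i, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  centers
}

#' K-means partition of voxel features
#'
#' Lloyd iterations with k-means++ seeding, multiple restarts, on
#' within-tumor z-scored features. Deterministic given `seed`.
#'
#' @param fmap A `voxel_feature_map`, or a plain numeric matrix.
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @param nstart Restarts (default 10).
#' @param iter_max Maximum Lloyd iterations (default 300).
#' @return List with `cluster` (integer labels per voxel/row), `centers`
#'   (in z-scored space), `inertia` (total within-cluster sum of squares).
#' @export
kmeans_partition <- function(fmap, k, seed = 1L, nstart = 10L,
                             iter_max = 300L) {
  x <- if (inherits(fmap, "voxel_feature_map")) fmap$features else as.matrix(fmap)
  n <- nrow(x)
  if (k > n) stop("k (", k, ") exceeds the number of voxels (", n, ")")
  if (k < 1) stop("k must be >= 1")
  xz <- zscore_cols(x)
  best <- NULL
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  for (s in seq_len(nstart)) {
    cen <- kmeanspp_centers(xz, k)
    km <- tryCatch(
      suppressWarnings(stats::kmeans(xz, centers = cen, iter.max = iter_max,
                                     algorithm = "Lloyd")),
      error = function(e) NULL)
    if (is.null(km)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss - 1e-6) best <- km
  }
  if (is.null(best)) stop("k-means failed for k = ", k)
  list(cluster = best$cluster, centers = best$centers,
       inertia = best$tot.withinss)
}

#' Calinski-Harabasz index
#'
#' Ratio of between- to within-cluster dispersion normalised by degrees of
#' freedom: CH = (trace(B)/(k-1)) / (trace(W)/(n-k)).
#'
#' @param features Numeric matrix (observations x variables).
#' @param labeling Integer cluster labels (each cluster nonempty).
#' @return Scalar index value.
#' @export
calinski_harabasz <- function(features, labeling) {
  x <- as.matrix(features)
  lab <- as.integer(factor(labeling))
  k <- max(lab)
  n <- nrow(x)
  if (k < 2) stop("need at least 2 clusters")
  if (length(unique(lab)) != k || any(tabulate(lab, k) == 0)) {
    stop("every cluster must be nonempty")
  }
  g <- colMeans(x)
  tr_b <- 0; tr_w <- 0
  for (j in seq_len(k)) {
    xi <- x[lab == j, , drop = FALSE]
    cj <- colMeans(xi)
    tr_b <- tr_b + nrow(xi) * sum((cj - g)^2)
    tr_w <- tr_w + sum(sweep(xi, 2, cj)^2)
  }
  (tr_b / (k - 1)) / (tr_w / (n - k))
}

#' Partition a tumor into habitats
#'
#' Clusters voxel-level local features with k-means for every candidate
#' cluster count, selects the count maximising the Calinski-Harabasz index
#' (ties toward the smaller K), and relabels habitats in ascending order of
#' mean APTw so that the highest habitat index always denotes the
#' highest-signal subregion ("h3" when K = 3) and is comparable across
#' patients.
#'
#' @param fmap A `voxel_feature_map`.
#' @param vol_aptw The APTw `volume` used for the ordering key.
#' @param k_range Candidate cluster counts (default 3:10).
#' @param seed Integer seed.
#' @return A `habitat_map`: `labels` (integer `volume`, 0 = background),
#'   `k`, `ch_scores` (named by K), `ordering_key` (mean APTw per habitat),
#'   `index` (voxel indices that were clustered).
#' @export
select_habitats <- function(fmap, vol_aptw, k_range = 3:10, seed = 1L) {
  stopifnot(inherits(fmap, "voxel_feature_map"))
  n <- nrow(fmap$features)
  if (n < 10) stop("need at least 10 clusterable voxels, got ", n)
  k_range <- sort(unique(as.integer(k_range)))
  if (max(k_range) > n) {
    k_range <- k_range[k_range <= n]
    warning("k range shrunk to ", paste(range(k_range), collapse = ".."),
            " (only ", n, " voxels)")
    if (!length(k_range) || max(k_range) < 3) {
      stop("too few voxels for habitat partitioning")
    }
  }
  fits <- lapply(k_range, function(k) {
    kmeans_partition(fmap, k, seed = seed + k)
  })
  ch <- vapply(seq_along(k_range), function(i) {
    calinski_harabasz(zscore_cols(fmap$features), fits[[i]]$cluster)
  }, numeric(1))
  names(ch) <- as.character(k_range)
  best <- which(ch >= max(ch) - 1e-9)
  pick <- best[which.min(k_range[best])]   # parsimony on ties
  k <- k_range[pick]
  cl <- fits[[pick]]$cluster

  aptw_vals <- vol_data(vol_aptw)[fmap$index]
  key <- vapply(seq_len(k), function(j) mean(aptw_vals[cl == j]), numeric(1))
  relabel <- match(seq_len(k), order(key))  # old label -> rank by mean APTw
  cl_ord <- relabel[cl]

  labels <- array(0L, dim = fmap$dims)
  labels[fmap$index] <- cl_ord
  # complete the partition: in-mask voxels without a full window inherit
  # the label of the nearest clustered voxel by iterative propagation
  remaining <- setdiff(fmap$mask_index, fmap$index)
  if (length(remaining)) {
    labels <- propagate_labels(labels, remaining)
  }
  structure(list(labels = volume(labels, spacing = fmap$spacing), k = k,
                 ch_scores = ch,
                 ordering_key = sort(key), index = fmap$index,
                 cluster = cl_ord),
            class = "habitat_map")
}

#' @export
print.habitat_map <- function(x, ...) {
  sizes <- tabulate(x$cluster, x$k)
  cat(sprintf("<habitat_map: K = %d (CH-selected), sizes %s, mean APTw %s>\n",
              x$k, paste(sizes, collapse = "/"),
              paste(sprintf("%.2f", x$ordering_key), collapse = " < ")))
  invisible(x)
}

# Iteratively dilate labels into the given unlabeled voxel set (26-conn).
propagate_labels <- function(labels, remaining) {
  d <- dim(labels)
  ai <- arrayInd(remaining, d)
  for (pass in 1:64) {
    if (!length(remaining)) break
    newlab <- integer(length(remaining))
    for (r in seq_along(remaining)) {
      xs <- max(1, ai[r, 1] - 1):min(d[1], ai[r, 1] + 1)
      ys <- max(1, ai[r, 2] - 1):min(d[2], ai[r, 2] + 1)
      zs <- max(1, ai[r, 3] - 1):min(d[3], ai[r, 3] + 1)
      nb <- labels[xs, ys, zs]
      nb <- nb[nb > 0]
      newlab[r] <- if (length(nb)) {
        as.integer(names(which.max(table(nb))))
      } else 0L
    }
    got <- newlab > 0
    labels[remaining[got]] <- newlab[got]
    remaining <- remaining[!got]
    ai <- ai[!got, , drop = FALSE]
  }
  if (length(remaining)) labels[remaining] <- 1L   # isolated voxels
  labels
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 for identical partitions (up to label permutation), ~0 for unrelated
#' ones. Used to score recovery of planted habitat structure.
#'
#' @param a,b Integer label vectors of equal length.
#' @return Scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("labelings must have equal length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
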