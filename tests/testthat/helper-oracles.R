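# Independent oracles and tiny fixtures, deliberately written in the most
# naive way possible so they share no code path with the implementation.

# Brute-force AUC: concordant-pair counting with half credit for ties.
pair_count_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (x in pos) for (y in neg) {
    total <- total + if (x > y) 1 else if (x == y) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Manual two-way ANOVA ICC(2,1) for a 2-column matrix, textbook formulas.
manual_icc21 <- function(x1, x2) {
  n <- length(x1); k <- 2
  mat <- cbind(x1, x2)
  grand <- mean(mat)
  ms_rows <- k * sum((rowMeans(mat) - grand)^2) / (n - 1)
  ms_cols <- n * sum((colMeans(mat) - grand)^2) / (k - 1)
  ss_tot <- sum((mat - grand)^2)
  ms_err <- (ss_tot - (n - 1) * ms_rows / 1 * 1 -
               (k - 1) * ms_cols / 1) / ((n - 1) * (k - 1))
  # recompute cleanly from sums of squares
  ssr <- k * sum((rowMeans(mat) - grand)^2)
  ssc <- n * sum((colMeans(mat) - grand)^2)
  sse <- ss_tot - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# Naive nested-loop recomputation of the 13 voxel-window descriptors,
# replicating the documented conventions (population moments, global-range
# 8-bin discretization, 13 symmetric co-occurrence directions).
naive_window_features <- function(vol, mask, min_neighbors = 26L) {
  d <- dim(vol)
  gmin <- min(vol[mask]); gmax <- max(vol[mask])
  dirs <- rbind(c(1,0,0), c(0,1,0), c(0,0,1), c(1,1,0), c(1,-1,0),
                c(1,0,1), c(1,0,-1), c(0,1,1), c(0,1,-1), c(1,1,1),
                c(1,1,-1), c(1,-1,1), c(1,-1,-1))
  out <- list(); idx <- integer(0)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    if (!mask[x, y, z]) next
    coords <- list(); vals <- c()
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      xx <- x + dx; yy <- y + dy; zz <- z + dz
      if (xx < 1 || yy < 1 || zz < 1 || xx > d[1] || yy > d[2] ||
          zz > d[3]) next
      if (!mask[xx, yy, zz]) next
      coords[[length(coords) + 1]] <- c(dx, dy, dz)
      vals <- c(vals, vol[xx, yy, zz])
    }
    if (length(vals) - 1 < min_neighbors) next
    n <- length(vals)
    mu <- mean(vals); m2 <- mean((vals - mu)^2)
    sk <- if (m2 > 0) mean((vals - mu)^3) / m2^1.5 else 0
    ku <- if (m2 > 0) mean((vals - mu)^4) / m2^2 else 0
    gr <- gmax - gmin
    lvl <- if (gr > 0) pmin(pmax(floor((vals - gmin) / (gr / 8)), 0), 7) + 1
           else rep(1, n)
    p_hist <- table(factor(lvl, levels = 1:8)) / n
    p_hist <- p_hist[p_hist > 0]
    ent <- -sum(p_hist * log2(p_hist))
    cooc <- matrix(0, 8, 8)
    key <- sapply(coords, paste, collapse = ",")
    for (i in seq_len(n)) for (k in 1:13) {
      tgt <- coords[[i]] + dirs[k, ]
      if (any(abs(tgt) > 1)) next
      j <- match(paste(tgt, collapse = ","), key)
      if (is.na(j)) next
      cooc[lvl[i], lvl[j]] <- cooc[lvl[i], lvl[j]] + 1
      cooc[lvl[j], lvl[i]] <- cooc[lvl[j], lvl[i]] + 1
    }
    tot <- sum(cooc)
    if (tot > 0) {
      pm <- cooc / tot
      ii <- row(pm) - 1; jj <- col(pm) - 1
      contrast <- sum(pm * (ii - jj)^2)
      homog <- sum(pm / (1 + abs(ii - jj)))
      genergy <- sum(pm^2)
      mi <- sum(ii * pm); mj <- sum(jj * pm)
      vi <- sum((ii - mi)^2 * pm); vj <- sum((jj - mj)^2 * pm)
      corr <- if (vi > 0 && vj > 0) {
        sum((ii - mi) * (jj - mj) * pm) / sqrt(vi * vj)
      } else 1
    } else {
      contrast <- 0; homog <- 1; genergy <- 1; corr <- 1
    }
    idx <- c(idx, x + d[1] * ((y - 1) + d[2] * (z - 1)))
    out[[length(out) + 1]] <- c(mu, m2, sk, ku, min(vals), max(vals),
                                max(vals) - min(vals), sum(vals^2), ent,
                                contrast, homog, corr, genergy)
  }
  list(index = idx, features = do.call(rbind, out))
}

# Small helper cohort configs used across tests (kept tiny for speed).
tiny_cohort_config <- function(seed = 1L, n = 8L, ...) {
  cohort_config(n_patients = n, seed = seed,
                grid_shape = c(24L, 24L, 16L), ...)
}

# Ball mask in an n^3 grid.
ball_mask <- function(r, n) {
  g <- seq_len(n) - (n + 1) / 2
  d2 <- outer(outer(g^2, g^2, "+"), g^2, "+")
  d2 <= r^2
}
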