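#' Synthetic cohort configuration
#'
#' The stated world of the phantom generator. Defaults emulate a cervical
#' cancer APTw cohort: 124 patients at 40% LVSI prevalence, whole-tumor
#' mean APTw near 2.3% in the negative and 4.4% in the positive class,
#' three planted intratumoral subpopulations ("habitats") with the
#' highest-signal subpopulation occupying a larger fraction in positive
#' patients, ADC anti-correlated with APTw, and clinical covariates drawn
#' from log-normal distributions parameterised to the published medians
#' and IQRs (CA125 22.5 U/mL, tumor size 33 mm, BMI 25, age 50).
#'
#' The outcome follows a logistic model in (high-habitat fraction,
#' log CA125, tumor size), conditioned on the exact class split so counts
#' match the prevalence to rounding. Setting `effect_size_aptw = 0` and
#' `label_coefs = c(0, 0, 0)` yields a null cohort where the label is
#' independent of every generated channel.
#'
#' @param n_patients Cohort size (>= 4).
#' @param prevalence_pos Positive-class fraction in (0, 1).
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of it.
#' @param grid_shape Voxels per axis (each >= 9 so the sliding window and
#'   habitat partitioning are feasible).
#' @param voxel_spacing mm per voxel.
#' @param n_habitat_sources Planted subpopulations per tumor (default 3).
#' @param effect_size_aptw Whole-tumor average APTw shift (percent units)
#'   of positive patients (default 1.40; together with the
#'   habitat-fraction difference this separates class means by ~2.05).
#'   The shift is distributed across habitats in proportion to
#'   `effect_profile_ratio^(k-1)` (normalised so the tumor-average shift
#'   equals `effect_size_aptw`): the aggressive high-signal subregion
#'   carries most of the class contrast, which is what makes its
#'   features dominate the selection.
#' @param noise_sd Voxel-level APTw noise SD of the lowest habitat, in
#'   percent units (default 0.45). Noise is uniform (light-tailed) and
#'   its SD grows by `noise_ratio` per habitat, so subregions differ in
#'   textural heterogeneity as well as signal level.
#' @param reader_noise_sd Per-ROI reader noise SD in percent units.
#' @param habitat_mean_step Spacing of adjacent habitat APTw means
#'   (percent units; default 1.0).
#' @param habitat_mean_base APTw mean of the lowest habitat (default 1.25).
#' @param noise_ratio Multiplicative SD step between adjacent habitats
#'   (default 1.7).
#' @param patient_effect_sd SD (percent units) of a per-patient APTw
#'   offset common to the whole tumor, emulating biological and scanner
#'   variability (default 1.2); without it regional mean features
#'   separate the classes perfectly, which no real cohort shows.
#' @param habitat_jitter_sd SD (percent units) of small additional
#'   per-habitat offsets, independent across habitats (default 0.15).
#'   They bound how precisely inter-habitat feature contrasts can cancel
#'   the common patient offset - without the jitter the selection
#'   cascade denoises the radiomic score into a near-perfect separator -
#'   while staying small enough not to scramble the planted signal
#'   ladder. The offsets are independent
#'   across habitats: a common offset could be cancelled by
#'   inter-habitat feature contrasts, letting the selection cascade
#'   denoise the score to a perfect separator, which no real cohort
#'   shows.
#' @param terrace_sigma Gaussian smoothing (voxels) applied to the
#'   staircase mean field, producing graded transitions between
#'   subregions; the planted ground-truth habitat map is defined from the
#'   smoothed noise-free field by nearest-plateau thresholds (default 1).
#' @param effect_profile_ratio Per-habitat ratio of the class shift
#'   (default 1.15); 1 spreads the shift uniformly.
#' @param label_coefs Logistic coefficients on the standardized
#'   (high-habitat fraction, log CA125, log tumor size).
#' @param clinical_params Per-covariate distribution settings; see
#'   [default_clinical_params()].
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 124L, prevalence_pos = 0.4,
                          seed = 1L, grid_shape = c(32L, 32L, 24L),
                          voxel_spacing = c(2, 2, 2),
                          n_habitat_sources = 3L,
                          effect_size_aptw = 1.40, noise_sd = 0.45,
                          reader_noise_sd = 0.25,
                          habitat_mean_step = 1.0, habitat_mean_base = 1.25,
                          noise_ratio = 1.7, terrace_sigma = 1.0,
                          patient_effect_sd = 1.2, habitat_jitter_sd = 0.15,
                          effect_profile_ratio = 1.15,
                          label_coefs = c(f_high = 1.8, log_ca125 = 0.75,
                                          tumor_size = 0.75),
                          clinical_params = default_clinical_params()) {
  if (n_patients < 4) stop("n_patients must be >= 4")
  if (prevalence_pos <= 0 || prevalence_pos >= 1) {
    stop("prevalence_pos must lie in (0, 1)")
  }
  if (any(grid_shape < 9)) {
    stop("grid_shape must be >= 9 per axis (3x3x3 sliding window margin)")
  }
  if (noise_sd < 0 || reader_noise_sd < 0) stop("noise SDs must be >= 0")
  if (n_habitat_sources < 1) stop("need at least one habitat source")
  structure(list(n_patients = as.integer(n_patients),
                 prevalence_pos = prevalence_pos, seed = as.integer(seed),
                 grid_shape = as.integer(grid_shape),
                 voxel_spacing = as.numeric(voxel_spacing),
                 n_habitat_sources = as.integer(n_habitat_sources),
                 effect_size_aptw = effect_size_aptw, noise_sd = noise_sd,
                 reader_noise_sd = reader_noise_sd,
                 habitat_mean_step = habitat_mean_step,
                 habitat_mean_base = habitat_mean_base,
                 noise_ratio = noise_ratio, terrace_sigma = terrace_sigma,
                 patient_effect_sd = patient_effect_sd,
                 habitat_jitter_sd = habitat_jitter_sd,
                 effect_profile_ratio = effect_profile_ratio,
                 label_coefs = label_coefs,
                 clinical_params = clinical_params),
            class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_clinical_params <- function() {
  list(
    bmi = list(median = 25.0, sdlog = 0.122, beta_u = 0.02),
    age = list(median = 50.0, sdlog = 0.218, beta_u = 0.05),
    ca125 = list(median = 22.5, sdlog = 0.73, beta_u = 0.15),
    tumor_size = list(median = 34.0, sdlog = 0.29, beta_u = 0.10,
                      min = 14, max = 58),
    menopause = list(p = 0.46, beta_u = 0.10),
    figo_gt2 = list(p = 0.097, beta_u = 0.15),
    f_high = list(center = 0.50, beta_u = 0.75, sd = 0.30)
  )
}

# Ellipsoid mask helper: semi-axes in voxels, centered.
ellipsoid_mask <- function(grid, center, semi) {
  gx <- array(rep(seq_len(grid[1]), times = grid[2] * grid[3]), grid)
  gy <- array(rep(rep(seq_len(grid[2]), each = grid[1]), times = grid[3]),
              grid)
  gz <- array(rep(seq_len(grid[3]), each = grid[1] * grid[2]), grid)
  ((gx - center[1]) / semi[1])^2 + ((gy - center[2]) / semi[2])^2 +
    ((gz - center[3]) / semi[3])^2 <= 1
}

# Plant K contiguous subpopulations: farthest-point seed voxels, then a
# weighted-Voronoi assignment whose radii steer the volume fractions.
plant_habitats <- function(mask, k, frac_high, spacing) {
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  pts <- sweep(idx, 2, spacing, "*")
  seeds <- integer(k)
  seeds[1] <- sample.int(n, 1)
  if (k > 1) {
    d2 <- rowSums(sweep(pts, 2, pts[seeds[1], ])^2)
    for (j in 2:k) {
      seeds[j] <- which.max(d2)
      d2 <- pmin(d2, rowSums(sweep(pts, 2, pts[seeds[j], ])^2))
    }
  }
  # order seeds along a random direction so that signal level increases
  # spatially: only adjacent-level habitats share interfaces, mirroring
  # the graded "functional subregion" layout rather than a random mosaic
  dirv <- stats::rnorm(3); dirv <- dirv / sqrt(sum(dirv^2))
  seeds <- seeds[order(pts[seeds, ] %*% dirv)]
  frac <- rep((1 - frac_high) / max(1, k - 1), k)
  frac[k] <- frac_high
  radii <- frac^(1 / 3)
  dist0 <- vapply(seq_len(k), function(j) {
    sqrt(rowSums(sweep(pts, 2, pts[seeds[j], ])^2))
  }, numeric(n))
  # the radius->fraction map of a weighted Voronoi is only approximate;
  # a few fixed-point corrections steer the realised fractions to target
  lab <- max.col(-sweep(dist0, 2, radii, "/"), ties.method = "first")
  for (it in 1:4) {
    actual <- tabulate(lab, k) / n
    radii <- radii * pmax(pmin((frac / pmax(actual, 1e-3))^(1 / 3), 1.5),
                          0.67)
    lab <- max.col(-sweep(dist0, 2, radii, "/"), ties.method = "first")
  }
  out <- array(0L, dim(mask))
  out[mask] <- lab
  out
}

#' Generate a synthetic phantom cohort
#'
#' Produces `n_patients` phantoms, each with an ellipsoidal tumor mask, a
#' planted ground-truth habitat map, an APTw volume (percent units), an
#' anti-correlated ADC volume (10^-3 mm^2/s), an optional necrosis mask,
#' and a clinical record. Deterministic given `config$seed`
#' (bit-identical on repeated calls).
#'
#' @param config A [cohort_config()].
#' @return A list of `phantom_patient` objects with the config attached as
#'   attribute `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  n <- config$n_patients
  grid <- config$grid_shape
  sp <- config$voxel_spacing
  k <- config$n_habitat_sources
  cp <- config$clinical_params
  means <- config$habitat_mean_base +
    config$habitat_mean_step * (seq_len(k) - 1)

  # ---- pass 1: latent aggressiveness, geometry, covariates -------------
  patients <- vector("list", n)
  eta <- numeric(n)
  for (i in seq_len(n)) {
    u <- stats::rnorm(1)
    size_target <- exp(log(cp$tumor_size$median) + cp$tumor_size$beta_u * u +
                         stats::rnorm(1, 0, cp$tumor_size$sdlog))
    size_target <- min(max(size_target, cp$tumor_size$min),
                       cp$tumor_size$max)
    # +0.5 voxel compensates the floor() bias of voxelising the ellipsoid,
    # so the realised mask extent matches the drawn size in expectation
    a_vox <- size_target / 2 / sp[1] + 0.25
    semi <- c(a_vox,
              a_vox * stats::runif(1, 0.75, 0.95) * sp[1] / sp[2],
              a_vox * stats::runif(1, 0.60, 0.85) * sp[1] / sp[3])
    semi <- pmin(semi, (grid - 3) / 2)
    center <- (grid + 1) / 2 + stats::runif(3, -1, 1)
    mask <- ellipsoid_mask(grid, center, semi)
    if (!any(mask)) stop("degenerate mask generated; grid too small")

    # optional necrotic core, carved out of the analysis mask
    necrosis <- array(FALSE, grid)
    if (stats::runif(1) < 0.6) {
      off <- stats::runif(3, -0.3, 0.3) * semi
      necrosis <- ellipsoid_mask(grid, center + off, pmax(semi * 0.18, 0.8))
      necrosis <- necrosis & mask
      mask <- mask & !necrosis
    }

    f_high_target <- stats::plogis(stats::qlogis(cp$f_high$center) +
                                     cp$f_high$beta_u * u +
                                     stats::rnorm(1, 0, cp$f_high$sd))
    habitats <- plant_habitats(mask, k, f_high_target, sp)
    f_high <- mean(habitats[mask] == k)

    ext <- apply(which(mask, arr.ind = TRUE), 2, range)
    tumor_size <- max((ext[2, ] - ext[1, ] + 1) * sp)

    ca125 <- exp(log(cp$ca125$median) + cp$ca125$beta_u * u +
                   stats::rnorm(1, 0, cp$ca125$sdlog))
    bmi <- exp(log(cp$bmi$median) + cp$bmi$beta_u * u +
                 stats::rnorm(1, 0, cp$bmi$sdlog))
    age <- exp(log(cp$age$median) + cp$age$beta_u * u +
                 stats::rnorm(1, 0, cp$age$sdlog))
    menopause <- as.integer(stats::runif(1) <
                              stats::plogis(stats::qlogis(cp$menopause$p) +
                                              cp$menopause$beta_u * u))
    figo_gt2 <- as.integer(stats::runif(1) <
                             stats::plogis(stats::qlogis(cp$figo_gt2$p) +
                                             cp$figo_gt2$beta_u * u))

    b <- config$label_coefs
    eta[i] <- b[1] * (f_high - 0.45) / 0.15 +
      b[2] * (log(ca125) - log(22.5)) / 0.71 +
      b[3] * (log(tumor_size) - log(34)) / 0.33

    patients[[i]] <- list(
      patient_id = sprintf("P%03d", i),
      mask = mask, necrosis = necrosis, habitats = habitats,
      clinical = list(age = age, bmi = bmi, ca125 = ca125,
                      tumor_size = tumor_size,
                      menopause = menopause, figo_gt2 = figo_gt2),
      f_high = f_high)
  }

  # ---- labels: logistic model conditioned on the exact class split ----
  n_pos <- round(n * config$prevalence_pos)
  rank_score <- eta + stats::rlogis(n)
  labels <- integer(n)
  labels[order(rank_score, decreasing = TRUE)[seq_len(n_pos)]] <- 1L

  # ---- pass 2: image channels conditioned on the label -----------------
  # The staircase of habitat means is smoothed (graded transitions, as in
  # real functional subregions); the planted ground truth is re-derived
  # from the smoothed noise-free field by nearest-plateau thresholds, so
  # transition voxels carry the level they actually express. Voxel noise
  # is uniform (light-tailed) with an SD ladder across habitats.
  smooth3 <- function(a, s) {
    if (s <= 0.05) return(a)
    for (ax in 1:3) a <- conv_axis(a, gaussian_kernel(s), ax)
    a
  }
  nscale <- config$noise_sd * config$noise_ratio^(seq_len(k) - 1)
  # distribute the class shift across habitats: weights normalised under
  # the expected volume fractions so the tumor-average shift stays at
  # effect_size_aptw
  w_raw <- config$effect_profile_ratio^(seq_len(k) - 1)
  f_exp <- rep((1 - 0.45) / max(1, k - 1), k); f_exp[k] <- 0.45
  shift_w <- w_raw / sum(f_exp * w_raw)
  for (i in seq_len(n)) {
    p <- patients[[i]]
    lvsi <- labels[i]
    offset_k <- stats::rnorm(1, 0, config$patient_effect_sd) +
      stats::rnorm(k, 0, config$habitat_jitter_sd)
    mu_vox <- array(0, grid)
    mu_vox[p$mask] <- means[p$habitats[p$mask]]
    w <- array(0, grid); w[p$mask] <- 1
    f0 <- smooth3(mu_vox, config$terrace_sigma) /
      pmax(smooth3(w, config$terrace_sigma), 1e-9)
    truth <- array(0L, grid)
    if (k > 1) {
      thr <- means[-1] - config$habitat_mean_step / 2
      truth[p$mask] <- findInterval(f0[p$mask], thr) + 1L
    } else truth[p$mask] <- 1L
    tm <- truth[p$mask]
    aptw <- array(0, grid)
    aptw[p$mask] <- f0[p$mask] + offset_k[tm] +
      config$effect_size_aptw * lvsi * shift_w[tm] +
      stats::runif(sum(p$mask), -sqrt(3), sqrt(3)) * nscale[tm]
    adc <- array(0, grid)
    adc[p$mask] <- pmax(2.765 - 0.444 * aptw[p$mask] +
                          stats::rnorm(sum(p$mask), 0, 0.08), 0.25)
    f_high <- mean(tm == k)

    patients[[i]] <- structure(list(
      patient_id = p$patient_id, lvsi_label = lvsi,
      volume_aptw = volume(aptw, spacing = sp),
      volume_adc = volume(adc, spacing = sp),
      mask = volume(array(as.numeric(p$mask), grid), spacing = sp),
      necrosis_mask = volume(array(as.numeric(p$necrosis), grid),
                             spacing = sp),
      true_habitat_map = volume(truth, spacing = sp),
      clinical = p$clinical, f_high = f_high),
      class = "phantom_patient")
  }
  attr(patients, "config") <- config
  class(patients) <- c("phantom_cohort", "list")
  patients
}

#' @export
print.phantom_cohort <- function(x, ...) {
  lab <- vapply(x, `[[`, integer(1), "lvsi_label")
  cat(sprintf("<phantom_cohort: %d patients, %d LVSI+ / %d LVSI->\n",
              length(x), sum(lab == 1), sum(lab == 0)))
  invisible(x)
}

#' Clinical table of a cohort
#'
#' @param cohort A `phantom_cohort`.
#' @return data.frame: patient_id, lvsi, age, bmi, ca125, tumor_size,
#'   menopause, figo_gt2.
#' @export
cohort_clinical_table <- function(cohort) {
  do.call(rbind, lapply(cohort, function(p) {
    data.frame(patient_id = p$patient_id, lvsi = p$lvsi_label,
               age = p$clinical$age, bmi = p$clinical$bmi,
               ca125 = p$clinical$ca125,
               tumor_size = p$clinical$tumor_size,
               menopause = p$clinical$menopause,
               figo_gt2 = p$clinical$figo_gt2,
               stringsAsFactors = FALSE)
  }))
}

#' Synthesise a z-spectrum stack consistent with an APTw field
#'
#' Direct water saturation is a Lorentzian centred at 0 ppm; an amide
#' resonance at +3.5 ppm is scaled by the local APTw value so that the
#' magnetization transfer ratio asymmetry at 3.5 ppm recovers the planted
#' APTw field (up to the far tail of the amide line, < 1% relative).
#'
#' @param aptw_vol APTw `volume` in percent units.
#' @param offsets ppm offsets (must include +/-3.5).
#' @param s0 Unsaturated signal level (a.u.).
#' @return A [zspectrum_stack()].
#' @export
synth_zspectrum <- function(aptw_vol, offsets = seq(-6, 6, by = 0.5),
                            s0 = 1000) {
  a <- vol_data(aptw_vol) / 100     # fractional asymmetry
  grid <- dim(a)
  sig <- array(0, c(grid, length(offsets)))
  for (t in seq_along(offsets)) {
    dw <- offsets[t]
    ds <- 0.85 / (1 + (dw / 1.2)^2)              # direct water saturation
    amide <- 1 / (1 + ((dw - 3.5) / 0.5)^2)      # amide line shape
    sig[, , , t] <- s0 * (1 - ds - a * amide)
  }
  zspectrum_stack(sig, offsets, array(s0, grid),
                  spacing = vox_spacing(aptw_vol))
}

#' Simulate two readers' three-ROI measurements
#'
#' Both readers share the deterministic ROI placement (same slice, same
#' circles) and differ by independent per-ROI measurement noise, so
#' `reader_noise_sd = 0` reproduces identical readings and ICC 1.
#'
#' @param patient A `phantom_patient`.
#' @param reader_noise_sd Per-ROI noise SD (percent units for APTw).
#' @param seed Integer seed.
#' @param roi_radius_mm ROI radius (default 2.5 mm).
#' @return List with `reader1` and `reader2` (each a `roi_measurement`
#'   for APTw) and `adc1`/`adc2` summary means for the ADC channel.
#' @export
simulate_two_readers <- function(patient, reader_noise_sd = 0.25,
                                 seed = 1L, roi_radius_mm = 2.5) {
  # small lesions get proportionally smaller ROIs, as in practice; below
  # 0.8 mm the placement error propagates
  r <- roi_radius_mm
  base <- NULL
  while (is.null(base)) {
    base <- tryCatch(
      measure_three_roi_mean(patient$volume_aptw, patient$mask,
                             exclusion_mask = patient$necrosis_mask,
                             roi_radius_mm = r, seed = seed),
      error = function(e) NULL)
    if (is.null(base)) {
      r <- r * 0.75
      if (r < 0.8) {
        stop("mask too small to fit three disjoint circular ROIs even at ",
             "0.8 mm radius")
      }
    }
  }
  base_adc <- measure_three_roi_mean(patient$volume_adc, patient$mask,
                                     exclusion_mask = patient$necrosis_mask,
                                     roi_radius_mm = r,
                                     seed = seed)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed + 7919L)
  perturb <- function(meas, sd_) {
    m <- meas
    m$per_roi_means <- m$per_roi_means + stats::rnorm(3, 0, sd_)
    m$summary_mean <- mean(m$per_roi_means)
    m
  }
  list(reader1 = perturb(base, reader_noise_sd),
       reader2 = perturb(base, reader_noise_sd),
       adc1 = perturb(base_adc, reader_noise_sd * 0.3),
       adc2 = perturb(base_adc, reader_noise_sd * 0.3))
}

#' Perturb a tumor mask to emulate a second segmentation
#'
#' Toggles a seeded fraction of surface voxels (erosion/dilation jitter),
#' emulating inter-reader segmentation variability for the feature-level
#' ICC stage.
#'
#' @param mask Binary `volume`.
#' @param flip_frac Fraction of boundary voxels to toggle (default 0.15).
#' @param seed Integer seed.
#' @return Perturbed binary `volume`.
#' @export
perturb_mask <- function(mask, flip_frac = 0.15, seed = 1L) {
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  reg <- vol_data(mask) > 0
  surf <- surface_voxels(reg)
  # dilation candidates: background voxels 6-adjacent to the region
  grown <- reg
  for (ax in 1:3) for (s in c(-1, 1)) grown <- grown | shift_bg(reg, ax, s)
  halo <- grown & !reg
  out <- reg
  si <- which(surf)
  hi <- which(halo)
  drop_n <- round(flip_frac * length(si))
  add_n <- round(flip_frac * 0.8 * length(hi))
  if (drop_n > 0) out[sample(si, drop_n)] <- FALSE
  if (add_n > 0) out[sample(hi, add_n)] <- TRUE
  volume(array(as.numeric(out), dim(reg)), spacing = vox_spacing(mask))
}
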