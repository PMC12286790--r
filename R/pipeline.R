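#' Pipeline configuration
#'
#' Nested, schema-checked configuration for the end-to-end run. Unknown
#' keys are rejected so typos fail fast rather than silently falling back
#' to defaults. A single global `seed` fans out deterministically to
#' per-stage seeds.
#'
#' @param seed Global integer seed.
#' @param out_dir Output directory for run artifacts.
#' @param cohort Arguments for [cohort_config()].
#' @param features Arguments for [feature_bank_config()].
#' @param selection Arguments for [selection_config()].
#' @param habitat List: `k_range` (default 3:10).
#' @param modeling List: `folds` (default 5).
#' @param write_volumes Write per-patient NIfTI volumes (default FALSE;
#'   the CLI `simulate` stage always writes them).
#' @param leakage_free Run the selection cascade inside each outer
#'   training fold (default TRUE); FALSE reproduces the global-filter
#'   reading for comparison.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, out_dir = NULL, cohort = list(),
                            features = list(), selection = list(),
                            habitat = list(), modeling = list(),
                            write_volumes = FALSE, leakage_free = TRUE) {
  check_keys <- function(given, allowed, where) {
    bad <- setdiff(names(given), allowed)
    if (length(bad)) {
      stop("unknown ", where, " config keys: ", paste(bad, collapse = ", "))
    }
  }
  check_keys(cohort, names(formals(cohort_config)), "cohort")
  check_keys(features, names(formals(feature_bank_config)), "features")
  check_keys(selection, names(formals(selection_config)), "selection")
  check_keys(habitat, c("k_range"), "habitat")
  check_keys(modeling, c("folds"), "modeling")
  seeds <- stage_seeds(seed)
  cohort$seed <- seeds["cohort"]
  selection$seed <- seeds["selection"]
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 cohort = do.call(cohort_config, cohort),
                 features = do.call(feature_bank_config, features),
                 selection = do.call(selection_config, selection),
                 habitat = utils::modifyList(list(k_range = 3:10), habitat),
                 modeling = utils::modifyList(list(folds = 5L), modeling),
                 write_volumes = isTRUE(write_volumes),
                 leakage_free = isTRUE(leakage_free),
                 stage_seeds = seeds),
            class = "pipeline_config")
}

# Deterministic fan-out of one global seed into per-stage seeds (< 2^31).
stage_seeds <- function(seed) {
  base <- (as.integer(seed) %% 1000000L) * 1009L
  c(cohort = base + 1L, habitat = base + 101L, readers = base + 202L,
    selection = base + 303L, modeling = base + 404L)
}

# ---------------------------------------------------------------------------
# Cohort I/O: per-patient NIfTI volumes + clinical CSV + JSON sidecar
# ---------------------------------------------------------------------------

#' Write a phantom cohort to disk
#'
#' Per patient: `<id>_aptw.nii`, `<id>_adc.nii` (float32), `<id>_mask.nii`,
#' `<id>_habitats.nii` (uint8); plus `cohort.csv` (clinical columns +
#' label) and `cohort.json` (config echo + seed).
#'
#' @param cohort A `phantom_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in cohort) {
    stem <- file.path(dir, p$patient_id)
    write_nifti(p$volume_aptw, paste0(stem, "_aptw.nii"))
    write_nifti(p$volume_adc, paste0(stem, "_adc.nii"))
    write_nifti(p$mask, paste0(stem, "_mask.nii"), datatype = "uint8")
    write_nifti(p$true_habitat_map, paste0(stem, "_habitats.nii"),
                datatype = "uint8")
    write_nifti(p$necrosis_mask, paste0(stem, "_necrosis.nii"),
                datatype = "uint8")
  }
  utils::write.csv(cohort_clinical_table(cohort),
                   file.path(dir, "cohort.csv"), row.names = FALSE)
  cfg <- attr(cohort, "config")
  jsonlite::write_json(
    list(config = unclass(cfg), n_patients = length(cohort)),
    file.path(dir, "cohort.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}

#' Read a phantom cohort written by [write_cohort()]
#'
#' @param dir Directory containing the cohort artifacts.
#' @return A `phantom_cohort` (without z-spectra).
#' @export
read_cohort <- function(dir) {
  clin <- utils::read.csv(file.path(dir, "cohort.csv"),
                          stringsAsFactors = FALSE)
  patients <- lapply(seq_len(nrow(clin)), function(i) {
    id <- clin$patient_id[i]
    stem <- file.path(dir, id)
    structure(list(
      patient_id = id, lvsi_label = clin$lvsi[i],
      volume_aptw = read_nifti(paste0(stem, "_aptw.nii")),
      volume_adc = read_nifti(paste0(stem, "_adc.nii")),
      mask = read_nifti(paste0(stem, "_mask.nii")),
      necrosis_mask = read_nifti(paste0(stem, "_necrosis.nii")),
      true_habitat_map = read_nifti(paste0(stem, "_habitats.nii")),
      clinical = as.list(clin[i, c("age", "bmi", "ca125", "tumor_size",
                                   "menopause", "figo_gt2")])),
      class = "phantom_patient")
  })
  class(patients) <- c("phantom_cohort", "list")
  patients
}

# ---------------------------------------------------------------------------
# Model comparison under leakage control
# ---------------------------------------------------------------------------

# Operating-point report from pooled scores (Table 3/6 shaped row).
operating_report <- function(scores, labels) {
  roc <- roc_auc(scores, labels)
  thr <- roc$threshold_star
  labels <- as_binary_labels(labels)
  pred <- as.integer(scores >= thr)
  cm <- confusion_metrics(tp = sum(pred == 1 & labels == 1),
                          fp = sum(pred == 1 & labels == 0),
                          tn = sum(pred == 0 & labels == 0),
                          fn = sum(pred == 0 & labels == 1))
  data.frame(threshold = thr, auc = roc$auc, auc_lo = roc$auc_ci95[1],
             auc_hi = roc$auc_ci95[2], specificity = cm$specificity,
             sensitivity = cm$sensitivity, accuracy = cm$accuracy,
             npv = cm$npv, ppv = cm$ppv, precision = cm$precision,
             recall = cm$recall, youden = cm$youden, f1 = cm$f1,
             z = roc$z, p = roc$p)
}

#' Compare the three logistic models under nested stratified CV
#'
#' The clinical-radiological model (CA125 + tumor size), the radiomic-
#' score model, and the combined model are evaluated in one outer
#' stratified k-fold loop. In leakage-free mode the whole selection
#' cascade (ICC filter, z-scoring, t-test, correlation pruning, mRMR,
#' LASSO) is refit on each outer-training fold and only then applied to
#' the held-out patients; the inner CV of the LASSO and of the logistic
#' ridge tuning never sees validation rows.
#'
#' @param feature_table Radiomic `feature_table` (reader 1).
#' @param clinical data.frame with `ca125` and `tumor_size` columns.
#' @param labels Binary labels.
#' @param feature_table_r2 Optional reader-2 table for the ICC stage.
#' @param folds Outer folds (default 5).
#' @param seed Integer seed.
#' @param sel_config A [selection_config()].
#' @param leakage_free Refit the cascade per outer fold (default TRUE).
#' @return A `model_comparison`: per-model `cv` results, `metrics`
#'   (pooled-OOF Table-style rows), `delong` (pairwise comparisons),
#'   `selection` (full-data cascade report, labelled as such), and
#'   `oof_scores`.
#' @export
run_model_comparison <- function(feature_table, clinical, labels,
                                 feature_table_r2 = NULL, folds = 5L,
                                 seed = 1L,
                                 sel_config = selection_config(),
                                 leakage_free = TRUE) {
  labels <- as_binary_labels(labels)
  n <- length(labels)
  fold <- stratified_folds(labels, folds, seed)
  h3_score <- rep(NA_real_, n)
  fold_reports <- vector("list", folds)

  if (leakage_free) {
    for (f in seq_len(folds)) {
      tr <- fold != f
      cfg <- sel_config
      cfg$seed <- cfg$seed + f
      rep_f <- run_selection_cascade(
        feature_table[tr, , drop = FALSE], labels[tr],
        table_reader2 = if (is.null(feature_table_r2)) NULL
                        else feature_table_r2[tr, , drop = FALSE],
        config = cfg)
      if (rep_f$empty) {
        # all coefficients shrunk to zero (typical under null labels):
        # the fold's radiomic score degenerates to a constant
        warning("empty LASSO selection in outer fold ", f,
                "; radiomic score is constant for its validation patients")
        h3_score[!tr] <- 0
      } else {
        h3_score[!tr] <- apply_radiomic_score(rep_f,
                                              feature_table[!tr, ,
                                                            drop = FALSE])
      }
      fold_reports[[f]] <- rep_f
    }
  } else {
    rep_all <- run_selection_cascade(feature_table, labels,
                                     table_reader2 = feature_table_r2,
                                     config = sel_config)
    if (rep_all$empty) stop("empty LASSO selection: radiomic model undefined")
    h3_score <- apply_radiomic_score(rep_all, feature_table)
    fold_reports <- list(rep_all)
  }

  # full-data cascade for reporting (explicitly labelled as refit)
  selection_full <- run_selection_cascade(feature_table, labels,
                                          table_reader2 = feature_table_r2,
                                          config = sel_config)

  pred_tab <- data.frame(ca125 = clinical$ca125,
                         tumor_size = clinical$tumor_size,
                         aptw_h3 = h3_score)
  specs <- list(model_spec("clinical_radiological"), model_spec("aptw_h3"),
                model_spec("combined"))
  cvs <- lapply(specs, function(s) {
    fit_cv(s, pred_tab, labels, folds = folds, seed = seed)
  })
  names(cvs) <- vapply(specs, `[[`, "", "name")

  oof <- lapply(cvs, `[[`, "oof_prob")
  metrics <- do.call(rbind, lapply(names(cvs), function(nm) {
    cbind(model = nm, operating_report(oof[[nm]], labels))
  }))
  pairs <- utils::combn(names(cvs), 2, simplify = FALSE)
  delong <- do.call(rbind, lapply(pairs, function(pr) {
    d <- delong_test(oof[[pr[1]]], oof[[pr[2]]], labels)
    data.frame(model1 = pr[1], model2 = pr[2], auc1 = d$auc1,
               auc2 = d$auc2, diff = d$diff, ci_lo = d$ci[1],
               ci_hi = d$ci[2], z = d$z, p = d$p)
  }))
  structure(list(cv = cvs, metrics = metrics, delong = delong,
                 oof_scores = as.data.frame(oof), fold = fold,
                 selection = selection_full,
                 fold_reports = fold_reports,
                 leakage_free = leakage_free),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("model comparison (pooled out-of-fold):\n")
  print(x$metrics[, c("model", "auc", "threshold", "sensitivity",
                      "specificity", "accuracy", "youden")], digits = 3,
        row.names = FALSE)
  cat("DeLong pairwise:\n")
  print(x$delong[, c("model1", "model2", "diff", "z", "p")], digits = 3,
        row.names = FALSE)
  invisible(x)
}

# ---------------------------------------------------------------------------
# End-to-end pipeline
# ---------------------------------------------------------------------------

#' Run the full habitat-radiomics pipeline
#'
#' simulate -> (optional z-spectrum APTw quantification check) -> habitat
#' partitioning -> two-reader feature extraction -> leakage-controlled
#' selection + model comparison -> evaluation reports. All artifacts are
#' written under `config$out_dir` (when set) together with a manifest
#' recording the seed fan-out, package version and file checksums;
#' re-running with an identical config reproduces identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param progress Print stage progress (default TRUE).
#' @return A `pipeline_result` list with the cohort, habitat maps, feature
#'   tables, comparison, reliability and association reports.
#' @export
run_pipeline <- function(config = pipeline_config(), progress = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (progress) message(sprintf(...))
  t0 <- Sys.time()
  seeds <- config$stage_seeds

  say("[simulate] generating cohort (n = %d)", config$cohort$n_patients)
  cohort <- generate_cohort(config$cohort)
  labels <- vapply(cohort, `[[`, integer(1), "lvsi_label")
  clinical <- cohort_clinical_table(cohort)

  say("[habitat] partitioning %d tumors", length(cohort))
  habitat_maps <- lapply(seq_along(cohort), function(i) {
    p <- cohort[[i]]
    fmap <- extract_voxel_features(p$volume_aptw, p$mask)
    select_habitats(fmap, p$volume_aptw, k_range = config$habitat$k_range,
                    seed = seeds["habitat"] + i)
  })

  say("[readers] conventional ROI measurements + second segmentation")
  readers <- lapply(seq_along(cohort), function(i) {
    simulate_two_readers(cohort[[i]],
                         reader_noise_sd = config$cohort$reader_noise_sd,
                         seed = seeds["readers"] + i)
  })
  aptw_r1 <- vapply(readers, function(r) r$reader1$summary_mean, numeric(1))
  aptw_r2 <- vapply(readers, function(r) r$reader2$summary_mean, numeric(1))
  adc_r1 <- vapply(readers, function(r) r$adc1$summary_mean, numeric(1))
  adc_r2 <- vapply(readers, function(r) r$adc2$summary_mean, numeric(1))
  reliability <- list(aptw = icc_two_rater(aptw_r1, aptw_r2),
                      adc = icc_two_rater(adc_r1, adc_r2))

  say("[features] reader-1 extraction (%d transforms)",
      length(config$features$transforms))
  ft1 <- extract_feature_table(cohort, habitat_maps, config$features)
  say("[features] reader-2 extraction (perturbed masks)")
  cohort2 <- lapply(seq_along(cohort), function(i) {
    p <- cohort[[i]]
    p$mask <- perturb_mask(p$mask, seed = seeds["readers"] + 5000L + i)
    p
  })
  habitat_maps2 <- lapply(seq_along(cohort2), function(i) {
    p <- cohort2[[i]]
    fmap <- extract_voxel_features(p$volume_aptw, p$mask)
    select_habitats(fmap, p$volume_aptw, k_range = config$habitat$k_range,
                    seed = seeds["habitat"] + i)
  })
  ft2 <- extract_feature_table(cohort2, habitat_maps2, config$features)

  say("[select+fit] %d-fold nested comparison (leakage_free = %s)",
      config$modeling$folds, config$leakage_free)
  comparison <- run_model_comparison(
    ft1, clinical, labels, feature_table_r2 = ft2,
    folds = config$modeling$folds, seed = seeds["modeling"],
    sel_config = config$selection, leakage_free = config$leakage_free)

  say("[evaluate] association analysis and group tests")
  assoc_tab <- data.frame(age = clinical$age, bmi = clinical$bmi,
                          ca125 = clinical$ca125,
                          tumor_size = clinical$tumor_size,
                          aptw_h3 = comparison$oof_scores$aptw_h3)
  association <- association_analysis(assoc_tab, labels)
  groups <- group_tests(clinical[, c("age", "bmi", "ca125", "tumor_size",
                                     "menopause", "figo_gt2")], labels)

  result <- structure(list(config = config, cohort = cohort,
                           habitat_maps = habitat_maps,
                           feature_table = ft1, feature_table_r2 = ft2,
                           reliability = reliability,
                           comparison = comparison,
                           association = association, group_tests = groups,
                           conventional = list(aptw = aptw_r1, adc = adc_r1),
                           elapsed = as.numeric(difftime(Sys.time(), t0,
                                                         units = "secs"))),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_run_artifacts(result, config$out_dir)
  say("[done] %.1f s", result$elapsed)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result: n = %d, elapsed %.1f s>\n",
              length(x$cohort), x$elapsed))
  print(x$comparison)
  invisible(x)
}

write_run_artifacts <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  if (cfg$write_volumes) write_cohort(result$cohort, file.path(dir, "cohort"))
  utils::write.csv(cohort_clinical_table(result$cohort),
                   file.path(dir, "clinical.csv"), row.names = FALSE)
  utils::write.csv(result$feature_table, file.path(dir, "features_r1.csv"),
                   row.names = FALSE)
  utils::write.csv(result$comparison$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(result$comparison$delong, file.path(dir, "delong.csv"),
                   row.names = FALSE)
  preds <- data.frame(patient_id = result$feature_table$patient_id,
                      fold = result$comparison$fold,
                      result$comparison$oof_scores)
  utils::write.csv(preds, file.path(dir, "predictions.csv"),
                   row.names = FALSE)
  sel <- result$comparison$selection
  jsonlite::write_json(
    list(surviving_per_stage = as.list(sel$surviving_per_stage),
         final_features = sel$final_features,
         coefficients = as.list(sel$coefficients),
         intercept = sel$intercept, lambda = sel$lambda,
         note = "full-data refit of the cascade; OOF scores use per-fold refits"),
    file.path(dir, "selection.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  ch_tab <- do.call(rbind, lapply(seq_along(result$habitat_maps), function(i) {
    hm <- result$habitat_maps[[i]]
    data.frame(patient_id = result$cohort[[i]]$patient_id,
               k = as.integer(names(hm$ch_scores)), ch = hm$ch_scores,
               selected = as.integer(names(hm$ch_scores)) == hm$k,
               row.names = NULL)
  }))
  utils::write.csv(ch_tab, file.path(dir, "habitat_ch_scores.csv"),
                   row.names = FALSE)
  files <- setdiff(list.files(dir, recursive = TRUE, full.names = TRUE),
                   file.path(dir, "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("aptwhabitat")),
    seed = cfg$seed, stage_seeds = as.list(cfg$stage_seeds),
    created = format(Sys.time(), tz = "UTC"),
    checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
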