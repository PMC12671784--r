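# End-to-end drivers: assemble labelled window datasets from records or
# cohorts on disk, and run the patient-specific cross-validated experiment
# on a synthetic cohort.

#' Load a cohort manifest into a window dataset
#'
#' Reads every record (EDF) and annotation file listed in a
#' [generate_cohort()] manifest, runs the preprocessing chain and
#' concatenates the per-patient window datasets.
#'
#' @param manifest manifest data frame (or path to `manifest.json`).
#' @param dir directory holding the referenced files.
#' @param ... passed to [build_window_dataset()].
#' @return list with `x` (feature matrix) and `windows` (data frame
#'   `patient_id`, `label`, `start_s`).
#' @export
load_cohort <- function(manifest, dir = ".", ...) {
  if (is.character(manifest)) {
    dir <- dirname(manifest)
    manifest <- as.data.frame(jsonlite::fromJSON(manifest))
  }
  xs <- list(); wins <- list()
  for (i in seq_len(nrow(manifest))) {
    ann <- read_annotations(file.path(dir, manifest$annotations[i]))
    rec <- read_edf(file.path(dir, manifest$edf[i]), annotations = ann)
    rec$patient_id <- manifest$patient_id[i]
    ds <- build_window_dataset(rec, ...)
    xs[[i]] <- ds$x
    wins[[i]] <- data.frame(patient_id = ds$patient_id, label = ds$y,
                            start_s = ds$start_s)
  }
  list(x = do.call(rbind, xs), windows = do.call(rbind, wins))
}

#' Synthetic-cohort cross-validation experiment
#'
#' Generates a seeded synthetic cohort (one seizure per patient, planted
#' preictal theta/alpha signature), extracts labelled window features
#' through the full preprocessing chain and runs per-patient stratified
#' k-fold cross-validation of the network.
#'
#' The defaults are the desk-scale experiment described in the package
#' vignette: 6 patients, 2 h and one seizure each, theta/alpha power gain 4,
#' base seed 8, and a reduced 20-epoch training budget.
#'
#' @param n_patients number of synthetic patients.
#' @param duration_s record length per patient in seconds.
#' @param onset_s seizure onset time within each record.
#' @param theta_alpha_gain planted preictal power gain.
#' @param sync_gain planted preictal shared-source fraction.
#' @param n_channels channels per record.
#' @param epochs training epochs per fold.
#' @param seed base seed for generation, splitting and training.
#' @param folds cross-validation folds.
#' @param verbose print per-patient progress.
#' @return list with `metrics` (per patient x fold data frame from
#'   [evaluate_cv()]) and `summary` (means over folds).
#' @export
run_cohort_experiment <- function(n_patients = 6, duration_s = 7200,
                                  onset_s = 6000, theta_alpha_gain = 4,
                                  sync_gain = 0.5, n_channels = 8,
                                  epochs = 20, seed = 8, folds = 5,
                                  verbose = FALSE) {
  xs <- list(); wins <- list()
  for (i in seq_len(n_patients)) {
    cfg <- synth_config(n_channels = n_channels, duration_s = duration_s,
                        seizure_onsets_s = onset_s,
                        theta_alpha_gain = theta_alpha_gain,
                        sync_gain = sync_gain, seed = seed + i)
    rec <- generate_record(cfg)
    rec$patient_id <- sprintf("S%02d", i)
    ds <- build_window_dataset(rec)
    xs[[i]] <- ds$x
    wins[[i]] <- data.frame(patient_id = ds$patient_id, label = ds$y,
                            start_s = ds$start_s)
    if (verbose) message(sprintf("patient %d: %d windows (%d preictal)",
                                 i, length(ds$y), sum(ds$y)))
  }
  x <- do.call(rbind, xs)
  windows <- do.call(rbind, wins)
  metrics <- evaluate_cv(x, windows,
                         train_cfg = train_config(epochs = epochs, seed = seed,
                                                  folds = folds))
  list(metrics = metrics,
       summary = c(acc = mean(metrics$acc), sen = mean(metrics$sen),
                   spe = mean(metrics$spe), f1 = mean(metrics$f1),
                   mcc = mean(metrics$mcc), auroc = mean(metrics$auroc)))
}
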