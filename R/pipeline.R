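# End-to-end orchestration: metadata CSV -> QC -> channel means -> split ->
# normalization -> features -> statistics -> models -> metrics, with
# machine-readable outputs and a run log. All output files are written
# atomically (temp + rename).

#' Pipeline run configuration
#'
#' @param metadata path to the metadata CSV (columns `image_id, path,
#'   roi_path, patient_id, wound_id, debridement_index, hospital,
#'   wound_area_cm2, days_post_injury, age, outcome`).
#' @param image_root directory that `path`/`roi_path` entries are relative
#'   to (defaults to the metadata file's directory).
#' @param out_dir output directory.
#' @param qc a [qc_thresholds()] list.
#' @param normalize_scope fit the normalization reference on the training
#'   split only (`"train"`, the leak-free default) or on all images
#'   (`"all"`).
#' @param split_fraction,split_seed stratified split parameters.
#' @param model_A latent variables per stage (or `"auto"`).
#' @param model_cv folds for `"auto"` selection.
#' @param model_threshold PLSDA decision threshold.
#' @param route_by stage-2 routing, `"truth"` or `"prediction"`.
#' @param mode `"full"` or `"threshold_only"` (univariate threshold model
#'   only).
#' @param threshold_cutoff cutoff for the univariate threshold rule on the
#'   normalized `(R-B)/(R^2+B^2)` variable.
#' @param perm_n,perm_seed,perm_folds permutation-test parameters
#'   (`perm_n = 0` skips the test).
#' @return list of class `run_config`.
#' @export
run_config <- function(metadata, image_root = NULL, out_dir,
                       qc = qc_thresholds(), normalize_scope = c("train", "all"),
                       split_fraction = 0.75, split_seed = 1,
                       model_A = "auto", model_cv = 10,
                       model_threshold = 0.5, route_by = "truth",
                       mode = c("full", "threshold_only"),
                       threshold_cutoff = 1.00,
                       perm_n = 200, perm_seed = 1, perm_folds = 5) {
  normalize_scope <- match.arg(normalize_scope)
  mode <- match.arg(mode)
  image_root <- image_root %||% dirname(metadata)
  structure(as.list(environment()), class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat key/value YAML whose keys are the [run_config()] arguments; `qc.*`
#' keys override individual QC thresholds.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  qc_keys <- grep("^qc\\.", names(y), value = TRUE)
  qc <- qc_thresholds()
  for (k in qc_keys) qc[[sub("^qc\\.", "", k)]] <- y[[k]]
  y <- y[setdiff(names(y), qc_keys)]
  do.call(run_config, c(y, list(qc = qc)))
}

read_metadata <- function(path) {
  req <- c("image_id", "path", "roi_path", "patient_id", "wound_id",
           "debridement_index", "hospital", "wound_area_cm2",
           "days_post_injury", "age", "outcome")
  meta <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(req, names(meta))
  if (length(miss)) {
    stop("metadata CSV lacks required column(s): ",
         paste(miss, collapse = ", "))
  }
  meta
}

#' Run the full wound-image analysis pipeline
#'
#' Quality-screens every image, extracts ROI channel means, splits the
#' cohort (stratified on the three-class outcome), fits the normalization
#' reference (training split by default), builds the 14-variable feature
#' table, runs the healed-versus-dehisced group comparison, evaluates the
#' univariate threshold rule, exports PCA scores, fits the sequential
#' two-stage classifier, computes validation diagnostics (confusion matrix,
#' sensitivity/specificity/accuracy, diagnostic odds ratio with Woolf CI)
#' and a permutation overfitting test. Writes `features.csv`,
#' `group_comparison.csv`, `pca_scores.csv`, `normalizer.json`,
#' `model.json`, `metrics.json` and `run.log` to the output directory.
#'
#' @param config a [run_config()] or path to a YAML config file.
#' @return the run report (contents of `metrics.json`), invisibly.
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log_msg <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  meta <- read_metadata(config$metadata)
  log_msg("read ", nrow(meta), " image records from ", config$metadata)

  # QC screen and channel means
  keep <- logical(nrow(meta))
  ch <- matrix(NA_real_, nrow(meta), 3, dimnames = list(NULL, c("r", "g", "b")))
  qc_reasons <- character(nrow(meta))
  for (i in seq_len(nrow(meta))) {
    img <- load_image(file.path(config$image_root, meta$path[i]))
    roi <- load_roi_mask(file.path(config$image_root, meta$roi_path[i]),
                         height = img$height, width = img$width)
    rep_i <- qc_screen(img, roi, config$qc)
    keep[i] <- rep_i$pass
    qc_reasons[i] <- paste(rep_i$reasons, collapse = "+")
    if (rep_i$pass) ch[i, ] <- roi_channel_means(img, roi)$mean
  }
  n_fail <- sum(!keep)
  log_msg(n_fail, " image(s) disregarded by quality screening (",
          paste(unique(qc_reasons[!keep]), collapse = ", "), ")")
  if (!any(keep)) stop("empty cohort: every image failed quality screening")
  meta <- meta[keep, , drop = FALSE]
  ch <- ch[keep, , drop = FALSE]
  channels <- cbind(meta, as.data.frame(ch))

  # Split before normalization so the reference can be fit leak-free.
  ds_idx <- labeled_dataset(matrix(0, nrow(meta), 1), meta$outcome,
                            ids = seq_len(nrow(meta)))
  split <- stratified_split(ds_idx, train_fraction = config$split_fraction,
                            seed = config$split_seed)
  train_rows <- split$train$ids
  valid_rows <- split$validation$ids
  log_msg("stratified split (seed ", config$split_seed, "): ",
          length(train_rows), " train / ", length(valid_rows), " validation")

  ref_rows <- if (config$normalize_scope == "train") train_rows
              else seq_len(nrow(meta))
  ref <- fit_normalizer(channels[ref_rows, , drop = FALSE])
  write_normalizer(ref, file.path(config$out_dir, "normalizer.json"))
  features <- extract_features(channels, ref)
  write_atomic(file.path(config$out_dir, "features.csv"), function(tmp) {
    cols <- c("image_id", "hospital", "outcome", raw_index_names(),
              paste0(raw_index_names(), "_norm"),
              "wound_area_cm2", "days_post_injury", "age")
    utils::write.csv(features[, cols], tmp, row.names = FALSE)
  })

  comparison <- group_compare(features)
  write_atomic(file.path(config$out_dir, "group_comparison.csv"),
               function(tmp) utils::write.csv(comparison, tmp,
                                              row.names = FALSE))

  # Univariate threshold rule on the validation split
  thr_pred <- threshold_classify(features$rb_over_r2b2_norm[valid_rows],
                                 cutoff = config$threshold_cutoff)
  thr_truth <- binarize_outcome(features$outcome[valid_rows])
  thr_ok <- !is.na(thr_pred)
  thr_cm <- confusion_from_labels(thr_truth[thr_ok], thr_pred[thr_ok])
  thr_metrics <- confusion_metrics(thr_cm)
  thr_dor <- diagnostic_odds_ratio(thr_cm)

  report <- list(
    split_seed = config$split_seed,
    n_images = nrow(meta) + n_fail,
    n_qc_disregarded = n_fail,
    n_train = length(train_rows),
    n_validation = length(valid_rows),
    threshold_model = list(
      cutoff = config$threshold_cutoff,
      confusion_matrix = unclass(thr_cm),
      sensitivity = thr_metrics$sensitivity,
      specificity = thr_metrics$specificity,
      accuracy = thr_metrics$accuracy,
      dor = thr_dor$dor,
      dor_ci = c(thr_dor$ci_low, thr_dor$ci_high)))

  # Rows with missing indices (zero denominators) drop out of modeling;
  # keep ids as row numbers so the split indices still align.
  ds <- labeled_dataset(as.matrix(features[, predictor_names()]),
                        features$outcome, ids = seq_len(nrow(features)))
  if (attr(ds, "n_dropped") > 0) {
    log_msg(attr(ds, "n_dropped"),
            " row(s) dropped from modeling for missing predictors")
  }
  pca <- pca_fit(ds$X, k = 2)
  write_atomic(file.path(config$out_dir, "pca_scores.csv"), function(tmp) {
    utils::write.csv(data.frame(image_id = features$image_id[ds$ids],
                                outcome = as.character(ds$y3),
                                pc1 = pca$scores[, 1], pc2 = pca$scores[, 2]),
                     tmp, row.names = FALSE)
  })

  if (config$mode == "full") {
    train <- subset_dataset(ds, which(ds$ids %in% train_rows))
    valid <- subset_dataset(ds, which(ds$ids %in% valid_rows))
    h <- fit_hierarchical(train, A = config$model_A, cv = config$model_cv,
                          seed = config$split_seed,
                          threshold = config$model_threshold,
                          route_by = config$route_by)
    write_model_json(h, file.path(config$out_dir, "model.json"))
    pred <- predict_hierarchical(h, valid$X)
    cm <- confusion_from_labels(valid$y2, pred)
    mets <- confusion_metrics(cm)
    dor <- diagnostic_odds_ratio(cm)
    report$confusion_matrix <- unclass(cm)
    report$sensitivity <- mets$sensitivity
    report$specificity <- mets$specificity
    report$accuracy <- mets$accuracy
    report$dor <- dor$dor
    report$dor_ci <- c(dor$ci_low, dor$ci_high)
    report$stage_components <- c(h$stage1$A, h$stage2$A)
    if (config$perm_n > 0) {
      A_perm <- if (identical(config$model_A, "auto")) {
        max(h$stage1$A, h$stage2$A)
      } else config$model_A
      perm <- permutation_test(
        train$X, train$y3,
        hierarchical_recipe(A = A_perm,
                            threshold = config$model_threshold,
                            route_by = config$route_by),
        n_perm = config$perm_n, seed = config$perm_seed,
        folds = config$perm_folds)
      report$permutation_seed <- config$perm_seed
      report$permutation_p <- perm$p
      report$permutation_observed <- perm$observed
      log_msg("permutation test: observed CV accuracy ",
              round(perm$observed, 4), ", p = ", round(perm$p, 4))
    }
  }

  write_atomic(file.path(config$out_dir, "metrics.json"), function(tmp) {
    jsonlite::write_json(report, tmp, auto_unbox = TRUE, digits = 10)
  })
  write_atomic(file.path(config$out_dir, "run.log"),
               function(tmp) writeLines(log_lines, tmp))
  invisible(report)
}

#' Serialize a fitted classifier to JSON
#'
#' Stores preprocessing vectors, weights, loadings, the regression vector,
#' the component count and threshold for each stage.
#'
#' @param model a `plsda_model` or `hierarchical_wound_classifier`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  ser_plsda <- function(m) {
    list(center = as.list(m$center), scale = as.list(m$scale),
         W = m$W, P = m$P, q = m$q, b = m$b, intercept = m$intercept,
         A = m$A, threshold = m$threshold, levels = m$levels)
  }
  obj <- if (inherits(model, "hierarchical_wound_classifier")) {
    list(type = "hierarchical", route_by = model$route_by,
         stage1 = ser_plsda(model$stage1), stage2 = ser_plsda(model$stage2))
  } else if (inherits(model, "plsda_model")) {
    list(type = "plsda", model = ser_plsda(model))
  } else {
    stop("unsupported model class")
  }
  write_atomic(path, function(tmp) {
    jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA)
  })
}
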