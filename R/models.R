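# Outcome models: labeled dataset container, univariate threshold rule,
# stratified splitting, the sequential two-stage classifier, and the
# permutation overfitting test.

outcome_levels <- function() c("healed", "delayed", "dehisced")

# Collapse the three-class outcome to the binary one: delayed-healing wounds
# did heal, so they count as healed.
binarize_outcome <- function(y3) {
  factor(ifelse(as.character(y3) == "dehisced", "dehisced", "healed"),
         levels = c("healed", "dehisced"))
}

#' Labeled modeling dataset
#'
#' Bundles the 17-column predictor matrix with the three-class outcome
#' (`healed`, `delayed`, `dehisced`) and the derived binary outcome
#' (delayed counts as healed). Rows with any missing predictor are dropped
#' with a message; the count is kept in attribute `n_dropped`.
#'
#' @param X numeric predictor matrix.
#' @param y3 three-class outcome vector (factor or character).
#' @param ids optional row identifiers.
#' @return object of class `wound_dataset` with `X`, `y3`, `y2`, `ids`.
#' @export
labeled_dataset <- function(X, y3, ids = NULL) {
  X <- as.matrix(X)
  y3 <- factor(as.character(y3), levels = outcome_levels())
  if (anyNA(y3)) stop("outcome labels must be healed/delayed/dehisced")
  stopifnot(nrow(X) == length(y3))
  ids <- ids %||% seq_len(nrow(X))
  keep <- stats::complete.cases(X)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message("dropping ", n_dropped, " row(s) with missing predictors")
  }
  structure(list(X = X[keep, , drop = FALSE], y3 = droplevels(y3[keep]),
                 y2 = binarize_outcome(y3[keep]), ids = ids[keep]),
            class = "wound_dataset", n_dropped = n_dropped)
}

#' Build a modeling dataset from a feature table
#'
#' @param features data frame from [extract_features()] joined with the
#'   clinical covariates and `outcome` (and optionally `image_id`).
#' @return a [labeled_dataset()] with the 17 canonical predictors.
#' @export
as_labeled_dataset <- function(features) {
  miss <- setdiff(c(predictor_names(), "outcome"), names(features))
  if (length(miss)) stop("feature table lacks column(s): ",
                         paste(miss, collapse = ", "))
  labeled_dataset(as.matrix(features[, predictor_names()]),
                  features$outcome,
                  ids = features$image_id %||% seq_len(nrow(features)))
}

subset_dataset <- function(ds, idx) {
  structure(list(X = ds$X[idx, , drop = FALSE],
                 y3 = droplevels(ds$y3[idx]),
                 y2 = ds$y2[idx], ids = ds$ids[idx]),
            class = "wound_dataset")
}

#' Univariate threshold classification
#'
#' Applies the fixed cutoff rule on the overall-mean-normalized
#' `(R-B)/(R^2+B^2)` index: values at or above the cutoff are called
#' dehisced, values below healed. Missing values are left unclassified
#' (`NA`) and counted in attribute `n_unclassified`.
#'
#' @param values numeric index values.
#' @param cutoff decision threshold (default 1.00).
#' @return factor over `healed`/`dehisced` with `NA` for missing input.
#' @export
threshold_classify <- function(values, cutoff = 1.00) {
  lab <- ifelse(is.na(values), NA_character_,
                ifelse(values >= cutoff, "dehisced", "healed"))
  structure(factor(lab, levels = c("healed", "dehisced")),
            n_unclassified = sum(is.na(values)))
}

#' Stratified train/validation split
#'
#' Splits by row (each débridement image an independent observation),
#' preserving each outcome class's prevalence in both parts to within one
#' sample. Deterministic for a given seed.
#'
#' @param ds a [labeled_dataset()].
#' @param train_fraction fraction of rows assigned to training
#'   (default 0.75).
#' @param seed RNG seed.
#' @param stratify_on `"y3"` (default) or `"y2"`.
#' @return list with `train` and `validation` datasets.
#' @export
stratified_split <- function(ds, train_fraction = 0.75, seed = 1,
                             stratify_on = c("y3", "y2")) {
  stopifnot(inherits(ds, "wound_dataset"),
            train_fraction > 0, train_fraction < 1)
  strata <- switch(match.arg(stratify_on), y3 = ds$y3, y2 = ds$y2)
  counts <- table(strata)
  if (any(counts < 2)) {
    stop("cannot stratify: class '", names(counts)[which.min(counts)],
         "' has fewer than 2 members")
  }
  train_idx <- local_seed(seed, {
    unlist(lapply(levels(strata), function(cl) {
      idx <- which(strata == cl)
      n_tr <- min(length(idx) - 1, max(1, round(train_fraction * length(idx))))
      sample(idx, n_tr)
    }), use.names = FALSE)
  })
  train_idx <- sort(train_idx)
  list(train = subset_dataset(ds, train_idx),
       validation = subset_dataset(ds, setdiff(seq_along(strata), train_idx)))
}

#' Fit the sequential two-stage wound classifier
#'
#' Stage 1 is a PLSDA separating delayed-healing from not-delayed wounds on
#' all training rows; stage 2 is a PLSDA separating healed from dehisced,
#' trained on the remaining (not-delayed) rows. At prediction time a sample
#' called delayed by stage 1 is labeled healed and never reaches stage 2.
#'
#' @param ds a [labeled_dataset()] containing all three outcome classes.
#' @param A latent-variable count or `"auto"`, passed to [plsda_fit()].
#' @param cv cross-validation folds for `"auto"`.
#' @param seed RNG seed for fold construction.
#' @param threshold decision threshold for both stages.
#' @param route_by train stage 2 on rows whose true label is not delayed
#'   (`"truth"`, default) or on rows stage 1 predicts as not delayed
#'   (`"prediction"`).
#' @return object of class `hierarchical_wound_classifier`.
#' @export
fit_hierarchical <- function(ds, A = "auto", cv = 10, seed = NULL,
                             threshold = 0.5,
                             route_by = c("truth", "prediction")) {
  stopifnot(inherits(ds, "wound_dataset"))
  route_by <- match.arg(route_by)
  present <- table(factor(ds$y3, levels = outcome_levels()))
  if (any(present == 0)) {
    stop("training data must contain all three classes; missing: ",
         paste(names(present)[present == 0], collapse = ", "))
  }
  y_delayed <- factor(ifelse(ds$y3 == "delayed", "delayed", "not_delayed"),
                      levels = c("not_delayed", "delayed"))
  stage1 <- plsda_fit(ds$X, y_delayed, A = A, cv = cv, seed = seed,
                      threshold = threshold)
  keep <- if (route_by == "truth") {
    ds$y3 != "delayed"
  } else {
    plsda_predict(stage1, ds$X)$label == "not_delayed"
  }
  y2_keep <- ds$y2[keep]
  if (length(unique(y2_keep)) < 2) {
    stop("stage 2 training rows contain a single class; cannot fit")
  }
  stage2 <- plsda_fit(ds$X[keep, , drop = FALSE], y2_keep, A = A, cv = cv,
                      seed = seed, threshold = threshold)
  structure(list(stage1 = stage1, stage2 = stage2, route_by = route_by,
                 stage2_rows = which(keep)),
            class = "hierarchical_wound_classifier")
}

#' Predict with the sequential two-stage classifier
#'
#' @param h a [fit_hierarchical()] classifier.
#' @param X_new predictor matrix.
#' @return factor over `healed`/`dehisced` (delayed is never a final label).
#' @export
predict_hierarchical <- function(h, X_new) {
  stopifnot(inherits(h, "hierarchical_wound_classifier"))
  X_new <- as.matrix(X_new)
  s1 <- plsda_predict(h$stage1, X_new)$label
  out <- rep("healed", nrow(X_new))
  pass <- s1 == "not_delayed"
  if (any(pass)) {
    s2 <- plsda_predict(h$stage2, X_new[pass, , drop = FALSE])$label
    out[pass] <- as.character(s2)
  }
  factor(out, levels = c("healed", "dehisced"))
}

#' Flat PLSDA model recipe
#'
#' A recipe is a function `(X, y3) -> prediction function` used by
#' [cv_accuracy()] and [permutation_test()]. The flat recipe fits one PLSDA
#' of dehisced against everything else.
#'
#' @param A latent-variable count or `"auto"`.
#' @param cv,seed,threshold passed to [plsda_fit()].
#' @return a recipe function.
#' @export
plsda_recipe <- function(A = 3, cv = 10, seed = NULL, threshold = 0.5) {
  function(X, y3) {
    m <- plsda_fit(X, binarize_outcome(y3), A = A, cv = cv, seed = seed,
                   threshold = threshold)
    function(X_new) plsda_predict(m, X_new)$label
  }
}

#' Sequential two-stage model recipe
#'
#' @inheritParams plsda_recipe
#' @param route_by passed to [fit_hierarchical()].
#' @return a recipe function for [cv_accuracy()] / [permutation_test()].
#' @export
hierarchical_recipe <- function(A = 3, cv = 10, seed = NULL, threshold = 0.5,
                                route_by = "truth") {
  function(X, y3) {
    h <- fit_hierarchical(labeled_dataset(X, y3), A = A, cv = cv,
                          seed = seed, threshold = threshold,
                          route_by = route_by)
    function(X_new) predict_hierarchical(h, X_new)
  }
}

#' Stratified cross-validated accuracy of a model recipe
#'
#' Accuracy is measured on the binary outcome (dehisced versus not), with
#' folds stratified on the labels handed to the recipe.
#'
#' @param X predictor matrix.
#' @param y3 outcome labels (three-class or binary).
#' @param recipe a recipe function (e.g. [hierarchical_recipe()]).
#' @param folds number of folds (default 5).
#' @param seed RNG seed for fold construction.
#' @return cross-validated accuracy in `[0, 1]`.
#' @export
cv_accuracy <- function(X, y3, recipe, folds = 5, seed = NULL) {
  X <- as.matrix(X)
  y3 <- factor(y3)
  truth <- binarize_outcome(y3)
  k <- max(2, min(folds, min(table(y3))))
  fold <- stratified_folds(as.character(y3), k, seed)
  correct <- 0
  for (f in seq_len(k)) {
    tr <- fold != f
    predict_fn <- recipe(X[tr, , drop = FALSE], y3[tr])
    pred <- predict_fn(X[!tr, , drop = FALSE])
    correct <- correct + sum(as.character(pred) ==
                               as.character(truth[!tr]))
  }
  correct / nrow(X)
}

#' Permutation test for classifier overfitting
#'
#' Measures the probability that a model fit to randomly relabeled data
#' performs as well as the model fit to the true labels (the "probability of
#' insignificance"). The observed score is the stratified cross-validated
#' accuracy of the recipe on the true labels; each permutation shuffles the
#' labels and re-runs the identical recipe. `p = (1 + #\{permuted >=
#' observed\}) / (1 + n_perm)`.
#'
#' @param X predictor matrix.
#' @param y3 outcome labels.
#' @param recipe a recipe function.
#' @param n_perm number of permutations (>= 19; default 200).
#' @param seed RNG seed driving the shuffles and fold construction.
#' @param folds cross-validation folds for the score.
#' @return object of class `permutation_result`: `observed`, `permuted`,
#'   `n_permutations`, `p`.
#' @export
permutation_test <- function(X, y3, recipe, n_perm = 200, seed = 1,
                             folds = 5) {
  if (n_perm < 19) stop("n_perm must be at least 19")
  X <- as.matrix(X)
  y3 <- factor(y3)
  observed <- cv_accuracy(X, y3, recipe, folds = folds,
                          seed = child_seed(seed, 0))
  permuted <- local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      for (attempt in 1:3) {
        y_p <- sample(y3)
        s <- tryCatch(
          cv_accuracy(X, y_p, recipe, folds = folds,
                      seed = child_seed(seed, i)),
          error = function(e) NA_real_)
        if (!is.na(s)) return(s)
      }
      observed # conservative: unfittable permutation counts as >= observed
    }, numeric(1))
  })
  structure(list(observed = observed, permuted = permuted,
                 n_permutations = n_perm,
                 p = (1 + sum(permuted >= observed)) / (1 + n_perm)),
            class = "permutation_result")
}
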