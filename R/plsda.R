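# Partial least squares discriminant analysis (PLS1 / NIPALS), written
# in-package, plus a thin PCA wrapper for class visualization.

# Autoscale helper: center and scale columns; zero-variance columns get
# scale 1 so they center to zero and carry no information.
autoscale_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

autoscale_apply <- function(X, pre) {
  sweep(sweep(X, 2, pre$center, "-"), 2, pre$scale, "/")
}

# NIPALS PLS1 on autoscaled X and centered y. Returns weights W, X-loadings
# P, y-loadings q and scores T for `A` components. Deflation: X <- X - t p',
# y <- y - q t.
nipals_pls1 <- function(Xs, yc, A) {
  n <- nrow(Xs); p <- ncol(Xs)
  W <- matrix(0, p, A); P <- matrix(0, p, A)
  q <- numeric(A); Tm <- matrix(0, n, A)
  Xd <- Xs; yd <- yc
  a_used <- 0
  for (a in seq_len(A)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- Xd %*% w
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pa <- crossprod(Xd, t) / tt
    qa <- sum(yd * t) / tt
    W[, a] <- w; P[, a] <- pa; q[a] <- qa; Tm[, a] <- t
    Xd <- Xd - tcrossprod(t, pa)
    yd <- yd - qa * t
    a_used <- a
  }
  list(W = W[, seq_len(a_used), drop = FALSE],
       P = P[, seq_len(a_used), drop = FALSE],
       q = q[seq_len(a_used)],
       scores = Tm[, seq_len(a_used), drop = FALSE],
       A = a_used)
}

# Regression vector in the autoscaled space using the first `a` components:
# b = W (P'W)^-1 q.
pls_regression_vector <- function(fit, a = fit$A) {
  W <- fit$W[, seq_len(a), drop = FALSE]
  P <- fit$P[, seq_len(a), drop = FALSE]
  q <- fit$q[seq_len(a)]
  drop(W %*% solve(crossprod(P, W), q))
}

# Coerce a response to 0/1 with remembered level names
# (negative level first).
binary_response <- function(y) {
  if (is.factor(y) || is.character(y)) {
    f <- factor(y)
    if (nlevels(f) != 2) stop("y must have exactly 2 classes, got ",
                              nlevels(f))
    list(y01 = as.numeric(f) - 1, levels = levels(f))
  } else {
    u <- sort(unique(y))
    if (!all(u %in% c(0, 1)) || length(u) != 2) {
      stop("numeric y must contain both 0 and 1")
    }
    list(y01 = as.numeric(y), levels = c("0", "1"))
  }
}

# Stratified fold assignment: shuffles within class, then deals fold ids
# round-robin so every fold mirrors the class balance.
stratified_folds <- function(y, k, seed = NULL) {
  local_seed(seed, {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Fit a PLSDA model
#'
#' PLS1 discriminant analysis: predictors are autoscaled (zero mean, unit
#' variance per column), the 0/1 class dummy is centered, and latent
#' variables are extracted by NIPALS with deflation. Prediction thresholds
#' the regression estimate of the class dummy.
#'
#' @param X numeric predictor matrix (n x p).
#' @param y binary response: 0/1 vector or two-level factor (second level =
#'   positive class).
#' @param A number of latent variables, or `"auto"` to pick the count (up to
#'   `a_max`) minimizing stratified cross-validated misclassification, ties
#'   going to the smaller model.
#' @param cv number of cross-validation folds used when `A = "auto"`.
#' @param seed RNG seed for the cross-validation folds.
#' @param threshold decision threshold on the predicted class dummy
#'   (default 0.5), or `"prevalence"` to place the cut at the training
#'   positive-class rate (a sensitivity-seeking operating point analogous to
#'   the Bayesian threshold of commercial PLSDA tools).
#' @param a_max cap on the latent-variable count considered by `"auto"`.
#' @return object of class `plsda_model`: preprocessing vectors, `W`, `P`,
#'   `q`, regression vector `b`, intercept, `A`, `threshold`, class levels
#'   and training scores.
#' @export
plsda_fit <- function(X, y, A = "auto", cv = 10, seed = NULL,
                      threshold = 0.5, a_max = 10) {
  X <- as.matrix(X)
  if (nrow(X) < 4) stop("need at least 4 training samples")
  resp <- binary_response(y)
  y01 <- resp$y01
  if (length(unique(y01)) < 2) stop("both classes must be present in y")
  if (identical(threshold, "prevalence")) threshold <- mean(y01)
  pre <- autoscale_fit(X)
  Xs <- autoscale_apply(X, pre)
  rank_x <- qr(Xs)$rank
  hard_max <- min(nrow(X) - 1, ncol(X), rank_x)
  if (identical(A, "auto")) {
    A <- choose_components(X, y01, min(a_max, hard_max), cv, seed, threshold)
  } else {
    A <- as.integer(A)
    if (A < 1) stop("A must be >= 1")
    if (A > hard_max) {
      warning("A = ", A, " exceeds the usable rank; truncated to ", hard_max)
      A <- hard_max
    }
  }
  ybar <- mean(y01)
  fit <- nipals_pls1(Xs, y01 - ybar, A)
  b <- pls_regression_vector(fit)
  structure(list(center = pre$center, scale = pre$scale,
                 W = fit$W, P = fit$P, q = fit$q, scores = fit$scores,
                 b = b, intercept = ybar, A = fit$A,
                 threshold = threshold, levels = resp$levels,
                 fitted = drop(ybar + Xs %*% b)),
            class = "plsda_model")
}

# Pick the component count by stratified cv-fold misclassification.
choose_components <- function(X, y01, a_max, cv, seed, threshold) {
  a_max <- max(1, a_max)
  k <- max(2, min(cv, min(table(y01))))
  fold <- stratified_folds(y01, k, seed)
  err <- numeric(a_max)
  for (f in seq_len(k)) {
    tr <- fold != f; te <- fold == f
    if (length(unique(y01[tr])) < 2) next
    pre <- autoscale_fit(X[tr, , drop = FALSE])
    Xs <- autoscale_apply(X[tr, , drop = FALSE], pre)
    ybar <- mean(y01[tr])
    a_fold <- min(a_max, sum(tr) - 1, qr(Xs)$rank)
    fit <- nipals_pls1(Xs, y01[tr] - ybar, a_fold)
    Xt <- autoscale_apply(X[te, , drop = FALSE], pre)
    for (a in seq_len(a_max)) {
      b <- pls_regression_vector(fit, min(a, fit$A))
      pred <- (ybar + Xt %*% b) >= threshold
      err[a] <- err[a] + sum(pred != (y01[te] == 1))
    }
  }
  which.min(err) # ties -> smaller A (which.min takes the first minimum)
}

#' Predict from a PLSDA model
#'
#' @param model a [plsda_fit()] model.
#' @param X_new numeric matrix with the training predictor columns.
#' @return list with `score` (predicted class dummy) and `label` (factor on
#'   the training levels; positive iff `score >= threshold`).
#' @export
plsda_predict <- function(model, X_new) {
  stopifnot(inherits(model, "plsda_model"))
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(model$center)) {
    stop("X_new has ", ncol(X_new), " columns; model expects ",
         length(model$center))
  }
  Xs <- autoscale_apply(X_new, list(center = model$center,
                                    scale = model$scale))
  score <- drop(model$intercept + Xs %*% model$b)
  label <- factor(model$levels[(score >= model$threshold) + 1],
                  levels = model$levels)
  list(score = score, label = label)
}

#' Principal component analysis for class visualization
#'
#' Autoscaled PCA via singular value decomposition. Constant columns are
#' dropped with a warning.
#'
#' @param X numeric matrix (n >= 2 rows).
#' @param k number of components to return (default all).
#' @return list with `scores`, `loadings`, `explained_variance` (fractions)
#'   and `dropped` (names/indices of constant columns).
#' @export
pca_fit <- function(X, k = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 rows for PCA")
  const <- apply(X, 2, function(col) stats::sd(col) == 0)
  dropped <- if (is.null(colnames(X))) which(const) else colnames(X)[const]
  if (any(const)) {
    warning("dropping ", sum(const), " constant column(s) before PCA")
    X <- X[, !const, drop = FALSE]
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(k %||% length(ev), length(ev))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       loadings = pc$rotation[, seq_len(k), drop = FALSE],
       explained_variance = ev[seq_len(k)],
       dropped = dropped)
}
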