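# Group-comparison statistics and diagnostic-performance metrics.

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples with midranks for ties.
#' The exact null distribution is used when `n_x * n_y <= 400` and there are
#' no ties; otherwise the normal approximation with tie and continuity
#' correction.
#'
#' @param x,y numeric samples.
#' @return list with `U` (the U statistic of `x`) and `p` (two-sided).
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 1 || length(y) < 1) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) * length(y) <= 400) && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  list(U = unname(ht$statistic), p = min(1, ht$p.value))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment: with p-values sorted ascending,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, returned in the input
#' order.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_fdr_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Without continuity correction; df = 1, upper-tail p.
#'
#' @param table 2x2 matrix of non-negative counts.
#' @return list with `chisq` and `p`.
#' @export
chi_squared_2x2 <- function(table) {
  m <- as.matrix(table)
  stopifnot(all(dim(m) == c(2, 2)), all(m >= 0))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("chi-squared undefined: zero row or column margin")
  }
  n <- sum(m)
  stat <- n * (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])^2 /
    prod(rowSums(m), colSums(m))
  list(chisq = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Confusion matrix (positive class: dehisced)
#'
#' @param tp,fn,fp,tn non-negative integer counts.
#' @return object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  cells <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("confusion counts must be non-negative integers")
  }
  if (sum(cells) < 1) stop("confusion matrix must contain at least one case")
  structure(as.list(cells), class = "confusion_matrix")
}

#' Confusion matrix from labels
#'
#' @param truth,pred factors or character vectors of class labels.
#' @param positive the positive-class label (default `"dehisced"`).
#' @return a [confusion_matrix()].
#' @export
confusion_from_labels <- function(truth, pred, positive = "dehisced") {
  stopifnot(length(truth) == length(pred))
  t_pos <- as.character(truth) == positive
  p_pos <- as.character(pred) == positive
  confusion_matrix(tp = sum(t_pos & p_pos), fn = sum(t_pos & !p_pos),
                   fp = sum(!t_pos & p_pos), tn = sum(!t_pos & !p_pos))
}

#' Sensitivity, specificity and accuracy
#'
#' @param cm a [confusion_matrix()].
#' @return list with `sensitivity`, `specificity`, `accuracy` (proportions).
#' @export
confusion_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$tp + cm$fn == 0 || cm$tn + cm$fp == 0) {
    stop("undefined metric: one outcome class is empty")
  }
  total <- cm$tp + cm$fn + cm$fp + cm$tn
  list(sensitivity = cm$tp / (cm$tp + cm$fn),
       specificity = cm$tn / (cm$tn + cm$fp),
       accuracy = (cm$tp + cm$tn) / total)
}

#' Diagnostic odds ratio with Woolf confidence interval
#'
#' `DOR = (TP * TN) / (FP * FN)`; the Woolf interval is
#' `exp(log DOR +/- z * sqrt(1/TP + 1/FN + 1/FP + 1/TN))`. With a zero cell
#' and `zero_correction = TRUE`, 0.5 is added to every cell
#' (Haldane-Anscombe) before both formulas.
#'
#' @param cm a [confusion_matrix()].
#' @param zero_correction apply the Haldane-Anscombe correction when any
#'   cell is zero.
#' @param conf_level confidence level (default 0.95).
#' @return list with `dor`, `ci_low`, `ci_high`.
#' @export
diagnostic_odds_ratio <- function(cm, zero_correction = TRUE,
                                  conf_level = 0.95) {
  stopifnot(inherits(cm, "confusion_matrix"))
  cells <- c(cm$tp, cm$fn, cm$fp, cm$tn)
  if (any(cells == 0)) {
    if (!zero_correction) {
      stop("diagnostic odds ratio undefined: zero cell in the confusion ",
           "matrix (enable zero_correction for Haldane-Anscombe)")
    }
    cells <- cells + 0.5
  }
  dor <- (cells[1] * cells[4]) / (cells[3] * cells[2])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(sum(1 / cells))
  list(dor = dor,
       ci_low = exp(log(dor) - z * se),
       ci_high = exp(log(dor) + z * se))
}

#' Enumerate confusion matrices consistent with printed metrics
#'
#' Finds every integer confusion matrix with the given total whose positive
#' count lies within one case of `prevalence * n_total` and whose
#' sensitivity, specificity and accuracy — as percentages rounded half away
#' from zero to one decimal — equal the printed values.
#'
#' @param n_total total number of cases.
#' @param prevalence positive-class prevalence.
#' @param sens_pct,spec_pct,acc_pct printed percentages (one decimal).
#' @return list of [confusion_matrix()] objects (possibly empty).
#' @export
enumerate_consistent_confusions <- function(n_total, prevalence,
                                            sens_pct, spec_pct, acc_pct) {
  target <- prevalence * n_total
  pos_range <- seq.int(max(1, ceiling(target - 1)), floor(target + 1))
  out <- list()
  for (pos in pos_range) {
    neg <- n_total - pos
    if (neg < 1) next
    for (tp in 0:pos) {
      if (round_half_up(100 * tp / pos, 1) != sens_pct) next
      for (tn in 0:neg) {
        if (round_half_up(100 * tn / neg, 1) != spec_pct) next
        if (round_half_up(100 * (tp + tn) / n_total, 1) != acc_pct) next
        out[[length(out) + 1]] <-
          confusion_matrix(tp = tp, fn = pos - tp, fp = neg - tn, tn = tn)
      }
    }
  }
  out
}

#' Healed-versus-dehisced group comparison report
#'
#' For each variable: group means and standard errors, the Mann-Whitney U
#' statistic, the raw two-sided p-value and the Benjamini-Hochberg adjusted
#' p-value across the variable set. Wounds with delayed healing count as
#' healed (the binary outcome).
#'
#' @param features feature data frame (from [extract_features()]) with an
#'   `outcome` column over `healed`, `delayed`, `dehisced`.
#' @param variables variable columns to compare; defaults to the 7
#'   overall-mean-normalized indices.
#' @return data frame with columns `variable, mean_healed, sem_healed,
#'   mean_dehisced, sem_dehisced, U, p_raw, p_adj`.
#' @export
group_compare <- function(features,
                          variables = paste0(raw_index_names(), "_norm")) {
  stopifnot("outcome" %in% names(features),
            all(variables %in% names(features)))
  binary <- ifelse(features$outcome == "dehisced", "dehisced", "healed")
  rows <- lapply(variables, function(v) {
    healed <- features[[v]][binary == "healed"]
    dehis <- features[[v]][binary == "dehisced"]
    mw <- mann_whitney_u(dehis, healed)
    data.frame(variable = v,
               mean_healed = mean(healed, na.rm = TRUE),
               sem_healed = sem(healed),
               mean_dehisced = mean(dehis, na.rm = TRUE),
               sem_dehisced = sem(dehis),
               U = mw$U, p_raw = mw$p)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_fdr_adjust(out$p_raw)
  out
}
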