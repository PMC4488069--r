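# Classification evaluation: thresholding predicted probabilities into
# presence/absence and summarising agreement with observations.
# Orientation convention throughout: rows are predictions, columns are
# observations, so TN = predicted absent & observed absent,
# FN = predicted absent & observed present, FP = predicted present &
# observed absent, TP = predicted present & observed present.

#' Build a threshold evaluation from confusion counts
#'
#' @param tn,fn,fp,tp non-negative integer confusion counts.
#' @param threshold the probability threshold that produced them (optional).
#' @return object of class `threshold_evaluation` with the counts, `n`,
#'   `sensitivity`, `specificity`, `pcc` (proportion correct), `kappa`,
#'   and `kappa_se`.
#' @export
threshold_evaluation <- function(tn, fn, fp, tp, threshold = NA_real_) {
  counts <- c(tn = tn, fn = fn, fp = fp, tp = tp)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers")
  n <- sum(counts)
  if (n == 0) stop("empty confusion matrix")
  po <- (tn + tp) / n
  pe <- ((tn + fn) * (tn + fp) + (fp + tp) * (fn + tp)) / n^2
  if (pe >= 1) {
    kap <- NA_real_
    kse <- NA_real_
    warning("degenerate marginals (chance agreement = 1); kappa undefined")
  } else {
    kap <- (po - pe) / (1 - pe)
    kse <- sqrt(po * (1 - po) / (n * (1 - pe)^2))
  }
  structure(list(threshold = threshold,
                 tn = tn, fn = fn, fp = fp, tp = tp, n = n,
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                 pcc = po, kappa = kap, kappa_se = kse),
            class = "threshold_evaluation")
}

#' @export
print.threshold_evaluation <- function(x, ...) {
  if (!is.na(x$threshold)) cat(sprintf("threshold = %g\n", x$threshold))
  m <- matrix(c(x$tn, x$fp, x$fn, x$tp), 2, 2,
              dimnames = list(predicted = c("absent", "present"),
                              observed = c("absent", "present")))
  print(m)
  cat(sprintf("PCC = %.1f%%  sens = %.3f  spec = %.3f  kappa = %.3f (SE %.3f)\n",
              100 * x$pcc, x$sensitivity, x$specificity, x$kappa, x$kappa_se))
  invisible(x)
}

#' Confusion matrix at a probability threshold
#'
#' Classifies predicted present where `probability >= t`, and tabulates
#' agreement with the observed 0/1 vector.
#'
#' @param observed 0/1 vector.
#' @param probabilities predicted probabilities, same length.
#' @param t threshold in `[0, 1]`.
#' @return a [threshold_evaluation()].
#' @export
confusion_matrix <- function(observed, probabilities, t) {
  if (length(observed) != length(probabilities))
    stop("observed and probabilities differ in length")
  stopifnot(all(observed %in% c(0, 1)), t >= 0, t <= 1)
  pred <- as.integer(probabilities >= t)
  threshold_evaluation(tn = sum(pred == 0 & observed == 0),
                       fn = sum(pred == 0 & observed == 1),
                       fp = sum(pred == 1 & observed == 0),
                       tp = sum(pred == 1 & observed == 1),
                       threshold = t)
}

#' Optimal classification threshold
#'
#' Scans the grid `t = 0, step, 2*step, ..., 1` and returns the threshold
#' maximising `sensitivity(t) + specificity(t)`. When several grid points
#' tie at the maximum, their mean is returned (which is how three-decimal
#' optima arise from a coarser grid).
#'
#' @param observed 0/1 vector containing both classes.
#' @param probabilities predicted probabilities.
#' @param step grid step; default 0.005.
#' @return the optimal threshold `t*`.
#' @export
optimal_threshold <- function(observed, probabilities, step = 0.005) {
  if (length(unique(observed)) < 2)
    stop("observed vector holds a single class; threshold undefined")
  grid <- seq(0, 1, by = step)
  score <- vapply(grid, function(t) {
    ev <- confusion_matrix(observed, probabilities, t)
    ev$sensitivity + ev$specificity
  }, numeric(1))
  best <- max(score)
  mean(grid[score >= best - 1e-12])
}

#' Percent of observations correctly classified
#'
#' @param eval a [threshold_evaluation()].
#' @param digits decimals to round to; default 1 (reporting convention).
#' @return PCC as a percentage.
#' @export
percent_correct <- function(eval, digits = 1) {
  stopifnot(inherits(eval, "threshold_evaluation"))
  round(100 * eval$pcc, digits)
}

#' Cohen's kappa for a 2x2 confusion matrix
#'
#' Chance-corrected agreement `kappa = (Po - Pe) / (1 - Pe)` with observed
#' agreement `Po = (TN + TP)/n` and chance agreement
#' `Pe = ((TN+FN)(TN+FP) + (FP+TP)(FN+TP)) / n^2`. The standard error uses
#' the large-sample approximation
#' `sqrt(Po (1 - Po) / (n (1 - Pe)^2))`; treat it as informative rather
#' than exact.
#'
#' @param eval a [threshold_evaluation()].
#' @return list with `kappa` and `se`.
#' @export
cohen_kappa <- function(eval) {
  stopifnot(inherits(eval, "threshold_evaluation"))
  list(kappa = eval$kappa, se = eval$kappa_se)
}

#' Evaluate predictions at their optimal threshold
#'
#' Convenience wrapper: finds the optimal threshold, then returns the full
#' evaluation at it.
#'
#' @inheritParams optimal_threshold
#' @return a [threshold_evaluation()] at the optimal threshold.
#' @export
evaluate_predictions <- function(observed, probabilities, step = 0.005) {
  t_star <- optimal_threshold(observed, probabilities, step = step)
  confusion_matrix(observed, probabilities, t_star)
}
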