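#' Maximum AIS over body regions
#'
#' @param head,chest AIS bands or ordinal codes (1..5), vectorized.
#' @return Integer MAIS ordinal codes.
#' @examples
#' mais(2, 3)  # 3
#' @export
mais <- function(head, chest) {
  pmax(ais_code(head), ais_code(chest))
}

#' Serious-injury binarization
#'
#' A casualty is classed as seriously injured when MAIS is at least 3
#' (the AIS 3+ triage threshold); below 3 is non-serious.
#'
#' @param mais_code Integer MAIS codes in 1..5.
#' @return Logical: `TRUE` for serious injury.
#' @export
binarize_serious <- function(mais_code) {
  code <- as.integer(mais_code)
  if (any(is.na(code)) || any(code < 1L | code > 5L)) {
    stop("MAIS codes must be integers in 1..5")
  }
  code >= 3L
}

#' Serious-injury confusion matrix
#'
#' Counts laid out as in the classification matrix for ROC analysis:
#' A = TP (predicted serious, actually serious), B = FN (predicted
#' non-serious, actually serious), C = FP, D = TN.
#'
#' @param predicted,observed Equal-length logical vectors (`TRUE` =
#'   serious).
#' @return Named integer vector `c(TP, FN, FP, TN)`.
#' @export
confusion_matrix <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop("`predicted` and `observed` must have equal length")
  }
  if (length(predicted) == 0L) stop("empty input")
  predicted <- as.logical(predicted)
  observed <- as.logical(observed)
  c(
    TP = sum(predicted & observed),
    FN = sum(!predicted & observed),
    FP = sum(predicted & !observed),
    TN = sum(!predicted & !observed)
  )
}

#' ROC curve and AUC for serious-injury prediction
#'
#' Sweeps a decision threshold over the unique prediction scores,
#' recording the true-positive rate (predicted-serious among actually
#' serious) against the false-positive rate, and integrates the area
#' under the curve by the trapezoid rule. Tied scores enter as a single
#' threshold, which makes the trapezoid AUC identical to the
#' Mann-Whitney pairwise statistic with ties credited one half.
#'
#' @param scores Finite continuous severity scores (higher = more
#'   severe).
#' @param observed Logical serious-injury labels; both classes must be
#'   present.
#' @return List with `roc_points` (data frame `fpr`, `tpr`, from (0,0)
#'   to (1,1)) and `auc`.
#' @examples
#' roc_auc(c(0.9, 0.4, 0.6, 0.2), c(TRUE, TRUE, FALSE, FALSE))$auc  # 0.75
#' @export
roc_auc <- function(scores, observed) {
  if (length(scores) != length(observed)) {
    stop("`scores` and `observed` must have equal length")
  }
  if (any(!is.finite(scores))) stop("scores must be finite")
  observed <- as.logical(observed)
  n_pos <- sum(observed)
  n_neg <- sum(!observed)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC undefined: need at least one serious and one non-serious case")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- observed[ord]
  # collapse tied scores into single threshold steps
  grp <- cumsum(c(TRUE, diff(s) != 0))
  tp_step <- tapply(y, grp, sum)
  fp_step <- tapply(!y, grp, sum)
  tpr <- c(0, cumsum(tp_step) / n_pos)
  fpr <- c(0, cumsum(fp_step) / n_neg)
  auc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
  list(
    roc_points = data.frame(fpr = as.numeric(fpr), tpr = as.numeric(tpr)),
    auc = auc
  )
}

#' Qualitative accuracy grade of an AUC
#'
#' Above 0.9 is high accuracy, 0.7 to 0.9 is medium, 0.5 to 0.7 is low,
#' and below 0.5 is worse than chance.
#'
#' @param auc A value in `[0, 1]`.
#' @return One of `"high"`, `"medium"`, `"low"`, `"below-chance"`.
#' @export
accuracy_grade <- function(auc) {
  if (!is.numeric(auc) || length(auc) != 1L || auc < 0 || auc > 1) {
    stop("`auc` must be a single value in [0, 1]")
  }
  if (auc > 0.9) "high"
  else if (auc >= 0.7) "medium"
  else if (auc >= 0.5) "low"
  else "below-chance"
}

#' Predicted-vs-observed consistency counts
#'
#' Counts cases where the predicted MAIS equals, exceeds, or falls below
#' the observed MAIS.
#'
#' @param predicted,observed Equal-length vectors of MAIS ordinal codes.
#' @return Named integer vector `c(equal, over, under)`.
#' @export
consistency_counts <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop("`predicted` and `observed` must have equal length")
  }
  p <- as.integer(predicted)
  o <- as.integer(observed)
  c(
    equal = sum(p == o),
    over = sum(p > o),
    under = sum(p < o)
  )
}

#' Validate a trained network against EDR-style records
#'
#' Runs the model on each record's crash condition, binarizes predicted
#' and observed injuries at MAIS >= 3, and assembles the confusion
#' matrix, consistency counts (on MAIS), ROC curve and AUC. The ROC is
#' swept over the continuous network score `max(head_score,
#' chest_score)` so that thresholds do not collapse onto the five
#' ordinal codes; a rounded-MAIS ROC is also reported for comparison.
#'
#' @param model A trained `ais_net`.
#' @param edr Data frame of EDR records: `delta_v`, `belted`,
#'   `deploy_time`, `head_ais`, `chest_ais` (observed codes).
#' @return An object of class `validation_result`: list with
#'   `confusion` (TP/FN/FP/TN), `consistency` (equal/over/under),
#'   `per_region_consistency`, `roc_points`, `auc`, `grade`,
#'   `auc_rounded` (rounded-MAIS score ROC), and `n`.
#' @export
validate_predictions <- function(model, edr) {
  pred <- predict_ais(model, edr)
  obs_mais <- mais(edr$head_ais, edr$chest_ais)
  pred_mais <- mais(pred$head_ais, pred$chest_ais)
  obs_serious <- binarize_serious(obs_mais)
  pred_serious <- binarize_serious(pred_mais)
  score <- pmax(pred$head_score, pred$chest_score)
  roc <- roc_auc(score, obs_serious)
  roc_r <- roc_auc(pred_mais, obs_serious)
  structure(
    list(
      confusion = confusion_matrix(pred_serious, obs_serious),
      consistency = consistency_counts(pred_mais, obs_mais),
      per_region_consistency = list(
        head = consistency_counts(pred$head_ais, ais_code(edr$head_ais)),
        chest = consistency_counts(pred$chest_ais, ais_code(edr$chest_ais))
      ),
      roc_points = roc$roc_points,
      auc = roc$auc,
      grade = accuracy_grade(roc$auc),
      auc_rounded = roc_r$auc,
      n = nrow(edr)
    ),
    class = "validation_result"
  )
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf(
    "<validation_result> n = %d, AUC = %.3f (%s accuracy)\n",
    x$n, x$auc, x$grade
  ))
  cat(sprintf(
    "  confusion TP %d / FN %d / FP %d / TN %d; consistency %d equal / %d over / %d under\n",
    x$confusion["TP"], x$confusion["FN"], x$confusion["FP"], x$confusion["TN"],
    x$consistency["equal"], x$consistency["over"], x$consistency["under"]
  ))
  invisible(x)
}
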