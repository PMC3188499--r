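# Labeled-set handling, ROC/AUC with the lower-score-is-positive
# orientation, operating-point statistics and threshold calibration.
#
# Orientation note: scores are energies, so LOWER scores indicate binders.
# Most ROC libraries assume higher-is-positive; every function here fixes
# the energy orientation globally.

#' Read a labeled peptide table
#'
#' Tab-separated with a header: \code{sequence<TAB>label[<TAB>score]}.
#' Labels must come from \code{allowedLabels}; sequences must be unique
#' valid Cxxx motifs.
#'
#' @param tableSource path to a TSV file, or a data.frame with the same
#'   columns.
#' @param positiveLabels labels counted as positives (default MTO/binder).
#' @param allowedLabels the label vocabulary.
#' @return a \linkS4class{LabeledPeptideSet}; per-label counts are reported
#'   via message().
#' @export
readLabeledSet <- function(tableSource,
                           positiveLabels = c("MTO", "binder"),
                           allowedLabels = c("MTO", "STO", "NON", "binder",
                                             "non_binder")) {
  d <- if (is.data.frame(tableSource)) tableSource
       else utils::read.delim(tableSource, stringsAsFactors = FALSE)
  if (!all(c("sequence", "label") %in% names(d)))
    stop("labeled table must have 'sequence' and 'label' columns")
  if (anyDuplicated(d$sequence))
    stop("duplicate sequence(s): ",
         paste(unique(d$sequence[duplicated(d$sequence)]), collapse = ", "))
  bad <- setdiff(unique(d$label), allowedLabels)
  if (length(bad) > 0)
    stop("unknown label(s): ", paste(bad, collapse = ", "))
  for (s in d$sequence) .validateCxxx(s)
  tab <- table(d$label)
  message("labeled set: ",
          paste(names(tab), tab, sep = "=", collapse = ", "))
  new("LabeledPeptideSet", records = d, positiveLabels = positiveLabels)
}

.asPositives <- function(labels, positiveLabels) {
  if (is.logical(labels)) return(labels)
  labels %in% positiveLabels
}

#' ROC curve for energy scores
#'
#' Builds the curve over all score thresholds with the lower-is-positive
#' orientation (a peptide is called positive when its score is at or below
#' the threshold). The AUC is computed by the trapezoid rule and
#' cross-checked internally against the concordant-pair (Mann-Whitney)
#' formulation with ties counted one half; the two must agree to 1e-9.
#'
#' @param scores numeric scores (energies).
#' @param labels logical (TRUE = positive) or label vector.
#' @param positiveLabels used when \code{labels} is not logical.
#' @return a \linkS4class{ROCCurve}.
#' @export
rocCurve <- function(scores, labels, positiveLabels = c("MTO", "binder")) {
  pos <- .asPositives(labels, positiveLabels)
  if (!any(pos) || all(pos))
    stop("ROC requires at least one positive and one negative")
  sp <- scores[pos]; sn <- scores[!pos]
  ths <- sort(unique(scores))
  tpr <- vapply(ths, function(t) mean(sp <= t), numeric(1))
  fpr <- vapply(ths, function(t) mean(sn <= t), numeric(1))
  pts <- data.frame(threshold = c(-Inf, ths), fpr = c(0, fpr),
                    tpr = c(0, tpr))
  aucTrap <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                    utils::tail(pts$tpr, -1)) / 2)
  # concordant pairs: positive scores lower than negative scores
  cmp <- outer(sp, sn, function(a, b) (a < b) + 0.5 * (a == b))
  aucMW <- mean(cmp)
  if (abs(aucTrap - aucMW) > 1e-9)
    stop("internal AUC cross-check failed (trapezoid ", aucTrap,
         " vs concordant pairs ", aucMW, ")")
  new("ROCCurve", points = pts, auc = aucTrap)
}

#' True- and false-positive rates at a score threshold
#'
#' A peptide is called positive when its score is at or below the
#' threshold (ties count as positive calls).
#'
#' @param scores numeric scores.
#' @param labels logical or label vector.
#' @param threshold numeric score threshold.
#' @param positiveLabels used when \code{labels} is not logical.
#' @return named numeric \code{c(tpr = , fpr = )}.
#' @export
ratesAtThreshold <- function(scores, labels, threshold,
                             positiveLabels = c("MTO", "binder")) {
  pos <- .asPositives(labels, positiveLabels)
  c(tpr = mean(scores[pos] <= threshold),
    fpr = mean(scores[!pos] <= threshold))
}

#' Calibrate classification thresholds from a labeled score set
#'
#' Replaces thresholds that were tuned for a different energy function.
#' The loose threshold either maximizes Youden's J (tpr - fpr; the default)
#' or achieves a requested false-positive-rate bound; the stringent
#' threshold is the largest threshold whose FPR stays at or below
#' \code{stringentFpr}. Thresholds are placed at the midpoint between the
#' selected score and the next higher observed score; ties in the
#' optimisation resolve toward the lower threshold. When a requested bound
#' forces a degenerate operating point (no positives recovered) the closest
#' attainable threshold is returned with a warning.
#'
#' @param scores numeric scores (lower = binder).
#' @param labels logical or label vector.
#' @param looseFpr optional FPR bound for the loose threshold; \code{NULL}
#'   (default) selects by Youden's J.
#' @param stringentFpr FPR bound for the stringent threshold (default
#'   0.02).
#' @param positiveLabels used when \code{labels} is not logical.
#' @return a \linkS4class{ClassifierConfig}.
#' @export
calibrateThresholds <- function(scores, labels, looseFpr = NULL,
                                stringentFpr = 0.02,
                                positiveLabels = c("MTO", "binder")) {
  pos <- .asPositives(labels, positiveLabels)
  if (!any(pos) || all(pos))
    stop("calibration requires both classes")
  sp <- scores[pos]; sn <- scores[!pos]
  cand <- sort(unique(c(scores, min(scores) - 1)))
  tpr <- vapply(cand, function(t) mean(sp <= t), numeric(1))
  fpr <- vapply(cand, function(t) mean(sn <= t), numeric(1))
  mid <- function(i) {
    nxt <- cand[cand > cand[i]]
    if (length(nxt) == 0) cand[i] else (cand[i] + min(nxt)) / 2
  }
  if (is.null(looseFpr)) {
    j <- tpr - fpr
    iLoose <- which(j == max(j))[1]  # ties -> lower threshold
  } else {
    okL <- which(fpr <= looseFpr)
    iLoose <- okL[length(okL)]
  }
  ok <- which(fpr <= stringentFpr)
  iStr <- ok[length(ok)]
  if (tpr[iStr] == 0 || (!is.null(looseFpr) && tpr[iLoose] == 0))
    warning("requested FPR bound only attainable at zero recall; ",
            "returning the closest attainable threshold")
  loose <- mid(iLoose)
  stringent <- min(mid(iStr), loose)
  classifierConfig(loose = loose, stringent = stringent)
}
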