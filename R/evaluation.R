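# ROC/AUC, Youden cutoff, confusion metrics, stratified evaluation and
# expert-agreement cross-tabulation.

#' ROC curve and AUC
#'
#' AUC via the rank (Mann-Whitney) statistic with half credit for tied
#' scores; the ROC polyline is swept over the unique observed scores with
#' (0,0) and (1,1) sentinels, so its trapezoidal integral equals the rank
#' AUC exactly.
#'
#' @param scores Numeric scores, higher meaning more likely positive.
#' @param labels Two-class labels.
#' @param positive The positive-class label (default `"malignant"`).
#' @return List with `auc` and `roc_points` (data frame of `threshold`,
#'   `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels, positive = "malignant") {
  y <- as_binary_label(labels, positive)
  pos <- y == positive
  if (anyNA(scores)) stopf("scores contain NA")
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  roc <- data.frame(threshold = c(Inf, thr, -Inf),
                    fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  list(auc = auc, roc_points = roc)
}

#' Youden-optimal cutoff
#'
#' The cutoff maximizing Youden's \eqn{J = sensitivity + specificity - 1},
#' where a subject is called positive when its score is at or above the
#' cutoff. Candidate cutoffs are the unique observed scores; ties in J are
#' resolved to the lowest cutoff.
#'
#' @inheritParams roc_auc
#' @return List with `cutoff` and `J`.
#' @export
youden_cutoff <- function(scores, labels, positive = "malignant") {
  y <- as_binary_label(labels, positive)
  pos <- y == positive
  thr <- sort(unique(scores))
  J <- vapply(thr, function(t) {
    mean(scores[pos] >= t) + mean(scores[!pos] < t) - 1
  }, numeric(1))
  best <- which.max(J)  # which.max returns the first (lowest) maximizer
  list(cutoff = thr[best], J = J[best])
}

#' Confusion-matrix metrics at a cutoff
#'
#' Sensitivity, specificity, PPV, NPV and accuracy of the rule
#' "positive iff score >= cutoff". Metrics whose denominator is zero are
#' reported as `NA` rather than raising an error.
#'
#' @inheritParams roc_auc
#' @param cutoff Decision cutoff.
#' @return Named list of the five metrics plus the 2x2 counts
#'   (`tp`, `fp`, `tn`, `fn`).
#' @export
confusion_metrics <- function(scores, labels, cutoff,
                              positive = "malignant") {
  y <- as_binary_label(labels, positive)
  pos <- y == positive
  call_pos <- scores >= cutoff
  tp <- sum(call_pos & pos); fp <- sum(call_pos & !pos)
  fn <- sum(!call_pos & pos); tn <- sum(!call_pos & !pos)
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  list(sensitivity = safe_div(tp, tp + fn),
       specificity = safe_div(tn, tn + fp),
       ppv = safe_div(tp, tp + fp),
       npv = safe_div(tn, tn + fn),
       accuracy = (tp + tn) / length(scores),
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Full evaluation report for a set of scores
#'
#' ROC/AUC plus the confusion metrics at the supplied cutoff (or at the
#' Youden cutoff of these scores when none is given).
#'
#' @inheritParams roc_auc
#' @param cutoff Decision cutoff; defaults to the Youden cutoff computed on
#'   `scores`.
#' @return Object of class `"evaluation_report"`.
#' @export
evaluation_report <- function(scores, labels, cutoff = NULL,
                              positive = "malignant") {
  ra <- roc_auc(scores, labels, positive)
  if (is.null(cutoff)) cutoff <- youden_cutoff(scores, labels, positive)$cutoff
  structure(list(auc = ra$auc, roc_points = ra$roc_points, cutoff = cutoff,
                 at_cutoff = confusion_metrics(scores, labels, cutoff,
                                               positive),
                 n = length(scores), positive = positive),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, digits = 3, ...) {
  cat(sprintf("Evaluation (n = %d, positive = %s)\n", x$n, x$positive))
  cat(sprintf("  AUC %.*f; cutoff %.*f\n", digits, x$auc, digits, x$cutoff))
  m <- x$at_cutoff
  cat(sprintf("  sens %.*f  spec %.*f  ppv %.*f  npv %.*f  acc %.*f\n",
              digits, m$sensitivity, digits, m$specificity, digits, m$ppv,
              digits, m$npv, digits, m$accuracy))
  invisible(x)
}

stratum_subsets <- function(metadata, strata) {
  out <- list()
  for (s in strata) {
    if (s == "ggn") {
      if (!"ggn" %in% names(metadata)) stopf("metadata has no 'ggn' column")
      out[["ggn"]] <- !is.na(metadata$ggn) & metadata$ggn
      out[["non_ggn"]] <- !is.na(metadata$ggn) & !metadata$ggn
    } else if (s %in% c("size20", "size10")) {
      if (!"nodule_size_mm" %in% names(metadata)) {
        stopf("metadata has no 'nodule_size_mm' column")
      }
      lim <- if (s == "size20") 20 else 10
      out[[paste0("size_le_", lim, "mm")]] <-
        !is.na(metadata$nodule_size_mm) & metadata$nodule_size_mm <= lim
    } else if (s == "stage") {
      if (!"stage" %in% names(metadata)) stopf("metadata has no 'stage' column")
      for (st in intersect(STAGES, stats::na.omit(metadata$stage))) {
        out[[paste0("stage_", st)]] <- metadata$label == "benign" |
          (!is.na(metadata$stage) & metadata$stage == st)
      }
    } else {
      stopf("unknown stratum key '%s'", s)
    }
  }
  out
}

#' Stratified diagnostic evaluation
#'
#' Evaluates a score vector overall and within clinically defined strata:
#' GGN vs non-GGN nodules, nodules of at most 20 mm / 10 mm, and per-stage
#' subsets (each stage pooled with all benign subjects). All strata reuse
#' the single global cutoff. A stratum missing one of the two classes is
#' reported as insufficient instead of failing. Also returns the
#' waterfall table of `score - cutoff` per subject, sorted by value.
#'
#' @inheritParams roc_auc
#' @param metadata Subject metadata aligned with `scores` (same order as
#'   `labels`; must contain `subject_id`).
#' @param cutoff Global decision cutoff; defaults to the Youden cutoff of
#'   the supplied scores.
#' @param strata Stratum keys among `"ggn"`, `"size20"`, `"size10"`,
#'   `"stage"`.
#' @return List with `overall` (an [evaluation_report()]), `strata` (named
#'   list of reports or `insufficient` markers) and `waterfall`.
#' @export
stratified_evaluation <- function(scores, labels, metadata,
                                  strata = c("ggn", "size20", "size10"),
                                  cutoff = NULL, positive = "malignant") {
  if (length(scores) != nrow(metadata)) {
    stopf("scores and metadata are misaligned")
  }
  if (is.null(cutoff)) cutoff <- youden_cutoff(scores, labels, positive)$cutoff
  overall <- evaluation_report(scores, labels, cutoff, positive)
  subsets <- stratum_subsets(metadata, strata)
  strat <- lapply(subsets, function(idx) {
    if (length(unique(labels[idx])) < 2L) {
      list(insufficient = TRUE, n = sum(idx),
           reason = "only one class present")
    } else {
      evaluation_report(scores[idx], labels[idx], cutoff, positive)
    }
  })
  wf <- data.frame(subject_id = metadata$subject_id, label = labels,
                   score_minus_cutoff = scores - cutoff,
                   stringsAsFactors = FALSE)
  wf <- wf[order(wf$score_minus_cutoff, wf$subject_id, method = "radix"), ,
           drop = FALSE]
  rownames(wf) <- NULL
  list(overall = overall, strata = strat, waterfall = wf, cutoff = cutoff)
}

#' Cross-tabulate model calls against expert calls and pathology truth
#'
#' Counts every (truth, expert, model) label combination, reports accuracy
#' per source and per-source lists of misclassified subjects.
#'
#' @param truth Named or plain vector of pathology labels.
#' @param model_labels Model calls, aligned with `truth`.
#' @param expert_labels Data frame (one column per rater) or vector of
#'   expert calls, aligned with `truth`.
#' @param subject_ids Optional subject identifiers for the misclassification
#'   lists.
#' @return List with `table` (counts data frame), `accuracy` (named vector)
#'   and `misclassified` (named list of subject ids).
#' @export
expert_agreement_table <- function(truth, model_labels, expert_labels,
                                   subject_ids = NULL) {
  if (is.null(dim(expert_labels))) {
    expert_labels <- data.frame(expert = expert_labels,
                                stringsAsFactors = FALSE)
  }
  n <- length(truth)
  if (length(model_labels) != n || nrow(expert_labels) != n) {
    stopf("truth, model and expert labels are misaligned")
  }
  subject_ids <- subject_ids %||% as.character(seq_len(n))
  combos <- data.frame(truth = as.character(truth),
                       expert_labels,
                       model = as.character(model_labels),
                       stringsAsFactors = FALSE)
  counts <- stats::aggregate(list(n = seq_len(n)), combos, FUN = length)
  sources <- c(names(expert_labels), "model")
  calls <- cbind(expert_labels, model = as.character(model_labels))
  accuracy <- vapply(sources, function(s) {
    mean(calls[[s]] == as.character(truth))
  }, numeric(1))
  mis <- lapply(sources, function(s) {
    subject_ids[calls[[s]] != as.character(truth)]
  })
  names(mis) <- sources
  list(table = counts, accuracy = accuracy, misclassified = mis)
}
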