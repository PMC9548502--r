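# Cohort feature assembly and feature ranking by random-forest importance
# and information gain.

CLINICAL_FEATURES <- c("ggn", "nodule_size_mm", "age_years", "sex")

#' Assemble the cohort feature table
#'
#' Inner-joins per-subject diversity profiles with clinical metadata into
#' one modelling table: TCR features (diversity indices, richness, clone
#' reads, clonal-homeostasis bin fractions) plus encoded clinical
#' covariates (`ggn` and `sex` as 0/1, sex: M = 0, F = 1). Missing numeric
#' covariates are imputed with the cohort median; imputations are recorded
#' in the `"imputation_log"` attribute.
#'
#' @param profiles Output of [diversity_profiles()].
#' @param metadata Subject metadata (see [read_metadata()]).
#' @return Data frame with `subject_id`, `label`, the TCR feature columns
#'   and available clinical columns. Attributes: `"tcr_features"` (names of
#'   TCR-derived columns, used by [ablate_tcr_features()]) and
#'   `"imputation_log"`.
#' @export
assemble_features <- function(profiles, metadata) {
  validate_metadata(metadata)
  orphans <- setdiff(profiles$subject_id, metadata$subject_id)
  if (length(orphans)) {
    stopf("profile subject(s) missing from metadata: %s",
          paste(orphans, collapse = ", "))
  }
  tcr_cols <- setdiff(names(profiles), "subject_id")
  keep_md <- c("subject_id", "label",
               intersect(CLINICAL_FEATURES, names(metadata)))
  tab <- merge(profiles, metadata[, keep_md], by = "subject_id")
  if ("ggn" %in% names(tab)) tab$ggn <- as.numeric(tab$ggn)
  if ("sex" %in% names(tab)) tab$sex <- as.numeric(tab$sex == "F")

  log <- data.frame(subject_id = character(0), column = character(0),
                    value = numeric(0), stringsAsFactors = FALSE)
  for (col in setdiff(names(tab), c("subject_id", "label"))) {
    miss <- is.na(tab[[col]])
    if (any(miss)) {
      med <- stats::median(tab[[col]], na.rm = TRUE)
      log <- rbind(log, data.frame(subject_id = tab$subject_id[miss],
                                   column = col, value = med,
                                   stringsAsFactors = FALSE))
      tab[[col]][miss] <- med
    }
  }
  tab <- tab[, c("subject_id", "label", tcr_cols,
                 setdiff(names(tab), c("subject_id", "label", tcr_cols)))]
  rownames(tab) <- NULL
  attr(tab, "tcr_features") <- tcr_cols
  attr(tab, "imputation_log") <- log
  tab
}

entropy_bits <- function(x) {
  p <- table(x) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Information gain of a feature about the class label
#'
#' \eqn{IG = H(label) - H(label \mid feature)} in bits. Continuous features
#' are discretized first (quartile bins by default); features with at most
#' `bins` distinct values are treated as categorical as-is.
#'
#' @param x Feature vector.
#' @param labels Two-class label vector.
#' @param bins Number of discretization bins (default 4).
#' @param binning `"quantile"` (default) or `"width"` (equal-width).
#' @return Information gain in bits, in \[0, H(label)\].
#' @export
information_gain <- function(x, labels, bins = 4L,
                             binning = c("quantile", "width")) {
  binning <- match.arg(binning)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) stopf("labels contain a single class")
  if (length(x) != length(labels)) stopf("x and labels differ in length")
  ux <- unique(x)
  if (length(ux) > bins) {
    breaks <- if (binning == "quantile") {
      unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1L),
                             na.rm = TRUE))
    } else {
      seq(min(x), max(x), length.out = bins + 1L)
    }
    if (length(breaks) < 2L) breaks <- c(breaks, breaks + 1)
    x <- cut(x, breaks = breaks, include.lowest = TRUE)
  }
  h <- entropy_bits(labels)
  cond <- 0
  for (lv in unique(x)) {
    idx <- x == lv
    cond <- cond + mean(idx) * entropy_bits(labels[idx])
  }
  max(h - cond, 0)
}

#' Random-forest feature importance
#'
#' Mean-decrease-impurity (Gini) importances from a classification random
#' forest, normalized to sum to 1. Reproducible under the supplied seed.
#'
#' @param x Data frame of numeric features.
#' @param labels Two-class label vector.
#' @param ntree Number of trees (default 500).
#' @param seed Integer seed.
#' @return Named numeric vector of importances summing to 1.
#' @export
rf_importance <- function(x, labels, ntree = 500L, seed = 1L) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) stopf("labels contain a single class")
  y <- factor(labels)
  imp <- with_seed(seed, {
    fit <- randomForest::randomForest(x = x, y = y, ntree = ntree)
    fit$importance[, "MeanDecreaseGini"]
  })
  if (sum(imp) > 0) imp <- imp / sum(imp)
  imp
}

#' Rank candidate features by random forest and information gain
#'
#' Computes both random-forest importance and information gain for every
#' feature, drops features that are constant across the cohort (with a
#' warning), and fuses the two orderings by the mean of the per-method
#' ranks; ties are broken by information gain, then by feature name.
#'
#' @param table Feature table from [assemble_features()].
#' @param label_col Name of the label column (default `"label"`).
#' @param exclude Columns to exclude from ranking (besides `subject_id` and
#'   the label).
#' @param ntree,seed Passed to [rf_importance()].
#' @param bins,binning Passed to [information_gain()].
#' @return Data frame of class `"feature_ranking"` with `feature`,
#'   `rf_importance`, `info_gain` and `combined_rank`, ordered best first.
#' @export
rank_features <- function(table, label_col = "label", exclude = character(0),
                          ntree = 500L, seed = 1L, bins = 4L,
                          binning = "quantile") {
  feats <- setdiff(names(table), c("subject_id", label_col, exclude))
  labels <- table[[label_col]]
  const <- vapply(table[feats], function(v) length(unique(v)) < 2L,
                  logical(1))
  if (any(const)) {
    warning(sprintf("dropping constant feature(s): %s",
                    paste(feats[const], collapse = ", ")), call. = FALSE)
    feats <- feats[!const]
  }
  if (!length(feats)) stopf("no non-constant features to rank")
  x <- table[feats]
  rf <- rf_importance(x, labels, ntree = ntree, seed = seed)
  ig <- vapply(feats, function(f) {
    information_gain(table[[f]], labels, bins = bins, binning = binning)
  }, numeric(1))
  rank_rf <- rank(-rf, ties.method = "average")
  rank_ig <- rank(-ig, ties.method = "average")
  mean_rank <- (rank_rf + rank_ig) / 2
  ord <- order(mean_rank, -ig, feats, method = "radix")
  out <- data.frame(feature = feats[ord],
                    rf_importance = unname(rf[ord]),
                    info_gain = unname(ig[ord]),
                    mean_rank = mean_rank[ord],
                    combined_rank = seq_along(feats),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("feature_ranking", "data.frame")
  out
}

#' Select the top-k features from a ranking
#' @param ranking A [rank_features()] result.
#' @param k Number of features (default 3, the size of the diagnostic
#'   feature triple used for the nodule classifier).
#' @return Character vector of the k best features, best first.
#' @export
select_top_features <- function(ranking, k = 3L) {
  stopifnot(inherits(ranking, "feature_ranking"))
  if (k > nrow(ranking)) {
    stopf("k (%d) exceeds the number of ranked features (%d)", k,
          nrow(ranking))
  }
  ranking$feature[seq_len(k)]
}
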