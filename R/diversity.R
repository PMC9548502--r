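# Repertoire diversity indices, clonal-homeostasis binning, and the cohort
# group comparisons / clinical correlations built on them.

check_fractions <- function(fractions, tol = 1e-8) {
  if (length(fractions) == 0L) stopf("empty fraction vector")
  if (any(!is.finite(fractions)) || any(fractions <= 0)) {
    stopf("clonal fractions must be positive and finite")
  }
  if (abs(sum(fractions) - 1) > tol) {
    stopf("clonal fractions must sum to 1 (got %.12g)", sum(fractions))
  }
  invisible(fractions)
}

#' Shannon diversity of a clonal-fraction distribution
#'
#' \eqn{H = -\sum_i p_i \ln p_i} in nats; 0 for a monoclonal repertoire and
#' \eqn{\ln S} for S equally abundant clones.
#'
#' @param fractions Positive clonal fractions summing to 1.
#' @return Non-negative Shannon entropy in nats.
#' @export
#' @examples
#' shannon_index(rep(0.25, 4))  # log(4)
shannon_index <- function(fractions) {
  check_fractions(fractions)
  -sum(fractions * log(fractions))
}

#' Pielou evenness and clonality
#'
#' Evenness is Shannon entropy normalized by its maximum, \eqn{H/\ln S};
#' clonality is its complement \eqn{1 - H/\ln S}. A monoclonal repertoire
#' (S = 1) takes the maximal-monoclonality limit: evenness 0, clonality 1.
#'
#' @inheritParams shannon_index
#' @return Named list with `evenness` and `clonality`, both in \[0, 1\].
#' @export
evenness_clonality <- function(fractions) {
  check_fractions(fractions)
  s <- length(fractions)
  evenness <- if (s < 2L) 0 else shannon_index(fractions) / log(s)
  list(evenness = evenness, clonality = 1 - evenness)
}

#' Gini-Simpson diversity
#'
#' \eqn{1 - \sum_i p_i^2}: the probability that two reads drawn at random
#' come from different clones.
#'
#' @inheritParams shannon_index
#' @return Value in \[0, 1).
#' @export
simpson_index <- function(fractions) {
  check_fractions(fractions)
  1 - sum(fractions^2)
}

#' Default clonal-homeostasis bin thresholds
#'
#' Upper clonal-fraction bounds of the rare/small/medium/large bins (the
#' hyperexpanded bin runs to 1). The widely used clonal-homeostasis
#' convention: rare (0, 1e-5], small (1e-5, 1e-4], medium (1e-4, 1e-3],
#' large (1e-3, 1e-2], hyperexpanded (1e-2, 1].
#'
#' @return Named numeric vector of four strictly increasing thresholds.
#' @export
clone_type_bins <- function() {
  c(rare = 1e-5, small = 1e-4, medium = 1e-3, large = 1e-2)
}

CLONE_TYPES <- c("rare", "small", "medium", "large", "hyperexpanded")

#' Classify clones into the five clonal-homeostasis types
#'
#' Each clone falls into exactly one right-closed clonal-fraction interval:
#' rare, small, medium, large, or hyperexpanded. Returns both the read mass
#' (summed clonal fraction) and the clone count per bin.
#'
#' @param rep A [repertoire()].
#' @param bins Four strictly increasing thresholds in (0, 1); see
#'   [clone_type_bins()].
#' @return List with `mass` and `counts`, each a named vector over the five
#'   types; the mass vector sums to 1.
#' @export
classify_clone_types <- function(rep, bins = clone_type_bins()) {
  stopifnot(inherits(rep, "repertoire"))
  bins <- as.numeric(bins)
  if (length(bins) != 4L || any(diff(bins) <= 0) || bins[1] <= 0 ||
      bins[4] >= 1) {
    stopf("bins must be 4 strictly increasing thresholds in (0, 1)")
  }
  breaks <- c(0, bins, 1)
  type <- cut(rep$clones$fraction, breaks = breaks, labels = CLONE_TYPES,
              right = TRUE)
  mass <- vapply(CLONE_TYPES, function(t) {
    sum(rep$clones$fraction[type == t])
  }, numeric(1))
  counts <- vapply(CLONE_TYPES, function(t) sum(type == t), numeric(1))
  list(mass = mass, counts = counts)
}

#' Per-subject diversity profile
#'
#' Computes the full per-subject feature vector: clone richness, total clone
#' reads, Shannon index, Pielou evenness, Gini-Simpson index, clonality, and
#' the read-mass fraction in each of the five clonal-homeostasis bins.
#'
#' @inheritParams classify_clone_types
#' @return One-row data frame.
#' @export
diversity_profile <- function(rep, bins = clone_type_bins()) {
  stopifnot(inherits(rep, "repertoire"))
  p <- rep$clones$fraction
  ec <- evenness_clonality(p)
  ct <- classify_clone_types(rep, bins)
  out <- data.frame(
    subject_id = rep$subject_id,
    richness = nrow(rep$clones),
    clone_reads = rep$total_count,
    shannon = shannon_index(p),
    evenness = ec$evenness,
    simpson = simpson_index(p),
    clonality = ec$clonality,
    stringsAsFactors = FALSE
  )
  for (t in CLONE_TYPES) out[[paste0("frac_", t)]] <- ct$mass[[t]]
  out
}

#' Diversity profiles for a list of repertoires
#' @param repertoires List of [repertoire()] objects.
#' @inheritParams classify_clone_types
#' @return Data frame, one row per subject.
#' @export
diversity_profiles <- function(repertoires, bins = clone_type_bins()) {
  do.call(rbind, lapply(repertoires, diversity_profile, bins = bins))
}

#' Compare a repertoire feature between benign and malignant groups
#'
#' Two-sided Wilcoxon rank-sum test of one profile feature between the two
#' label groups, optionally run separately within the strata of a metadata
#' covariate (e.g. GGN vs non-GGN).
#'
#' @param profiles Data frame from [diversity_profiles()] (or any per-subject
#'   feature table with `subject_id`).
#' @param metadata Subject metadata (see [read_metadata()]).
#' @param feature Name of the feature column to compare.
#' @param stratify_by Optional metadata column; the test is run within each
#'   of its levels.
#' @return Data frame with one row per stratum: the stratum, group medians,
#'   Wilcoxon W, two-sided p-value, direction (sign of the
#'   benign-minus-malignant median difference) and the test name.
#' @export
compare_groups <- function(profiles, metadata, feature,
                           stratify_by = NULL) {
  if (!feature %in% names(profiles)) stopf("unknown feature '%s'", feature)
  dat <- merge(profiles[, c("subject_id", feature)],
               metadata, by = "subject_id")
  strata <- if (is.null(stratify_by)) list(all = rep(TRUE, nrow(dat))) else {
    if (!stratify_by %in% names(dat)) stopf("unknown covariate '%s'",
                                            stratify_by)
    v <- dat[[stratify_by]]
    lv <- sort(unique(v[!is.na(v)]))
    stats::setNames(lapply(lv, function(s) !is.na(v) & v == s),
                    as.character(lv))
  }
  rows <- lapply(names(strata), function(sname) {
    sub <- dat[strata[[sname]], , drop = FALSE]
    x <- sub[[feature]][sub$label == "benign"]
    y <- sub[[feature]][sub$label == "malignant"]
    if (length(x) < 2L || length(y) < 2L) {
      stopf("stratum '%s' has fewer than 2 subjects in a group", sname)
    }
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = NULL))
    p_val <- wt$p.value
    if (is.na(p_val)) p_val <- 1  # fully tied groups carry no evidence
    data.frame(feature = feature, stratum = sname,
               group_a = "benign", group_b = "malignant",
               median_a = stats::median(x), median_b = stats::median(y),
               statistic = unname(wt$statistic), p_value = p_val,
               direction = sign(stats::median(x) - stats::median(y)),
               test = "wilcoxon_rank_sum", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Spearman correlations between repertoire features and clinical covariates
#'
#' Tie-corrected Spearman rank correlation for every feature-covariate pair,
#' using pairwise-complete observations. A constant feature or covariate
#' yields `NA` with a warning rather than an error.
#'
#' @inheritParams compare_groups
#' @param features Feature columns of `profiles` to use; defaults to all
#'   numeric columns.
#' @param covariates Metadata columns to use; defaults to the numeric and
#'   logical clinical columns present.
#' @return List with matrices `rho` and `p_value` (features x covariates).
#' @export
correlate_features_clinical <- function(profiles, metadata, features = NULL,
                                        covariates = NULL) {
  dat <- merge(profiles, metadata, by = "subject_id")
  if (is.null(features)) {
    features <- setdiff(names(profiles)[vapply(profiles, is.numeric,
                                               logical(1))], "subject_id")
  }
  if (is.null(covariates)) {
    cand <- c("nodule_size_mm", "age_years", "ggn")
    covariates <- intersect(cand, names(metadata))
  }
  if (nrow(dat) < 3L) stopf("need at least 3 subjects for correlation")
  rho <- p <- matrix(NA_real_, length(features), length(covariates),
                     dimnames = list(features, covariates))
  for (f in features) for (cv in covariates) {
    x <- dat[[f]]
    y <- as.numeric(dat[[cv]])
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3L) next
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      warning(sprintf("constant values for %s/%s: correlation undefined",
                      f, cv), call. = FALSE)
      next
    }
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok],
                                           method = "spearman"))
    rho[f, cv] <- unname(ct$estimate)
    p[f, cv] <- ct$p.value
  }
  list(rho = rho, p_value = p)
}
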