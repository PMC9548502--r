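# Subject metadata and feature-table serialization.

STAGES <- c("I", "II", "III")

validate_metadata <- function(md) {
  req <- c("subject_id", "label")
  miss <- setdiff(req, names(md))
  if (length(miss)) stopf("metadata missing column(s): %s",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(md$subject_id)) {
    stopf("duplicate subject_id in metadata: %s",
          paste(unique(md$subject_id[duplicated(md$subject_id)]),
                collapse = ", "))
  }
  bad <- setdiff(unique(md$label), c("benign", "malignant"))
  if (length(bad)) stopf("unknown label(s): %s", paste(bad, collapse = ", "))
  if ("stage" %in% names(md)) {
    has_stage <- !is.na(md$stage) & nzchar(as.character(md$stage))
    bad <- setdiff(unique(md$stage[has_stage]), STAGES)
    if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
    wrong <- has_stage & md$label == "benign"
    if (any(wrong)) {
      stopf("stage recorded for benign subject(s): %s",
            paste(md$subject_id[wrong], collapse = ", "))
    }
  }
  if ("nodule_size_mm" %in% names(md)) {
    sz <- md$nodule_size_mm
    if (any(!is.na(sz) & sz <= 0)) stopf("nodule_size_mm must be positive")
  }
  if ("sex" %in% names(md)) {
    bad <- setdiff(unique(md$sex[!is.na(md$sex)]), c("M", "F"))
    if (length(bad)) stopf("unknown sex value(s): %s",
                           paste(bad, collapse = ", "))
  }
  invisible(md)
}

#' Read a subject metadata table
#'
#' Reads a CSV or TSV with one row per subject. Required columns:
#' `subject_id` and `label` (`benign`/`malignant`). Recognized optional
#' columns: `stage` (I/II/III, malignant subjects only), `ggn` (logical
#' ground-glass-nodule flag, also accepts 0/1/yes/no), `nodule_size_mm`,
#' `age_years`, `sex` (M/F). Unknown labels, duplicated subjects, stages on
#' benign subjects and non-positive nodule sizes are rejected.
#'
#' @param path Path to a `.csv` (comma) or `.tsv`/`.txt` (tab) file.
#' @return A data frame of validated subject metadata.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stopf("metadata file not found: %s", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  md <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, na.strings = c("", "NA"))
  md$subject_id <- as.character(md$subject_id)
  md$label <- as.character(md$label)
  if ("ggn" %in% names(md)) {
    g <- tolower(as.character(md$ggn))
    md$ggn <- g %in% c("true", "t", "1", "yes")
    md$ggn[is.na(g)] <- NA
  }
  if ("stage" %in% names(md)) md$stage <- as.character(md$stage)
  if ("sex" %in% names(md)) md$sex <- toupper(as.character(md$sex))
  validate_metadata(md)
}

#' Write a subject metadata table
#' @param md Metadata data frame (see [read_metadata()]).
#' @param path Output path (`.csv` for comma-separated, otherwise tab).
#' @return Invisibly, `path`.
#' @export
write_metadata <- function(md, path) {
  validate_metadata(md)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(md, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

# Full-precision numeric formatting so feature tables round-trip exactly.
format_full <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Write a cohort feature table
#'
#' Serializes a subjects-by-features table as TSV with a deterministic column
#' order, full numeric precision (17 significant digits, so values survive a
#' write/read round trip bit-exactly) and empty strings for missing values.
#'
#' @param table Data frame with at least one row; typically the output of
#'   [assemble_features()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stopf("feature table must be a non-empty data frame")
  }
  out <- table
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- format_full(out[[j]])
    if (is.logical(out[[j]])) out[[j]] <- ifelse(is.na(out[[j]]), "",
                                                 as.character(out[[j]]))
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stopf("failed to write feature table to %s: %s",
                         path, conditionMessage(ok))
  invisible(path)
}

#' Read a cohort feature table written by [write_feature_table()]
#' @param path TSV path.
#' @return Data frame with numeric columns restored.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stopf("feature table not found: %s", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE, na.strings = "",
                           check.names = FALSE)
  for (j in seq_along(tab)) {
    v <- tab[[j]]
    if (is.character(v)) {
      if (all(is.na(v) | v %in% c("TRUE", "FALSE"))) {
        tab[[j]] <- as.logical(v)
      }
    }
  }
  tab
}
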