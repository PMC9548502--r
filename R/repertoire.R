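# Clonotype repertoires: construction, validation, and AIRR-style table input.

#' Column mapping for AIRR-style clonotype tables
#'
#' Describes how the columns of a tab-separated clonotype table map onto the
#' fields of a clonotype record. The defaults follow the AIRR Rearrangement
#' naming convention (`junction_aa`, `v_call`, `j_call`, `duplicate_count`);
#' override any entry to read other dialects (e.g. MiXCR exports).
#'
#' @param cdr3_aa Column holding the CDR3\eqn{\beta} amino-acid sequence.
#' @param v_gene,j_gene Columns holding V/J gene calls; set to `NA` if the
#'   table has none.
#' @param count Column holding the clone read/copy count.
#' @return A named list usable as the `dialect` argument of
#'   [read_clonotype_table()].
#' @export
#' @examples
#' airr_dialect()
#' airr_dialect(cdr3_aa = "aaSeqCDR3", count = "cloneCount")
airr_dialect <- function(cdr3_aa = "junction_aa", v_gene = "v_call",
                         j_gene = "j_call", count = "duplicate_count") {
  list(cdr3_aa = cdr3_aa, v_gene = v_gene, j_gene = j_gene, count = count)
}

validate_cdr3 <- function(cdr3_aa, allow_special = FALSE) {
  if (any(is.na(cdr3_aa)) || any(!nzchar(cdr3_aa))) {
    stopf("CDR3 amino-acid sequences must be non-empty")
  }
  alphabet <- AA_LETTERS
  if (allow_special) alphabet <- c(alphabet, "*", "_")
  ok <- !grepl(sprintf("[^%s]", paste(gsub("([*])", "\\\\\\1", alphabet),
                                      collapse = "")), cdr3_aa)
  if (!all(ok)) {
    bad <- utils::head(unique(cdr3_aa[!ok]), 5L)
    stopf("non-amino-acid characters in CDR3 sequence(s): %s",
          paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Construct a clonotype repertoire
#'
#' Bundles one subject's clonotypes into a validated repertoire: records with
#' the same clone key are aggregated by summing counts, clonal fractions
#' (count / total reads) are computed, and clones are ordered by descending
#' count with lexicographic tie-breaking so the representation is
#' deterministic.
#'
#' @param subject_id Subject identifier.
#' @param cdr3_aa Character vector of CDR3\eqn{\beta} amino-acid sequences
#'   over the 20-letter alphabet.
#' @param count Positive integer read/copy counts, one per sequence.
#' @param v_gene,j_gene Optional gene calls, recycled to the number of rows.
#' @param clone_key `"cdr3_aa"` (default; sequence-level identity, the
#'   convention used for public-clone sharing analyses) or `"cdr3_vj"` to key
#'   clones on the (sequence, V, J) triple.
#' @param allow_special If `TRUE`, accept `*` and `_` (stop/frameshift
#'   markers) in sequences instead of rejecting them.
#' @return An object of class `"repertoire"`: a list with `subject_id`,
#'   `clones` (data frame with `cdr3_aa`, `v_gene`, `j_gene`, `count`,
#'   `fraction`), and `total_count`.
#' @export
#' @examples
#' r <- repertoire("S1", c("CASSLGYF", "CASSPGQF", "CASSLGYF"), c(4, 3, 6))
#' r$clones
repertoire <- function(subject_id, cdr3_aa, count, v_gene = NA_character_,
                       j_gene = NA_character_,
                       clone_key = c("cdr3_aa", "cdr3_vj"),
                       allow_special = FALSE) {
  clone_key <- match.arg(clone_key)
  cdr3_aa <- as.character(cdr3_aa)
  if (length(cdr3_aa) == 0L) stopf("repertoire must contain at least one clone")
  if (length(count) != length(cdr3_aa)) {
    stopf("'count' must have one entry per sequence")
  }
  bad <- which(!is.finite(count) | count < 1 | count != floor(count))
  if (length(bad)) {
    stopf("counts must be positive integers; offending row(s): %s",
          paste(utils::head(bad, 5L), collapse = ", "))
  }
  validate_cdr3(cdr3_aa, allow_special = allow_special)
  v_gene <- rep_len(as.character(v_gene), length(cdr3_aa))
  j_gene <- rep_len(as.character(j_gene), length(cdr3_aa))

  key <- if (clone_key == "cdr3_aa") cdr3_aa else {
    paste(cdr3_aa, v_gene, j_gene, sep = "\r")
  }
  agg <- rowsum(as.numeric(count), group = key, reorder = FALSE)
  first <- !duplicated(key)
  clones <- data.frame(
    cdr3_aa = cdr3_aa[first],
    v_gene = v_gene[first],
    j_gene = j_gene[first],
    count = as.numeric(agg[match(key[first], rownames(agg)), 1L]),
    stringsAsFactors = FALSE
  )
  ord <- order(-clones$count, clones$cdr3_aa, clones$v_gene, clones$j_gene,
               method = "radix")
  clones <- clones[ord, , drop = FALSE]
  rownames(clones) <- NULL
  total <- sum(clones$count)
  clones$fraction <- clones$count / total
  structure(
    list(subject_id = as.character(subject_id), clones = clones,
         total_count = total, clone_key = clone_key),
    class = "repertoire"
  )
}

#' @export
print.repertoire <- function(x, ...) {
  cat(sprintf("TCR repertoire: subject %s\n", x$subject_id))
  cat(sprintf("  %d distinct clones, %s total reads (clone key: %s)\n",
              nrow(x$clones), format(x$total_count, big.mark = ","),
              x$clone_key))
  cat(sprintf("  top clone fraction: %.4g\n", max(x$clones$fraction)))
  invisible(x)
}

# Clone keys of a repertoire under its configured identity.
clone_keys <- function(rep) {
  if (rep$clone_key == "cdr3_aa") rep$clones$cdr3_aa else {
    paste(rep$clones$cdr3_aa, rep$clones$v_gene, rep$clones$j_gene,
          sep = "\r")
  }
}

#' Read a clonotype table into a repertoire
#'
#' Parses a tab-separated clonotype/rearrangement table (AIRR-style column
#' names by default), validates every row, aggregates duplicate clone keys,
#' and returns a normalized [repertoire()].
#'
#' @param path Path to a TSV file with one header row.
#' @param dialect Column mapping, see [airr_dialect()].
#' @param subject_id Subject identifier; defaults to the file name without
#'   extension.
#' @inheritParams repertoire
#' @return A `"repertoire"` object.
#' @export
read_clonotype_table <- function(path, dialect = airr_dialect(),
                                 subject_id = NULL,
                                 clone_key = c("cdr3_aa", "cdr3_vj"),
                                 allow_special = FALSE) {
  clone_key <- match.arg(clone_key)
  if (!file.exists(path)) stopf("clonotype table not found: %s", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE, comment.char = "",
                           check.names = FALSE)
  for (field in c("cdr3_aa", "count")) {
    col <- dialect[[field]]
    if (is.null(col) || !col %in% names(tab)) {
      stopf("required column '%s' (field %s) missing from %s",
            col %||% "<unset>", field, path)
    }
  }
  count <- tab[[dialect$count]]
  bad <- which(!is.finite(count) | count < 1)
  if (length(bad)) {
    stopf("non-positive count in %s at data row(s): %s",
          path, paste(utils::head(bad, 5L), collapse = ", "))
  }
  getcol <- function(field) {
    col <- dialect[[field]]
    if (!is.null(col) && !is.na(col) && col %in% names(tab)) tab[[col]]
    else NA_character_
  }
  repertoire(
    subject_id = subject_id %||% sub("\\.[^.]*$", "", basename(path)),
    cdr3_aa = tab[[dialect$cdr3_aa]], count = count,
    v_gene = getcol("v_gene"), j_gene = getcol("j_gene"),
    clone_key = clone_key, allow_special = allow_special
  )
}

#' Write a repertoire as an AIRR-style clonotype table
#'
#' @param rep A `"repertoire"` object.
#' @param path Output TSV path.
#' @param dialect Column naming, see [airr_dialect()].
#' @return Invisibly, `path`.
#' @export
write_clonotype_table <- function(rep, path, dialect = airr_dialect()) {
  stopifnot(inherits(rep, "repertoire"))
  out <- data.frame(rep$clones$cdr3_aa, rep$clones$v_gene,
                    rep$clones$j_gene, rep$clones$count,
                    stringsAsFactors = FALSE)
  names(out) <- c(dialect$cdr3_aa, dialect$v_gene, dialect$j_gene,
                  dialect$count)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
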