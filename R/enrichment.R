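# Clone sharing across subjects, group-exclusive clones, enriched CDR3-beta
# sequence selection (top-30 / top-3000 / >=2-subjects rule) and common-motif
# extraction.

#' Index which subjects carry each clone
#'
#' Builds an exact-match index from clone key (CDR3\eqn{\beta} sequence by
#' default) to the set of subjects carrying it, together with the metadata
#' needed to resolve group membership.
#'
#' @param repertoires List of [repertoire()] objects.
#' @param metadata Subject metadata; every repertoire subject must appear.
#' @return Object of class `"sharing_index"`: list with `carriers` (named
#'   list clone key -> character vector of subject ids) and `metadata`.
#' @export
build_sharing_index <- function(repertoires, metadata) {
  validate_metadata(metadata)
  ids <- vapply(repertoires, function(r) r$subject_id, character(1))
  missing <- setdiff(ids, metadata$subject_id)
  if (length(missing)) {
    stopf("repertoire subject(s) absent from metadata: %s",
          paste(missing, collapse = ", "))
  }
  pairs <- do.call(rbind, lapply(repertoires, function(r) {
    data.frame(key = clone_keys(r), subject_id = r$subject_id,
               stringsAsFactors = FALSE)
  }))
  pairs <- unique(pairs)
  carriers <- split(pairs$subject_id, pairs$key)
  structure(list(carriers = carriers, metadata = metadata),
            class = "sharing_index")
}

#' @export
print.sharing_index <- function(x, ...) {
  supp <- lengths(x$carriers)
  cat(sprintf("Clone sharing index: %d distinct clones across %d subjects\n",
              length(x$carriers), length(unique(unlist(x$carriers)))))
  cat(sprintf("  public (>=2 subjects): %d (%.1f%%)\n", sum(supp >= 2),
              100 * mean(supp >= 2)))
  invisible(x)
}

group_subjects <- function(metadata, target_group) {
  if (target_group %in% metadata$label) {
    metadata$subject_id[metadata$label == target_group]
  } else if ("stage" %in% names(metadata) &&
             target_group %in% stats::na.omit(metadata$stage)) {
    metadata$subject_id[!is.na(metadata$stage) &
                          metadata$stage == target_group]
  } else {
    stopf("unknown group '%s' (not a label or stage in the metadata)",
          target_group)
  }
}

#' Clones exclusive to one group of subjects
#'
#' Returns the clone keys present in at least one subject of the target
#' group (a label, e.g. `"malignant"`, or a stage, e.g. `"I"`) and in no
#' subject outside it, plus the fraction of all distinct clones they
#' represent.
#'
#' @param index A [build_sharing_index()] result.
#' @param target_group Label or stage value defining the target group.
#' @return List with `keys` (character vector) and `exclusive_fraction`.
#' @export
group_exclusive_clones <- function(index, target_group) {
  stopifnot(inherits(index, "sharing_index"))
  target <- group_subjects(index$metadata, target_group)
  if (!length(target)) stopf("group '%s' has no subjects", target_group)
  excl <- vapply(index$carriers, function(s) all(s %in% target), logical(1))
  list(keys = names(index$carriers)[excl],
       exclusive_fraction = sum(excl) / length(index$carriers))
}

# top n sequences of one repertoire by fraction desc, count desc, sequence.
top_sequences <- function(rep, n) {
  cl <- rep$clones
  ord <- order(-cl$fraction, -cl$count, cl$cdr3_aa, method = "radix")
  cl$cdr3_aa[utils::head(ord, n)]
}

#' Select enriched CDR3\eqn{\beta} amino-acid sequences
#'
#' Implements the enrichment rule used to nominate condition-associated
#' sequences: the union of (a) every subject's top `top_per_subject`
#' sequences by clonal fraction and (b) the `top_pooled` sequences by summed
#' clonal fraction across subjects, filtered to sequences present in at
#' least `min_subjects` subjects. Ties are broken deterministically
#' (fraction, then count, then lexicographic). `rule` restricts selection to
#' one of the two sub-rules.
#'
#' @param repertoires List of [repertoire()] objects (typically the target
#'   group, e.g. malignant subjects).
#' @param top_per_subject Per-subject depth (default 30).
#' @param top_pooled Pooled depth (default 3000).
#' @param min_subjects Minimum subjects a sequence must appear in (default 2).
#' @param rule `"union"` (default), `"top_subject"`, or `"top_pooled"`.
#' @return Object of class `"enriched_set"`: data frame with `sequence`,
#'   `n_subjects`, `pooled_fraction` and `source`
#'   (`top30`/`top3000`/`both`), ordered by pooled fraction.
#' @export
select_enriched_sequences <- function(repertoires, top_per_subject = 30L,
                                      top_pooled = 3000L, min_subjects = 2L,
                                      rule = c("union", "top_subject",
                                               "top_pooled")) {
  rule <- match.arg(rule)
  if (length(repertoires) < 2L) stopf("need at least 2 subjects")
  if (min_subjects > length(repertoires)) {
    stopf("min_subjects (%d) exceeds the number of subjects (%d)",
          min_subjects, length(repertoires))
  }
  per_subject <- unique(unlist(lapply(repertoires, top_sequences,
                                      n = top_per_subject)))

  all_seq <- unlist(lapply(repertoires, function(r) r$clones$cdr3_aa))
  all_frac <- unlist(lapply(repertoires, function(r) r$clones$fraction))
  all_count <- unlist(lapply(repertoires, function(r) r$clones$count))
  pooled_frac <- rowsum(all_frac, all_seq)
  pooled_count <- rowsum(all_count, all_seq)
  seqs <- rownames(pooled_frac)
  ord <- order(-pooled_frac[, 1L], -pooled_count[, 1L], seqs,
               method = "radix")
  pooled <- seqs[utils::head(ord, top_pooled)]

  support <- table(unlist(lapply(repertoires, function(r) {
    unique(r$clones$cdr3_aa)
  })))

  chosen <- switch(rule,
                   union = union(per_subject, pooled),
                   top_subject = per_subject,
                   top_pooled = pooled)
  n_subj <- as.integer(support[chosen])
  keep <- n_subj >= min_subjects
  chosen <- chosen[keep]
  n_subj <- n_subj[keep]
  src <- ifelse(chosen %in% per_subject & chosen %in% pooled, "both",
                ifelse(chosen %in% per_subject, "top30", "top3000"))
  out <- data.frame(sequence = chosen, n_subjects = n_subj,
                    pooled_fraction = pooled_frac[chosen, 1L],
                    source = src, stringsAsFactors = FALSE)
  out <- out[order(-out$pooled_fraction, out$sequence, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enriched_set", "data.frame")
  out
}

all_substrings <- function(s, min_length) {
  n <- nchar(s)
  if (n < min_length) return(character(0))
  out <- unlist(lapply(min_length:n, function(L) {
    substring(s, seq_len(n - L + 1L), seq_len(n - L + 1L) + L - 1L)
  }))
  unique(out)
}

#' Find common amino-acid motifs among enriched sequences
#'
#' Enumerates all substrings of length at least `min_length`, keeps those
#' contained in at least `min_support` of the supplied sequences, and reports only
#' maximal motifs: a substring is suppressed when a longer substring is
#' carried by exactly the same set of sequences. Results are ranked by
#' support, then length, then alphabetically.
#'
#' @param sequences Character vector of sequences or an
#'   [select_enriched_sequences()] result.
#' @param min_length Minimum motif length (>= 3; default 5).
#' @param min_support Minimum number of distinct sequences containing the
#'   motif (default 2).
#' @return Data frame with `motif`, `support`, `length`, ranked best first.
#' @export
find_common_motifs <- function(sequences, min_length = 5L,
                               min_support = 2L) {
  if (inherits(sequences, "enriched_set")) sequences <- sequences$sequence
  sequences <- as.character(sequences)
  if (!length(sequences)) stopf("no sequences supplied")
  if (min_length < 3L) stopf("min_length must be >= 3")

  subs <- lapply(sequences, all_substrings, min_length = min_length)
  support <- table(unlist(subs))
  cand <- names(support)[support >= min_support]
  if (!length(cand)) {
    return(data.frame(motif = character(0), support = integer(0),
                      length = integer(0), stringsAsFactors = FALSE))
  }
  # support sets only for the (few) candidates
  sets <- lapply(cand, function(m) {
    which(vapply(sequences, function(s) {
      grepl(m, s, fixed = TRUE)
    }, logical(1), USE.NAMES = FALSE))
  })
  set_key <- vapply(sets, paste, character(1), collapse = ",")
  lens <- nchar(cand)
  keep <- rep(TRUE, length(cand))
  for (grp in split(seq_along(cand), set_key)) {
    if (length(grp) == 1L) next
    for (i in grp) {
      longer <- grp[lens[grp] > lens[i]]
      if (length(longer) &&
          any(grepl(cand[i], cand[longer], fixed = TRUE))) {
        keep[i] <- FALSE
      }
    }
  }
  out <- data.frame(motif = cand[keep],
                    support = as.integer(support[cand[keep]]),
                    length = lens[keep], stringsAsFactors = FALSE)
  out <- out[order(-out$support, -out$length, out$motif, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
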