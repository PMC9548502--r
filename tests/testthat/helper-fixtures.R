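# Shared fixture builders; everything generated in code at test time.

# A tiny repertoire from explicit counts.
toy_repertoire <- function(counts, subject_id = "S1",
                           seqs = NULL) {
  if (is.null(seqs)) {
    seqs <- vapply(seq_along(counts), function(i) {
      paste0("CASS", paste(rep(LETTERS[(i %% 20) + 1], 3), collapse = ""),
             "EQYF")
    }, character(1))
    # LETTERS includes non-amino-acid codes; map to a safe alphabet
    seqs <- chartr("BJOUXZ", "ACDEFG", seqs)
  }
  repertoire(subject_id, seqs, counts)
}

# Random repertoire with n clones and heavy-tailed counts.
random_repertoire <- function(n, subject_id = "R1") {
  counts <- pmax(1, round(stats::rlnorm(n, meanlog = 3, sdlog = 1.5)))
  seqs <- unique(tcrnodule:::random_cdr3(3 * n, c(8, 18)))[seq_len(n)]
  repertoire(subject_id, seqs, counts)
}

# Small cohort config for fast tests; any argument can be overridden.
fast_sim_config <- function(...) {
  args <- utils::modifyList(
    list(n_benign = 5L, n_malignant = 5L, clones_per_subject = 150L,
         reads_per_subject = 8000L),
    list(...))
  do.call(cohort_sim_config, args)
}

fast_ga <- function(seed = 1L, ...) {
  ga_config(population_size = 6L, generations = 3L, cv_folds = 3L,
            seed = seed, ...)
}

# Deterministic two-class feature table with one informative feature.
toy_feature_table <- function(n = 30, seed = 1) {
  tcrnodule:::with_seed(seed, {
    lab <- rep(c("benign", "malignant"), each = n / 2)
    data.frame(
      subject_id = sprintf("S%02d", seq_len(n)),
      label = lab,
      signal = stats::rnorm(n, ifelse(lab == "malignant", 2, 0)),
      noise = stats::rnorm(n),
      stringsAsFactors = FALSE
    )
  })
}

# Brute-force oracles ------------------------------------------------------

# AUC by exhaustive pair counting with half credit for ties.
auc_pairs <- function(scores, labels, positive = "malignant") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}

# Youden J by scanning every observed score as a candidate cutoff.
youden_scan <- function(scores, labels, positive = "malignant") {
  pos <- labels == positive
  best_j <- -Inf
  best_c <- NA_real_
  for (t in sort(unique(scores))) {
    j <- mean(scores[pos] >= t) + mean(scores[!pos] < t) - 1
    if (j > best_j + 1e-15) { best_j <- j; best_c <- t }
  }
  list(cutoff = best_c, J = best_j)
}

# All motifs >= min_length appearing in >= min_support sequences, maximal
# within identical support sets; independent of the package implementation.
motif_bruteforce <- function(seqs, min_length, min_support) {
  subs <- list()
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    n <- nchar(s)
    out <- character(0)
    for (L in min_length:n) {
      if (L > n) break
      for (st in 1:(n - L + 1)) out <- c(out, substr(s, st, st + L - 1))
    }
    subs[[i]] <- unique(out)
  }
  tab <- table(unlist(subs))
  cand <- names(tab)[tab >= min_support]
  supp_set <- lapply(cand, function(m) which(vapply(seqs, function(s)
    grepl(m, s, fixed = TRUE), logical(1))))
  keep <- vapply(seq_along(cand), function(i) {
    !any(vapply(seq_along(cand), function(j) {
      j != i && nchar(cand[j]) > nchar(cand[i]) &&
        identical(supp_set[[i]], supp_set[[j]]) &&
        grepl(cand[i], cand[j], fixed = TRUE)
    }, logical(1)))
  }, logical(1))
  data.frame(motif = cand[keep], support = as.integer(tab[cand[keep]]),
             stringsAsFactors = FALSE)
}
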