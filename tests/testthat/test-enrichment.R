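toy_cohort_reps <- function() {
  dir <- system.file("extdata", "toy_cohort", package = "tcrnodule")
  md <- read_metadata(file.path(dir, "metadata.tsv"))
  reps <- lapply(md$subject_id, function(id) {
    read_clonotype_table(file.path(dir, paste0(id, ".tsv")),
                         subject_id = id)
  })
  names(reps) <- md$subject_id
  list(reps = reps, md = md)
}

test_that("the sharing index maps clones to their carriers", {
  r1 <- repertoire("A", c("CASSLGYF", "CASSPGQF"), c(3, 2))
  r2 <- repertoire("B", c("CASSLGYF", "CASRDDWF"), c(5, 1))
  md <- data.frame(subject_id = c("A", "B"),
                   label = c("benign", "malignant"),
                   stringsAsFactors = FALSE)
  idx <- build_sharing_index(list(r1, r2), md)
  expect_setequal(idx$carriers[["CASSLGYF"]], c("A", "B"))
  expect_equal(idx$carriers[["CASRDDWF"]], "B")

  # disjoint repertoires: every key has support 1
  r3 <- repertoire("B", "CASSYYYF", 4)
  idx2 <- build_sharing_index(list(r1, r3), md)
  expect_true(all(lengths(idx2$carriers) == 1L))

  expect_error(build_sharing_index(list(repertoire("Z", "CASSF", 1)), md),
               "Z")
})

test_that("group-exclusive clones match hand enumeration", {
  # 5-subject fixture with hand-built overlaps
  mk <- function(id, seqs) repertoire(id, seqs, seq_along(seqs) + 1)
  reps <- list(
    mk("M1", c("AAAA", "TTTT", "SHARED")),
    mk("M2", c("AAAA", "CCCC")),
    mk("M3", c("DDDD")),
    mk("B1", c("SHARED", "EEEE")),
    mk("B2", c("FFFF", "CCCC"))
  )
  md <- data.frame(subject_id = c("M1", "M2", "M3", "B1", "B2"),
                   label = c("malignant", "malignant", "malignant",
                             "benign", "benign"),
                   stage = c("I", "I", "II", NA, NA),
                   stringsAsFactors = FALSE)
  idx <- build_sharing_index(reps, md)
  excl <- group_exclusive_clones(idx, "malignant")
  # hand count: AAAA, TTTT, DDDD are malignant-only; SHARED and CCCC are
  # carried by benign subjects too; total distinct keys = 7
  expect_setequal(excl$keys, c("AAAA", "TTTT", "DDDD"))
  expect_equal(excl$exclusive_fraction, 3 / 7)

  # stage-level target group
  excl_I <- group_exclusive_clones(idx, "I")
  expect_setequal(excl_I$keys, c("AAAA", "TTTT"))

  # exclusive keys never appear in any non-target repertoire
  non_target <- unlist(lapply(reps[4:5], function(r) r$clones$cdr3_aa))
  expect_length(intersect(excl$keys, non_target), 0)

  expect_error(group_exclusive_clones(idx, "III"), "unknown group")

  # degenerate: when every subject is in the target group all clones are
  # exclusive
  md_all <- transform(md, label = "malignant",
                      stage = c("I", "I", "II", "I", "II"))
  excl_all <- group_exclusive_clones(build_sharing_index(reps, md_all),
                                     "malignant")
  expect_equal(excl_all$exclusive_fraction, 1)
})

test_that("planted group-private clone fraction is recovered", {
  # construct a cohort where the target group carries a known private set
  set.seed(77)
  shared <- tcrnodule:::random_cdr3(40, c(10, 14))
  private <- tcrnodule:::random_cdr3(60, c(10, 14))
  private <- setdiff(private, shared)
  mk <- function(id, seqs) repertoire(id, seqs, rep(2, length(seqs)))
  reps <- list(
    mk("M1", c(shared[1:20], private[1:25])),
    mk("M2", c(shared[11:30], private[20:45])),
    mk("B1", c(shared[1:25])),
    mk("B2", c(shared[15:40]))
  )
  md <- data.frame(subject_id = c("M1", "M2", "B1", "B2"),
                   label = c("malignant", "malignant", "benign", "benign"),
                   stringsAsFactors = FALSE)
  excl <- group_exclusive_clones(build_sharing_index(reps, md), "malignant")
  truth <- unique(c(private[1:25], private[20:45]))
  expect_setequal(excl$keys, truth)
  expect_equal(excl$exclusive_fraction,
               length(truth) / length(unique(c(shared[1:40], truth))))
})

test_that("enriched-sequence selection applies the >=2-subject rule", {
  toy <- toy_cohort_reps()
  es <- select_enriched_sequences(toy$reps)
  # hand enumeration over the packaged fixture: exactly four sequences
  # appear in at least two of the three subjects
  expect_setequal(es$sequence,
                  c("CASSLAPGATNEKLFF", "CASSSGGSSYEQYF",
                    "CASSPDRGAYEQYF", "CASSLKQGNTEAFF"))
  expect_equal(es$n_subjects[es$sequence == "CASSLAPGATNEKLFF"], 3L)

  # invariant to subject input order
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    es_p <- select_enriched_sequences(toy$reps[perm])
    expect_setequal(es_p$sequence, es$sequence)
  }

  # fully disjoint repertoires yield an empty set
  r1 <- repertoire("A", c("AAAA", "TTTT"), c(2, 1))
  r2 <- repertoire("B", c("CCCC", "DDDD"), c(2, 1))
  expect_equal(nrow(select_enriched_sequences(list(r1, r2))), 0L)

  # top_per_subject larger than the repertoire clamps without error
  es2 <- select_enriched_sequences(toy$reps, top_per_subject = 1000L)
  expect_setequal(es2$sequence, es$sequence)

  expect_error(select_enriched_sequences(toy$reps, min_subjects = 4),
               "min_subjects")
})

test_that("common-motif extraction finds a planted motif with support", {
  set.seed(9)
  motif <- "SSGGSSYEQYF"
  flanks <- replicate(5, paste(sample(tcrnodule:::AA_LETTERS, 3),
                               collapse = ""))
  seqs <- paste0("CA", flanks, motif, "F")
  res <- find_common_motifs(seqs, min_length = 5, min_support = 5)
  expect_gte(nrow(res), 1L)
  top <- res$motif[1]
  expect_true(grepl(motif, top, fixed = TRUE) ||
                grepl(top, motif, fixed = TRUE))
  expect_equal(res$support[1], 5L)

  # two identical sequences: the whole sequence is the single motif
  res2 <- find_common_motifs(c("CASSLGYEQYF", "CASSLGYEQYF"),
                             min_length = 5, min_support = 2)
  expect_equal(res2$motif, "CASSLGYEQYF")
  expect_equal(res2$support, 2L)

  # sequences with no shared >=5-mer by construction
  res3 <- find_common_motifs(c("AAAAAAAA", "CCCCCCCC", "DDDDDDDD"),
                             min_length = 5, min_support = 2)
  expect_equal(nrow(res3), 0L)
})

test_that("motif extraction agrees with brute-force enumeration", {
  for (i in 1:6) {
    set.seed(500 + i)
    n <- sample(5:15, 1)
    seqs <- tcrnodule:::random_cdr3(n, c(6, 15))
    # plant partial sharing so non-trivial motifs exist
    seqs[2] <- paste0(substr(seqs[1], 1, 6), seqs[2])
    seqs[4] <- paste0(seqs[3], substr(seqs[1], 1, 5))
    got <- find_common_motifs(seqs, min_length = 4, min_support = 2)
    want <- motif_bruteforce(seqs, min_length = 4, min_support = 2)
    expect_setequal(got$motif, want$motif)
    expect_equal(got$support[order(got$motif)],
                 want$support[order(want$motif)])
  }
})
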