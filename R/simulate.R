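# Synthetic cohort generator.
#
# Emulates the statistical structure a peripheral-blood TCR nodule study
# assumes: heavy-tailed (Zipf-over-ranks) clone-size spectra, lower diversity
# with excess hyperexpanded clones in malignant subjects, public clones
# shared across the cohort, a shared pool of malignant-associated
# motif-carrier clonotypes, and correlated clinical covariates.

#' Configuration for the synthetic cohort generator
#'
#' The defaults define the study-like conditions every simulated cohort is
#' generated under: two-class cohorts with Zipf-distributed clone sizes, a
#' malignant-specific reallocation of read mass into the top clones (lower
#' Shannon diversity, more hyperexpanded clones), a cohort-wide pool of
#' public clonotypes, a pool of malignant-associated motif-carrier
#' clonotypes whose sequences all contain `planted_motif`, and clinical
#' covariates (GGN flag, log-normal nodule sizes, stage, age, sex) whose
#' class-conditional distributions make GGN and nodule size informative.
#'
#' @param n_benign,n_malignant Subjects per class.
#' @param clones_per_subject Expected distinct clones per repertoire;
#'   per-subject richness is log-normal around this value with
#'   `richness_lognorm_sd`.
#' @param reads_per_subject Expected total reads per repertoire; realized
#'   reads are coupled to nodule size via `reads_size_coupling` so that total
#'   clone reads correlates positively with nodule diameter.
#' @param powerlaw_exponent_benign,powerlaw_exponent_malignant Mean Zipf
#'   exponent (> 1) of the rank-frequency law within each class; a steeper
#'   malignant exponent shifts read mass from small-type into expanded
#'   clones, lowering diversity.
#' @param powerlaw_exponent_sd Per-subject normal jitter of the exponent
#'   (biological heterogeneity within a class).
#' @param clone_mass_jitter_sd Log-normal scatter multiplying each clone's
#'   Zipf mass; makes individual top-clone sizes strongly stochastic, as in
#'   real repertoires.
#' @param richness_lognorm_sd Log-scale spread of per-subject clone
#'   richness (biological component, independent of depth).
#' @param read_depth_lognorm_sd Log-scale spread of per-subject total read
#'   depth (technical library-size variation across samples).
#' @param richness_depth_exponent Saturation exponent linking observed
#'   richness to read depth (observed clones scale like
#'   depth^exponent, emulating incomplete sampling of the repertoire).
#' @param richness_ratio_malignant Multiplier on the expected richness of
#'   malignant subjects (< 1 emulates clonal expansion crowding out the
#'   repertoire).
#' @param hyperexpanded_boost_malignant Fraction of malignant read mass
#'   reallocated uniformly onto the `boost_top_clones` largest clones.
#' @param boost_top_clones Number of top-rank clones receiving the boost.
#' @param public_clone_pool_size,public_clone_rate Size of the cohort-wide
#'   public clonotype pool and the per-clone probability of drawing from it.
#' @param planted_motif Amino-acid substring carried by every motif-pool
#'   sequence (default `"SSGGSSYEQYF"`).
#' @param motif_spike_rate_malignant Per-clone probability (malignant
#'   subjects, non-public clones) of drawing a motif-carrier sequence; the
#'   effective per-clone motif rate is
#'   `motif_spike_rate_malignant * (1 - public_clone_rate)`.
#' @param motif_pool_size Number of distinct motif-carrier sequences shared
#'   across malignant subjects.
#' @param cdr3_length_range Inclusive range of de-novo CDR3 lengths (aa).
#' @param ggn_rate_benign,ggn_rate_malignant Class-conditional
#'   ground-glass-nodule probabilities.
#' @param nodule_size_params Per-class log-normal `meanlog`/`sdlog` for the
#'   nodule diameter in mm (defaults give a pooled mean near 14 mm).
#' @param stage_probs Stage proportions among malignant subjects.
#' @param age_mean,age_sd Age distribution (years), shared by both classes.
#' @param reads_size_coupling Strength of the log-reads / log-size coupling.
#' @param force_public_clones Force exactly this many public clones per
#'   subject instead of the Bernoulli rate (must not exceed
#'   `clones_per_subject`).
#' @param seed Integer seed; one global seed fans out into per-subject
#'   substreams, so a cohort is reproducible regardless of subject order.
#' @return A validated list of class `"cohort_sim_config"`.
#' @export
cohort_sim_config <- function(n_benign = 20L, n_malignant = 20L,
                              clones_per_subject = 1000L,
                              reads_per_subject = 50000L,
                              powerlaw_exponent_benign = 1.05,
                              powerlaw_exponent_malignant = 1.13,
                              powerlaw_exponent_sd = 0.03,
                              clone_mass_jitter_sd = 1.0,
                              richness_lognorm_sd = 0.3,
                              read_depth_lognorm_sd = 0.7,
                              richness_depth_exponent = 0.6,
                              richness_ratio_malignant = 0.75,
                              hyperexpanded_boost_malignant = 0.03,
                              boost_top_clones = 10L,
                              public_clone_pool_size = 200L,
                              public_clone_rate = 0.05,
                              planted_motif = "SSGGSSYEQYF",
                              motif_spike_rate_malignant = 0.2,
                              motif_pool_size = 200L,
                              cdr3_length_range = c(8L, 20L),
                              ggn_rate_benign = 0.08,
                              ggn_rate_malignant = 0.80,
                              nodule_size_params = list(
                                benign = c(meanlog = log(12.5), sdlog = 0.45),
                                malignant = c(meanlog = log(15), sdlog = 0.45)),
                              stage_probs = c(I = 0.6, II = 0.25, III = 0.15),
                              age_mean = 55.5, age_sd = 10,
                              reads_size_coupling = 0.15,
                              force_public_clones = 0L,
                              seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$n_benign + cfg$n_malignant == 0) {
    stopf("cohort must contain at least one subject")
  }
  if (!is_count(cfg$clones_per_subject)) stopf("clones_per_subject must be >= 1")
  if (!is_count(cfg$reads_per_subject)) stopf("reads_per_subject must be >= 1")
  for (f in c("powerlaw_exponent_benign", "powerlaw_exponent_malignant")) {
    if (cfg[[f]] <= 1) stopf("%s must be > 1", f)
  }
  for (f in c("public_clone_rate", "motif_spike_rate_malignant",
              "ggn_rate_benign", "ggn_rate_malignant")) {
    if (!is_prob(cfg[[f]])) stopf("%s must be a probability in [0,1]", f)
  }
  if (cfg$hyperexpanded_boost_malignant < 0 ||
      cfg$hyperexpanded_boost_malignant >= 1) {
    stopf("hyperexpanded_boost_malignant must be in [0,1)")
  }
  validate_cdr3(cfg$planted_motif)
  if (cfg$force_public_clones > cfg$clones_per_subject) {
    stopf("force_public_clones (%d) exceeds clones_per_subject (%d)",
          cfg$force_public_clones, cfg$clones_per_subject)
  }
  for (f in c("powerlaw_exponent_sd", "clone_mass_jitter_sd",
              "richness_lognorm_sd", "read_depth_lognorm_sd",
              "richness_depth_exponent")) {
    if (cfg[[f]] < 0) stopf("%s must be non-negative", f)
  }
  if (abs(sum(cfg$stage_probs) - 1) > 1e-9) stopf("stage_probs must sum to 1")
  if (cfg$reads_per_subject <= cfg$clones_per_subject) {
    stopf("reads_per_subject must exceed clones_per_subject")
  }
  structure(cfg, class = "cohort_sim_config")
}

# n random CDR3 sequences, uniform composition, lengths uniform in range.
# One big sampled string + substring() keeps this fast for deep repertoires.
random_cdr3 <- function(n, len_range) {
  if (n == 0L) return(character(0))
  lens <- sample(seq.int(len_range[1], len_range[2]), n, replace = TRUE)
  pool <- paste(sample(AA_LETTERS, sum(lens), replace = TRUE), collapse = "")
  ends <- cumsum(lens)
  substring(pool, ends - lens + 1L, ends)
}

# Shared pools derive from the cohort seed only, so every subject sees the
# same public and motif-carrier sequences.
shared_pools <- function(config) {
  with_seed(derive_seeds(config$seed, 1L, salt = 1L), {
    public <- unique(random_cdr3(config$public_clone_pool_size,
                                 config$cdr3_length_range))
    motif <- character(0)
    if (config$motif_pool_size > 0L) {
      flank <- function(n) vapply(sample(0:4, n, replace = TRUE), function(L) {
        paste(sample(AA_LETTERS, L, replace = TRUE), collapse = "")
      }, character(1))
      motif <- unique(paste0(flank(config$motif_pool_size),
                             config$planted_motif,
                             flank(config$motif_pool_size)))
      motif <- setdiff(motif, public)
    }
    list(public = public, motif = motif)
  })
}

# Zipf-over-ranks clone-size probabilities with multiplicative log-normal
# scatter (real clone-size spectra are far noisier than an exact power law,
# especially among the top clones), optionally with extra mass moved
# uniformly onto the top clones (the hyperexpansion effect). Draws from the
# current RNG stream.
zipf_probs <- function(n, exponent, boost = 0, top = 5L, jitter_sd = 0) {
  w <- seq_len(n)^(-exponent)
  if (jitter_sd > 0) w <- w * exp(stats::rnorm(n, 0, jitter_sd))
  p <- sort(w / sum(w), decreasing = TRUE)
  if (boost > 0 && n > 1L) {
    k <- min(as.integer(top), n)
    p <- (1 - boost) * p
    p[seq_len(k)] <- p[seq_len(k)] + boost / k
  }
  p
}

#' Simulate one subject's repertoire
#'
#' Draws clone counts from a Zipf rank-frequency law (with the
#' class-specific exponent and, for malignant subjects, the hyperexpansion
#' boost), then assigns each clone a CDR3\eqn{\beta} sequence: with
#' probability `public_clone_rate` from the cohort public pool, otherwise —
#' for malignant subjects, with probability `motif_spike_rate_malignant` —
#' from the malignant motif-carrier pool, otherwise de novo. Every clone
#' receives at least one read and the realized total equals the requested
#' read count.
#'
#' @param config A [cohort_sim_config()].
#' @param label `"benign"` or `"malignant"`.
#' @param subject_id Subject identifier.
#' @param seed Substream seed; defaults to `config$seed`.
#' @param reads Total reads for this subject; defaults to
#'   `config$reads_per_subject`.
#' @param pools Shared sequence pools (internal; computed from the config
#'   when not supplied).
#' @return A [repertoire()].
#' @export
simulate_repertoire <- function(config, label = c("benign", "malignant"),
                                subject_id = "S1", seed = NULL,
                                reads = NULL, pools = NULL) {
  stopifnot(inherits(config, "cohort_sim_config"))
  label <- match.arg(label)
  pools <- pools %||% shared_pools(config)
  reads <- as.integer(reads %||% config$reads_per_subject)
  if (reads <= config$clones_per_subject) {
    stopf("reads (%d) must exceed clones_per_subject (%d)", reads,
          config$clones_per_subject)
  }
  mean_exponent <- if (label == "benign") config$powerlaw_exponent_benign
                   else config$powerlaw_exponent_malignant
  boost <- if (label == "malignant") config$hyperexpanded_boost_malignant else 0

  with_seed(seed %||% config$seed, {
    depth_mult <- if (config$read_depth_lognorm_sd > 0) {
      stats::rlnorm(1, 0, config$read_depth_lognorm_sd)
    } else 1
    reads <- as.integer(max(round(reads * depth_mult), 100L))
    n <- config$clones_per_subject
    if (label == "malignant") n <- n * config$richness_ratio_malignant
    n <- n * depth_mult^config$richness_depth_exponent
    if (config$richness_lognorm_sd > 0) {
      n <- stats::rlnorm(1, log(n), config$richness_lognorm_sd)
    }
    n <- as.integer(min(max(round(n), 2), reads - 1L,
                        20L * config$clones_per_subject))
    exponent <- max(1.005,
                    stats::rnorm(1, mean_exponent,
                                 config$powerlaw_exponent_sd))
    p <- zipf_probs(n, exponent, boost, config$boost_top_clones,
                    config$clone_mass_jitter_sd)
    counts <- drop(stats::rmultinom(1L, reads - n, p)) + 1L

    source <- rep("denovo", n)
    if (config$force_public_clones > 0L) {
      k <- min(config$force_public_clones, length(pools$public))
      source[sample.int(n, k)] <- "public"
    } else if (config$public_clone_rate > 0 && length(pools$public)) {
      is_pub <- stats::runif(n) < config$public_clone_rate
      if (sum(is_pub) > length(pools$public)) {
        is_pub[sample(which(is_pub), sum(is_pub) - length(pools$public))] <- FALSE
      }
      source[is_pub] <- "public"
    }
    if (label == "malignant" && config$motif_spike_rate_malignant > 0 &&
        length(pools$motif)) {
      cand <- which(source == "denovo")
      is_mot <- cand[stats::runif(length(cand)) <
                       config$motif_spike_rate_malignant]
      if (length(is_mot) > length(pools$motif)) {
        is_mot <- sample(is_mot, length(pools$motif))
      }
      source[is_mot] <- "motif"
    }

    seqs <- character(n)
    seqs[source == "public"] <- sample(pools$public, sum(source == "public"))
    seqs[source == "motif"] <- sample(pools$motif, sum(source == "motif"))
    free <- which(source == "denovo")
    seqs[free] <- random_cdr3(length(free), config$cdr3_length_range)
    # de-novo sequences must not collide with pools or each other
    repeat {
      dup <- free[duplicated(seqs)[free] | seqs[free] %in%
                    c(pools$public, pools$motif)]
      if (!length(dup)) break
      seqs[dup] <- random_cdr3(length(dup), config$cdr3_length_range)
    }
    repertoire(subject_id, seqs, counts)
  })
}

#' Simulate a two-class cohort of repertoires with metadata
#'
#' Generates `n_benign + n_malignant` subjects. Clinical covariates are drawn
#' per class: GGN flags Bernoulli with the class rate, nodule diameters
#' log-normal with the class parameters, stages (malignant only) from
#' `stage_probs`, age normal and sex balanced in both classes. Each subject's
#' total read count is coupled to its nodule size on the log scale, so clone
#' reads and nodule diameter correlate positively. The single `seed` fans out
#' into per-subject substreams, making the cohort reproducible regardless of
#' the order subjects are generated in.
#'
#' @param config A [cohort_sim_config()].
#' @return A list of class `"tcr_cohort"` with elements `repertoires` (named
#'   list of [repertoire()] objects) and `metadata` (data frame).
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_sim_config(n_benign = 3, n_malignant = 3,
#'                                             clones_per_subject = 50,
#'                                             reads_per_subject = 2000,
#'                                             seed = 7))
#' cohort$metadata
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  n_b <- as.integer(config$n_benign)
  n_m <- as.integer(config$n_malignant)
  ids <- c(sprintf("B%03d", seq_len(n_b)), sprintf("M%03d", seq_len(n_m)))
  labels <- c(rep("benign", n_b), rep("malignant", n_m))
  n <- n_b + n_m

  pools <- shared_pools(config)
  subject_seeds <- derive_seeds(config$seed, n, salt = 2L)

  md <- with_seed(derive_seeds(config$seed, 1L, salt = 3L), {
    ggn_rate <- ifelse(labels == "malignant", config$ggn_rate_malignant,
                       config$ggn_rate_benign)
    ggn <- stats::runif(n) < ggn_rate
    size <- numeric(n)
    for (cls in c("benign", "malignant")) {
      idx <- labels == cls
      par <- config$nodule_size_params[[cls]]
      size[idx] <- stats::rlnorm(sum(idx), par[["meanlog"]], par[["sdlog"]])
    }
    stage <- rep(NA_character_, n)
    if (n_m > 0L) {
      stage[labels == "malignant"] <- sample(names(config$stage_probs), n_m,
                                             replace = TRUE,
                                             prob = config$stage_probs)
    }
    age <- pmin(pmax(stats::rnorm(n, config$age_mean, config$age_sd), 25), 90)
    sex <- sample(c("M", "F"), n, replace = TRUE)
    data.frame(subject_id = ids, label = labels, stage = stage, ggn = ggn,
               nodule_size_mm = round(size, 1), age_years = round(age, 1),
               sex = sex, stringsAsFactors = FALSE)
  })

  # log-reads coupled to standardized log nodule size
  z <- vapply(seq_len(n), function(i) {
    par <- config$nodule_size_params[[labels[i]]]
    (log(md$nodule_size_mm[i]) - par[["meanlog"]]) / par[["sdlog"]]
  }, numeric(1))
  reads <- pmax(as.integer(round(config$reads_per_subject *
                                   exp(config$reads_size_coupling * z))),
                config$clones_per_subject + 1L)

  reps <- vector("list", n)
  names(reps) <- ids
  for (i in seq_len(n)) {
    reps[[i]] <- simulate_repertoire(config, labels[i], ids[i],
                                     seed = subject_seeds[i],
                                     reads = reads[i], pools = pools)
  }
  validate_metadata(md)
  structure(list(repertoires = reps, metadata = md, config = config),
            class = "tcr_cohort")
}

#' @export
print.tcr_cohort <- function(x, ...) {
  tab <- table(x$metadata$label)
  cat(sprintf("Synthetic TCR cohort: %d subjects (%s)\n",
              nrow(x$metadata),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Write a simulated cohort to disk in the formats the readers accept
#'
#' One AIRR-style clonotype TSV per subject plus a metadata TSV; the emitted
#' files round-trip through [read_clonotype_table()] and [read_metadata()].
#'
#' @param cohort A `"tcr_cohort"`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a character vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "tcr_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(cohort$repertoires, function(r) {
    write_clonotype_table(r, file.path(dir, paste0(r$subject_id, ".tsv")))
  }, character(1))
  md_path <- file.path(dir, "metadata.tsv")
  write_metadata(cohort$metadata, md_path)
  invisible(c(paths, md_path))
}
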