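# End-to-end orchestration: cohort (simulated or read from disk) ->
# diversity -> enrichment -> feature selection -> classifier -> evaluation,
# with every intermediate written to disk and a hash manifest for
# reproducibility audits.

#' Pipeline configuration
#'
#' One document resolving every stage's parameters. Data come either from
#' the synthetic generator (`sim`, plus validation cohort sizes) or from
#' disk (`discovery_dir`/`validation_dir`, each holding per-subject
#' clonotype TSVs and a `metadata.tsv`).
#'
#' @param sim A [cohort_sim_config()] describing the discovery cohort (its
#'   seed is re-derived from `seed`).
#' @param validation_n_benign,validation_n_malignant Validation cohort
#'   sizes (simulated under the same structural config).
#' @param discovery_dir,validation_dir Optional input directories; when set,
#'   `sim` is ignored.
#' @param bins Clonal-homeostasis thresholds, see [clone_type_bins()].
#' @param top_per_subject,top_pooled,min_subjects Enrichment rule
#'   parameters, see [select_enriched_sequences()].
#' @param motif_min_length,motif_min_support Motif extraction parameters.
#' @param select_k Number of features kept for the classifier.
#' @param ga A [ga_config()] (its seed is re-derived from `seed`).
#' @param strata Evaluation strata, see [stratified_evaluation()].
#' @param ablation If `TRUE`, also fit the without-TCR comparison model.
#' @param out_dir Output directory for all artifacts.
#' @param seed Global integer seed; all stage seeds derive from it.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(sim = cohort_sim_config(),
                            validation_n_benign = 20L,
                            validation_n_malignant = 20L,
                            discovery_dir = NULL, validation_dir = NULL,
                            bins = clone_type_bins(),
                            top_per_subject = 30L, top_pooled = 3000L,
                            min_subjects = 2L,
                            motif_min_length = 5L, motif_min_support = 2L,
                            select_k = 3L, ga = ga_config(),
                            strata = c("ggn", "size20", "size10"),
                            ablation = TRUE, out_dir = tempfile("tcr_run_"),
                            seed = 1L) {
  cfg <- as.list(environment())
  if (is.null(cfg$discovery_dir) && !inherits(cfg$sim, "cohort_sim_config")) {
    stopf("either 'discovery_dir' or a valid 'sim' config is required")
  }
  if (!is.null(cfg$discovery_dir) && is.null(cfg$validation_dir)) {
    stopf("'validation_dir' is required when reading cohorts from disk")
  }
  structure(cfg, class = "pipeline_config")
}

read_cohort_dir <- function(dir) {
  md <- read_metadata(file.path(dir, "metadata.tsv"))
  reps <- lapply(md$subject_id, function(id) {
    read_clonotype_table(file.path(dir, paste0(id, ".tsv")), subject_id = id)
  })
  names(reps) <- md$subject_id
  structure(list(repertoires = reps, metadata = md), class = "tcr_cohort")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort acquisition (simulation or ingest), diversity
#' profiling, benign/malignant group comparisons and clinical correlations,
#' sharing/enrichment/motif analysis, feature ranking and top-k selection,
#' GA-tuned SVM training on the discovery cohort, and Youden-cutoff
#' evaluation (overall and stratified) on the validation cohort, optionally
#' with the without-TCR ablation. Every intermediate is written under
#' `config$out_dir`; the returned manifest records seeds and the MD5 of
#' every artifact, so a rerun with the same config and seed is
#' byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 4L)
  log_stage <- function(...) message(sprintf(...))

  # -- data -------------------------------------------------------------
  cohorts <- run_stage("data", {
    if (!is.null(config$discovery_dir)) {
      log_stage("stage data: reading cohorts from disk")
      list(discovery = read_cohort_dir(config$discovery_dir),
           validation = read_cohort_dir(config$validation_dir))
    } else {
      log_stage("stage data: simulating cohorts (seed %d)", config$seed)
      sim_d <- config$sim
      sim_d$seed <- seeds[1L]
      sim_v <- config$sim
      sim_v$n_benign <- config$validation_n_benign
      sim_v$n_malignant <- config$validation_n_malignant
      sim_v$seed <- seeds[2L]
      list(discovery = simulate_cohort(sim_d),
           validation = simulate_cohort(sim_v))
    }
  })
  disc <- cohorts$discovery
  val <- cohorts$validation

  # -- diversity --------------------------------------------------------
  profiles <- run_stage("diversity", {
    log_stage("stage diversity: %d + %d subjects",
              nrow(disc$metadata), nrow(val$metadata))
    list(discovery = diversity_profiles(disc$repertoires, config$bins),
         validation = diversity_profiles(val$repertoires, config$bins))
  })
  write_feature_table(profiles$discovery,
                      file.path(out, "profiles_discovery.tsv"))
  write_feature_table(profiles$validation,
                      file.path(out, "profiles_validation.tsv"))

  comparisons <- run_stage("group_comparison", {
    do.call(rbind, lapply(
      c("shannon", "evenness", "simpson", "clonality",
        "frac_small", "frac_hyperexpanded"),
      function(f) compare_groups(profiles$discovery, disc$metadata, f)))
  })
  write_feature_table(comparisons, file.path(out, "group_comparisons.tsv"))

  correlations <- run_stage("correlation", {
    correlate_features_clinical(profiles$discovery, disc$metadata)
  })
  corr_df <- data.frame(
    feature = rownames(correlations$rho)[row(correlations$rho)],
    covariate = colnames(correlations$rho)[col(correlations$rho)],
    rho = as.vector(correlations$rho),
    p_value = as.vector(correlations$p_value), stringsAsFactors = FALSE)
  write_feature_table(corr_df, file.path(out, "correlations.tsv"))

  # -- enrichment -------------------------------------------------------
  enrich <- run_stage("enrichment", {
    log_stage("stage enrichment: sharing index + motif extraction")
    index <- build_sharing_index(disc$repertoires, disc$metadata)
    excl <- group_exclusive_clones(index, "malignant")
    mal_ids <- disc$metadata$subject_id[disc$metadata$label == "malignant"]
    enriched <- select_enriched_sequences(
      disc$repertoires[mal_ids],
      top_per_subject = config$top_per_subject,
      top_pooled = config$top_pooled,
      min_subjects = config$min_subjects)
    motifs <- find_common_motifs(enriched,
                                 min_length = config$motif_min_length,
                                 min_support = config$motif_min_support)
    list(exclusive = excl, enriched = enriched, motifs = motifs)
  })
  write_feature_table(data.frame(clone = enrich$exclusive$keys,
                                 stringsAsFactors = FALSE),
                      file.path(out, "exclusive_clones.tsv"))
  write_feature_table(as.data.frame(enrich$enriched),
                      file.path(out, "enriched_set.tsv"))
  if (nrow(enrich$motifs)) {
    write_feature_table(enrich$motifs, file.path(out, "motifs.tsv"))
  }

  # -- feature selection ------------------------------------------------
  feats <- run_stage("feature_selection", {
    log_stage("stage feature_selection: ranking candidates")
    tab_d <- assemble_features(profiles$discovery, disc$metadata)
    tab_v <- assemble_features(profiles$validation, val$metadata)
    ranking <- rank_features(tab_d, seed = seeds[3L])
    selected <- select_top_features(ranking, k = config$select_k)
    list(table_discovery = tab_d, table_validation = tab_v,
         ranking = ranking, selected = selected)
  })
  write_feature_table(feats$table_discovery,
                      file.path(out, "features_discovery.tsv"))
  write_feature_table(feats$table_validation,
                      file.path(out, "features_validation.tsv"))
  write_feature_table(as.data.frame(feats$ranking),
                      file.path(out, "feature_ranking.tsv"))
  write_json_artifact(feats$selected, file.path(out, "selected_features.json"))

  # -- classifier -------------------------------------------------------
  ga <- config$ga
  ga$seed <- seeds[4L]
  fit <- run_stage("classifier", {
    log_stage("stage classifier: GA-tuned SVM on %s",
              paste(feats$selected, collapse = ", "))
    if (config$ablation) {
      ab <- ablate_tcr_features(feats$table_discovery, feats$selected,
                                ga = ga)
      ab
    } else {
      list(with_tcr = ga_svm(stats::reformulate(feats$selected, "label"),
                             feats$table_discovery, ga = ga))
    }
  })
  write_model(fit$with_tcr, file.path(out, "model.json"))
  if (!is.null(fit$without_tcr)) {
    write_model(fit$without_tcr, file.path(out, "model_without_tcr.json"))
  }

  # -- evaluation -------------------------------------------------------
  evaluation <- run_stage("evaluation", {
    log_stage("stage evaluation: validation cohort")
    pred <- predict(fit$with_tcr, feats$table_validation)
    strat <- stratified_evaluation(pred, feats$table_validation$label,
                                   val$metadata, strata = config$strata,
                                   cutoff = fit$with_tcr$youden_cutoff)
    res <- list(
      training = unclass(evaluation_report(
        fit$with_tcr$fitted, fit$with_tcr$y,
        cutoff = fit$with_tcr$youden_cutoff)),
      validation = unclass(strat$overall),
      strata = lapply(strat$strata, unclass),
      waterfall = strat$waterfall,
      predictions = data.frame(subject_id = val$metadata$subject_id,
                               label = feats$table_validation$label,
                               predicted_value = pred,
                               stringsAsFactors = FALSE)
    )
    if (!is.null(fit$without_tcr)) {
      pred_no <- predict(fit$without_tcr, feats$table_validation)
      res$validation_without_tcr <- unclass(evaluation_report(
        pred_no, feats$table_validation$label,
        cutoff = fit$without_tcr$youden_cutoff))
    }
    res
  })
  write_feature_table(evaluation$predictions,
                      file.path(out, "predictions_validation.tsv"))
  eval_json <- evaluation
  eval_json$predictions <- NULL
  write_json_artifact(eval_json, file.path(out, "evaluation.json"))

  # -- manifest ---------------------------------------------------------
  files <- sort(setdiff(list.files(out), "manifest.json"))
  hashes <- tools::md5sum(file.path(out, files))
  manifest <- list(
    package = "tcrnodule",
    version = as.character(utils::packageVersion("tcrnodule")),
    seed = config$seed,
    stage_seeds = list(data_discovery = seeds[1L], data_validation = seeds[2L],
                       feature_ranking = seeds[3L], classifier = seeds[4L]),
    selected_features = feats$selected,
    hyperparameters = list(kernel = fit$with_tcr$kernel,
                           cost = fit$with_tcr$cost,
                           gamma = fit$with_tcr$gamma),
    youden_cutoff = fit$with_tcr$youden_cutoff,
    validation_auc = evaluation$validation$auc,
    artifacts = stats::setNames(as.list(unname(hashes)), files)
  )
  write_json_artifact(manifest, file.path(out, "manifest.json"))
  invisible(manifest)
}
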