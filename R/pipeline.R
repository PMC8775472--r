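# End-to-end orchestration: simulate -> (preprocess -> extract -> train ->
# stage) -> metrics -> compare, from one validated config and one master
# seed.

#' Pipeline configuration
#'
#' Validated bundle of all module settings. Unknown argument names are
#' rejected.
#'
#' @param n_exposed,n_sham Cohort sizes (defaults 21 and 20).
#' @param base [architecture_params()] for the sham group.
#' @param effect [group_effect()] applied to the exposed group.
#' @param template [spectral_template()] for EEG synthesis.
#' @param rate Sampling rate in Hz.
#' @param channel Staging channel label.
#' @param feature_cfg [feature_config()].
#' @param with_staging Run the EEG synthesis + staging branch (slow); when
#'   FALSE metrics are computed from the ground-truth hypnograms.
#' @param k Feature-subset size.
#' @param folds Cross-validation folds (0 disables CV inside the run).
#' @param bootstrap_B Bootstrap samples for comparison CIs.
#' @param seed Master seed.
#' @param out_dir Optional directory; when given, hypnograms, metrics and
#'   the comparison table are written there as CSV.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_exposed = 21, n_sham = 20,
                            base = architecture_params(),
                            effect = group_effect(),
                            template = spectral_template(),
                            rate = 100, channel = "Pz-Oz",
                            feature_cfg = feature_config(),
                            with_staging = FALSE, k = 8, folds = 0,
                            bootstrap_B = 1000, seed = 1, out_dir = NULL) {
  cfg <- as.list(environment())
  stopifnot(inherits(cfg$base, "architecture_params"),
            inherits(cfg$effect, "group_effect"),
            inherits(cfg$template, "spectral_template"),
            inherits(cfg$feature_cfg, "feature_config"),
            cfg$rate >= 100, cfg$k >= 1, cfg$bootstrap_B >= 100)
  structure(cfg, class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Simulates the two-group cohort, optionally stages each night from its
#' synthesized EEG with a model trained on held-out simulated subjects,
#' computes per-night sleep metrics, and compares the groups. Fully
#' deterministic given the config (which includes the master seed).
#'
#' @param cfg A [pipeline_config()].
#' @return A list with `config`, `cohort_metrics` (per-night table),
#'   `comparison` (a `cohort_comparison`), optionally `cv` (when
#'   `folds > 0` and staging is enabled), and `timing` (seconds per stage).
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  timing <- c()
  tick <- function(expr, name) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    timing[[name]] <<- proc.time()[["elapsed"]] - t0
    res
  }
  cohort <- tick(simulate_cohort(cfg$n_exposed, cfg$n_sham, cfg$base,
                                 cfg$effect, seed = cfg$seed,
                                 with_eeg = cfg$with_staging,
                                 template = cfg$template, rate = cfg$rate,
                                 channels = cfg$channel),
                 "simulate")
  cv <- NULL
  if (cfg$with_staging) {
    feats <- tick({
      fl <- lapply(cohort, function(s) {
        rec <- preprocess_recording(s$recording, target_rate = 100)
        extract_features(rec, cfg$channel, cfg$feature_cfg,
                         stages = s$hypnogram)
      })
      do.call(rbind, fl)
    }, "extract")
    if (cfg$folds > 0)
      cv <- tick(cross_validate(feats, folds = cfg$folds, k = cfg$k,
                                seed = cfg$seed), "cross_validate")
    staged <- tick({
      ranking <- rank_features_gini(feats[, feature_names()], feats$stage)
      subset <- select_subset(ranking, cfg$k)
      model <- train_ovr_svm(feats[, feature_names()], feats$stage,
                             subset = subset, seed = cfg$seed)
      lapply(cohort, function(s) {
        idx <- feats$subject_id == s$subject_id
        pred <- predict_stage(model, feats[idx, feature_names()])$stage
        s$hypnogram <- hypnogram(pred)
        s
      })
    }, "stage")
    metrics <- tick(cohort_metrics(staged, tsc = cfg$base$tsc_hours),
                    "metrics")
  } else {
    metrics <- tick(cohort_metrics(cohort, tsc = cfg$base$tsc_hours),
                    "metrics")
  }
  comparison <- tick(
    compare_cohorts(metrics[metrics$group == "exposed", ],
                    metrics[metrics$group == "sham", ],
                    B = cfg$bootstrap_B, seed = cfg$seed),
    "compare")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort(cohort, cfg$out_dir)
    write.csv(metrics, file.path(cfg$out_dir, "metrics.csv"),
              row.names = FALSE)
    write.csv(format_comparison_table(comparison),
              file.path(cfg$out_dir, "comparison.csv"), row.names = FALSE)
  }
  list(config = cfg, cohort_metrics = metrics, comparison = comparison,
       cv = cv, timing = unlist(timing))
}
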