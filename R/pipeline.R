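#' Build a pipeline configuration
#'
#' All tunables of an end-to-end run in one list. Every stochastic stage
#' receives its own seed derived from the master seed with [stage_seed()],
#' so stages can be rerun independently and identical configurations give
#' identical outputs.
#'
#' @param seed master seed.
#' @param n_sets recording sets in the synthetic cohort.
#' @param generator the ground-truth connectivity rule (a [motif_model()];
#'   the default is the chain-rule model `M4` calibrated to the overall rate
#'   of the independent-pair models).
#' @param analysis_models models fitted against the observed motif counts.
#' @param n_runs Monte Carlo runs per model.
#' @param n_ephys_cells cells for which step recordings are generated and
#'   features extracted (traces are the expensive stage; the connectivity
#'   analysis uses the whole cohort regardless).
#' @param n_coupling_pairs coupled and uncoupled pairs (each) put through
#'   the trace-level coupling estimator.
#' @param calibrate_rate overall connection rate the `M4` generator is
#'   calibrated to (skipped when `generator$base_p` is supplied or the
#'   generator is not `M4`).
#' @param output_dir optional directory for CSV/JSON outputs.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, n_sets = 100,
                            generator = motif_model("M4"),
                            analysis_models = list(M1 = motif_model("M1"),
                                                   M2 = motif_model("M2"),
                                                   M3 = motif_model("M3")),
                            n_runs = 1000, n_ephys_cells = 6,
                            n_coupling_pairs = 8,
                            calibrate_rate = 0.0438,
                            output_dir = NULL) {
  structure(
    list(seed = seed, n_sets = n_sets, generator = generator,
         analysis_models = analysis_models, n_runs = n_runs,
         n_ephys_cells = n_ephys_cells, n_coupling_pairs = n_coupling_pairs,
         calibrate_rate = calibrate_rate, output_dir = output_dir),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields override [pipeline_config()] defaults; `generator` and
#' `analysis_models` entries are lists of [motif_model()] arguments.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("generator", "analysis_models"))]
  if (!is.null(y$generator)) {
    args$generator <- do.call(motif_model, y$generator)
  }
  if (!is.null(y$analysis_models)) {
    args$analysis_models <- purrr::map(y$analysis_models,
                                       ~ do.call(motif_model, .x))
  }
  do.call(pipeline_config, args)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Generates a cohort of recording sets under the configured ground-truth
#' rule, extracts intrinsic-feature vectors from synthetic step recordings
#' for a subset of cells, estimates coupling coefficients from synthetic
#' paired trials (coupled pairs and an equal number of uncoupled pairs),
#' computes connectivity rates by type and distance, counts the observed
#' motifs, and compares them with the configured null models by closed-form
#' expectation and Monte Carlo simulation.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `pipeline_report`: `cohort`, `features`,
#'   `coupling`, `rates_by_type`, `rates_by_distance`, `observed_motifs`,
#'   `predictions` (one `motif_prediction` per analysis model), and a
#'   `summary` tibble (one row per model, from [glance()]).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  spec <- cohort_spec(n_sets = config$n_sets)
  gen <- config$generator
  if (gen$model == "M4" && !is.null(config$calibrate_rate)) {
    # the chain sampler draws each set's edge count binomially at base_p,
    # so the overall rate is matched by construction
    gen$base_p <- config$calibrate_rate
  }
  cohort <- generate_recording_sets(spec, gen,
                                    seed = stage_seed(config$seed, 2))

  # intrinsic features on a subsample of cells
  n_cells <- min(config$n_ephys_cells, nrow(cohort$cells))
  features <- if (n_cells > 0) {
    cells <- cohort$cells[seq_len(n_cells), ]
    params <- sample_cell_params(n_cells, cells$cell_type,
                                 seed = stage_seed(config$seed, 3))
    purrr::map_dfr(seq_len(n_cells), function(i) {
      rec <- generate_step_recording(params[i, ],
                                     noise_sd_mv = spec$noise_sd_mv,
                                     seed = stage_seed(config$seed, 100 + i))
      dplyr::bind_cols(cells[i, c("set_id", "cell_id", "cell_type")],
                       extract_feature_vector(rec))
    })
  } else {
    tibble::tibble()
  }

  # trace-level coupling estimation on a subsample of pairs
  coupled_idx <- which(cohort$pairs$connected)
  uncoupled_idx <- which(!cohort$pairs$connected)
  take <- function(idx, k) head(idx, min(k, length(idx)))
  pick <- c(take(coupled_idx, config$n_coupling_pairs),
            take(uncoupled_idx, config$n_coupling_pairs))
  coupling <- purrr::map_dfr(pick, function(k) {
    pr <- cohort$pairs[k, ]
    trials <- generate_coupled_pair_trials(
      pr$cc_true, n_trials = 10, noise_sd_mv = spec$noise_sd_mv,
      seed = stage_seed(config$seed, 200 + k))
    est <- estimate_coupling(trials)
    est$coupled <- classify_electrical_connection(est)
    dplyr::bind_cols(pr[, c("set_id", "cell_i", "cell_j", "distance_um",
                            "cc_true")], est)
  })

  rates_type <- connectivity_rates(cohort$pairs, by = "type")
  rates_dist <- connectivity_rates(cohort$pairs, by = c("type", "distance"))
  observed <- count_motifs(cohort$pairs)

  predictions <- purrr::imap(config$analysis_models, function(model, name) {
    runs <- simulate_cohort(cohort, model, n_runs = config$n_runs,
                            seed = stage_seed(config$seed, 4))
    summarize_prediction(runs, observed,
                         expected = expected_motif_counts(cohort, model))
  })
  summary <- purrr::imap_dfr(predictions, function(p, name) {
    dplyr::mutate(glance(p), model = name, .before = 1)
  })

  report <- structure(
    list(cohort = cohort, features = features, coupling = coupling,
         rates_by_type = rates_type, rates_by_distance = rates_dist,
         observed_motifs = observed, predictions = predictions,
         summary = summary, config = config),
    class = "pipeline_report"
  )
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' Write pipeline outputs to disk
#'
#' Per-cell feature table, per-pair coupling table, rates, motif counts
#' (CSV), per-set graphs (JSON), and the model summary (JSON).
#'
#' @param report a `pipeline_report`.
#' @param dir output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(x, name) {
    utils::write.csv(x, file.path(dir, name), row.names = FALSE)
  }
  wcsv(report$features, "features.csv")
  wcsv(report$coupling, "coupling.csv")
  wcsv(report$rates_by_type, "rates_by_type.csv")
  wcsv(report$rates_by_distance, "rates_by_distance.csv")
  wcsv(report$observed_motifs, "observed_motifs.csv")
  wcsv(report$summary, "model_summary.csv")
  write_recording_sets_json(report$cohort, file.path(dir, "graphs.json"))
  jsonlite::write_json(
    purrr::map(report$predictions,
               ~ list(summary = .x$summary, ratios = .x$ratios)),
    file.path(dir, "predictions.json"), dataframe = "rows", digits = NA)
  invisible(dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Multipatch analysis pipeline report\n")
  cat(sprintf("  %d recording sets, %d tested pairs, %d connections\n",
              length(unique(x$cohort$cells$set_id)), nrow(x$cohort$pairs),
              sum(x$cohort$pairs$connected)))
  cat("  Observed motif counts:\n")
  print(x$observed_motifs)
  cat("  Model comparison:\n")
  print(x$summary)
  invisible(x)
}
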