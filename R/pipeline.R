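#' Pipeline configuration
#'
#' Configuration for the end-to-end screen-to-replication analysis on
#' simulated cohorts: cohort sizes, planted effect sizes, metric task set,
#' and statistical thresholds. All randomness derives from `seed`.
#'
#' @param seed master RNG seed
#' @param n_screen screen-cohort size, default 16
#' @param n_replication replication-cohort size, default 11
#' @param n_ca3_missing_screen,n_ca3_missing_replication mice without CA3
#'   sites in each cohort, defaults 3 and 1
#' @param task `"MWM"` or `"APA"`
#' @param effect_r2_abundance,effect_r2_sg planted effect sizes, defaults
#'   0.51 and 0.77
#' @param alpha significance level, default 0.05
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(seed = 1L, n_screen = 16L, n_replication = 11L,
                            n_ca3_missing_screen = 3L,
                            n_ca3_missing_replication = 1L,
                            task = c("MWM", "APA"),
                            effect_r2_abundance = 0.51, effect_r2_sg = 0.77,
                            alpha = 0.05) {
  task <- match.arg(task)
  structure(list(seed = as.integer(seed), n_screen = as.integer(n_screen),
                 n_replication = as.integer(n_replication),
                 n_ca3_missing_screen = as.integer(n_ca3_missing_screen),
                 n_ca3_missing_replication = as.integer(n_ca3_missing_replication),
                 task = task, effect_r2_abundance = effect_r2_abundance,
                 effect_r2_sg = effect_r2_sg, alpha = alpha),
            class = "pipeline_config")
}

# z-score all metric columns of a cohort table
.zscore_table <- function(metrics) {
  out <- metrics["mouse_id"]
  for (m in setdiff(names(metrics), "mouse_id"))
    out[[m]] <- zscore_metric(metrics[[m]])
  out
}

# analyze one cohort: z table, composite scores, per-metric correlations
.analyze_cohort <- function(cohort, task, alpha) {
  signs <- if (task == "MWM")
    list(learning = mwm_learning_signs, precision = mwm_precision_signs)
  else
    list(learning = apa_learning_signs, precision = apa_precision_signs)
  z <- .zscore_table(cohort$metrics)
  learn_score <- composite_score(z, names(signs$learning), signs$learning)
  prec_score <- composite_score(z, names(signs$precision), signs$precision)
  abundance_z <- zscore_metric(cohort$features$swr_abundance_hz)
  sg_z <- zscore_metric(cohort$features$sg_z_ca3)
  cors <- list()
  for (m in names(signs$learning))
    cors[[paste0("abundance~", m)]] <- correlate(abundance_z, z[[m]])
  for (m in names(signs$precision))
    cors[[paste0("sg_ca3~", m)]] <- correlate(sg_z, z[[m]])
  list(z = z, learning_score = learn_score, precision_score = prec_score,
       abundance_z = abundance_z, sg_z = sg_z, correlations = cors,
       kept_metrics = redundancy_filter(cohort$metrics))
}

#' Run the screen-to-replication pipeline on simulated cohorts
#'
#' Simulates a screen and a replication cohort with the configured planted
#' effects, computes composite learning and memory-precision scores,
#' correlates each SWR feature with each component metric (Holm-Sidak
#' adjusted within the replication cohort), tests enrichment of
#' significant comparisons against the binomial null, fits the
#' feature-to-score linear models on the screen cohort, evaluates them on
#' the replication cohort, and checks leave-one-out robustness of the
#' score-level relationships. Deterministic given the config.
#'
#' @param config a [pipeline_config()]
#' @param quiet suppress stage messages, default `TRUE`
#' @return nested report list (JSON-serializable)
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  screen <- simulate_cohort(cohort_sim_params(
    seed = config$seed, n_mice = config$n_screen,
    n_ca3_missing = config$n_ca3_missing_screen,
    effect_r2_abundance = config$effect_r2_abundance,
    effect_r2_sg = config$effect_r2_sg, task = config$task))
  repl <- simulate_cohort(cohort_sim_params(
    seed = config$seed + 10000L, n_mice = config$n_replication,
    n_ca3_missing = config$n_ca3_missing_replication,
    effect_r2_abundance = config$effect_r2_abundance,
    effect_r2_sg = config$effect_r2_sg, task = config$task))
  say("simulated cohorts: screen n=%d, replication n=%d",
      config$n_screen, config$n_replication)

  A <- .analyze_cohort(screen, config$task, config$alpha)
  B <- .analyze_cohort(repl, config$task, config$alpha)

  # Holm-Sidak adjustment within the replication cohort
  p_rep <- vapply(B$correlations, `[[`, numeric(1), "p")
  p_adj <- holm_sidak(p_rep)
  for (i in seq_along(B$correlations)) B$correlations[[i]]$p_adjusted <- p_adj[i]

  k_sig <- sum(vapply(A$correlations, `[[`, numeric(1), "p") < config$alpha)
  n_comp <- length(A$correlations)
  enrich_p <- binomial_enrichment(k_sig, n_comp, config$alpha)
  say("screen: %d/%d significant comparisons (binomial p = %.3g)",
      k_sig, n_comp, enrich_p)

  model_learn <- fit_linear_predictor(A$abundance_z, A$learning_score$score)
  model_prec <- fit_linear_predictor(A$sg_z, A$precision_score$score)
  pred_learn <- predict_and_evaluate(model_learn, B$abundance_z,
                                     B$learning_score$score)
  pred_prec <- predict_and_evaluate(model_prec, B$sg_z, B$precision_score$score)
  say("cross-cohort prediction: learning r2=%.3f, precision r2=%.3f",
      pred_learn$r2, pred_prec$r2)

  loo_learn <- loo_robustness(B$abundance_z, B$learning_score$score,
                              config$alpha)
  ok_prec <- !is.na(B$sg_z) & !is.na(B$precision_score$score)
  loo_prec <- loo_robustness(B$sg_z[ok_prec], B$precision_score$score[ok_prec],
                             config$alpha)

  strip <- function(cors) lapply(cors, function(cr)
    cr[intersect(c("method", "r", "n", "p", "p_adjusted"), names(cr))])
  list(schema_version = 1L,
       config = unclass(config),
       screen = list(
         scores = data.frame(mouse_id = screen$features$mouse_id,
                             learning = A$learning_score$score,
                             precision = A$precision_score$score),
         correlations = strip(A$correlations),
         kept_metrics = A$kept_metrics,
         n_significant = k_sig, n_comparisons = n_comp,
         enrichment_p = enrich_p),
       replication = list(
         scores = data.frame(mouse_id = repl$features$mouse_id,
                             learning = B$learning_score$score,
                             precision = B$precision_score$score),
         correlations = strip(B$correlations),
         kept_metrics = B$kept_metrics),
       models = list(
         learning = unclass(model_learn), precision = unclass(model_prec)),
       prediction = list(
         learning = pred_learn[c("r2", "F", "p", "n")],
         precision = pred_prec[c("r2", "F", "p", "n")]),
       robustness = list(
         learning = loo_learn, precision = loo_prec))
}

#' Write a pipeline report as JSON
#'
#' @param report a [run_pipeline()] result
#' @param path output file
#' @return invisible `path`
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = 10,
                       dataframe = "columns")
  invisible(path)
}
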