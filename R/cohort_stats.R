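#' Metric sets and sign maps for the composite performance scores
#'
#' Each composite score averages the sign-oriented z-scores of a fixed
#' metric set. Orientation `-1` means lower raw values indicate better
#' performance (the z-score is negated before averaging), `+1` means
#' higher is better.
#'
#' * MWM learning: escape-latency slope over days 1-2 and 1-3, escape
#'   latency on day 3, overnight latency change over days 1-2 (all lower
#'   is better).
#' * MWM memory precision: percent time in target quadrant on probes 1-2
#'   and target crossings on probe 1 (higher is better); distance-to-
#'   platform AUC on probes 1-2 (lower is better).
#' * APA learning (day 2): latency to first entrance, path length, percent
#'   time opposite the shock zone (higher is better).
#' * APA memory precision: entrances on day 2 (lower is better), per-bout
#'   distance relative to the shock zone on days 2-3 (higher is better).
#'
#' @format Named numeric vectors (+1 higher-is-better, -1 lower-is-better).
#' @name score_definitions
NULL

#' @rdname score_definitions
#' @export
mwm_learning_signs <- c(latency_slope_d1_2 = -1, latency_slope_d1_3 = -1,
                        latency_day3 = -1, overnight_change_d1_2 = -1)

#' @rdname score_definitions
#' @export
mwm_precision_signs <- c(quadrant_time_p1 = 1, quadrant_time_p2 = 1,
                         target_crossings_p1 = 1,
                         distance_auc_p1 = -1, distance_auc_p2 = -1)

#' @rdname score_definitions
#' @export
apa_learning_signs <- c(latency_first_entrance_d2 = 1, path_length_d2 = 1,
                        opposite_quadrant_time_d2 = 1)

#' @rdname score_definitions
#' @export
apa_precision_signs <- c(entrances_d2 = -1,
                         bout_distance_d2 = 1, bout_distance_d3 = 1)

#' Z-score a per-mouse metric
#'
#' Standardizes with the sample SD (n - 1 denominator); missing values
#' stay missing and do not contribute to the reference moments.
#'
#' @param values numeric vector (may contain `NA`)
#' @return z-scored vector of the same length
#' @export
zscore_metric <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 3) stop("zscore_metric: need at least 3 non-missing values")
  s <- stats::sd(values[ok])
  if (s <= 0) stop("zscore_metric: zero variance")
  (values - mean(values[ok])) / s
}

#' Composite performance score
#'
#' Per mouse, the mean over the listed metrics of the sign-oriented
#' z-score. Mice with fewer than half of the metrics present get `NA`.
#' With no missing data the cohort mean is 0 by construction.
#'
#' @param z_table data.frame of z-scored metrics; rows are mice, must
#'   contain a `mouse_id` column plus one column per metric
#' @param metrics character vector of metric columns to combine
#' @param sign_map named vector (see [score_definitions]) covering `metrics`
#' @return data.frame `mouse_id`, `score`
#' @export
composite_score <- function(z_table, metrics, sign_map) {
  missing_signs <- setdiff(metrics, names(sign_map))
  if (length(missing_signs))
    stop("composite_score: no sign-map entry for: ",
         paste(missing_signs, collapse = ", "))
  if (!all(metrics %in% names(z_table)))
    stop("composite_score: metric column(s) absent from z_table")
  Z <- as.matrix(z_table[metrics])
  Z <- sweep(Z, 2, sign_map[metrics], "*")
  n_ok <- rowSums(!is.na(Z))
  score <- rowMeans(Z, na.rm = TRUE)
  score[n_ok < length(metrics) / 2] <- NA_real_
  score[n_ok == 0] <- NA_real_
  data.frame(mouse_id = z_table$mouse_id, score = score)
}

#' Redundancy filter on behavioral metrics
#'
#' Greedy scan in declared (column) order: a metric is dropped if its
#' pairwise R^2 with any already-kept metric is at least `r2_max`, so the
#' retained set captures distinct aspects of behavior.
#'
#' @param metric_table data.frame of raw metrics (non-metric `mouse_id`
#'   column ignored)
#' @param r2_max redundancy threshold, default 0.5
#' @return character vector of kept metric names
#' @export
redundancy_filter <- function(metric_table, r2_max = 0.5) {
  cols <- setdiff(names(metric_table), "mouse_id")
  if (length(cols) < 2) stop("redundancy_filter: need at least 2 metrics")
  kept <- character(0)
  for (m in cols) {
    redundant <- FALSE
    for (k in kept) {
      r <- stats::cor(metric_table[[m]], metric_table[[k]],
                      use = "pairwise.complete.obs")
      if (!is.na(r) && r^2 >= r2_max) { redundant <- TRUE; break }
    }
    if (!redundant) kept <- c(kept, m)
  }
  kept
}

#' Correlation with normality-based method choice
#'
#' Shapiro-Wilk is run on each variable; if both pass at
#' `alpha_normality`, a Pearson correlation with a two-sided t-based p is
#' used, otherwise a Spearman rank correlation.
#'
#' @param x,y paired numeric vectors (pairwise-complete; n >= 4)
#' @param alpha_normality Shapiro-Wilk alpha, default 0.05
#' @return list `method` ("PEARSON"/"SPEARMAN"), `r`, `n`, `p`
#' @export
correlate <- function(x, y, alpha_normality = 0.05) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("correlate: need at least 4 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("correlate: constant input")
  normal <- stats::shapiro.test(x)$p.value > alpha_normality &&
            stats::shapiro.test(y)$p.value > alpha_normality
  if (normal) {
    ct <- stats::cor.test(x, y, method = "pearson")
    list(method = "PEARSON", r = unname(ct$estimate), n = length(x),
         p = ct$p.value)
  } else {
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    list(method = "SPEARMAN", r = unname(ct$estimate), n = length(x),
         p = ct$p.value)
  }
}

#' Holm-Sidak step-down adjusted p values
#'
#' Sorts the p values ascending and sets
#' `adj_(i) = max_(j <= i) 1 - (1 - p_(j))^(m - j + 1)`, clipped at 1,
#' returned in the original order.
#'
#' @param p numeric vector of p values in (0, 1]
#' @return adjusted p values, same order
#' @export
holm_sidak <- function(p) {
  if (any(p <= 0 | p > 1 | is.na(p))) stop("holm_sidak: p values must be in (0, 1]")
  m <- length(p)
  o <- order(p)
  adj_sorted <- pmin(cummax(1 - (1 - p[o])^(m - seq_len(m) + 1)), 1)
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

#' Exact binomial enrichment of significant comparisons
#'
#' One-sided upper-tail probability `P(X >= k)` for
#' `X ~ Binomial(n, alpha)`: the chance of observing at least `k`
#' significant results among `n` independent comparisons if none of the
#' tested relationships were real.
#'
#' @param k_significant observed significant count
#' @param n_comparisons number of comparisons
#' @param alpha per-comparison significance level, default 0.05
#' @return p value
#' @export
binomial_enrichment <- function(k_significant, n_comparisons, alpha = 0.05) {
  if (k_significant < 0 || n_comparisons < 0 || k_significant > n_comparisons)
    stop("binomial_enrichment: need 0 <= k <= n")
  if (k_significant == 0) return(1)
  stats::pbinom(k_significant - 1, n_comparisons, alpha, lower.tail = FALSE)
}

#' Fit a linear feature-to-score predictor
#'
#' Ordinary least squares of the performance score on the z-scored SWR
#' feature in the source cohort.
#'
#' @param predictor_z z-scored feature values (per mouse)
#' @param score performance scores (per mouse)
#' @param source_cohort label recorded with the model
#' @return list of class `linear_predictor`: `slope`, `intercept`, `n`,
#'   `source_cohort`
#' @export
fit_linear_predictor <- function(predictor_z, score, source_cohort = "SCREEN") {
  ok <- !is.na(predictor_z) & !is.na(score)
  if (sum(ok) < 4) stop("fit_linear_predictor: need at least 4 paired values")
  if (stats::sd(predictor_z[ok]) == 0)
    stop("fit_linear_predictor: degenerate predictor")
  fit <- stats::lm(score[ok] ~ predictor_z[ok])
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 n = sum(ok), source_cohort = source_cohort),
            class = "linear_predictor")
}

#' Apply a fitted predictor to a new cohort and evaluate it
#'
#' Predicts scores from the target cohort's (within-cohort z-scored)
#' feature using the source-cohort model, then evaluates predicted versus
#' actual: R^2 is the squared Pearson correlation, with F and p from the
#' simple regression of actual on predicted.
#'
#' @param model a [fit_linear_predictor()] result
#' @param predictor_z target-cohort z-scored feature
#' @param actual target-cohort actual scores
#' @return list `predicted`, `r2`, `F`, `p`, `n`
#' @export
predict_and_evaluate <- function(model, predictor_z, actual) {
  ok <- !is.na(predictor_z) & !is.na(actual)
  if (sum(ok) < 4) stop("predict_and_evaluate: need at least 4 paired values")
  predicted <- model$intercept + model$slope * predictor_z
  fit <- stats::lm(actual[ok] ~ predicted[ok])
  sm <- summary(fit)
  list(predicted = predicted,
       r2 = unname(stats::cor(predicted[ok], actual[ok])^2),
       F = unname(sm$fstatistic[1]),
       p = stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                     lower.tail = FALSE),
       n = sum(ok))
}

#' Leave-one-out robustness of a correlation
#'
#' Re-runs [correlate()] on every n-1 subset; the relationship is robust
#' iff it stays significant (p < alpha) after removing any single animal.
#'
#' @param x,y paired numeric vectors, n >= 5
#' @param alpha significance level, default 0.05
#' @return list `robust` (logical), `p_values` (per left-out point)
#' @export
loo_robustness <- function(x, y, alpha = 0.05) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5) stop("loo_robustness: need at least 5 paired values")
  p <- vapply(seq_len(n), function(i) correlate(x[-i], y[-i])$p, numeric(1))
  list(robust = all(p < alpha), p_values = p)
}
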