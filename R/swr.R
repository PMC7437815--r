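#' SWR detection parameters
#'
#' Defaults implement the primary detection rule: ripple-band (150-250 Hz)
#' envelope exceeding 5 baseline SDs for at least 15 ms during extended
#' immobility. The robustness variants used to check band/threshold
#' sensitivity are expressed by passing `band = c(125, 250)` or
#' `threshold_sd = 3`.
#'
#' @param band ripple band (Hz), default `c(150, 250)`
#' @param threshold_sd detection threshold in baseline-SD units, default 5
#' @param min_duration_s minimum supra-threshold duration (s), default 0.015
#' @param merge_gap_s supra-threshold runs closer than this are merged,
#'   default 0.015
#' @return object of class `detection_params`
#' @export
detection_params <- function(band = c(150, 250), threshold_sd = 5,
                             min_duration_s = 0.015, merge_gap_s = 0.015) {
  stopifnot(threshold_sd > 0, min_duration_s > 0, merge_gap_s >= 0)
  structure(list(band = band, threshold_sd = threshold_sd,
                 min_duration_s = min_duration_s, merge_gap_s = merge_gap_s),
            class = "detection_params")
}

# analytic signal via frequency-domain construction
.analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Ripple-band amplitude envelope
#'
#' Magnitude of the analytic (Hilbert) signal of the already ripple-filtered
#' trace, smoothed with a Gaussian kernel (default sigma 4 ms).
#'
#' @param x ripple-band-filtered signal (uV)
#' @param sample_rate sampling rate (Hz)
#' @param smooth_sigma_s Gaussian smoothing sigma (s), default 0.004
#' @return non-negative envelope, same length as `x`
#' @export
ripple_envelope <- function(x, sample_rate, smooth_sigma_s = 0.004) {
  env <- Mod(.analytic_signal(x))
  .gauss_smooth(env, smooth_sigma_s * sample_rate)
}

#' Envelope baseline statistics during immobility
#'
#' Mean and sample SD of the envelope over samples inside the immobility
#' intervals, in a single pass with no event exclusion. These define the
#' "baseline" and "SD" of the detection threshold.
#'
#' @param env envelope (uV)
#' @param immobility an [interval_set()] with positive total duration
#' @param sample_rate sampling rate (Hz)
#' @return list with `baseline_mean`, `baseline_sd` (uV), `n_samples`
#' @export
envelope_stats <- function(env, immobility, sample_rate) {
  if (interval_total(immobility) <= 0)
    stop("envelope_stats: empty immobility set")
  mask <- interval_mask(immobility, length(env), sample_rate)
  v <- env[mask]
  if (length(v) < 2) stop("envelope_stats: too few immobility samples")
  s <- stats::sd(v)
  if (s <= 0) stop("envelope_stats: zero envelope variance during immobility")
  list(baseline_mean = mean(v), baseline_sd = s, n_samples = length(v))
}

#' Detect sharp-wave ripples from a ripple-band envelope
#'
#' Supra-threshold runs (envelope > baseline_mean + threshold_sd * baseline_sd,
#' restricted to immobility samples) separated by less than `merge_gap_s`
#' are merged; merged runs of at least `min_duration_s` become events.
#' `onset_s` is the threshold-crossing time (the t = 0 anchor for all
#' peri-event windows); `start_s`/`end_s` extend outward to the nearest
#' crossing of the baseline mean; `peak_sd` is the envelope peak in
#' baseline-SD units.
#'
#' @param env envelope (uV)
#' @param stats_ baseline statistics from [envelope_stats()]
#' @param params a [detection_params()]
#' @param immobility an [interval_set()]
#' @param sample_rate sampling rate (Hz)
#' @return data.frame with columns `start_s`, `onset_s`, `peak_s`, `end_s`,
#'   `peak_sd`, `duration_s` (possibly zero rows)
#' @export
detect_swrs <- function(env, stats_, params, immobility, sample_rate) {
  thr <- stats_$baseline_mean + params$threshold_sd * stats_$baseline_sd
  mask <- (env > thr) & interval_mask(immobility, length(env), sample_rate)
  runs <- .bool_runs(mask)
  empty <- data.frame(start_s = numeric(0), onset_s = numeric(0),
                      peak_s = numeric(0), end_s = numeric(0),
                      peak_sd = numeric(0), duration_s = numeric(0))
  if (!nrow(runs)) return(empty)
  # merge runs separated by < merge_gap_s
  gap <- params$merge_gap_s * sample_rate
  if (nrow(runs) > 1) {
    merged <- list()
    cur <- runs[1, ]
    for (i in 2:nrow(runs)) {
      if (runs[i, "first"] - cur["last"] - 1 < gap) {
        cur["last"] <- runs[i, "last"]
      } else {
        merged[[length(merged) + 1]] <- cur
        cur <- runs[i, ]
      }
    }
    merged[[length(merged) + 1]] <- cur
    runs <- do.call(rbind, merged)
  }
  dur <- (runs[, "last"] - runs[, "first"] + 1) / sample_rate
  runs <- runs[dur >= params$min_duration_s, , drop = FALSE]
  if (!nrow(runs)) return(empty)
  below <- env <= stats_$baseline_mean
  n <- length(env)
  ev <- lapply(seq_len(nrow(runs)), function(i) {
    a <- runs[i, "first"]; b <- runs[i, "last"]
    # extend outward to the nearest baseline-mean crossing
    s <- a
    while (s > 1 && !below[s - 1]) s <- s - 1
    e <- b
    while (e < n && !below[e + 1]) e <- e + 1
    pk <- a - 1 + which.max(env[a:b])
    data.frame(start_s = (s - 1) / sample_rate,
               onset_s = (a - 1) / sample_rate,
               peak_s = (pk - 1) / sample_rate,
               end_s = e / sample_rate,
               peak_sd = (env[pk] - stats_$baseline_mean) / stats_$baseline_sd,
               duration_s = (b - a + 1) / sample_rate)
  })
  out <- do.call(rbind, ev)
  rownames(out) <- NULL
  out
}

#' SWR abundance (events per second of qualified immobility)
#'
#' @param events event table from [detect_swrs()]
#' @param immobility an [interval_set()] with positive total duration
#' @return abundance in events/s
#' @export
swr_abundance <- function(events, immobility) {
  tot <- interval_total(immobility)
  if (tot <= 0) stop("swr_abundance: zero immobility time")
  nrow(events) / tot
}

#' Multi-unit spike times by amplitude thresholding
#'
#' The wideband trace is referenced (wideband minus reference), band-pass
#' Butterworth filtered at 600-6000 Hz, and upward crossings of
#' `threshold_uv` with a 1 ms refractory period are reported as spikes.
#'
#' @param wideband wideband trace (uV), sampled at `sample_rate >= 20000`
#' @param reference reference-electrode trace, same length
#' @param sample_rate sampling rate (Hz)
#' @param threshold_uv spike threshold (uV), default 75
#' @return numeric vector of spike times (s)
#' @export
mua_spike_times <- function(wideband, reference, sample_rate, threshold_uv = 75) {
  if (length(wideband) != length(reference))
    stop("mua_spike_times: wideband and reference lengths differ")
  if (sample_rate < 20000)
    stop("mua_spike_times: wideband input must be sampled at >= 20 kHz")
  spec <- filter_spec("butter", 600, 6000, order = 4)
  y <- bandpass_filter(wideband - reference, spec, sample_rate)
  up <- which(y[-1] > threshold_uv & y[-length(y)] <= threshold_uv) + 1L
  if (!length(up)) return(numeric(0))
  refr <- round(0.001 * sample_rate)
  # enforce the refractory period with a sequential scan (a vectorized
  # diff() pass would mis-handle chains of near crossings)
  sel <- up[1]; last <- up[1]
  for (i in up[-1]) if (i - last > refr) { sel <- c(sel, i); last <- i }
  (sel - 1) / sample_rate
}

#' Multi-unit modulation by SWRs
#'
#' Ratio of the spike rate inside event windows (`onset_s` to
#' `onset_s + 0.1` s) to the spike rate during immobility outside event
#' windows. Ratios above 1 indicate SWR-locked firing, the signature used
#' to verify pyramidal-layer electrode placement. If all spikes fall inside
#' event windows the ratio is `Inf`.
#'
#' @param spikes spike times (s)
#' @param events event table from [detect_swrs()]
#' @param immobility an [interval_set()]
#' @param window_s in-event window length after onset (s), default 0.1
#' @return dimensionless rate ratio
#' @export
mua_swr_modulation <- function(spikes, events, immobility, window_s = 0.1) {
  if (!nrow(events)) stop("mua_swr_modulation: no events")
  if (interval_total(immobility) <= 0) stop("mua_swr_modulation: zero immobility time")
  evw <- .union_intervals(events$onset_s, events$onset_s + window_s)
  in_ev <- in_intervals(spikes, evw)
  in_imm <- in_intervals(spikes, immobility)
  t_in <- interval_total(evw)
  # immobility time not covered by event windows
  t_out <- interval_total(immobility) - .overlap_total(immobility, evw)
  rate_in <- sum(in_ev) / t_in
  n_out <- sum(in_imm & !in_ev)
  if (n_out == 0) return(Inf)
  rate_in / (n_out / t_out)
}

# total overlap duration between two interval sets
.overlap_total <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(0)
  tot <- 0
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a$start_s[i], b$start_s)
    hi <- pmin(a$end_s[i], b$end_s)
    tot <- tot + sum(pmax(hi - lo, 0))
  }
  tot
}
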