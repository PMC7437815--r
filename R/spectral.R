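#' Multitaper spectrogram specification
#'
#' Defaults follow common peri-ripple practice: 100 ms sliding window,
#' 10 ms step, time-bandwidth product 2 with 3 Slepian tapers (giving a
#' +/-20 Hz analysis half-bandwidth at a 100 ms window).
#'
#' @param window_s window length (s), default 0.1
#' @param step_s window step (s), default 0.01
#' @param time_bandwidth time-bandwidth product NW, default 2
#' @param n_tapers number of tapers K (must satisfy K <= 2NW - 1), default 3
#' @return object of class `spectrogram_spec`
#' @export
spectrogram_spec <- function(window_s = 0.1, step_s = 0.01,
                             time_bandwidth = 2, n_tapers = 3) {
  stopifnot(n_tapers <= 2 * time_bandwidth - 1, window_s > 0, step_s > 0)
  structure(list(window_s = window_s, step_s = step_s,
                 time_bandwidth = time_bandwidth, n_tapers = as.integer(n_tapers)),
            class = "spectrogram_spec")
}

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed from the symmetric tridiagonal commuting matrix; eigenvectors
#' are returned unit-normalized, ordered by decreasing energy
#' concentration, with the polarity convention that each taper has
#' non-negative mean (even orders) or non-negative initial slope (odd
#' orders).
#'
#' @param n taper length (samples)
#' @param nw time-bandwidth product
#' @param k number of tapers
#' @return n x k matrix of tapers, each with unit sum of squares
#' @export
dpss_tapers <- function(n, nw, k) {
  stopifnot(k >= 1, k <= n, nw > 0)
  w <- nw / n
  t <- 0:(n - 1)
  d <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  e <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A <- matrix(0, n, n)
  A[cbind(1:n, 1:n)] <- d
  A[cbind(1:(n - 1), 2:n)] <- e
  A[cbind(2:n, 1:(n - 1))] <- e
  eg <- eigen(A, symmetric = TRUE)
  V <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    v <- V[, j] / sqrt(sum(V[, j]^2))
    # polarity: positive mean (symmetric orders) or positive leading lobe
    s <- sum(v)
    if (abs(s) < 1e-8) s <- sum(v[seq_len(ceiling(n / 2))])
    if (s < 0) v <- -v
    V[, j] <- v
  }
  V
}

#' Sliding-window multitaper spectrogram
#'
#' Power spectral density (uV^2/Hz, one-sided) estimated per window as the
#' mean of the K tapered eigenspectra. Window centers lie on the step grid
#' starting at `window_s / 2`; the frequency grid has resolution
#' `1 / window_s` (no zero padding).
#'
#' @param x signal (uV)
#' @param sample_rate sampling rate (Hz)
#' @param spec a [spectrogram_spec()]
#' @param freq_range optional `c(lo, hi)` (Hz) to retain a sub-band
#' @return list with `time_s` (window centers), `freq_hz`, and `power`
#'   (windows x frequencies matrix), plus `spec`
#' @export
multitaper_spectrogram <- function(x, sample_rate, spec = spectrogram_spec(),
                                   freq_range = NULL) {
  nwin <- round(spec$window_s * sample_rate)
  step <- round(spec$step_s * sample_rate)
  if (nwin > length(x)) stop("multitaper_spectrogram: window longer than signal")
  if (nwin < 32) stop("multitaper_spectrogram: window shorter than 32 samples")
  tapers <- dpss_tapers(nwin, spec$time_bandwidth, spec$n_tapers)
  starts <- seq(1L, length(x) - nwin + 1L, by = step)
  nf <- nwin %/% 2 + 1
  freq <- (0:(nf - 1)) * sample_rate / nwin
  fsel <- if (is.null(freq_range)) seq_len(nf) else
    which(freq >= freq_range[1] & freq <= freq_range[2])
  P <- matrix(0, length(starts), length(fsel))
  chunk <- 8192L
  idx0 <- outer(0:(nwin - 1L), starts, "+")   # nwin x nwindows index matrix
  for (c0 in seq(1L, length(starts), by = chunk)) {
    c1 <- min(c0 + chunk - 1L, length(starts))
    seg <- matrix(x[idx0[, c0:c1]], nrow = nwin)
    acc <- 0
    for (k in seq_len(spec$n_tapers)) {
      F <- stats::mvfft(seg * tapers[, k])
      acc <- acc + Mod(F[fsel, , drop = FALSE])^2
    }
    # one-sided PSD: double all bins except DC (and Nyquist for even nwin)
    scale <- rep(2, length(fsel))
    scale[freq[fsel] == 0] <- 1
    if (nwin %% 2 == 0) scale[fsel == nf] <- 1
    P[c0:c1, ] <- t(acc / spec$n_tapers / sample_rate * scale)
  }
  list(time_s = (starts - 1 + (nwin - 1) / 2) / sample_rate,
       freq_hz = freq[fsel], power = P, spec = spec)
}

#' Z-score a spectrogram against a baseline window set
#'
#' Each frequency bin is standardized by the mean and sample SD of its
#' power over the baseline windows (typically all windows whose centers
#' fall in immobility). At least 100 baseline windows are required for a
#' stable reference.
#'
#' @param power windows x frequencies power matrix
#' @param baseline_mask logical vector over windows selecting the baseline
#' @return z matrix of the same shape
#' @export
zscore_spectrogram <- function(power, baseline_mask) {
  stopifnot(length(baseline_mask) == nrow(power))
  if (sum(baseline_mask) < 100)
    stop("zscore_spectrogram: baseline must contain at least 100 windows")
  mu <- colMeans(power[baseline_mask, , drop = FALSE])
  sd_ <- apply(power[baseline_mask, , drop = FALSE], 2, stats::sd)
  bad <- which(sd_ <= 0)
  if (length(bad))
    stop(sprintf("zscore_spectrogram: zero baseline variance in bin(s) %s",
                 paste(bad, collapse = ", ")))
  sweep(sweep(power, 2, mu, "-"), 2, sd_, "/")
}

#' Slow-gamma power during SWRs
#'
#' Mean z-scored power over the slow-gamma band in the 0-100 ms window
#' after event onset: frequency bins with centers inside `sg_band`,
#' spectrogram windows with centers in `(onset, onset + window[2]]`
#' (right-closed), averaged within each event and then across events.
#'
#' @param z z-scored spectrogram matrix (windows x frequencies)
#' @param time_s window-center times (s)
#' @param freq_hz frequency-bin centers (Hz)
#' @param events event table from [detect_swrs()]
#' @param sg_band slow-gamma band (Hz), default `c(30, 50)`
#' @param window peri-onset window (s), default `c(0, 0.1)`
#' @return scalar z (dimensionless)
#' @export
sg_power_during_swrs <- function(z, time_s, freq_hz, events,
                                 sg_band = c(30, 50), window = c(0, 0.1)) {
  if (!nrow(events)) stop("sg_power_during_swrs: no events")
  fsel <- freq_hz >= sg_band[1] & freq_hz <= sg_band[2]
  if (!any(fsel)) stop("sg_power_during_swrs: no frequency bins in band")
  per_event <- vapply(seq_len(nrow(events)), function(i) {
    t0 <- events$onset_s[i]
    wsel <- time_s > t0 + window[1] & time_s <= t0 + window[2]
    if (!any(wsel))
      stop(sprintf("sg_power_during_swrs: no spectrogram window in (%g, %g] s",
                   t0 + window[1], t0 + window[2]))
    mean(z[wsel, fsel, drop = FALSE])
  }, numeric(1))
  mean(per_event)
}

#' Aggregate per-site feature values to one number per mouse
#'
#' Values are averaged over sites within a region to give a session value,
#' then averaged (unweighted) over a mouse's included sessions, so each
#' mouse contributes a single number per feature. A mouse with no site in
#' a region gets `NA` for that region but is retained for the others.
#'
#' @param site_values data.frame with columns `mouse_id`, `session`,
#'   `region`, `value`
#' @param regions regions to report, default `c("CA1_SR", "CA3", "DG")`
#' @return data.frame: one row per mouse, one column per region (z units)
#' @export
aggregate_features <- function(site_values,
                               regions = c("CA1_SR", "CA3", "DG")) {
  stopifnot(all(c("mouse_id", "session", "region", "value") %in% names(site_values)))
  mice <- unique(site_values$mouse_id)
  out <- data.frame(mouse_id = mice, stringsAsFactors = FALSE)
  for (rg in regions) {
    out[[rg]] <- vapply(mice, function(m) {
      sv <- site_values[site_values$mouse_id == m & site_values$region == rg, ]
      if (!nrow(sv)) return(NA_real_)
      sess <- tapply(sv$value, sv$session, mean)   # region mean per session
      mean(sess)                                    # unweighted over sessions
    }, numeric(1))
  }
  out
}
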