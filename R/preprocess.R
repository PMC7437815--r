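#' Band-pass filter specification
#'
#' Two designs are supported, matching standard extracellular-LFP practice:
#' a Butterworth IIR applied forward-backward (zero phase), and an
#' equiripple (Parks-McClellan) FIR applied with group-delay compensation.
#' The wide LFP band (0.1-300 Hz) uses the Butterworth design; narrow
#' oscillation bands (ripple 150-250 Hz, slow gamma 30-50 Hz) use the
#' equiripple design.
#'
#' @param kind `"butter"` or `"fir_equiripple"`
#' @param low_hz,high_hz band edges (Hz), `0 < low < high < fs/2`
#' @param order Butterworth order (default 4)
#' @param transition_hz FIR transition-band width (default 10 Hz)
#' @return object of class `filter_spec`
#' @export
filter_spec <- function(kind = c("butter", "fir_equiripple"),
                        low_hz, high_hz, order = 4L, transition_hz = 10) {
  kind <- match.arg(kind)
  stopifnot(low_hz > 0, high_hz > low_hz)
  structure(list(kind = kind, low_hz = low_hz, high_hz = high_hz,
                 order = as.integer(order), transition_hz = transition_hz),
            class = "filter_spec")
}

# design an equiripple band-pass; taps chosen for >= 40 dB stopband with
# the requested transition width (Harris estimate, rounded up to odd)
.design_fir <- function(spec, sample_rate) {
  df <- spec$transition_hz / sample_rate
  n <- ceiling(40 / (22 * df))            # ~ atten_dB / (22 * normalized transition)
  if (n %% 2 == 0) n <- n + 1             # odd length -> integer group delay
  f <- c(0, spec$low_hz - spec$transition_hz, spec$low_hz,
         spec$high_hz, spec$high_hz + spec$transition_hz, sample_rate / 2)
  f <- pmax(pmin(f / (sample_rate / 2), 1), 0)
  signal::remez(n - 1, f, c(0, 0, 1, 1, 0, 0))
}

#' Zero-phase band-pass filtering
#'
#' Butterworth filters are applied forward-backward (`signal::filtfilt`);
#' FIR filters are applied by FFT convolution with the group delay of
#' `(n_taps - 1) / 2` samples removed, so both paths are zero phase.
#'
#' @param x numeric signal (uV)
#' @param spec a [filter_spec()]
#' @param sample_rate sampling rate (Hz)
#' @return filtered signal, same length as `x`
#' @export
bandpass_filter <- function(x, spec, sample_rate) {
  stopifnot(inherits(spec, "filter_spec"))
  if (spec$high_hz >= sample_rate / 2)
    stop("bandpass_filter: band edge at or above Nyquist")
  if (spec$kind == "butter") {
    bf <- signal::butter(spec$order,
                         c(spec$low_hz, spec$high_hz) / (sample_rate / 2),
                         type = "pass")
    as.numeric(signal::filtfilt(bf, x))
  } else {
    h <- as.numeric(unclass(.design_fir(spec, sample_rate)))
    .fir_filter_zerophase(x, h)
  }
}

# FFT convolution with the (n_taps - 1)/2 group delay removed
.fir_filter_zerophase <- function(x, h) {
  n <- length(x); nh <- length(h)
  d <- (nh - 1) / 2
  nfft <- 2^ceiling(log2(n + nh - 1))
  X <- stats::fft(c(x, numeric(nfft - n)))
  H <- stats::fft(c(h, numeric(nfft - nh)))
  y <- Re(stats::fft(X * H, inverse = TRUE)) / nfft
  y[(d + 1):(d + n)]
}

#' Anti-aliased integer-factor downsampling
#'
#' Low-pass filters at 80% of the target Nyquist (8th-order Butterworth,
#' applied forward-backward, so the passband is flat and DC gain is
#' exactly 1) and then decimates. The source rate must be an integer
#' multiple of the target rate.
#'
#' @param x numeric signal
#' @param sample_rate source rate (Hz)
#' @param target_rate target rate (Hz)
#' @return decimated signal of length `floor(length(x) * target / source)`
#' @export
downsample_signal <- function(x, sample_rate, target_rate) {
  if (target_rate > sample_rate)
    stop("downsample_signal: target rate exceeds source rate")
  q <- sample_rate / target_rate
  if (abs(q - round(q)) > 1e-9)
    stop("downsample_signal: sample_rate must be an integer multiple of target_rate")
  q <- round(q)
  n_out <- floor(length(x) / q)
  # decimate in stages of at most 10 (large single-stage factors push the
  # anti-alias poles too close to the unit circle)
  while (q > 1) {
    stage <- q
    while (stage > 10 || (q %% stage != 0)) stage <- stage - 1
    bf <- signal::butter(8, 0.8 / stage)
    x <- signal::filtfilt(bf, x)
    x <- x[seq(1, length(x), by = stage)]
    q <- q / stage
  }
  x[seq_len(min(n_out, length(x)))]
}

#' Gaussian-smoothed speed from a position track
#'
#' Positions are smoothed with a Gaussian kernel (sigma in seconds,
#' truncated at 4 sigma, edge-renormalized), then speed is computed by
#' central differences; the first and last samples use one-sided
#' differences.
#'
#' @param position data.frame with columns `t_s`, `x_cm`, `y_cm`
#'   (30 Hz camera grid)
#' @param smoothing_sigma_s Gaussian sigma (s); default 0.25
#' @return data.frame of class `velocity_series` with columns `t_s`, `v_cm_s`
#' @export
velocity_from_position <- function(position, smoothing_sigma_s = 0.25) {
  stopifnot(nrow(position) >= 2)
  t <- position$t_s
  if (any(diff(t) <= 0)) stop("velocity_from_position: timestamps must be strictly increasing")
  dt <- stats::median(diff(t))
  xs <- .gauss_smooth(position$x_cm, smoothing_sigma_s / dt)
  ys <- .gauss_smooth(position$y_cm, smoothing_sigma_s / dt)
  n <- length(t)
  v <- numeric(n)
  if (n > 2) {
    i <- 2:(n - 1)
    v[i] <- sqrt((xs[i + 1] - xs[i - 1])^2 + (ys[i + 1] - ys[i - 1])^2) /
      (t[i + 1] - t[i - 1])
  }
  v[1] <- sqrt((xs[2] - xs[1])^2 + (ys[2] - ys[1])^2) / (t[2] - t[1])
  v[n] <- sqrt((xs[n] - xs[n - 1])^2 + (ys[n] - ys[n - 1])^2) / (t[n] - t[n - 1])
  out <- data.frame(t_s = t, v_cm_s = v)
  class(out) <- c("velocity_series", "data.frame")
  out
}

# Gaussian smoothing with sigma in samples; edge-renormalized
.gauss_smooth <- function(x, sigma_samples) {
  if (sigma_samples <= 0) return(x)
  half <- max(1L, ceiling(4 * sigma_samples))
  k <- stats::dnorm(-half:half, sd = sigma_samples)
  k <- k / sum(k)
  n <- length(x)
  # FFT convolution padded to a highly composite length (stats::convolve
  # pads to exactly n + m - 1, which can have a disastrous factorization)
  nfft <- stats::nextn(n + length(k) - 1, c(2, 3, 5))
  num <- Re(stats::fft(stats::fft(c(x, numeric(nfft - n))) *
                         stats::fft(c(k, numeric(nfft - length(k)))),
                       inverse = TRUE))[(half + 1):(half + n)] / nfft
  # interior kernel mass is 1; only the first/last `half` samples see a
  # truncated kernel and need renormalizing
  cum <- cumsum(k)
  den <- rep(1, n)
  edge <- seq_len(min(half, n))
  den[edge] <- cum[half + edge]
  den[n + 1 - edge] <- pmin(den[n + 1 - edge], cum[half + edge])
  num / den
}

#' Extended-immobility intervals from a velocity series
#'
#' A maximal run of samples with speed below `threshold_cm_s` that lasts at
#' least `qualify_s` contributes the interval starting `qualify_s` after run
#' onset: analysis time begins only after the animal has already been still
#' for the qualification period. Setting `count_full_run = TRUE` instead
#' counts the whole sub-threshold run (the alternative reading of the
#' inclusion rule).
#'
#' @param vel a [velocity_from_position()] result
#' @param threshold_cm_s immobility speed threshold (cm/s), default 1
#' @param qualify_s qualification period (s), default 30
#' @param count_full_run logical; include the first `qualify_s` of each run
#' @return an [interval_set()]
#' @export
immobility_intervals <- function(vel, threshold_cm_s = 1, qualify_s = 30,
                                 count_full_run = FALSE) {
  t <- vel$t_s
  dt <- stats::median(diff(t))
  runs <- .bool_runs(vel$v_cm_s < threshold_cm_s)
  if (!nrow(runs)) return(interval_set())
  start <- t[runs[, "first"]]
  end <- t[runs[, "last"]] + dt            # half-open on the sample grid
  keep <- (end - start) >= qualify_s
  if (!any(keep)) return(interval_set())
  start <- start[keep]; end <- end[keep]
  if (!count_full_run) start <- start + qualify_s
  nonempty <- end > start + 1e-12       # a run of exactly qualify_s is empty
  interval_set(start[nonempty], end[nonempty])
}

#' Session inclusion by total immobility time
#'
#' A session enters SWR analysis only if it contains at least
#' `min_total_s` of qualified immobility (default 10 of the 60 session
#' minutes). The boundary counts as included.
#'
#' @param immobility an [interval_set()]
#' @param min_total_s minimum total immobility (s), default 600
#' @return logical
#' @export
session_passes_inclusion <- function(immobility, min_total_s = 600) {
  interval_total(immobility) >= min_total_s
}
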