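#' Construct a set of half-open time intervals
#'
#' An `interval_set` is a sorted, pairwise-disjoint collection of half-open
#' intervals `[start, end)` in seconds from session start. It is the
#' container used for immobility periods and for all restricted-time
#' analyses (SWR detection, baseline statistics, abundance).
#'
#' @param start_s,end_s numeric vectors of equal length; each interval must
#'   satisfy `end_s > start_s` and intervals must not overlap.
#' @return An object of class `interval_set`: a data.frame with columns
#'   `start_s`, `end_s`, and attribute `total_s` (summed length).
#' @export
interval_set <- function(start_s = numeric(0), end_s = numeric(0)) {
  stopifnot(length(start_s) == length(end_s))
  if (length(start_s)) {
    o <- order(start_s)
    start_s <- start_s[o]; end_s <- end_s[o]
    if (any(end_s <= start_s)) stop("interval_set: every interval needs end > start")
    if (length(start_s) > 1 && any(start_s[-1] < end_s[-length(end_s)]))
      stop("interval_set: intervals overlap")
  }
  iv <- data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s))
  class(iv) <- c("interval_set", "data.frame")
  iv
}

#' Total duration of an interval set
#' @param iv an `interval_set`
#' @return total length in seconds
#' @export
interval_total <- function(iv) {
  if (!nrow(iv)) return(0)
  sum(iv$end_s - iv$start_s)
}

#' Membership of time points in an interval set
#'
#' @param t_s numeric vector of times (s)
#' @param iv an `interval_set`
#' @return logical vector: `TRUE` where `t_s` falls inside some `[start, end)`
#' @export
in_intervals <- function(t_s, iv) {
  out <- logical(length(t_s))
  if (!nrow(iv)) return(out)
  # findInterval against the interleaved boundaries: odd slot = inside
  bounds <- as.vector(rbind(iv$start_s, iv$end_s))
  idx <- findInterval(t_s, bounds)
  idx %% 2L == 1L
}

#' Sample mask for an interval set on a regular grid
#'
#' @param iv an `interval_set`
#' @param n_samples number of samples
#' @param sample_rate sampling rate (Hz); sample i is at time (i-1)/rate
#' @return logical vector of length `n_samples`
#' @export
interval_mask <- function(iv, n_samples, sample_rate) {
  in_intervals((seq_len(n_samples) - 1) / sample_rate, iv)
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("<interval_set> %d interval(s), total %.3f s\n",
              nrow(x), interval_total(x)))
  invisible(x)
}

# union of possibly-overlapping intervals -> valid interval_set
.union_intervals <- function(start_s, end_s) {
  if (!length(start_s)) return(interval_set())
  o <- order(start_s)
  start_s <- start_s[o]; end_s <- end_s[o]
  us <- start_s[1]; ue <- end_s[1]
  for (i in seq_along(start_s)[-1]) {
    if (start_s[i] <= ue[length(ue)]) {
      ue[length(ue)] <- max(ue[length(ue)], end_s[i])
    } else {
      us <- c(us, start_s[i]); ue <- c(ue, end_s[i])
    }
  }
  interval_set(us, ue)
}

# runs of TRUE in a logical vector -> integer matrix [first, last] (inclusive)
.bool_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(first = starts[keep], last = ends[keep])
}
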