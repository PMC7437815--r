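# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately use explicit scans rather than the
# package's vectorized code paths.

# threshold-scan SWR oracle: mask -> runs -> merge -> duration filter ->
# boundary extension, sample by sample
oracle_detect <- function(env, stats_, params, immobility, sample_rate) {
  thr <- stats_$baseline_mean + params$threshold_sd * stats_$baseline_sd
  t <- (seq_along(env) - 1) / sample_rate
  imm <- rep(FALSE, length(env))
  for (i in seq_len(nrow(immobility)))
    imm <- imm | (t >= immobility$start_s[i] & t < immobility$end_s[i])
  above <- env > thr & imm
  # runs
  runs <- list(); i <- 1
  while (i <= length(above)) {
    if (above[i]) {
      j <- i
      while (j < length(above) && above[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  if (!length(runs)) return(data.frame(onset_s = numeric(0), end_s = numeric(0)))
  # merge
  gap <- params$merge_gap_s * sample_rate
  merged <- list(runs[[1]])
  for (r in runs[-1]) {
    last <- merged[[length(merged)]]
    if (r[1] - last[2] - 1 < gap) merged[[length(merged)]] <- c(last[1], r[2])
    else merged[[length(merged) + 1]] <- r
  }
  keep <- Filter(function(r) (r[2] - r[1] + 1) / sample_rate >= params$min_duration_s,
                 merged)
  if (!length(keep)) return(data.frame(onset_s = numeric(0), end_s = numeric(0)))
  out <- lapply(keep, function(r) {
    s <- r[1]
    while (s > 1 && env[s - 1] > stats_$baseline_mean) s <- s - 1
    e <- r[2]
    while (e < length(env) && env[e + 1] > stats_$baseline_mean) e <- e + 1
    pk <- r[1] - 1 + which.max(env[r[1]:r[2]])
    data.frame(start_s = (s - 1) / sample_rate, onset_s = (r[1] - 1) / sample_rate,
               peak_s = (pk - 1) / sample_rate, end_s = e / sample_rate,
               peak_sd = (env[pk] - stats_$baseline_mean) / stats_$baseline_sd,
               duration_s = (r[2] - r[1] + 1) / sample_rate)
  })
  do.call(rbind, out)
}

# step-down Sidak by the literal max formula, element by element
oracle_holm_sidak <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    vals <- numeric(i)
    for (j in seq_len(i)) vals[j] <- 1 - (1 - p[o[j]])^(m - j + 1)
    adj[o[i]] <- min(max(vals), 1)
  }
  adj
}

# upper-tail binomial probability by direct pmf summation
oracle_binom_tail <- function(k, n, alpha) {
  if (k == 0) return(1)
  sum(dbinom(k:n, n, alpha))
}

# random envelope with occasional excursions, for detector oracle checks
random_envelope <- function(n = 2000, sample_rate = 1000) {
  env <- abs(rnorm(n, 1, 0.2))
  for (k in seq_len(rpois(1, 3))) {
    at <- sample.int(n - 60, 1)
    len <- sample(5:50, 1)
    env[at:(at + len)] <- env[at:(at + len)] + runif(1, 0.5, 3)
  }
  env
}

# standard session layout used across detection tests: one mobile lead-in,
# one long immobile block giving ~600 s of qualified immobility
accept_schedule <- function(immobile_s = 630) {
  matrix(c(35, immobile_s, 35, 0), ncol = 2, byrow = TRUE)
}

detect_chain <- function(session, params = detection_params(), site = 1) {
  imm <- immobility_intervals(velocity_from_position(session$position))
  rip <- bandpass_filter(session$signals[site, ],
                         filter_spec("fir_equiripple", params$band[1], params$band[2]),
                         session$sample_rate)
  env <- ripple_envelope(rip, session$sample_rate)
  st <- envelope_stats(env, imm, session$sample_rate)
  list(immobility = imm, envelope = env, stats = st,
       events = detect_swrs(env, st, params, imm, session$sample_rate))
}
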