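#' Parameters for a synthetic LFP session
#'
#' The generator emulates the statistical structure of a 60-minute
#' home-cage rest recording: 1/f background noise per electrode site, a
#' mobility/immobility schedule realized in the position track, and
#' planted SWR complexes during qualified immobility, each composed of a
#' ripple-band burst on the CA1 pyramidal site, a negative sharp wave on
#' CA1 stratum radiatum, and a 40 Hz slow-gamma burst (amplitude
#' `sg_mod_amp`) on CA3/CA1-SR/DG in the 0-100 ms post-onset window.
#'
#' `ripple_rate_hz` is the Poisson event rate over qualified immobility
#' time (the portion of each still block after the 30 s qualification
#' period), so planted rates compare directly with measured SWR abundance.
#' `ripple_amp_sd` scales burst amplitude in units of the SD of the
#' ripple-band-filtered background noise.
#'
#' @param seed RNG seed
#' @param duration_s session length (s), default 3600
#' @param sample_rate LFP rate (Hz), default 1000
#' @param noise_exponent 1/f spectral exponent, default 1
#' @param noise_sd_uv background noise SD (uV), default 30
#' @param ripple_rate_hz planted event rate during qualified immobility,
#'   default 0.2
#' @param ripple_amp_sd ripple burst amplitude in band-noise SD units,
#'   default 8
#' @param ripple_freq_range per-event carrier frequency range (Hz),
#'   default `c(150, 220)`
#' @param ripple_env_sigma_s ripple Gaussian envelope sigma (s), default 0.02
#' @param sharp_wave_amp_uv sharp-wave amplitude (uV), default 150
#' @param sg_mod_amp slow-gamma burst amplitude (uV), default 40
#' @param sg_burst_sigma_s slow-gamma burst envelope sigma (s), default 0.025
#' @param immobility_schedule two-column matrix of alternating
#'   `(mobile_s, immobile_s)` block pairs; must tile `duration_s`
#' @param site_regions region labels of the simulated sites
#' @return object of class `lfp_sim_params`
#' @export
lfp_sim_params <- function(seed = 1L, duration_s = 3600, sample_rate = 1000,
                           noise_exponent = 1, noise_sd_uv = 30,
                           ripple_rate_hz = 0.2, ripple_amp_sd = 8,
                           ripple_freq_range = c(150, 220),
                           ripple_env_sigma_s = 0.02,
                           sharp_wave_amp_uv = 150, sg_mod_amp = 40,
                           sg_burst_sigma_s = 0.025,
                           immobility_schedule = NULL,
                           site_regions = c("CA1_PYR", "CA1_SR", "CA3", "DG")) {
  if (is.null(immobility_schedule)) {
    n_blocks <- ceiling(duration_s / 300)
    immobility_schedule <- matrix(rep(c(60, 240), n_blocks),
                                  ncol = 2, byrow = TRUE)
  }
  if (abs(sum(immobility_schedule) - duration_s) > 1e-6)
    stop("lfp_sim_params: immobility schedule does not tile the session duration")
  structure(list(seed = as.integer(seed), duration_s = duration_s,
                 sample_rate = sample_rate, noise_exponent = noise_exponent,
                 noise_sd_uv = noise_sd_uv, ripple_rate_hz = ripple_rate_hz,
                 ripple_amp_sd = ripple_amp_sd,
                 ripple_freq_range = ripple_freq_range,
                 ripple_env_sigma_s = ripple_env_sigma_s,
                 sharp_wave_amp_uv = sharp_wave_amp_uv,
                 sg_mod_amp = sg_mod_amp, sg_burst_sigma_s = sg_burst_sigma_s,
                 immobility_schedule = immobility_schedule,
                 site_regions = site_regions),
            class = "lfp_sim_params")
}

# 1/f^alpha noise via spectral shaping, rescaled to sd_uv
.pink_noise <- function(n, exponent, sd_uv, floor_hz = 1, sample_rate = 1000) {
  W <- stats::fft(stats::rnorm(n))
  f <- c(0, pmin(1:(n - 1), n - (1:(n - 1)))) * sample_rate / n
  g <- 1 / pmax(f, floor_hz)^(exponent / 2)
  g[1] <- 0                                  # no DC drift
  x <- Re(stats::fft(W * g, inverse = TRUE)) / n
  x * sd_uv / stats::sd(x)
}

#' Simulate one LFP session with planted ground truth
#'
#' Seed-deterministic. See [lfp_sim_params()] for the generative model.
#' Ground-truth `onset_s` is the nominal burst start, two envelope sigmas
#' before the burst peak; events are planted at least 1 s inside the
#' qualified part of each immobility block and at least 250 ms apart.
#'
#' @param params an [lfp_sim_params()]
#' @return list `session` (an [lfp_session()]) and `truth` (list with
#'   `events` data.frame `onset_s`/`center_s`/`freq_hz`, `qualified`
#'   interval_set, `band_noise_sd_uv`, and the params)
#' @export
simulate_lfp_session <- function(params) {
  stopifnot(inherits(params, "lfp_sim_params"))
  set.seed(params$seed)
  fs <- params$sample_rate
  n <- round(params$duration_s * fs)
  regions <- params$site_regions

  # schedule -> block edges; qualified immobility = [imm_start + 30, imm_end)
  sched <- params$immobility_schedule
  edges <- cumsum(as.vector(t(sched)))
  imm_start <- c(0, edges)[seq(1, 2 * nrow(sched), by = 2)] + sched[, 1]
  imm_end <- imm_start + sched[, 2]
  qual <- sched[, 2] > 30
  qualified <- interval_set(imm_start[qual] + 30, imm_end[qual])

  # planted events: Poisson count over qualified time, times placed by
  # rejection under a 250 ms hard-core constraint (thinning a Poisson
  # process instead would bias the planted rate low by ~rate * 0.25)
  centers <- numeric(0)
  for (i in which(qual)) {
    lo <- imm_start[i] + 30 + 1; hi <- imm_end[i] - 1
    if (hi <= lo) next
    k <- stats::rpois(1, params$ripple_rate_hz * (imm_end[i] - imm_start[i] - 30))
    if (k == 0) next
    tt <- numeric(0)
    attempts <- 0L
    while (length(tt) < k && attempts < 200L * k) {
      cand <- stats::runif(1, lo, hi)
      if (!length(tt) || all(abs(tt - cand) >= 0.25)) tt <- c(tt, cand)
      attempts <- attempts + 1L
    }
    centers <- c(centers, sort(tt))
  }
  freqs <- stats::runif(length(centers), params$ripple_freq_range[1],
                        params$ripple_freq_range[2])
  phases <- stats::runif(length(centers), 0, 2 * pi)

  # background noise per site; ripple-band SD measured on the CA1_PYR noise
  signals <- matrix(0, length(regions), n)
  for (s in seq_along(regions))
    signals[s, ] <- .pink_noise(n, params$noise_exponent, params$noise_sd_uv,
                                sample_rate = fs)
  band_sd <- NA_real_
  if ("CA1_PYR" %in% regions) {
    rip_spec <- filter_spec("fir_equiripple", 150, 250)
    band_sd <- stats::sd(bandpass_filter(signals[match("CA1_PYR", regions), ],
                                         rip_spec, fs))
  }

  tgrid <- (seq_len(n) - 1) / fs
  add_burst <- function(row, center, sigma, freq, amp, phase = 0) {
    lo <- max(1, floor((center - 4 * sigma) * fs)); hi <- min(n, ceiling((center + 4 * sigma) * fs))
    idx <- lo:hi
    env <- exp(-(tgrid[idx] - center)^2 / (2 * sigma^2))
    signals[row, idx] <<- signals[row, idx] +
      amp * env * if (is.na(freq)) 1 else sin(2 * pi * freq * (tgrid[idx] - center) + phase)
  }
  i_pyr <- match("CA1_PYR", regions)
  i_sr <- match("CA1_SR", regions)
  sg_rows <- which(regions %in% c("CA3", "CA1_SR", "DG"))
  for (e in seq_along(centers)) {
    c0 <- centers[e]
    if (!is.na(i_pyr))
      add_burst(i_pyr, c0, params$ripple_env_sigma_s, freqs[e],
                params$ripple_amp_sd * band_sd, phases[e])
    if (!is.na(i_sr))
      add_burst(i_sr, c0 + 0.01, 0.03, NA, -params$sharp_wave_amp_uv)
    if (params$sg_mod_amp > 0) {
      onset <- c0 - 2 * params$ripple_env_sigma_s
      for (r in sg_rows)
        add_burst(r, onset + 0.05, params$sg_burst_sigma_s, 40,
                  params$sg_mod_amp)
    }
  }

  # position track realizing the schedule (30 Hz)
  pt <- seq(0, params$duration_s - 1 / 30, by = 1 / 30)
  has_imm <- imm_end > imm_start            # schedule may have 0 s blocks
  mobile <- !in_intervals(pt, interval_set(imm_start[has_imm], imm_end[has_imm]))
  speed <- ifelse(mobile, pmax(stats::rnorm(length(pt), 8, 2), 2), 0)
  heading <- cumsum(stats::rnorm(length(pt), 0, 0.3))
  jit <- 0.003
  x <- cumsum(speed * cos(heading) / 30 + stats::rnorm(length(pt), 0, jit))
  y <- cumsum(speed * sin(heading) / 30 + stats::rnorm(length(pt), 0, jit))
  position <- data.frame(t_s = pt, x_cm = x, y_cm = y)

  sites <- do.call(rbind, lapply(seq_along(regions), function(i)
    electrode_site(sprintf("site%02d", i), shank_index = 1L, depth_index = i,
                   region_label = regions[i])))
  session <- lfp_session(mouse_id = sprintf("sim%03d", params$seed),
                         genotype = "E4", age_group = "OLD",
                         session_index = 1L, sample_rate = fs,
                         signals = signals, sites = sites,
                         position = position)
  # ground-truth onset convention: the time the planted burst's noiseless
  # (smoothed) envelope crosses this session's nominal 5 SD detection
  # level, so onset errors measure detector timing jitter rather than a
  # definitional offset. Falls back to 2 sigma before the peak when the
  # pyramidal site (and hence a detection level) is absent.
  onset <- centers - 2 * params$ripple_env_sigma_s
  detectable <- rep(TRUE, length(centers))
  if (!is.na(i_pyr) && length(centers)) {
    env <- ripple_envelope(bandpass_filter(signals[i_pyr, ], rip_spec, fs), fs)
    ev_mask <- interval_mask(qualified, n, fs)
    mu <- mean(env[ev_mask]); sd_ <- stats::sd(env[ev_mask])
    thr <- mu + 5 * sd_
    sig_eff <- sqrt(params$ripple_env_sigma_s^2 + 0.004^2)
    a_eff <- params$ripple_amp_sd * band_sd * params$ripple_env_sigma_s / sig_eff
    detectable <- rep(a_eff > thr, length(centers))
    if (a_eff > thr)
      onset <- centers - sig_eff * sqrt(2 * log(a_eff / thr))
  }
  truth <- list(events = data.frame(onset_s = onset, center_s = centers,
                                    freq_hz = freqs, detectable = detectable),
                qualified = qualified, band_noise_sd_uv = band_sd,
                params = params)
  list(session = session, truth = truth)
}

# random walk in a disc with optional attraction toward a point
.disc_walk <- function(n, radius, start, attract = NULL, strength = 0,
                       step_sd = 1.5) {
  x <- numeric(n); y <- numeric(n)
  x[1] <- start[1]; y[1] <- start[2]
  dx <- stats::rnorm(n, 0, step_sd); dy <- stats::rnorm(n, 0, step_sd)
  for (i in 2:n) {
    px <- x[i - 1] + dx[i]; py <- y[i - 1] + dy[i]
    if (!is.null(attract)) {
      px <- px + strength * (attract[1] - x[i - 1])
      py <- py + strength * (attract[2] - y[i - 1])
    }
    r <- sqrt(px^2 + py^2)
    if (r > radius) { px <- px * radius / r; py <- py * radius / r }
    x[i] <- px; y[i] <- py
  }
  cbind(x, y)
}

#' Simulate Morris water maze trials for one mouse
#'
#' Five hidden days of four trials plus two probe trials. Expected escape
#' latency decreases across days in proportion to `skill`; probe paths
#' concentrate near the previous platform location in proportion to
#' `skill` (at `skill = 0` the probe path is an unbiased reflected random
#' walk, giving ~25% target-quadrant time by symmetry).
#'
#' @param skill scalar in `[0, 1]`
#' @param seed RNG seed
#' @param platform_center platform location (cm), default `c(30, 30)`
#' @return list of [mwm_trial()] objects
#' @export
simulate_mwm_trials <- function(skill, seed = 1L, platform_center = c(30, 30)) {
  stopifnot(skill >= 0, skill <= 1)
  set.seed(seed)
  pool_r <- 61
  trials <- list()
  for (day in 1:5) {
    base <- 55 - 42 * skill * (day - 1) / 4
    for (tr in 1:4) {
      lat <- min(max(stats::rnorm(1, base, 6), 4), 60)
      nfr <- max(round(lat * 30), 8)
      th <- stats::runif(1, 0, 2 * pi)
      start <- 0.92 * pool_r * c(cos(th), sin(th))
      target <- if (lat < 60) platform_center else {
        th2 <- stats::runif(1, 0, 2 * pi)
        0.5 * pool_r * c(cos(th2), sin(th2))
      }
      s <- seq(0, 1, length.out = nfr)
      perp <- c(-(target[2] - start[2]), target[1] - start[1])
      perp <- perp / sqrt(sum(perp^2))
      wig <- 12 * sin(s * pi * stats::runif(1, 1, 3)) * (1 - skill * 0.5) +
        stats::rnorm(nfr, 0, 1.5)
      x <- start[1] + s * (target[1] - start[1]) + perp[1] * wig * sin(s * pi)
      y <- start[2] + s * (target[2] - start[2]) + perp[2] * wig * sin(s * pi)
      r <- sqrt(x^2 + y^2); over <- r > pool_r
      x[over] <- x[over] * pool_r / r[over]; y[over] <- y[over] * pool_r / r[over]
      trials[[length(trials) + 1]] <- mwm_trial(
        day = day, trial_index = tr, kind = "HIDDEN",
        track = data.frame(t_s = (seq_len(nfr) - 1) / 30, x_cm = x, y_cm = y),
        escape_latency_s = lat, platform_center = platform_center)
    }
  }
  for (p in 1:2) {
    nfr <- 60 * 30
    w <- .disc_walk(nfr, pool_r, start = c(0, 0), attract = platform_center,
                    strength = 0.012 * skill, step_sd = 1.6)
    trials[[length(trials) + 1]] <- mwm_trial(
      day = 5 + p, trial_index = 1, kind = "PROBE",
      track = data.frame(t_s = (seq_len(nfr) - 1) / 30,
                         x_cm = w[, 1], y_cm = w[, 2]),
      escape_latency_s = NA_real_, platform_center = platform_center)
  }
  trials
}

#' Simulate active place avoidance trials for one mouse
#'
#' Four training days plus a probe. The animal's room-frame angle follows
#' `d(theta)/dt = (1 - a) * rotation + a * repulsion(theta) + noise` with
#' `a = avoidance`: at `a = 0` the animal rides the rotating arena and
#' sweeps through the room-fixed zone once per rotation (~10 entrances per
#' 600 s); at `a = 1` repulsion from the zone dominates and the animal
#' holds a room-fixed position away from it.
#'
#' @param avoidance scalar in `[0, 1]`
#' @param seed RNG seed
#' @param zone_center_deg shock-zone center (deg, room frame), default 0
#' @param duration_s trial length (s), default 600
#' @return list of [apa_trial()] objects (days 1-4 TRAIN, day 5
#'   PROBE_REINSTATE)
#' @export
simulate_apa_trials <- function(avoidance, seed = 1L, zone_center_deg = 0,
                                duration_s = 600) {
  stopifnot(avoidance >= 0, avoidance <= 1)
  set.seed(seed)
  trials <- list()
  for (day in 1:5) {
    nfr <- round(duration_s * 30)
    dt <- 1 / 30
    th <- numeric(nfr)
    th[1] <- (zone_center_deg + 180) %% 360
    noise <- stats::rnorm(nfr, 0, 1.2 * sqrt(dt) * 57.3 * 0.05)
    for (i in 2:nfr) {
      d <- .ang_diff(th[i - 1], zone_center_deg)
      repel <- ifelse(abs(d) < 150, sign(d) * 25 * (1 - abs(d) / 150), 0)
      if (d == 0) repel <- 25
      th[i] <- (th[i - 1] + ((1 - avoidance) * 6 + avoidance * repel) * dt +
                  noise[i]) %% 360
    }
    r <- 14 + 3 * sin(cumsum(stats::rnorm(nfr, 0, 0.02)))
    r <- pmin(pmax(r, 3), 19)
    t_s <- (seq_len(nfr) - 1) * dt
    th_arena <- (th - 6 * t_s) * pi / 180
    trials[[length(trials) + 1]] <- apa_trial(
      day = day, kind = if (day == 5) "PROBE_REINSTATE" else "TRAIN",
      track = data.frame(t_s = t_s, x_cm = r * cos(th_arena),
                         y_cm = r * sin(th_arena)),
      zone_center_deg = zone_center_deg, duration_s = duration_s)
  }
  trials
}

#' Parameters for a simulated cohort
#'
#' The cohort generator plants the study's effect structure at the metric
#' level: each mouse has independent latent SWR-abundance and CA3
#' slow-gamma factors; a latent behavioral ability per score is a mixture
#' of the designated feature (weight `sqrt(R2)`) and independent noise;
#' each behavioral metric loads on that ability with reliability
#' `metric_reliability` (pairwise metric R^2 = reliability^2, kept below
#' the 0.5 redundancy threshold) and is mapped to its natural units and
#' orientation.
#'
#' @param seed RNG seed
#' @param n_mice number of mice, default 16
#' @param n_ca3_missing mice without CA3 electrode sites (their SG feature
#'   and precision metrics are `NA`), default 3
#' @param effect_r2_abundance planted population R^2 between z-scored
#'   abundance and the learning ability, default 0.51
#' @param effect_r2_sg planted R^2 between CA3 SG power and the precision
#'   ability, default 0.77
#' @param metric_reliability loading of each metric on its ability,
#'   default 0.6
#' @param task `"MWM"` or `"APA"` metric set
#' @return object of class `cohort_sim_params`
#' @export
cohort_sim_params <- function(seed = 1L, n_mice = 16L, n_ca3_missing = 3L,
                              effect_r2_abundance = 0.51, effect_r2_sg = 0.77,
                              metric_reliability = 0.6,
                              task = c("MWM", "APA")) {
  task <- match.arg(task)
  stopifnot(effect_r2_abundance >= 0, effect_r2_abundance < 1,
            effect_r2_sg >= 0, effect_r2_sg < 1)
  structure(list(seed = as.integer(seed), n_mice = as.integer(n_mice),
                 n_ca3_missing = as.integer(n_ca3_missing),
                 effect_r2_abundance = effect_r2_abundance,
                 effect_r2_sg = effect_r2_sg,
                 metric_reliability = metric_reliability, task = task),
            class = "cohort_sim_params")
}

# natural-unit scales for the simulated metric tables
.metric_scales <- list(
  MWM = list(
    learning = data.frame(
      metric = c("latency_slope_d1_2", "latency_slope_d1_3", "latency_day3",
                 "overnight_change_d1_2"),
      mean = c(-8, -9, 30, -5), sd = c(4, 3, 10, 8)),
    precision = data.frame(
      metric = c("quadrant_time_p1", "quadrant_time_p2", "target_crossings_p1",
                 "distance_auc_p1", "distance_auc_p2"),
      mean = c(35, 32, 3, 150, 160), sd = c(12, 12, 2, 40, 40))),
  APA = list(
    learning = data.frame(
      metric = c("latency_first_entrance_d2", "path_length_d2",
                 "opposite_quadrant_time_d2"),
      mean = c(100, 2000, 35), sd = c(80, 500, 10)),
    precision = data.frame(
      metric = c("entrances_d2", "bout_distance_d2", "bout_distance_d3"),
      mean = c(8, 5, 5), sd = c(4, 4, 4))))

#' Simulate a cohort with planted feature-behavior effects
#'
#' @param params a [cohort_sim_params()]
#' @return list `features` (data.frame `mouse_id`, `swr_abundance_hz`,
#'   `sg_z_ca3`), `metrics` (mouse x metric data.frame in natural units),
#'   `truth` (latents and planted parameters)
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_sim_params"))
  set.seed(params$seed)
  n <- params$n_mice
  signs <- if (params$task == "MWM")
    list(learning = mwm_learning_signs, precision = mwm_precision_signs)
  else
    list(learning = apa_learning_signs, precision = apa_precision_signs)
  scales <- .metric_scales[[params$task]]

  L_A <- stats::rnorm(n)                    # abundance latent
  L_G <- stats::rnorm(n)                    # CA3 slow-gamma latent
  abundance <- pmax(0.16 + 0.045 * L_A, 0.01)
  sg_ca3 <- 0.8 + 0.35 * L_G
  ca3_missing <- if (params$n_ca3_missing > 0)
    sample.int(n, params$n_ca3_missing) else integer(0)
  sg_obs <- sg_ca3
  sg_obs[ca3_missing] <- NA_real_

  make_metrics <- function(latent, r2, sc, sgn) {
    rel <- params$metric_reliability
    # the planted R^2 targets the composite score (what the study reports);
    # averaging m metrics of reliability `rel` attenuates the score-ability
    # correlation by rel / (rel + (1 - rel) / m), so the ability-feature
    # R^2 is raised to compensate
    atten <- rel / (rel + (1 - rel) / nrow(sc))
    q <- min(r2 / atten, 0.97)
    ability <- sqrt(q) * latent + sqrt(1 - q) * stats::rnorm(n)
    out <- list()
    for (i in seq_len(nrow(sc))) {
      m <- sqrt(rel) * ability + sqrt(1 - rel) * stats::rnorm(n)
      out[[sc$metric[i]]] <- sc$mean[i] + sc$sd[i] * sgn[[sc$metric[i]]] * m
    }
    list(tbl = as.data.frame(out), ability = ability)
  }
  learn <- make_metrics(L_A, params$effect_r2_abundance,
                        scales$learning, signs$learning)
  prec <- make_metrics(L_G, params$effect_r2_sg,
                       scales$precision, signs$precision)
  # mice without CA3 sites keep their behavior; only the SG feature is
  # missing, so they drop out of SG analyses pairwise
  mouse_id <- sprintf("m%02d", seq_len(n))
  list(features = data.frame(mouse_id = mouse_id,
                             swr_abundance_hz = abundance, sg_z_ca3 = sg_obs),
       metrics = cbind(data.frame(mouse_id = mouse_id), learn$tbl, prec$tbl),
       truth = list(latent_abundance = L_A, latent_sg = L_G,
                    learning_ability = learn$ability,
                    precision_ability = prec$ability,
                    ca3_missing = ca3_missing, params = params))
}
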