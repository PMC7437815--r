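#' Morris water maze trial
#'
#' Pool-frame trial record. The pool is 122 cm in diameter with a 14 x 14 cm
#' hidden platform; hidden trials are capped at 60 s.
#'
#' @param day training day (1-5 hidden; probes follow)
#' @param trial_index trial within the day (1-4)
#' @param kind `"HIDDEN"`, `"PROBE"` or `"VISIBLE"`
#' @param track data.frame `t_s`, `x_cm`, `y_cm` at 30 Hz, pool frame
#'   centered on the pool
#' @param escape_latency_s escape latency (s, capped at 60; `NA` for probes)
#' @param platform_center length-2 numeric, platform center (cm)
#' @param platform_half_width half width of the square platform (cm), default 7
#' @param pool_radius pool radius (cm), default 61
#' @return object of class `mwm_trial`
#' @export
mwm_trial <- function(day, trial_index, kind = c("HIDDEN", "PROBE", "VISIBLE"),
                      track, escape_latency_s = NA_real_,
                      platform_center = c(30, 30),
                      platform_half_width = 7, pool_radius = 61) {
  kind <- match.arg(kind)
  if (!is.na(escape_latency_s) && escape_latency_s > 60)
    stop("mwm_trial: escape latency exceeds the 60 s trial cap")
  structure(list(day = day, trial_index = trial_index, kind = kind,
                 track = track, escape_latency_s = escape_latency_s,
                 platform_center = platform_center,
                 platform_half_width = platform_half_width,
                 pool_radius = pool_radius),
            class = "mwm_trial")
}

#' Active place avoidance trial
#'
#' Arena-frame trial record. The 40 cm arena rotates at 1 rpm (6 deg/s);
#' the shock zone is a 60 degree sector fixed in the room frame.
#'
#' @param day training day
#' @param kind `"HABITUATION"`, `"TRAIN"` or `"PROBE_REINSTATE"`
#' @param track data.frame `t_s`, `x_cm`, `y_cm` at 30 Hz in the rotating
#'   arena frame, centered on the arena
#' @param arena_radius arena radius (cm), default 20
#' @param rotation_deg_s arena rotation rate (deg/s), default 6
#' @param zone_center_deg shock-zone center angle in the room frame (deg)
#' @param zone_width_deg shock-zone angular width (deg), default 60
#' @param duration_s trial duration (s), default 600
#' @return object of class `apa_trial`
#' @export
apa_trial <- function(day, kind = c("TRAIN", "HABITUATION", "PROBE_REINSTATE"),
                      track, arena_radius = 20, rotation_deg_s = 6,
                      zone_center_deg = 0, zone_width_deg = 60,
                      duration_s = 600) {
  kind <- match.arg(kind)
  structure(list(day = day, kind = kind, track = track,
                 arena_radius = arena_radius, rotation_deg_s = rotation_deg_s,
                 zone_center_deg = zone_center_deg,
                 zone_width_deg = zone_width_deg, duration_s = duration_s),
            class = "apa_trial")
}

# ---- MWM metrics ----------------------------------------------------------

#' Mean daily escape latency
#'
#' Escape latency averaged across a day's hidden trials (nominally 4) to
#' give one value per day.
#'
#' @param trials list of [mwm_trial()]
#' @param day day to average
#' @return mean latency (s)
#' @export
mwm_daily_latency <- function(trials, day) {
  lat <- vapply(trials, function(tr)
    if (tr$kind == "HIDDEN" && tr$day == day) tr$escape_latency_s else NA_real_,
    numeric(1))
  lat <- lat[!is.na(lat)]
  if (!length(lat)) stop(sprintf("mwm_daily_latency: no hidden trials on day %d", day))
  if (length(lat) == 1)
    warning(sprintf("mwm_daily_latency: only one hidden trial on day %d", day))
  mean(lat)
}

#' Escape-latency slope across days
#'
#' Least-squares slope of the first-degree polynomial fit to the average
#' daily escape latencies over the inclusive day range.
#'
#' @param daily data.frame with columns `day`, `latency_s`
#' @param day_range inclusive `c(first, last)` day range
#' @return slope (s/day)
#' @export
latency_slope <- function(daily, day_range) {
  d <- daily[daily$day >= day_range[1] & daily$day <= day_range[2], ]
  if (nrow(d) < 2) stop("latency_slope: need at least 2 days in range")
  unname(stats::coef(stats::lm(latency_s ~ day, data = d))[2])
}

#' Overnight change in escape latency
#'
#' Latency of the first trial of day d+1 minus latency of the last trial of
#' day d; negative values indicate overnight improvement (consolidation
#' across the ~19 h rest).
#'
#' @param trials list of [mwm_trial()]
#' @param day_pair `c(d, d + 1)`
#' @return change (s)
#' @export
overnight_change <- function(trials, day_pair) {
  hid <- Filter(function(tr) tr$kind == "HIDDEN", trials)
  on_day <- function(d) Filter(function(tr) tr$day == d, hid)
  a <- on_day(day_pair[1]); b <- on_day(day_pair[2])
  if (!length(a) || !length(b))
    stop("overnight_change: missing trials for requested day pair")
  last_a <- a[[which.max(vapply(a, `[[`, numeric(1), "trial_index"))]]
  first_b <- b[[which.min(vapply(b, `[[`, numeric(1), "trial_index"))]]
  first_b$escape_latency_s - last_a$escape_latency_s
}

# pool quadrant index 0..3 by half-open angular convention [0,90), [90,180)...
.pool_quadrant <- function(x, y) {
  ang <- (atan2(y, x) * 180 / pi) %% 360
  floor(ang / 90) %% 4
}

#' Percent probe time in the target quadrant
#'
#' Fraction of tracked frames in the pool quadrant containing the previous
#' platform location, with quadrants delimited by half-open 90 degree
#' angular sectors in the pool frame.
#'
#' @param trial a probe [mwm_trial()]
#' @return percent of frames (0-100)
#' @export
probe_quadrant_time <- function(trial) {
  tr <- trial$track
  if (!nrow(tr)) stop("probe_quadrant_time: empty track")
  target_q <- .pool_quadrant(trial$platform_center[1], trial$platform_center[2])
  100 * mean(.pool_quadrant(tr$x_cm, tr$y_cm) == target_q)
}

#' Number of target (previous platform) crossings
#'
#' Entries of the tracked point into the platform square: any inside frame
#' following an outside frame counts one crossing of the 14 x 14 cm
#' axis-aligned square; starting inside is not a crossing.
#'
#' @param trial a probe [mwm_trial()]
#' @return integer count
#' @export
probe_target_crossings <- function(trial) {
  tr <- trial$track
  hw <- trial$platform_half_width
  inside <- abs(tr$x_cm - trial$platform_center[1]) <= hw &
            abs(tr$y_cm - trial$platform_center[2]) <= hw
  if (length(inside) < 2) return(0L)
  sum(inside[-1] & !inside[-length(inside)])
}

#' Area under the distance-to-platform curve
#'
#' Trapezoid integral of the distance from the tracked point to the
#' previous platform center over the first `horizon_s` seconds of the
#' probe, a measure of initial-approach efficiency.
#'
#' @param trial a probe [mwm_trial()]
#' @param horizon_s integration horizon (s), default 5
#' @return area (cm*s)
#' @export
probe_distance_auc <- function(trial, horizon_s = 5) {
  tr <- trial$track
  t <- tr$t_s - tr$t_s[1]
  if (max(t) < horizon_s) stop("probe_distance_auc: track shorter than horizon")
  keep <- t <= horizon_s + 1e-9
  d <- sqrt((tr$x_cm - trial$platform_center[1])^2 +
            (tr$y_cm - trial$platform_center[2])^2)[keep]
  tt <- t[keep]
  sum(diff(tt) * (d[-1] + d[-length(d)]) / 2)
}

# ---- APA metrics ----------------------------------------------------------

#' Convert an arena-frame track to room-frame polar coordinates
#'
#' The arena rotates at `rotation_deg_s`, so a point fixed on the arena
#' sweeps through the room at that rate:
#' `angle_room = angle_arena + rotation_deg_s * t (mod 360)`.
#'
#' @param trial an [apa_trial()]
#' @return data.frame `t_s`, `angle_room_deg` (0-360), `radius_cm`
#' @export
apa_room_frame <- function(trial) {
  tr <- trial$track
  ang_arena <- atan2(tr$y_cm, tr$x_cm) * 180 / pi
  data.frame(t_s = tr$t_s,
             angle_room_deg = (ang_arena + trial$rotation_deg_s * tr$t_s) %% 360,
             radius_cm = sqrt(tr$x_cm^2 + tr$y_cm^2))
}

# signed angular difference in (-180, 180]
.ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

# logical: inside the room-frame shock zone
.in_zone <- function(angle_room_deg, trial) {
  abs(.ang_diff(angle_room_deg, trial$zone_center_deg)) <= trial$zone_width_deg / 2
}

# entrance events (frame indices) with hysteresis: a new entrance requires
# >= hysteresis_s continuously outside the zone since the last exit
.apa_entry_frames <- function(trial, hysteresis_s = 0.5) {
  rf <- apa_room_frame(trial)
  inside <- .in_zone(rf$angle_room_deg, trial)
  t <- rf$t_s
  entries <- integer(0)
  # starting inside the zone is not an entrance: the counter arms only
  # after the animal has first been outside
  armed <- length(inside) > 0 && !inside[1]
  outside_since <- if (length(t)) t[1] else 0
  prev_inside <- FALSE
  for (i in seq_along(inside)) {
    if (inside[i]) {
      if (!prev_inside && armed) entries <- c(entries, i)
      armed <- FALSE
      prev_inside <- TRUE
    } else {
      if (prev_inside) outside_since <- t[i]
      if (!armed && t[i] - outside_since >= hysteresis_s) armed <- TRUE
      prev_inside <- FALSE
    }
  }
  list(entries = entries, rf = rf, inside = inside)
}

#' Number of entrances into the shock zone
#'
#' Outside-to-inside transitions of the room-frame 60 degree sector, with a
#' 0.5 s hysteresis so boundary jitter at the camera frame rate is not
#' double counted.
#'
#' @param trial an [apa_trial()]
#' @param hysteresis_s minimum continuous time outside before a new
#'   entrance counts (s), default 0.5
#' @return integer count
#' @export
apa_entrances <- function(trial, hysteresis_s = 0.5) {
  length(.apa_entry_frames(trial, hysteresis_s)$entries)
}

#' Latency to first shock-zone entrance
#'
#' @param trial an [apa_trial()]
#' @return time of first entrance (s); `duration_s` if the zone is never
#'   entered
#' @export
apa_latency_first_entrance <- function(trial) {
  ef <- .apa_entry_frames(trial)
  if (length(ef$inside) && ef$inside[1]) return(0)   # starts in the zone
  if (!length(ef$entries)) return(trial$duration_s)
  ef$rf$t_s[ef$entries[1]] - ef$rf$t_s[1]
}

#' Path length in the arena frame
#'
#' Sum of frame-to-frame Euclidean distances in the rotating (arena) frame,
#' so a mouse riding the arena passively accrues zero path length.
#'
#' @param trial an [apa_trial()]
#' @return path length (cm)
#' @export
apa_path_length <- function(trial) {
  tr <- trial$track
  if (nrow(tr) < 2) stop("apa_path_length: need at least 2 frames")
  sum(sqrt(diff(tr$x_cm)^2 + diff(tr$y_cm)^2))
}

#' Percent time in the quadrant opposite the shock zone
#'
#' Fraction of frames inside the 90 degree room-frame sector centered 180
#' degrees from the shock-zone center.
#'
#' @param trial an [apa_trial()]
#' @return percent of frames (0-100)
#' @export
apa_opposite_quadrant_time <- function(trial) {
  rf <- apa_room_frame(trial)
  opp <- (trial$zone_center_deg + 180) %% 360
  100 * mean(abs(.ang_diff(rf$angle_room_deg, opp)) <= 45)
}

#' Mean distance traveled relative to the shock zone per movement bout
#'
#' Movement bouts are runs of arena-frame speed above `speed_cm_s`
#' sustained at least `min_on_s`, separated by at least `min_off_s` below
#' threshold. For each bout the net change in angular arc distance from
#' the nearest zone boundary (positive outside the zone, negative inside)
#' is converted to cm at the animal's mean radius; positive values mean
#' the bout ended farther from the zone than it began. Returns the mean
#' over bouts, or `NA` if there are none.
#'
#' @param trial an [apa_trial()]
#' @param speed_cm_s bout speed threshold (cm/s), default 2
#' @param min_on_s minimum bout duration (s), default 0.5
#' @param min_off_s minimum inter-bout gap (s), default 1
#' @param cumulative logical; if `TRUE`, sum signed frame-to-frame changes
#'   instead of the net start-to-end change
#' @return mean per-bout distance (cm), or `NA_real_`
#' @export
apa_bout_distance <- function(trial, speed_cm_s = 2, min_on_s = 0.5,
                              min_off_s = 1, cumulative = FALSE) {
  tr <- trial$track
  rf <- apa_room_frame(trial)
  t <- tr$t_s
  dt <- stats::median(diff(t))
  v <- c(0, sqrt(diff(tr$x_cm)^2 + diff(tr$y_cm)^2) / diff(t))
  fast <- v > speed_cm_s
  runs <- .bool_runs(fast)
  if (nrow(runs)) {
    # merge fast runs separated by less than min_off_s
    if (nrow(runs) > 1) {
      keep <- list(); cur <- runs[1, ]
      for (i in 2:nrow(runs)) {
        if ((runs[i, "first"] - cur["last"] - 1) * dt < min_off_s) {
          cur["last"] <- runs[i, "last"]
        } else { keep[[length(keep) + 1]] <- cur; cur <- runs[i, ] }
      }
      keep[[length(keep) + 1]] <- cur
      runs <- do.call(rbind, keep)
    }
    dur <- (runs[, "last"] - runs[, "first"] + 1) * dt
    runs <- runs[dur >= min_on_s, , drop = FALSE]
  }
  if (!nrow(runs)) return(NA_real_)
  # signed angular distance (deg) from the nearest zone boundary
  half <- trial$zone_width_deg / 2
  dist_deg <- abs(.ang_diff(rf$angle_room_deg, trial$zone_center_deg)) - half
  per_bout <- vapply(seq_len(nrow(runs)), function(i) {
    a <- runs[i, "first"]; b <- runs[i, "last"]
    r_mean <- mean(rf$radius_cm[a:b])
    if (cumulative) {
      sum(diff(dist_deg[a:b])) * pi / 180 * r_mean
    } else {
      (dist_deg[b] - dist_deg[a]) * pi / 180 * r_mean
    }
  }, numeric(1))
  mean(per_bout)
}

#' Pseudoshocks per entrance on the probe trial
#'
#' Simulates the training shock schedule on a shock-off probe: a shock at
#' each entrance, repeated every `period_s` while the animal remains in
#' the zone. Returns total pseudoshocks divided by the number of
#' entrances, or `NA` if the zone is never entered.
#'
#' @param trial an [apa_trial()] (probe)
#' @param period_s shock repetition period while inside (s), default 1.5
#' @return pseudoshocks per entrance, or `NA_real_`
#' @export
apa_pseudoshocks_per_entrance <- function(trial, period_s = 1.5) {
  ef <- .apa_entry_frames(trial)
  if (!length(ef$entries)) return(NA_real_)
  t <- ef$rf$t_s
  dt <- stats::median(diff(t))
  inside <- ef$inside
  total <- 0L
  for (e in ef$entries) {
    # contiguous inside period starting at this entrance
    j <- e
    while (j < length(inside) && inside[j + 1]) j <- j + 1
    dwell <- t[j] - t[e] + dt            # half-open occupancy
    total <- total + (floor((dwell - 1e-9) / period_s) + 1L)
  }
  total / length(ef$entries)
}
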