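# minimal track helpers
.track30 <- function(x, y, dur = NULL) {
  n <- max(length(x), length(y))
  data.frame(t_s = (seq_len(n) - 1) / 30, x_cm = rep_len(x, n), y_cm = rep_len(y, n))
}

test_that("daily escape latency averages the day's hidden trials", {
  mk <- function(day, idx, lat) mwm_trial(day, idx, "HIDDEN",
                                          .track30(0, 0), lat)
  trials <- list(mk(1, 1, 60), mk(1, 2, 40), mk(1, 3, 20), mk(1, 4, 40),
                 mk(2, 1, 60))
  expect_equal(mwm_daily_latency(trials, 1), 40)
  expect_warning(l2 <- mwm_daily_latency(trials, 2), "one")
  expect_equal(l2, 60)
  expect_error(mwm_daily_latency(trials, 3), "no hidden")
  expect_equal(mwm_daily_latency(list(mk(1, 1, 60), mk(1, 2, 60)), 1), 60)
})

test_that("latency slope is the least-squares fit over the day range", {
  d <- data.frame(day = 1:3, latency_s = c(40, 30, 20))
  expect_equal(latency_slope(d, c(1, 3)), -10)
  expect_equal(latency_slope(d, c(1, 2)), -10)
  expect_equal(latency_slope(data.frame(day = 1:4, latency_s = 25), c(1, 4)), 0)
  expect_error(latency_slope(d, c(3, 3)), "2 days")
  # non-collinear closed form
  d2 <- data.frame(day = 1:3, latency_s = c(50, 20, 35))
  expect_equal(latency_slope(d2, c(1, 3)),
               cov(d2$day, d2$latency_s) / var(d2$day))
})

test_that("overnight change is next-day-first minus prior-day-last latency", {
  mk <- function(day, idx, lat) mwm_trial(day, idx, "HIDDEN", .track30(0, 0), lat)
  trials <- list(mk(1, 1, 55), mk(1, 4, 50), mk(2, 1, 30), mk(2, 4, 25))
  expect_equal(overnight_change(trials, c(1, 2)), -20)
  trials2 <- list(mk(1, 4, 20), mk(2, 1, 60))
  expect_equal(overnight_change(trials2, c(1, 2)), 40)
  expect_equal(overnight_change(list(mk(1, 4, 30), mk(2, 1, 30)), c(1, 2)), 0)
  expect_error(overnight_change(trials, c(2, 3)), "missing")
})

test_that("probe quadrant time follows the half-open angular convention", {
  # entirely inside the target quadrant (platform at 45 degrees)
  inq <- mwm_trial(6, 1, "PROBE", .track30(rep(20, 90), rep(25, 90)),
                   platform_center = c(30, 30))
  expect_equal(probe_quadrant_time(inq), 100)

  # uniform circular sweep: exactly one quarter of frames per quadrant
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  sweep <- mwm_trial(6, 1, "PROBE",
                     .track30(40 * cos(th), 40 * sin(th)),
                     platform_center = c(30, 30))
  expect_equal(probe_quadrant_time(sweep), 25, tolerance = 2)

  # boundary frames are assigned to exactly one quadrant
  onb <- mwm_trial(6, 1, "PROBE", .track30(c(10, 0, -10, 0), c(0, 10, 0, -10)),
                   platform_center = c(30, 30))
  qsum <- sum(sapply(list(c(30, 30), c(-30, 30), c(-30, -30), c(30, -30)),
                     function(pc) {
                       tr <- onb; tr$platform_center <- pc
                       probe_quadrant_time(tr)
                     }))
  expect_equal(qsum, 100)
  expect_error(probe_quadrant_time(
    mwm_trial(6, 1, "PROBE", .track30(numeric(0), numeric(0)),
              platform_center = c(30, 30))), "empty")
})

test_that("quadrant times of any track sum to 100 percent", {
  set.seed(14)
  for (rep in 1:20) {
    w <- matrix(rnorm(200, 0, 20), ncol = 2)
    tot <- sum(sapply(list(c(30, 30), c(-30, 30), c(-30, -30), c(30, -30)),
                      function(pc) probe_quadrant_time(
                        mwm_trial(6, 1, "PROBE", .track30(w[, 1], w[, 2]),
                                  platform_center = pc))))
    expect_equal(tot, 100, tolerance = 1e-9)
  }
})

test_that("target crossings count outside-to-inside entries of the platform square", {
  pc <- c(30, 30)
  # crosses the square twice
  x <- c(0, 30, 50, 30, 0); y <- c(0, 30, 50, 30, 0)
  tr <- mwm_trial(6, 1, "PROBE", .track30(x, y), platform_center = pc)
  expect_equal(probe_target_crossings(tr), 2)
  # never inside
  far <- mwm_trial(6, 1, "PROBE", .track30(c(0, -40), c(0, -40)), platform_center = pc)
  expect_equal(probe_target_crossings(far), 0)
  # grazing a corner frame counts once
  graze <- mwm_trial(6, 1, "PROBE", .track30(c(0, 24, 0), c(0, 24, 0)),
                     platform_center = pc)
  expect_equal(probe_target_crossings(graze), 1)
})

test_that("probe distance AUC matches closed-form trapezoids", {
  pc <- c(0, 0)
  n <- 151
  t <- (seq_len(n) - 1) / 30
  # constant 30 cm distance over 5 s -> 150 cm s
  const <- mwm_trial(6, 1, "PROBE", data.frame(t_s = t, x_cm = 30, y_cm = 0),
                     platform_center = pc)
  expect_equal(probe_distance_auc(const), 150, tolerance = 1e-9)
  # linear 30 -> 0 over 5 s -> 75 cm s
  lin <- mwm_trial(6, 1, "PROBE",
                   data.frame(t_s = t, x_cm = 30 * (1 - t / 5), y_cm = 0),
                   platform_center = pc)
  expect_equal(probe_distance_auc(lin), 75, tolerance = 1e-6)
  # smooth analytic curve sampled at 30 Hz matches its integral within 1%
  curve <- mwm_trial(6, 1, "PROBE",
                     data.frame(t_s = t, x_cm = 20 + 10 * cos(t), y_cm = 0),
                     platform_center = pc)
  expect_equal(probe_distance_auc(curve), 100 + 10 * sin(5),
               tolerance = 0.01 * (100 + 10 * sin(5)))
  shorty <- mwm_trial(6, 1, "PROBE", data.frame(t_s = t[1:60], x_cm = 30, y_cm = 0),
                      platform_center = pc)
  expect_error(probe_distance_auc(shorty), "horizon")
})

test_that("room-frame conversion adds the rotation and preserves radius", {
  tr <- apa_trial(1, "TRAIN", data.frame(t_s = c(0, 10, 60), x_cm = 15, y_cm = 0))
  rf <- apa_room_frame(tr)
  expect_equal(rf$angle_room_deg, c(0, 60, 0), tolerance = 1e-9)
  expect_equal(rf$radius_cm, rep(15, 3))
  tr0 <- apa_trial(1, "TRAIN", data.frame(t_s = c(0, 10), x_cm = 0, y_cm = 12),
                   rotation_deg_s = 0)
  expect_equal(apa_room_frame(tr0)$angle_room_deg, c(90, 90))
})

test_that("a mouse stationary in the arena frame sweeps the zone once per rotation", {
  n <- 600 * 30
  tr <- apa_trial(1, "TRAIN",
                  data.frame(t_s = (seq_len(n) - 1) / 30, x_cm = 15, y_cm = 0),
                  zone_center_deg = 0)
  expect_equal(apa_entrances(tr), 10)
  # starts at zone center: inside at t = 0
  expect_equal(apa_latency_first_entrance(tr), 0)
  expect_equal(apa_path_length(tr), 0, tolerance = 1e-9)

  # tracking the rotation while opposite the zone: never enters
  t <- (seq_len(n) - 1) / 30
  th <- (180 - 6 * t) * pi / 180
  opp <- apa_trial(1, "TRAIN",
                   data.frame(t_s = t, x_cm = 15 * cos(th), y_cm = 15 * sin(th)),
                   zone_center_deg = 0)
  expect_equal(apa_entrances(opp), 0)
  expect_equal(apa_latency_first_entrance(opp), 600)
  expect_equal(apa_opposite_quadrant_time(opp), 100)
})

test_that("boundary jitter is counted once per hysteresis period", {
  # oscillate across the zone edge at 30 Hz for 2 s, then leave for good
  t <- (0:119) / 30
  th_room <- ifelse(seq_along(t) %% 2 == 0, 29, 31)   # zone edge at 30 deg
  th_arena <- (th_room - 6 * t) * pi / 180
  jig <- apa_trial(1, "TRAIN",
                   data.frame(t_s = t, x_cm = 15 * cos(th_arena),
                              y_cm = 15 * sin(th_arena)),
                   zone_center_deg = 0, duration_s = 4)
  expect_equal(apa_entrances(jig), 1)
})

test_that("path length is computed in the rotating arena frame", {
  tr <- apa_trial(1, "TRAIN",
                  data.frame(t_s = c(0, 1), x_cm = c(0, 3), y_cm = c(0, 0)))
  expect_equal(apa_path_length(tr), 3)
  n <- 101
  walk <- apa_trial(1, "TRAIN",
                    data.frame(t_s = (seq_len(n) - 1) / 30,
                               x_cm = seq(-10, 10, length.out = n) / 2,
                               y_cm = seq(0, 10, length.out = n)))
  expect_equal(apa_path_length(walk), 10 * sqrt(2), tolerance = 1e-9)
  expect_error(apa_path_length(apa_trial(1, "TRAIN",
                                         data.frame(t_s = 0, x_cm = 0, y_cm = 0))),
               "2 frames")
})

test_that("opposite-quadrant time uses the 90 degree antipodal sector", {
  n <- 300
  t <- (seq_len(n) - 1) / 30
  th <- (180 - 6 * t) * pi / 180                  # holds room angle 180
  anti <- apa_trial(1, "TRAIN",
                    data.frame(t_s = t, x_cm = 15 * cos(th), y_cm = 15 * sin(th)),
                    zone_center_deg = 0)
  expect_equal(apa_opposite_quadrant_time(anti), 100)
  inz <- apa_trial(1, "TRAIN",
                   data.frame(t_s = t, x_cm = 15 * cos(-6 * t * pi / 180),
                              y_cm = 15 * sin(-6 * t * pi / 180)),
                   zone_center_deg = 0)
  expect_equal(apa_opposite_quadrant_time(inz), 0)
  # uniform angular sweep: 25%
  th2 <- seq(0, 2 * pi, length.out = 721)[-721]
  sweep <- apa_trial(1, "TRAIN",
                     .track30(15 * cos(th2), 15 * sin(th2)), rotation_deg_s = 0)
  expect_equal(apa_opposite_quadrant_time(sweep), 25, tolerance = 2)
})

test_that("per-bout distance is the net arc change from the zone boundary", {
  # one bout: radius 15, room angle from the 30 deg boundary to the antipode
  pre <- 45                                        # 1.5 s stationary lead-in
  move <- 150                                      # 5 s of motion
  post <- 45
  t <- (seq_len(pre + move + post) - 1) / 30
  th_room <- c(rep(30, pre), seq(30, 180, length.out = move), rep(180, post))
  # hold room angle during padding (counter-rotate the arena track)
  th_arena <- (th_room - 6 * t) * pi / 180
  tr <- apa_trial(1, "TRAIN",
                  data.frame(t_s = t, x_cm = 15 * cos(th_arena),
                             y_cm = 15 * sin(th_arena)),
                  zone_center_deg = 0)
  d <- apa_bout_distance(tr)
  expect_equal(d, pi * 15 * 150 / 180, tolerance = 1.5)

  # no movement at all -> missing sentinel
  still <- apa_trial(1, "TRAIN", .track30(rep(15, 200), rep(0, 200)))
  expect_true(is.na(apa_bout_distance(still)))

  # bout returning to its start nets zero
  th_rt <- c(rep(90, pre), seq(90, 150, length.out = 75),
             seq(150, 90, length.out = 75), rep(90, post))
  t2 <- (seq_along(th_rt) - 1) / 30
  th_a2 <- (th_rt - 6 * t2) * pi / 180
  rt <- apa_trial(1, "TRAIN",
                  data.frame(t_s = t2, x_cm = 15 * cos(th_a2),
                             y_cm = 15 * sin(th_a2)),
                  zone_center_deg = 0)
  expect_equal(apa_bout_distance(rt), 0, tolerance = 1.5)
})

test_that("pseudoshock schedule delivers one shock per 1.5 s inside", {
  mk_dwell <- function(dwell_s) {
    # outside 2 s, inside dwell_s, outside 2 s; hold room angle via
    # counter-rotated arena coordinates
    nin <- round(dwell_s * 30)
    th_room <- c(rep(90, 60), rep(0, nin), rep(90, 60))
    t <- (seq_along(th_room) - 1) / 30
    th_a <- (th_room - 6 * t) * pi / 180
    apa_trial(5, "PROBE_REINSTATE",
              data.frame(t_s = t, x_cm = 15 * cos(th_a), y_cm = 15 * sin(th_a)),
              zone_center_deg = 0)
  }
  expect_equal(apa_pseudoshocks_per_entrance(mk_dwell(4)), 3)
  expect_equal(apa_pseudoshocks_per_entrance(mk_dwell(1)), 1)
  t <- (0:99) / 30
  th_a <- (180 - 6 * t) * pi / 180                # holds the antipodal angle
  never <- apa_trial(5, "PROBE_REINSTATE",
                     data.frame(t_s = t, x_cm = 15 * cos(th_a),
                                y_cm = 15 * sin(th_a)),
                     zone_center_deg = 0)
  expect_true(is.na(apa_pseudoshocks_per_entrance(never)))
})

test_that("MWM metrics are invariant to rigid rotation of the pool frame", {
  set.seed(15)
  w <- matrix(rnorm(600, 0, 25), ncol = 2)
  pc <- c(30, 30)
  rot <- function(m, a) m %*% matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
  tr1 <- mwm_trial(6, 1, "PROBE", .track30(w[, 1], w[, 2]), platform_center = pc)
  a <- pi / 2                     # quadrant-preserving rotation
  w2 <- rot(w, a); pc2 <- as.vector(rot(matrix(pc, 1), a))
  tr2 <- mwm_trial(6, 1, "PROBE", .track30(w2[, 1], w2[, 2]), platform_center = pc2)
  expect_equal(probe_quadrant_time(tr1), probe_quadrant_time(tr2), tolerance = 1e-9)
  expect_equal(probe_distance_auc(tr1), probe_distance_auc(tr2), tolerance = 1e-9)
})

test_that("APA entrances agree with a brute-force frame scan on random walks", {
  set.seed(16)
  for (rep in 1:50) {
    n <- 900
    t <- (seq_len(n) - 1) / 30
    x <- cumsum(rnorm(n, 0, 1)); y <- cumsum(rnorm(n, 0, 1))
    r <- pmin(sqrt(x^2 + y^2), 19); th <- atan2(y, x)
    tr <- apa_trial(1, "TRAIN",
                    data.frame(t_s = t, x_cm = r * cos(th), y_cm = r * sin(th)),
                    zone_center_deg = 0)
    # brute-force: frame scan with explicit hysteresis clock
    rf <- apa_room_frame(tr)
    d <- (rf$angle_room_deg - 0) %% 360
    inside <- pmin(d, 360 - d) <= 30
    cnt <- 0; out_t <- -Inf; arm <- !inside[1]; prev <- FALSE
    for (i in seq_len(n)) {
      if (inside[i]) {
        if (!prev && arm) cnt <- cnt + 1
        arm <- FALSE; prev <- TRUE
      } else {
        if (prev) out_t <- t[i]
        if (!arm && t[i] - out_t >= 0.5) arm <- TRUE
        prev <- FALSE
      }
    }
    expect_equal(apa_entrances(tr), cnt)
  }
})
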