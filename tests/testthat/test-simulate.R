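test_that("static profiles give a constant quaternion and zero angular
           velocity", {
  q <- euler_to_quat(0.2, 0.3, -0.4)
  prof <- activity_profile("static", base_orientation = q)
  tr <- make_orientation_trajectory(prof, 3, 50)
  expect_equal(nrow(tr$q), 150)
  expect_true(all(apply(tr$q, 1, function(r) quat_angle(r, q)) < 1e-12))
  expect_true(all(tr$omega == 0))
})

test_that("pure yaw oscillation has the analytic angular-velocity derivative", {
  a <- 0.4; f <- 1.25; rate <- 50
  prof <- activity_profile("yawosc", osc_amp = c(0, 0, a),
                           osc_freq = c(0, 0, f))
  tr <- make_orientation_trajectory(prof, 4, rate)
  expect_equal(tr$omega[, 3], a * 2 * pi * f * cos(2 * pi * f * tr$time),
               tolerance = 1e-12)
  expect_true(all(tr$omega[, 1:2] == 0))
})

test_that("returned angular velocity matches a central-difference derivative
           of the returned quaternion path", {
  prof <- activity_profile("dyn", osc_amp = c(0.3, 0.2, 0.25),
                           osc_freq = c(1.1, 0.7, 0.4),
                           phase = c(0.3, 1.2, -0.5))
  rate <- 50
  tr <- make_orientation_trajectory(prof, 5, rate)
  n <- nrow(tr$q)
  # truncation bound of the central difference: max_axis A (2 pi f)^3 / 6
  # times dt^2, with headroom for the cross-axis coupling terms
  bound <- 3 * max(prof$osc_amp * (2 * pi * prof$osc_freq)^3 / 6) / rate^2
  worst <- 0
  for (i in seq(2, n - 1, by = 7)) {
    qd <- (tr$q[i + 1, ] - tr$q[i - 1, ]) * rate / 2
    w_num <- 2 * quat_multiply(quat_conjugate(tr$q[i, ]), qd)[2:4]
    worst <- max(worst, max(abs(w_num - tr$omega[i, ])))
  }
  expect_lt(worst, bound)
  # and the bound shrinks quadratically with the rate
  tr2 <- make_orientation_trajectory(prof, 5, 4 * rate)
  worst2 <- 0
  for (i in seq(2, nrow(tr2$q) - 1, by = 29)) {
    qd <- (tr2$q[i + 1, ] - tr2$q[i - 1, ]) * 4 * rate / 2
    w_num <- 2 * quat_multiply(quat_conjugate(tr2$q[i, ]), qd)[2:4]
    worst2 <- max(worst2, max(abs(w_num - tr2$omega[i, ])))
  }
  expect_lt(worst2, bound / 8)
})

test_that("non-unit base orientation is rejected", {
  expect_error(activity_profile("bad", base_orientation = c(1, 1, 0, 0)),
               "unit quaternion")
})

test_that("synthesized sensors reproduce the measurement model in the
           noise-free static case", {
  fl <- reference_fields()
  tr <- make_orientation_trajectory(activity_profile("s"), 2, 50)
  imu <- synthesize_imu(tr, fl, sensor_noise_model(0, 0, 0, 0))
  expect_true(all(abs(imu$acc_x) < 1e-12 & abs(imu$acc_y) < 1e-12))
  expect_true(all(abs(imu$acc_z - 9.81) < 1e-12))
  expect_true(all(abs(imu$mag_x - fl$mag_n[1]) < 1e-12))
  expect_true(all(abs(imu$mag_z - fl$mag_n[3]) < 1e-12))
})

test_that("gyroscope output is the true rate plus the configured bias", {
  a <- 0.3; f <- 0.8
  prof <- activity_profile("yawosc", osc_amp = c(0, 0, a),
                           osc_freq = c(0, 0, f))
  tr <- make_orientation_trajectory(prof, 2, 50)
  bias <- c(0.01, -0.02, 0.03)
  imu <- synthesize_imu(tr, noise = sensor_noise_model(0, 0, 0, bias))
  expect_equal(imu$gyr_x, tr$omega[, 1] + bias[1], tolerance = 1e-12)
  expect_equal(imu$gyr_z, tr$omega[, 3] + bias[3], tolerance = 1e-12)
})

test_that("empirical noise standard deviation matches the configured model", {
  tr <- make_orientation_trajectory(activity_profile("s"), 200, 50)
  clean <- synthesize_imu(tr, noise = sensor_noise_model(0, 0, 0, 0))
  noisy <- synthesize_imu(tr, noise = sensor_noise_model(0.08, 0.004, 0.012, 0),
                          seed = 99)
  for (col in c("acc_x", "acc_y", "acc_z"))
    expect_equal(sd(noisy[[col]] - clean[[col]]), 0.08, tolerance = 0.05)
  expect_equal(sd(noisy$gyr_y - clean$gyr_y), 0.004, tolerance = 0.05)
  expect_equal(sd(noisy$mag_z - clean$mag_z), 0.012, tolerance = 0.05)
})

test_that("noise-free samples conserve the reference field magnitudes", {
  q <- euler_to_quat(0.7, 0.5, -1.0)
  tr <- make_orientation_trajectory(
    activity_profile("s", base_orientation = q), 2, 50)
  fl <- reference_fields()
  imu <- synthesize_imu(tr, fl, sensor_noise_model(0, 0, 0, 0))
  an <- sqrt(imu$acc_x^2 + imu$acc_y^2 + imu$acc_z^2)
  mn <- sqrt(imu$mag_x^2 + imu$mag_y^2 + imu$mag_z^2)
  expect_true(all(abs(an - 9.81) < 1e-9))
  expect_true(all(abs(mn - 1) < 1e-9))
})

test_that("protocol 1 sitting segments contribute one minute of sitting
           samples each at 50 Hz", {
  script <- har_protocol(1, loops = 1)
  recs <- generate_protocol_dataset(script, subjects = 1, seed = 5)
  r <- recs[[1]]
  expect_equal(sum(r$label == "sitting"), 3000)     # one 60 s segment
  expect_equal(nrow(r), sum(round(script$duration * 50)))
  expect_true(all(diff(r$time) - 1 / 50 < 1e-12))
})

test_that("identical seeds reproduce recordings exactly and different seeds
           do not", {
  script <- har_protocol(3, loops = 1, time_scale = 0.2)
  a <- generate_protocol_dataset(script, subjects = 2, seed = 7)
  b <- generate_protocol_dataset(script, subjects = 2, seed = 7)
  d <- generate_protocol_dataset(script, subjects = 2, seed = 8)
  expect_identical(a, b)
  expect_false(identical(a[[1]]$acc_x, d[[1]]$acc_x))
  # subjects differ from each other under per-subject jitter
  expect_false(identical(a[[1]]$acc_x, a[[2]]$acc_x))
})

test_that("protocol 3 alternates stair classes the scripted number of times", {
  loops <- 5
  script <- har_protocol(3, loops = loops, time_scale = 0.2)
  rec <- generate_protocol_dataset(script, subjects = 1, seed = 3)[[1]]
  runs <- rle(as.character(rec$label))$values
  expect_equal(sum(runs == "upstairs"), loops)
  expect_equal(sum(runs == "downstairs"), loops)
  stair_runs <- runs[runs %in% c("upstairs", "downstairs")]
  expect_equal(stair_runs, rep(c("upstairs", "downstairs"), loops))
  # between every pair of stair segments there is a marker segment
  expect_true(all(runs[which(runs == "upstairs") + 1] %in%
                    c("turn+wait", "turn", "wait")))
})

test_that("marker stripping removes exactly the flagged samples and leaves
           only target classes", {
  rec <- generate_protocol_dataset(har_protocol(1, loops = 1,
                                                time_scale = 0.1),
                                   subjects = 1, seed = 2)[[1]]
  n_marker <- sum(rec$marker)
  expect_gt(n_marker, 0)
  out <- strip_marker_segments(rec)
  expect_equal(nrow(out), nrow(rec) - n_marker)
  expect_false(any(out$label %in% c("jumping jacks", "wait")))
  expect_true(all(out$label %in% c("standing", "sitting", "laying", "leaning",
                                   "walking", "downstairs", "upstairs")))
  # a marker-free recording passes through unchanged
  again <- strip_marker_segments(out)
  expect_equal(nrow(again), nrow(out))
  expect_equal(again$acc_x, out$acc_x)
})

test_that("ground-truth gyro stream of a protocol recording integrates back
           to the truth quaternions (kinematic consistency)", {
  # full-scale segment durations: scaled-down scripts compress the marker
  # transitions and raise the integration error of the blend spikes
  rec <- generate_protocol_dataset(har_protocol(3, loops = 1),
                                   subjects = 1,
                                   noise = sensor_noise_model(0, 0, 0, 0),
                                   seed = 11)[[1]]
  st <- filter_state(q = c(rec$qw[1], rec$qx[1], rec$qy[1], rec$qz[1]),
                     beta = 0, dt = 1 / 50)
  for (i in 2:nrow(rec))
    st <- gyro_propagate(st, c(rec$gyr_x[i - 1], rec$gyr_y[i - 1],
                               rec$gyr_z[i - 1]))
  qt <- c(rec$qw[nrow(rec)], rec$qx[nrow(rec)], rec$qy[nrow(rec)],
          rec$qz[nrow(rec)])
  expect_lt(quat_angle(st$q, qt) * 180 / pi, 0.5)
})

test_that("stair classes overlap in acceleration norm but separate in pitch", {
  recs <- generate_protocol_dataset(har_protocol(3, loops = 4,
                                                 time_scale = 0.5),
                                    subjects = 3, seed = 21)
  up <- c(); down <- c(); up_p <- c(); down_p <- c()
  for (r in recs) {
    an <- sqrt(r$acc_x^2 + r$acc_y^2 + r$acc_z^2)
    pitch <- vapply(seq_len(nrow(r)), function(i)
      quat_to_euler(c(r$qw[i], r$qx[i], r$qy[i], r$qz[i]))["pitch"], 0)
    up <- c(up, an[r$label == "upstairs"])
    down <- c(down, an[r$label == "downstairs"])
    up_p <- c(up_p, pitch[r$label == "upstairs"])
    down_p <- c(down_p, pitch[r$label == "downstairs"])
  }
  pooled_sd <- sqrt((var(up) + var(down)) / 2)
  expect_lt(abs(mean(up) - mean(down)), 0.1 * pooled_sd)
  expect_gt((mean(up_p) - mean(down_p)) * 180 / pi, 10)
})

test_that("unknown location and missing profiles are rejected", {
  expect_error(generate_protocol_dataset(har_protocol(1, loops = 1),
                                         subjects = 1, location = "XX"),
               "arg")
  script <- har_protocol(2, loops = 1)
  profs <- default_activity_profiles("LB")
  profs$run <- NULL
  expect_error(generate_protocol_dataset(script, subjects = 1,
                                         profiles = profs),
               "no activity profile")
})
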