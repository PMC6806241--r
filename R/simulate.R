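# Synthetic 9-axis IMMU recordings for scripted activity protocols.
#
# The generator emulates what a body-worn inertial/magnetic module records:
# per-subject streams of specific force, angular velocity and magnetic field
# at 50 Hz, with white Gaussian sensor noise and a constant gyroscope bias,
# labeled per sample from a protocol script.  Each activity is modeled as a
# base posture (orientation signature at the worn location) plus sinusoidal
# orientation oscillation and sinusoidal body-frame linear acceleration; the
# ground-truth angular velocity is the exact analytic derivative of the
# orientation path, so the streams are kinematically consistent.

TARGET_CLASSES <- c("standing", "sitting", "laying", "leaning",
                    "walking", "downstairs", "upstairs")

#' Sensor noise model
#'
#' White Gaussian measurement noise (per axis, uncorrelated) plus a constant
#' per-recording gyroscope bias.
#'
#' @param acc_noise_std Accelerometer noise standard deviation, m/s^2.
#' @param gyr_noise_std Gyroscope noise standard deviation, rad/s.
#' @param mag_noise_std Magnetometer noise standard deviation, in normalized
#'   field units.
#' @param gyr_bias Constant gyroscope bias, rad/s; scalar (replicated) or
#'   length-3.
#' @param sample_rate Sampling frequency, Hz.
#' @return Object of class `sensor_noise_model`.
#' @export
sensor_noise_model <- function(acc_noise_std = 0.05, gyr_noise_std = 0.005,
                               mag_noise_std = 0.01, gyr_bias = 0.01,
                               sample_rate = 50) {
  if (length(gyr_bias) == 1L) gyr_bias <- rep(gyr_bias, 3L)
  stopifnot(acc_noise_std >= 0, gyr_noise_std >= 0, mag_noise_std >= 0,
            sample_rate > 0, length(gyr_bias) == 3L)
  structure(list(acc_noise_std = acc_noise_std, gyr_noise_std = gyr_noise_std,
                 mag_noise_std = mag_noise_std, gyr_bias = gyr_bias,
                 sample_rate = sample_rate),
            class = "sensor_noise_model")
}

#' Activity motion profile
#'
#' Parametric signature of one activity at one worn location: a base
#' orientation (unit quaternion), per-axis sinusoidal orientation
#' oscillation (intrinsic roll/pitch/yaw path around the base), and
#' per-axis sinusoidal body-frame linear acceleration.  Static postures have
#' all oscillation frequencies zero.
#'
#' @param name Activity label.
#' @param base_orientation Unit quaternion (body-to-Earth) of the posture.
#' @param osc_amp,osc_freq Orientation oscillation amplitude (rad) and
#'   frequency (Hz) for the roll, pitch, yaw axes.
#' @param lin_amp,lin_freq Body-frame linear acceleration amplitude (m/s^2)
#'   and frequency (Hz) per axis.
#' @param phase,lin_phase Fixed phases (rad) per axis, used when
#'   `random_phase` is `FALSE`.
#' @param random_phase Draw phases uniformly per trajectory (seeded).
#' @param edge_ramp Raised-cosine on/off ramp, seconds, applied to the
#'   oscillation and linear acceleration at both segment ends so that
#'   concatenated segments remain continuous; 0 disables.
#' @param marker `TRUE` for synchronization/transition activities that are
#'   stripped before classification.
#' @return Object of class `activity_profile`.
#' @export
activity_profile <- function(name, base_orientation = c(1, 0, 0, 0),
                             osc_amp = c(0, 0, 0), osc_freq = c(0, 0, 0),
                             lin_amp = c(0, 0, 0), lin_freq = c(0, 0, 0),
                             phase = c(0, 0, 0), lin_phase = c(0, 0, 0),
                             random_phase = FALSE, edge_ramp = 0,
                             marker = FALSE) {
  if (abs(sqrt(sum(base_orientation^2)) - 1) > 1e-9)
    stop("base_orientation must be a unit quaternion")
  stopifnot(length(osc_amp) == 3L, length(osc_freq) == 3L,
            all(osc_freq >= 0), all(lin_freq >= 0), edge_ramp >= 0)
  structure(list(name = name, base_orientation = base_orientation,
                 osc_amp = osc_amp, osc_freq = osc_freq,
                 lin_amp = lin_amp, lin_freq = lin_freq,
                 phase = phase, lin_phase = lin_phase,
                 random_phase = random_phase, edge_ramp = edge_ramp,
                 marker = marker),
            class = "activity_profile")
}

# vectorized Hamilton product of N x 4 quaternion matrices (or one constant)
.qmul_mat <- function(A, B) {
  if (is.null(dim(A))) A <- matrix(A, nrow(B), 4L, byrow = TRUE)
  if (is.null(dim(B))) B <- matrix(B, nrow(A), 4L, byrow = TRUE)
  cbind(A[, 1] * B[, 1] - A[, 2] * B[, 2] - A[, 3] * B[, 3] - A[, 4] * B[, 4],
        A[, 1] * B[, 2] + A[, 2] * B[, 1] + A[, 3] * B[, 4] - A[, 4] * B[, 3],
        A[, 1] * B[, 3] - A[, 2] * B[, 4] + A[, 3] * B[, 1] + A[, 4] * B[, 2],
        A[, 1] * B[, 4] + A[, 2] * B[, 3] - A[, 3] * B[, 2] + A[, 4] * B[, 1])
}

# rows of N x 4 quaternion matrix applied inversely to an Earth vector
# (fixed length-3, or N x 3 with one vector per row):
# out[i, ] = R(q_i)' v_i  (what a body-fixed sensor sees)
.qrot_inv_mat <- function(Q, v) {
  w <- Q[, 1]; x <- Q[, 2]; y <- Q[, 3]; z <- Q[, 4]
  if (is.null(dim(v))) {
    dx <- v[1L]; dy <- v[2L]; dz <- v[3L]
  } else {
    dx <- v[, 1L]; dy <- v[, 2L]; dz <- v[, 3L]
  }
  cbind(dx * (1 - 2 * y^2 - 2 * z^2) + dy * 2 * (x * y + w * z) + dz * 2 * (x * z - w * y),
        dx * 2 * (x * y - w * z) + dy * (1 - 2 * x^2 - 2 * z^2) + dz * 2 * (y * z + w * x),
        dx * 2 * (x * z + w * y) + dy * 2 * (y * z - w * x) + dz * (1 - 2 * x^2 - 2 * y^2))
}

# shortest-arc axis and angle taking quaternion a to quaternion b
.rel_axis_angle <- function(a, b) {
  rel <- quat_canonical(quat_multiply(quat_conjugate(a), b))
  theta <- 2 * acos(min(1, rel[1L]))
  u <- rel[2:4]
  u <- if (sum(u^2) > 0) u / sqrt(sum(u^2)) else c(0, 0, 1)
  list(u = u, theta = theta)
}

# raised-cosine on/off envelope and its time derivative over [0, dur]
.edge_envelope <- function(t, dur, ramp) {
  w <- rep(1, length(t)); wd <- rep(0, length(t))
  if (ramp <= 0) return(list(w = w, wd = wd))
  ramp <- min(ramp, dur / 2)
  i <- t < ramp
  w[i]  <- 0.5 * (1 - cos(pi * t[i] / ramp))
  wd[i] <- 0.5 * pi / ramp * sin(pi * t[i] / ramp)
  j <- t > dur - ramp
  w[j]  <- 0.5 * (1 - cos(pi * (dur - t[j]) / ramp))
  wd[j] <- -0.5 * pi / ramp * sin(pi * (dur - t[j]) / ramp)
  list(w = w, wd = wd)
}

# Core trajectory builder.  `from_base` slerps smoothly from a previous
# posture into this profile's base orientation at the segment start, and
# `to_base` slerps toward the next posture at the segment end, each over
# `blend` seconds; the slerp angular velocity is folded into the returned
# body-frame omega so the stream stays kinematically consistent.  Protocol
# assembly places these blends inside marker segments, keeping
# target-labeled samples free of transitions.
.orientation_trajectory <- function(profile, duration, rate, seed = NULL,
                                    from_base = NULL, to_base = NULL,
                                    blend = 0) {
  n <- max(1L, round(duration * rate))
  t <- (seq_len(n) - 1L) / rate
  dur <- n / rate
  ph <- profile$phase; lph <- profile$lin_phase
  if (isTRUE(profile$random_phase)) {
    if (!is.null(seed)) set.seed(seed)
    ph <- stats::runif(3L, 0, 2 * pi)
    lph <- stats::runif(3L, 0, 2 * pi)
  }
  env <- .edge_envelope(t, dur, profile$edge_ramp)
  A <- profile$osc_amp; f <- profile$osc_freq
  ang <- matrix(0, n, 3L); angd <- matrix(0, n, 3L)
  for (k in 1:3) {
    s <- sin(2 * pi * f[k] * t + ph[k])
    cdot <- A[k] * 2 * pi * f[k] * cos(2 * pi * f[k] * t + ph[k])
    ang[, k]  <- env$w * A[k] * s
    angd[, k] <- env$wd * A[k] * s + env$w * cdot
  }
  r <- ang[, 1]; p <- ang[, 2]; yw <- ang[, 3]
  rd <- angd[, 1]; pd <- angd[, 2]; yd <- angd[, 3]
  # intrinsic ZYX Euler path -> quaternion, columnwise
  cr <- cos(r / 2); sr <- sin(r / 2); cp <- cos(p / 2); sp <- sin(p / 2)
  cy <- cos(yw / 2); sy <- sin(yw / 2)
  P <- cbind(cy * cp * cr + sy * sp * sr,
             cy * cp * sr - sy * sp * cr,
             cy * sp * cr + sy * cp * sr,
             sy * cp * cr - cy * sp * sr)
  # exact body-frame rates of the ZYX Euler path
  omega <- cbind(rd - yd * sin(p),
                 pd * cos(r) + yd * cos(p) * sin(r),
                 -pd * sin(r) + yd * cos(p) * cos(r))
  base <- profile$base_orientation
  QB <- matrix(base, n, 4L, byrow = TRUE)
  wb <- matrix(0, n, 3L)          # base-path angular rate, base frame
  tau <- min(blend, dur / 2)
  if (!is.null(from_base) && tau > 0 &&
      quat_angle(from_base, base) > 1e-12) {
    aa <- .rel_axis_angle(from_base, base)
    i <- which(t < tau)
    s  <- 0.5 * (1 - cos(pi * t[i] / tau))
    sd <- 0.5 * pi / tau * sin(pi * t[i] / tau)
    half <- aa$theta * s / 2
    QB[i, ] <- .qmul_mat(from_base, cbind(cos(half), sin(half) * aa$u[1L],
                                          sin(half) * aa$u[2L],
                                          sin(half) * aa$u[3L]))
    wb[i, ] <- outer(aa$theta * sd, aa$u)
  }
  if (!is.null(to_base) && tau > 0 &&
      quat_angle(to_base, base) > 1e-12) {
    aa <- .rel_axis_angle(base, to_base)
    i <- which(t > dur - tau)
    s  <- 0.5 * (1 - cos(pi * (t[i] - (dur - tau)) / tau))
    sd <- 0.5 * pi / tau * sin(pi * (t[i] - (dur - tau)) / tau)
    half <- aa$theta * s / 2
    QB[i, ] <- .qmul_mat(base, cbind(cos(half), sin(half) * aa$u[1L],
                                     sin(half) * aa$u[2L],
                                     sin(half) * aa$u[3L]))
    wb[i, ] <- outer(aa$theta * sd, aa$u)
  }
  Q <- .qmul_mat(QB, P)
  # the base-path rate lives in the (blended) base frame; express it in the
  # final body frame through the oscillation quaternion
  if (any(wb != 0)) omega <- omega + .qrot_inv_mat(P, wb)
  list(time = t, q = Q, omega = omega)
}

#' Ground-truth orientation trajectory for an activity profile
#'
#' Builds the orientation path of one activity segment and the exact
#' body-frame angular velocity of that path (the analytic derivative through
#' the quaternion kinematic relation), at the requested rate.
#'
#' @param profile An [activity_profile()].
#' @param duration Segment duration, seconds (> 0).
#' @param rate Sampling rate, Hz (> 0).
#' @param seed Integer seed; used to draw oscillation phases when
#'   `profile$random_phase` is `TRUE`.
#' @return List with `time` (seconds), `q` (N x 4 unit quaternions,
#'   body-to-Earth) and `omega` (N x 3 body-frame angular velocity, rad/s).
#' @export
make_orientation_trajectory <- function(profile, duration, rate = 50,
                                        seed = NULL) {
  stopifnot(inherits(profile, "activity_profile"), duration > 0, rate > 0)
  .orientation_trajectory(profile, duration, rate, seed)
}

# body-frame linear acceleration pattern of a profile
.linear_accel <- function(profile, duration, rate, seed = NULL) {
  n <- max(1L, round(duration * rate))
  t <- (seq_len(n) - 1L) / rate
  lph <- profile$lin_phase
  if (isTRUE(profile$random_phase)) {
    if (!is.null(seed)) set.seed(seed + 1L)
    stats::runif(3L)  # keep phase draws distinct from orientation draws
    lph <- stats::runif(3L, 0, 2 * pi)
  }
  env <- .edge_envelope(t, n / rate, profile$edge_ramp)
  out <- matrix(0, n, 3L)
  for (k in 1:3)
    out[, k] <- env$w * profile$lin_amp[k] *
      sin(2 * pi * profile$lin_freq[k] * t + lph[k])
  out
}

#' Synthesize 9-axis sensor streams from a ground-truth trajectory
#'
#' Applies the measurement model of a strapped-down IMMU: the accelerometer
#' reads the specific force `R(q)' g_n + a_lin` (reaction to gravity plus
#' body-frame linear acceleration), the gyroscope reads the body angular
#' velocity plus a constant bias, the magnetometer reads the Earth field in
#' the body frame; each corrupted by i.i.d. zero-mean Gaussian noise.
#'
#' @param trajectory Output of [make_orientation_trajectory()].
#' @param fields [reference_fields()].
#' @param noise [sensor_noise_model()].
#' @param linear_accel N x 3 body-frame linear acceleration (m/s^2), or
#'   `NULL` for none.
#' @param seed Integer seed for the noise draws.
#' @return Data frame with columns `acc_x..z, gyr_x..z, mag_x..z`.
#' @export
synthesize_imu <- function(trajectory, fields = reference_fields(),
                           noise = sensor_noise_model(), linear_accel = NULL,
                           seed = NULL) {
  Q <- trajectory$q
  n <- nrow(Q)
  if (is.null(linear_accel)) linear_accel <- matrix(0, n, 3L)
  stopifnot(nrow(linear_accel) == n)
  if (!is.null(seed)) set.seed(seed)
  acc <- .qrot_inv_mat(Q, fields$gravity_n) + linear_accel
  mag <- .qrot_inv_mat(Q, fields$mag_n)
  gyr <- trajectory$omega +
    matrix(noise$gyr_bias, n, 3L, byrow = TRUE)
  if (noise$acc_noise_std > 0)
    acc <- acc + matrix(stats::rnorm(3L * n, 0, noise$acc_noise_std), n, 3L)
  if (noise$gyr_noise_std > 0)
    gyr <- gyr + matrix(stats::rnorm(3L * n, 0, noise$gyr_noise_std), n, 3L)
  if (noise$mag_noise_std > 0)
    mag <- mag + matrix(stats::rnorm(3L * n, 0, noise$mag_noise_std), n, 3L)
  out <- data.frame(acc, gyr, mag)
  names(out) <- c("acc_x", "acc_y", "acc_z", "gyr_x", "gyr_y", "gyr_z",
                  "mag_x", "mag_y", "mag_z")
  out
}

#' Default activity profiles for a body location
#'
#' Motion signatures for the seven target classes plus the marker activities
#' used by the protocols (jumping jacks, wait, run, jump, turn, turn+wait).
#' Base postures are distinct orientations of the module at the given
#' location; stair ascent and descent share identical oscillation and
#' linear-acceleration statistics and differ only in the sign of the mean
#' pitch (+/- 15 degrees), so their acceleration-norm distributions overlap
#' while their attitudes separate — the structure that makes quaternion
#' features informative for those classes.
#'
#' @param location `"LB"` (lower back), `"LT"` (left thigh) or `"LF"` (left
#'   foot).  Locations differ in posture signatures and dynamic intensity.
#' @return Named list of [activity_profile()] objects.
#' @export
default_activity_profiles <- function(location = c("LB", "LT", "LF")) {
  location <- match.arg(location)
  scale <- switch(location, LB = 1, LT = 1.2, LF = 1.6)
  sit_pitch <- switch(location, LB = 35, LT = 75, LF = 20) * pi / 180
  deg <- pi / 180
  stair <- function(name, pitch_deg) activity_profile(
    name, base_orientation = euler_to_quat(0, pitch_deg * deg, 0),
    osc_amp = c(0.12, 0.20, 0.10), osc_freq = c(1.6, 1.6, 0.8),
    lin_amp = scale * c(5, 2.5, 6), lin_freq = c(1.6, 1.6, 3.2))
  list(
    standing = activity_profile("standing"),
    sitting = activity_profile("sitting",
      base_orientation = euler_to_quat(0, sit_pitch, 0)),
    laying = activity_profile("laying",
      base_orientation = euler_to_quat(85 * deg, 0, 0)),
    leaning = activity_profile("leaning",
      base_orientation = euler_to_quat(8 * deg, -20 * deg, 0)),
    walking = activity_profile("walking",
      osc_amp = c(0.10, 0.15, 0.12), osc_freq = c(0.9, 1.8, 0.9),
      lin_amp = scale * c(2.5, 1.5, 3.5), lin_freq = c(1.8, 1.8, 3.6)),
    upstairs = stair("upstairs", 15),
    downstairs = stair("downstairs", -15),
    `jumping jacks` = activity_profile("jumping jacks",
      osc_amp = c(0.30, 0.25, 0.10), osc_freq = c(2.4, 2.4, 1.2),
      lin_amp = scale * c(6, 6, 11), lin_freq = c(2.4, 2.4, 2.4),
      marker = TRUE),
    wait = activity_profile("wait", marker = TRUE),
    run = activity_profile("run",
      osc_amp = c(0.15, 0.25, 0.15), osc_freq = c(1.3, 2.6, 1.3),
      lin_amp = scale * c(6, 3.5, 9), lin_freq = c(2.6, 2.6, 5.2),
      marker = TRUE),
    jump = activity_profile("jump",
      osc_amp = c(0.10, 0.15, 0.05), osc_freq = c(2.0, 2.0, 1.0),
      lin_amp = scale * c(3, 3, 13), lin_freq = c(2.0, 2.0, 2.0),
      marker = TRUE),
    turn = activity_profile("turn",
      osc_amp = c(0.05, 0.05, 1.5), osc_freq = c(1.0, 1.0, 0.25),
      lin_amp = scale * c(1, 1, 1), lin_freq = c(1.0, 1.0, 1.0),
      marker = TRUE),
    `turn+wait` = activity_profile("turn+wait",
      osc_amp = c(0.02, 0.02, 0.8), osc_freq = c(0.5, 0.5, 0.1),
      lin_amp = scale * c(0.5, 0.5, 0.5), lin_freq = c(0.5, 0.5, 0.5),
      marker = TRUE)
  )
}

#' Protocol scripts
#'
#' The three scripted recording protocols, expanded segment by segment, plus
#' a `"full"` script that concatenates all three and a leaning block so that
#' every target class is represented.  Durations follow the protocol cards:
#' sitting/standing/laying/walk/run one minute, waits 30 s, a stair flight of
#' 11 steps ~ 8 s, two jumping jacks ~ 4 s, ten jumps ~ 10 s, a turn ~ 2 s.
#'
#' @param which 1, 2, 3 or `"full"`.
#' @param loops Number of repetitions of each protocol loop (default 5).
#' @param time_scale Multiplier on all segment durations; values below 1
#'   produce scaled-down datasets with identical structure.
#' @return Object of class `protocol_script`: data frame with columns
#'   `activity`, `duration` (s), `marker`.
#' @export
har_protocol <- function(which = 1, loops = 5, time_scale = 1) {
  stopifnot(loops >= 1, time_scale > 0)
  seg <- function(activity, duration)
    data.frame(activity = activity, duration = duration)
  loop <- function(df, k) df[rep(seq_len(nrow(df)), k), , drop = FALSE]
  p1 <- rbind(
    loop(rbind(seg("jumping jacks", 4), seg("sitting", 60),
               seg("jumping jacks", 4), seg("standing", 60),
               seg("jumping jacks", 4), seg("wait", 30)), loops),
    loop(rbind(seg("jumping jacks", 4), seg("laying", 60),
               seg("jumping jacks", 4), seg("standing", 60),
               seg("jumping jacks", 4), seg("wait", 30)), loops))
  p2 <- loop(rbind(seg("wait", 30), seg("walking", 60), seg("wait", 30),
                   seg("run", 60), seg("wait", 30), seg("jump", 10)), loops)
  p3 <- loop(rbind(seg("wait", 30), seg("upstairs", 8),
                   seg("turn+wait", 30), seg("downstairs", 8),
                   seg("turn", 2)), loops)
  lean <- loop(rbind(seg("wait", 30), seg("leaning", 60),
                     seg("jumping jacks", 4)), loops)
  script <- switch(as.character(which),
                   "1" = p1, "2" = p2, "3" = p3,
                   "full" = rbind(p1, p2, p3, lean),
                   stop("unknown protocol: ", which))
  script$duration <- script$duration * time_scale
  script$marker <- !(script$activity %in% TARGET_CLASSES)
  rownames(script) <- NULL
  class(script) <- c("protocol_script", "data.frame")
  script
}

# deterministic substream seed below 2^31, so independent draws can be
# replayed per subject / segment / purpose
.substream_seed <- function(seed, stream, index = 0L) {
  h <- sum(utf8ToInt(stream) * (seq_along(utf8ToInt(stream)) + 13))
  as.integer((abs(seed) * 48271 + h * 1299721 + index * 7919) %% 2147483629)
}

# per-subject perturbation: +/-10% multiplicative on amplitudes and
# frequencies, +/-5 degrees about a random axis on the base orientation
.jitter_profiles <- function(profiles, seed, amp_jitter = 0.1,
                             angle_jitter = 5 * pi / 180) {
  set.seed(seed)
  lapply(profiles, function(p) {
    p$osc_amp <- p$osc_amp * stats::runif(3L, 1 - amp_jitter, 1 + amp_jitter)
    p$osc_freq <- p$osc_freq * stats::runif(3L, 1 - amp_jitter, 1 + amp_jitter)
    p$lin_amp <- p$lin_amp * stats::runif(3L, 1 - amp_jitter, 1 + amp_jitter)
    p$lin_freq <- p$lin_freq * stats::runif(3L, 1 - amp_jitter, 1 + amp_jitter)
    ax <- stats::rnorm(3L)
    dq <- quat_from_axis_angle(ax, stats::runif(1L, -angle_jitter, angle_jitter))
    p$base_orientation <- quat_canonical(
      quat_multiply(p$base_orientation, dq))
    p
  })
}

#' Generate labeled recordings for a protocol
#'
#' Simulates one recording per subject: the protocol script is expanded into
#' ground-truth orientation and linear-acceleration segments (continuous
#' across segment boundaries via a short slerp blend), the 9-axis
#' measurement model is applied, and every sample is labeled from the script
#' segment covering it.  Per-subject variability comes from seeded jitter of
#' the profile parameters, so leave-one-subject-out validation is
#' non-trivial.
#'
#' @param protocol A [har_protocol()] script (or the protocol id passed to
#'   it).
#' @param subjects Number of subjects (>= 1).
#' @param location `"LB"`, `"LT"` or `"LF"`.
#' @param noise [sensor_noise_model()].
#' @param seed Integer root seed; all subject, trajectory and noise draws
#'   derive from it.
#' @param fields [reference_fields()].
#' @param profiles Activity profiles; defaults to
#'   [default_activity_profiles()] for the location.
#' @return List of `labeled_recording` data frames (columns `time`,
#'   `acc_*`, `gyr_*`, `mag_*`, `label`, `marker`, `qw,qx,qy,qz`), with
#'   attributes `subject`, `location`, `sample_rate`.
#' @export
generate_protocol_dataset <- function(protocol, subjects = 8,
                                      location = "LB",
                                      noise = sensor_noise_model(),
                                      seed = 1,
                                      fields = reference_fields(),
                                      profiles = NULL) {
  if (!inherits(protocol, "protocol_script")) protocol <- har_protocol(protocol)
  stopifnot(subjects >= 1)
  location <- match.arg(location, c("LB", "LT", "LF"))
  if (is.null(profiles)) profiles <- default_activity_profiles(location)
  missing <- setdiff(unique(protocol$activity), names(profiles))
  if (length(missing))
    stop("no activity profile for: ", paste(missing, collapse = ", "))
  rate <- noise$sample_rate
  lapply(seq_len(subjects), function(s) {
    sseed <- .substream_seed(seed, "subject", s)
    profs <- .jitter_profiles(profiles, sseed)
    segs <- vector("list", nrow(protocol))
    nseg <- nrow(protocol)
    bases <- lapply(protocol$activity, function(a)
      profs[[a]]$base_orientation)
    prev_base <- bases[[1L]]
    for (k in seq_len(nseg)) {
      prof <- profs[[protocol$activity[k]]]
      prof$random_phase <- TRUE
      prof$edge_ramp <- min(0.5, protocol$duration[k] / 4)
      gseed <- .substream_seed(sseed, "segment", k)
      # posture transitions live inside marker segments (they are stripped
      # before classification, like the transitions in the protocols);
      # target segments keep a constant base unless two targets touch
      marker <- protocol$marker[k]
      from_b <- if (quat_angle(prev_base, bases[[k]]) > 1e-12)
        prev_base else NULL
      to_b <- if (marker && k < nseg) bases[[k + 1L]] else NULL
      traj <- .orientation_trajectory(prof, protocol$duration[k], rate,
                                      seed = gseed, from_base = from_b,
                                      to_base = to_b, blend = 1)
      lin <- .linear_accel(prof, protocol$duration[k], rate, seed = gseed)
      segs[[k]] <- list(traj = traj, lin = lin,
                        label = protocol$activity[k],
                        marker = marker)
      prev_base <- if (!is.null(to_b)) to_b else bases[[k]]
    }
    Q <- do.call(rbind, lapply(segs, function(x) x$traj$q))
    omega <- do.call(rbind, lapply(segs, function(x) x$traj$omega))
    lin <- do.call(rbind, lapply(segs, function(x) x$lin))
    labels <- unlist(lapply(segs, function(x)
      rep(x$label, nrow(x$traj$q))))
    marker <- unlist(lapply(segs, function(x)
      rep(x$marker, nrow(x$traj$q))))
    sens <- synthesize_imu(list(q = Q, omega = omega), fields, noise,
                           linear_accel = lin,
                           seed = .substream_seed(sseed, "noise"))
    rec <- data.frame(time = (seq_len(nrow(Q)) - 1L) / rate,
                      sens,
                      label = labels, marker = marker,
                      qw = Q[, 1L], qx = Q[, 2L], qy = Q[, 3L], qz = Q[, 4L])
    attr(rec, "subject") <- s
    attr(rec, "location") <- location
    attr(rec, "sample_rate") <- rate
    class(rec) <- c("labeled_recording", "data.frame")
    rec
  })
}

#' Remove marker segments from a recording
#'
#' Drops every sample whose marker flag is set (synchronization and
#' transition activities such as jumping jacks, waits and turns), keeping
#' the remaining samples in their original order, so that only the seven
#' target classes remain.
#'
#' @param rec A `labeled_recording` with a `marker` column.
#' @return The filtered `labeled_recording`.
#' @export
strip_marker_segments <- function(rec) {
  if (is.null(rec$marker)) stop("recording has no marker column")
  out <- rec[!rec$marker, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("subject", "location", "sample_rate"))
    attr(out, a) <- attr(rec, a)
  class(out) <- class(rec)
  out
}
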