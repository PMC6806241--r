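# Gradient-descent attitude estimation from 9-axis IMMU streams.
#
# The filter fuses gyroscope integration (kinematic equation
# q_dot = 1/2 q x (0, gyr)) with the direction of steepest descent of an
# accelerometer/magnetometer alignment objective, scaled by a single gain
# beta (rad/s).  This is the classic single-gain gradient-descent MARG
# (Madgwick-type) filter, including magnetic distortion compensation and an
# optional integral gyroscope-bias feedback term.

#' Earth-frame reference fields
#'
#' Gravity and magnetic reference vectors in the NED Earth frame.  The
#' magnetic reference is a fixed unit vector with a dip angle (default 60
#' degrees), a stand-in for a site-specific geomagnetic model: any unit
#' vector not parallel to gravity makes full attitude observable.
#'
#' @param gravity Gravity magnitude, m/s^2.
#' @param mag Earth-frame unit magnetic field vector; normalized internally.
#' @return Object of class `reference_fields` with elements `gravity_n`
#'   (`c(0, 0, gravity)`) and `mag_n` (unit 3-vector).
#' @export
reference_fields <- function(gravity = 9.81,
                             mag = c(cos(60 * pi / 180), 0, sin(60 * pi / 180))) {
  stopifnot(gravity > 0, length(mag) == 3L, sum(mag^2) > 0)
  structure(list(gravity_n = c(0, 0, gravity),
                 mag_n = mag / sqrt(sum(mag^2))),
            class = "reference_fields")
}

#' Attitude filter state
#'
#' @param q Initial attitude estimate, unit quaternion (body-to-Earth).
#' @param beta Fusion gain in rad/s: the rate at which the
#'   accelerometer/magnetometer correction can slew the estimate.  Zero
#'   disables the correction (pure gyro integration).
#' @param dt Sample interval in seconds (default 1/50 for 50 Hz).
#' @param fields [reference_fields()] object.
#' @param zeta Integral gain (rad/s) for gyroscope bias drift compensation;
#'   default 0 (off).
#' @param use_mag Use the magnetometer in the correction.  Without it yaw is
#'   unobservable and only roll/pitch converge.
#' @return Object of class `filter_state`.
#' @export
filter_state <- function(q = c(1, 0, 0, 0), beta = 0.1, dt = 1 / 50,
                         fields = reference_fields(), zeta = 0,
                         use_mag = TRUE) {
  stopifnot(beta >= 0, dt > 0, zeta >= 0)
  structure(list(q = quat_normalize(q), beta = beta, dt = dt,
                 fields = fields, zeta = zeta, use_mag = use_mag,
                 bias = c(0, 0, 0)),
            class = "filter_state")
}

#' One explicit-Euler step of the quaternion kinematic equation
#'
#' Propagates the attitude estimate through one sample of angular velocity:
#' `q_dot = 1/2 q x (0, gyr)`, `q <- normalize(q + q_dot * dt)`.
#'
#' @param state A [filter_state()].
#' @param gyr Body-frame angular velocity, rad/s, length 3.
#' @return The updated `filter_state`.
#' @export
gyro_propagate <- function(state, gyr) {
  qd <- 0.5 * quat_multiply(state$q, c(0, gyr))
  state$q <- quat_normalize(state$q + qd * state$dt)
  state
}

# Body-frame image of an Earth-frame reference vector d under attitude q,
# f = R(q)' d, and its 3x4 Jacobian with respect to q.  Both are exact
# polynomials in q; the Jacobian is what makes the descent direction
# analytic rather than numeric.
.field_residual <- function(q, d, meas) {
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  dx <- d[1L]; dy <- d[2L]; dz <- d[3L]
  f <- c(dx * (1 - 2 * y^2 - 2 * z^2) + dy * 2 * (x * y + w * z) + dz * 2 * (x * z - w * y),
         dx * 2 * (x * y - w * z) + dy * (1 - 2 * x^2 - 2 * z^2) + dz * 2 * (y * z + w * x),
         dx * 2 * (x * z + w * y) + dy * 2 * (y * z - w * x) + dz * (1 - 2 * x^2 - 2 * y^2)) -
    meas
  J <- matrix(c(
    2 * dy * z - 2 * dz * y,  2 * dy * y + 2 * dz * z,
    -4 * dx * y + 2 * dy * x - 2 * dz * w, -4 * dx * z + 2 * dy * w + 2 * dz * x,
    -2 * dx * z + 2 * dz * x,  2 * dx * y - 4 * dy * x + 2 * dz * w,
    2 * dx * x + 2 * dz * z,  -2 * dx * w - 4 * dy * z + 2 * dz * y,
    2 * dx * y - 2 * dy * x,  2 * dx * z - 2 * dy * w - 4 * dz * x,
    2 * dx * w + 2 * dy * z - 4 * dz * y, 2 * dx * x + 2 * dy * y
  ), nrow = 3L, byrow = TRUE)
  list(f = f, J = J)
}

#' Alignment objective and gradient of the accelerometer/magnetometer fusion
#'
#' The objective stacks the residuals `R(q)' g_hat - acc_hat` and
#' `R(q)' b_hat - mag_hat`, where hats denote unit vectors and `b_hat` is the
#' magnetic-distortion-compensated reference: the measured field is rotated
#' into the Earth frame and its horizontal components collapsed onto
#' `(b_x, 0, b_z)`, so that only the magnetic dip (not local declination or
#' horizontal soft-iron error) constrains the estimate.
#'
#' @param q Unit quaternion at which to evaluate.
#' @param acc Body-frame specific force, any positive magnitude.
#' @param mag Body-frame magnetic field, any positive magnitude, or `NULL`
#'   for the accelerometer-only variant.
#' @param fields [reference_fields()].
#' @param b_ref Optional fixed magnetic reference `(b_x, 0, b_z)`.  By
#'   default it is recomputed from `q` and the measured field each call (the
#'   filter's distortion compensation); passing the returned `b_ref` back in
#'   freezes it, which makes the objective a fixed function of `q` — the
#'   form whose exact gradient this function returns.
#' @return List with `gradient` (the unnormalized 4-vector `J' f`, the exact
#'   gradient of `0.5 * ||f||^2` at fixed `b_ref`), `direction`
#'   (unit-normalized gradient, the step direction used by [fuse_step()];
#'   zero 4-vector when the objective is already at its minimum),
#'   `objective` (`0.5 * ||f||^2`) and `b_ref`.
#'   Zero-norm `acc` or `mag` signal an uninformative sample: `NULL` is
#'   returned and the caller skips the correction for that tick.
#' @export
gd_correction <- function(q, acc, mag = NULL, fields = reference_fields(),
                          b_ref = NULL) {
  an <- sqrt(sum(acc^2))
  if (an == 0) return(NULL)
  ga <- .field_residual(q, c(0, 0, 1), acc / an)
  f <- ga$f; J <- ga$J
  b <- NULL
  if (!is.null(mag)) {
    mn <- sqrt(sum(mag^2))
    if (mn == 0) return(NULL)
    mhat <- mag / mn
    if (is.null(b_ref)) {
      h <- quat_rotate(q, mhat)                # measured field in Earth frame
      b <- c(sqrt(h[1L]^2 + h[2L]^2), 0, h[3L])  # distortion-compensated ref
    } else b <- b_ref
    gm <- .field_residual(q, b, mhat)
    f <- c(f, gm$f)
    J <- rbind(J, gm$J)
  }
  grad <- drop(crossprod(J, f))
  gn <- sqrt(sum(grad^2))
  # at (numerical) convergence the gradient is pure rounding noise; a unit
  # normalization of it would inject a full-size step in a random direction,
  # so the correction is zeroed below machine-scale gradients
  list(gradient = grad,
       direction = if (gn > 1e-12) grad / gn else c(0, 0, 0, 0),
       objective = 0.5 * sum(f^2),
       b_ref = b)
}

#' One fusion step of the gradient-descent attitude filter
#'
#' Combines the gyroscope propagation rate with the descent direction of the
#' alignment objective:
#' `q <- normalize(q + (0.5 q x (0, gyr - bias) - beta * dir) * dt)`.
#' With `zeta > 0` the angular-rate error implied by the descent direction is
#' integrated into a gyroscope bias estimate.  Hemisphere continuity with the
#' previous estimate is enforced.
#'
#' @param state A [filter_state()].
#' @param acc,gyr,mag Body-frame sensor sample (length-3 each; `mag` may be
#'   `NULL` for the IMU-only variant when `state$use_mag` is `FALSE`).
#' @return Updated `filter_state`.
#' @export
fuse_step <- function(state, acc, gyr, mag = NULL) {
  q <- state$q
  corr <- if (state$beta > 0 || state$zeta > 0)
    gd_correction(q, acc, if (state$use_mag) mag else NULL, state$fields)
  else NULL
  g <- gyr - state$bias
  if (!is.null(corr)) {
    if (state$zeta > 0) {
      # angular-rate error direction: 2 q* x grad_dir, vector part
      werr <- 2 * quat_multiply(quat_conjugate(q), corr$direction)[2:4]
      state$bias <- state$bias + state$zeta * werr * state$dt
      g <- gyr - state$bias
    }
    qd <- 0.5 * quat_multiply(q, c(0, g)) - state$beta * corr$direction
  } else {
    qd <- 0.5 * quat_multiply(q, c(0, g))
  }
  qn <- quat_normalize(q + qd * state$dt)
  if (sum(qn * q) < 0) qn <- -qn
  state$q <- qn
  state
}

# Algebraic attitude from one accelerometer + magnetometer sample
# (TRIAD-style): build an orthonormal Earth-axis triad in the body frame
# from the measured gravity and magnetic field directions.
.algebraic_init <- function(acc, mag = NULL) {
  an <- sqrt(sum(acc^2))
  if (an == 0) return(c(1, 0, 0, 0))
  d <- acc / an                                # down axis in body frame
  if (!is.null(mag) && sqrt(sum(mag^2)) > 0) {
    m <- mag / sqrt(sum(mag^2))
    e <- c(d[2L] * m[3L] - d[3L] * m[2L],      # east = down x mag
           d[3L] * m[1L] - d[1L] * m[3L],
           d[1L] * m[2L] - d[2L] * m[1L])
    if (sum(e^2) < 1e-12) return(.algebraic_init(acc))
  } else {
    # no magnetic information: pick an arbitrary horizontal axis (yaw free)
    e <- c(d[2L], -d[1L], 0)
    if (sum(e^2) < 1e-12) e <- c(0, 1, 0)
  }
  e <- e / sqrt(sum(e^2))
  n <- c(e[2L] * d[3L] - e[3L] * d[2L],        # north = east x down
         e[3L] * d[1L] - e[1L] * d[3L],
         e[1L] * d[2L] - e[2L] * d[1L])
  R <- rbind(n, e, d)                          # Earth-from-body rotation
  # rotation matrix -> quaternion (Shepperd's method, stable branch choice)
  tr <- R[1L, 1L] + R[2L, 2L] + R[3L, 3L]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3L, 2L] - R[2L, 3L]) / s,
           (R[1L, 3L] - R[3L, 1L]) / s, (R[2L, 1L] - R[1L, 2L]) / s)
  } else if (R[1L, 1L] >= R[2L, 2L] && R[1L, 1L] >= R[3L, 3L]) {
    s <- sqrt(1 + R[1L, 1L] - R[2L, 2L] - R[3L, 3L]) * 2
    q <- c((R[3L, 2L] - R[2L, 3L]) / s, s / 4,
           (R[1L, 2L] + R[2L, 1L]) / s, (R[1L, 3L] + R[3L, 1L]) / s)
  } else if (R[2L, 2L] >= R[3L, 3L]) {
    s <- sqrt(1 + R[2L, 2L] - R[1L, 1L] - R[3L, 3L]) * 2
    q <- c((R[1L, 3L] - R[3L, 1L]) / s, (R[1L, 2L] + R[2L, 1L]) / s,
           s / 4, (R[2L, 3L] + R[3L, 2L]) / s)
  } else {
    s <- sqrt(1 + R[3L, 3L] - R[1L, 1L] - R[2L, 2L]) * 2
    q <- c((R[2L, 1L] - R[1L, 2L]) / s, (R[1L, 3L] + R[3L, 1L]) / s,
           (R[2L, 3L] + R[3L, 2L]) / s, s / 4)
  }
  quat_canonical(quat_normalize(q))
}

#' Estimate an attitude stream for a labeled recording
#'
#' Runs the gradient-descent fusion filter over every sample of a recording
#' and returns one unit quaternion (and its Euler angles) per sample, aligned
#' 1:1 with the labels.
#'
#' @param rec A `labeled_recording` (see [generate_protocol_dataset()] or
#'   [read_recording()]).
#' @param beta Fusion gain, rad/s.
#' @param q_init_mode `"algebraic"` (default) initializes from the first
#'   accelerometer/magnetometer sample, avoiding a convergence transient in
#'   the per-sample features; `"identity"` starts at the identity quaternion.
#' @param use_mag Use the magnetometer (full MARG variant, default).
#' @param zeta Gyroscope bias integral gain, rad/s (default 0).
#' @param fields [reference_fields()].
#' @return Data frame with columns `qw,qx,qy,qz,roll,pitch,yaw`, one row per
#'   input sample.  Quaternions are unit, canonical-hemisphere continuous.
#' @export
estimate_attitude <- function(rec, beta = 0.1,
                              q_init_mode = c("algebraic", "identity"),
                              use_mag = TRUE, zeta = 0,
                              fields = reference_fields()) {
  q_init_mode <- match.arg(q_init_mode)
  n <- nrow(rec)
  if (is.null(n) || n == 0L) stop("empty recording")
  acc <- as.matrix(rec[, c("acc_x", "acc_y", "acc_z")])
  gyr <- as.matrix(rec[, c("gyr_x", "gyr_y", "gyr_z")])
  mag <- as.matrix(rec[, c("mag_x", "mag_y", "mag_z")])
  dt <- if (n > 1L) rec$time[2L] - rec$time[1L] else 1 / 50
  q0 <- if (q_init_mode == "algebraic")
    .algebraic_init(acc[1L, ], if (use_mag) mag[1L, ] else NULL)
  else c(1, 0, 0, 0)
  st <- filter_state(q = q0, beta = beta, dt = dt, fields = fields,
                     zeta = zeta, use_mag = use_mag)
  Q <- matrix(NA_real_, n, 4L)
  E <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    st <- fuse_step(st, acc[i, ], gyr[i, ], mag[i, ])
    Q[i, ] <- st$q
    E[i, ] <- quat_to_euler(st$q)
  }
  out <- data.frame(qw = Q[, 1L], qx = Q[, 2L], qy = Q[, 3L], qz = Q[, 4L],
                    roll = E[, 1L], pitch = E[, 2L], yaw = E[, 3L])
  out
}
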