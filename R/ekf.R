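#' Kalman filter state
#'
#' Holds the estimate, covariance and noise models used by [ekf_attitude()].
#' The attitude state is `x = [q_w, q_x, q_y, q_z, b_x, b_y, b_z]`:
#' orientation quaternion plus gyro bias (rad/s).
#'
#' @param x initial state vector (default: identity quaternion, zero bias).
#' @param P initial error covariance (7x7, symmetric PSD).
#' @param Q_proc process noise covariance scale (per-axis, default 1e-5).
#' @param R_meas measurement noise covariance scale (per-axis, default 1e-2).
#' @return object of class `kalman_state`.
#' @export
kalman_state <- function(x = c(1, 0, 0, 0, 0, 0, 0),
                         P = diag(c(rep(1e-4, 4), rep(1e-6, 3))),
                         Q_proc = 1e-5, R_meas = 1e-2) {
  stopifnot(length(x) == 7, all(dim(P) == c(7, 7)))
  if (max(abs(P - t(P))) > 1e-9 || min(eigen(P, symmetric = TRUE,
                                             only.values = TRUE)$values) < -1e-9)
    stop("P must be symmetric positive semidefinite")
  structure(list(x = x, P = (P + t(P)) / 2, Q_proc = Q_proc, R_meas = R_meas),
            class = "kalman_state")
}

#' Linear Kalman measurement update
#'
#' The textbook update `x_post = x_prior + K (z - H x_prior)` with
#' `K = P H' (H P H' + R)^-1`, returned together with the posterior
#' covariance `(I - K H) P`.
#'
#' @param x prior state estimate.
#' @param P prior covariance.
#' @param z measurement vector.
#' @param H observation matrix.
#' @param R measurement noise covariance.
#' @param K optional gain override (e.g. 0 or I for diagnostics).
#' @return list with `x`, `P`, `K`, `innovation`.
#' @export
kalman_update <- function(x, P, z, H, R, K = NULL) {
  innov <- z - H %*% x
  if (is.null(K)) {
    S <- H %*% P %*% t(H) + R
    K <- P %*% t(H) %*% solve(S)
  }
  x_post <- as.numeric(x + K %*% innov)
  P_post <- (diag(length(x)) - K %*% H) %*% P
  list(x = x_post, P = (P_post + t(P_post)) / 2, K = K,
       innovation = as.numeric(innov))
}

# Quaternion utilities (scalar-first convention)
qmult <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

qnorm1 <- function(q) q / sqrt(sum(q^2))

# Rotation matrix (body -> world) from quaternion
q_to_R <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Euler angles (deg) from quaternion: roll (x), pitch (y), yaw (z)
q_to_euler <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  roll <- atan2(2 * (w * x + y * z), 1 - 2 * (x^2 + y^2))
  sp <- 2 * (w * y - z * x)
  pitch <- asin(pmin(pmax(sp, -1), 1))
  yaw <- atan2(2 * (w * z + x * y), 1 - 2 * (z^2 + x^2))
  c(roll, pitch, yaw) * 180 / pi
}

# Predicted gravity direction in body frame
gravity_body <- function(q) as.numeric(t(q_to_R(q)) %*% c(0, 0, 1))

#' Extended Kalman filter attitude fusion
#'
#' Fuses gyroscope and accelerometer streams into an orientation estimate.
#' Each step propagates the quaternion with the bias-corrected angular rate
#' (predict), then corrects it with the accelerometer gravity direction as
#' the measurement (update). The quaternion is renormalized after every
#' step. Jacobians are computed by central finite differences; the state is
#' quaternion + gyro bias.
#'
#' @param gyro `signal_stream` with channels `gyro_x, gyro_y, gyro_z` in
#'   deg/s.
#' @param accel `signal_stream` with channels `accel_x, accel_y, accel_z`
#'   in m/s^2; must share the gyro's sampling rate and timeline.
#' @param state0 a [kalman_state()].
#' @return list with `angles` (a 3-channel `signal_stream` of Euler angles
#'   roll/pitch/yaw in degrees) and `state` (final `kalman_state`).
#' @export
ekf_attitude <- function(gyro, accel, state0 = kalman_state()) {
  stopifnot(inherits(gyro, "signal_stream"), inherits(accel, "signal_stream"),
            inherits(state0, "kalman_state"))
  if (abs(gyro$fs - accel$fs) > 1e-9 || ncol(gyro$samples) != ncol(accel$samples))
    stop("gyro and accel streams must be time-aligned at the same fs")
  n <- ncol(gyro$samples)
  dt <- 1 / gyro$fs
  x <- state0$x
  P <- state0$P
  Q <- diag(c(rep(state0$Q_proc, 4), rep(state0$Q_proc * 0.1, 3)))
  R <- diag(state0$R_meas, 3)
  g_idx <- grep("^gyro", gyro$channel_names)
  a_idx <- grep("^accel", accel$channel_names)
  if (length(g_idx) != 3 || length(a_idx) != 3)
    stop("expected 3 gyro and 3 accel channels")
  W <- gyro$samples[g_idx, , drop = FALSE] * pi / 180
  A <- accel$samples[a_idx, , drop = FALSE]

  predict_fn <- function(x, w) {
    q <- x[1:4]; b <- x[5:7]
    wc <- w - b
    ang <- sqrt(sum(wc^2)) * dt
    dq <- if (ang < 1e-12) c(1, 0, 0, 0) else {
      axis <- wc / sqrt(sum(wc^2))
      c(cos(ang / 2), axis * sin(ang / 2))
    }
    c(qnorm1(qmult(q, dq)), b)
  }
  num_jac <- function(f, x, eps = 1e-6) {
    m <- length(f(x))
    J <- matrix(0, m, length(x))
    for (j in seq_along(x)) {
      xp <- x; xm <- x
      xp[j] <- xp[j] + eps; xm[j] <- xm[j] - eps
      J[, j] <- (f(xp) - f(xm)) / (2 * eps)
    }
    J
  }

  angles <- matrix(0, 3, n)
  for (k in seq_len(n)) {
    w <- W[, k]
    f <- function(xx) predict_fn(xx, w)
    Fk <- num_jac(f, x)
    x <- f(x)
    P <- Fk %*% P %*% t(Fk) + Q
    a <- A[, k]
    na <- sqrt(sum(a^2))
    if (na > 1e-6) {
      z <- a / na
      h <- function(xx) gravity_body(qnorm1(xx[1:4]))
      Hk <- num_jac(h, x)
      S <- Hk %*% P %*% t(Hk) + R
      K <- P %*% t(Hk) %*% solve(S)
      x <- as.numeric(x + K %*% (z - h(x)))
      P <- (diag(7) - K %*% Hk) %*% P
      P <- (P + t(P)) / 2
    }
    x[1:4] <- qnorm1(x[1:4])
    angles[, k] <- q_to_euler(x[1:4])
  }
  ang_stream <- signal_stream(angles, gyro$fs, t0 = gyro$t0,
                              modality = "angle",
                              channel_names = c("roll", "pitch", "yaw"),
                              units = "deg")
  list(angles = ang_stream,
       state = kalman_state(x, P, state0$Q_proc, state0$R_meas))
}
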