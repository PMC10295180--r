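#' Constant-velocity Kalman filter over box state
#'
#' The motion model tracks the 8-vector state
#' `(u, v, a, h, du, dv, da, dh)`: box center, aspect ratio and height plus
#' their per-frame rates. Transition is constant-velocity (position +=
#' velocity each frame, dt = 1 frame); the observation model reads the first
#' four components directly. Noise scales with the box height `h`, so large
#' (near) animals tolerate proportionally larger innovations: measurement
#' std is `(sigma_p*h, sigma_p*h, 0.1, sigma_p*h)` and process std
#' `(sigma_p*h, sigma_p*h, 0.01, sigma_p*h, sigma_v*h, sigma_v*h, 1e-5,
#' sigma_v*h)` with defaults `sigma_p = 1/20`, `sigma_v = 1/160`.
#'
#' @param box a 1-row center-form box matrix (the first measurement).
#' @param config a [pipeline_config()] supplying `sigma_p`, `sigma_v`.
#' @return `kf_init()` returns a `motion_state`: list with `mean` (length-8)
#'   and `cov` (8x8), positions set to the measurement and velocities zero.
#' @name kalman
#' @export
kf_init <- function(box, config = pipeline_config()) {
  box <- as_box_matrix(box)
  mean <- c(box[1L, ], rep(0, 4))
  h <- box[1L, 4L]
  std <- c(2 * config$sigma_p * h, 2 * config$sigma_p * h, 1e-2,
           2 * config$sigma_p * h,
           10 * config$sigma_v * h, 10 * config$sigma_v * h, 1e-5,
           10 * config$sigma_v * h)
  structure(list(mean = unname(mean), cov = diag(std^2)),
            class = "motion_state")
}

kf_transition <- function() {
  F8 <- diag(8)
  F8[cbind(1:4, 5:8)] <- 1
  F8
}

kf_process_cov <- function(h, config) {
  std <- c(config$sigma_p * h, config$sigma_p * h, 1e-2, config$sigma_p * h,
           config$sigma_v * h, config$sigma_v * h, 1e-5, config$sigma_v * h)
  diag(std^2)
}

kf_measurement_cov <- function(h, config) {
  std <- c(config$sigma_p * h, config$sigma_p * h, 1e-1, config$sigma_p * h)
  diag(std^2)
}

#' @rdname kalman
#' @param state a `motion_state`.
#' @return `kf_predict()` returns the one-step-ahead prior state.
#' @export
kf_predict <- function(state, config = pipeline_config()) {
  if (!all(is.finite(state$mean))) stop("non-finite motion state")
  F8 <- kf_transition()
  mean <- as.numeric(F8 %*% state$mean)
  cov <- F8 %*% state$cov %*% t(F8) + kf_process_cov(state$mean[4L], config)
  structure(list(mean = mean, cov = symmetrize(cov)), class = "motion_state")
}

#' @rdname kalman
#' @return `kf_update()` returns the posterior state after fusing the
#'   measurement; the posterior covariance never exceeds the prior in the
#'   positive-semidefinite order.
#' @export
kf_update <- function(state, box, config = pipeline_config()) {
  box <- as_box_matrix(box)
  z <- unname(box[1L, ])
  proj <- kf_project(state, config)
  # Kalman gain via Cholesky solve of the innovation covariance S
  ch <- tryCatch(chol(proj$S), error = function(e) {
    stop("singular innovation covariance")
  })
  PHt <- state$cov[, 1:4, drop = FALSE]
  K <- t(backsolve(ch, forwardsolve(t(ch), t(PHt))))
  innov <- z - proj$mean
  mean <- state$mean + as.numeric(K %*% innov)
  cov <- state$cov - K %*% proj$S %*% t(K)
  structure(list(mean = mean, cov = symmetrize(cov)), class = "motion_state")
}

# project the state onto measurement space: mean Hx, covariance HPH' + R
kf_project <- function(state, config) {
  mean <- state$mean[1:4]
  S <- state$cov[1:4, 1:4, drop = FALSE] +
    kf_measurement_cov(state$mean[4L], config)
  list(mean = mean, S = symmetrize(S))
}

#' @rdname kalman
#' @param boxes an `n x 4` center-form box matrix of candidate measurements.
#' @return `kf_gating_distance()` returns the squared Mahalanobis distance of
#'   each measurement from the state's projected distribution (length `n`,
#'   all `>= 0`).
#' @export
kf_gating_distance <- function(state, boxes, config = pipeline_config()) {
  boxes <- as_box_matrix(boxes)
  proj <- kf_project(state, config)
  ch <- tryCatch(chol(proj$S), error = function(e) {
    stop("singular innovation covariance")
  })
  diff <- sweep(boxes, 2L, proj$mean)           # n x 4 residuals
  y <- forwardsolve(t(ch), t(diff))             # solves L y = diff'
  colSums(y^2)
}

symmetrize <- function(m) (m + t(m)) / 2
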