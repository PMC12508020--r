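#' Add distance, velocity, and acceleration channels
#'
#' Appends three derived feature channels to a representation:
#' \describe{
#'   \item{dist}{Euclidean distance from the previous sample (px); the first
#'     sample is undefined (`NA`).}
#'   \item{vel}{speed `dist / dt` (px/ms), unsigned; first sample `NA`.}
#'   \item{acc}{forward difference of velocity,
#'     `(vel[i+1] - vel[i]) / (t[i+1] - t[i])` (px/ms^2); undefined at the
#'     first and last samples.}
#' }
#'
#' @inheritParams remap_symmetric
#' @return `track_data` with the channels appended to `use`.
#' @export
add_derivatives <- function(ds, use = "trajectories") {
  ids <- dimnames(get_trajectories(ds, use))[[1L]]
  arr <- map_trials(get_trajectories(ds, use), function(m, i) {
    L <- nrow(m)
    t <- m[, "timestamps"]
    dt <- diff(t)
    d <- sqrt(diff(m[, "xpos"])^2 + diff(m[, "ypos"])^2)
    if (any(dt == 0 & d > 0))
      stop("trial '", ids[i], "' has repeated timestamps with nonzero ",
           "displacement (infinite velocity)")
    vel <- c(NA_real_, d / dt)
    acc <- rep(NA_real_, L)
    if (L >= 3L)
      acc[2:(L - 1L)] <- diff(vel[-1L]) / dt[-1L]
    cbind(m, dist = c(NA_real_, d), vel = vel, acc = acc)
  })
  ds <- set_trajectories(ds, use, arr)
  add_provenance(ds, "add_derivatives", list(use = use))
}

#' Add movement-angle channels
#'
#' Appends two angle channels to a representation:
#' \describe{
#'   \item{angle_v}{signed angle (radians, range `(-pi, pi]`) between each
#'     two-point segment and the vertical axis. 0 means straight up;
#'     positive angles point toward negative x (the left, i.e. toward the
#'     chosen option after left-remapping), negative toward positive x.
#'     Zero-length segments give `NA`.}
#'   \item{angle_p}{interior angle (radians, `[0, pi]`) at each point
#'     between the incoming and outgoing segments; `pi` for a collinear
#'     continuation. Undefined at the endpoints and for degenerate
#'     segments.}
#' }
#'
#' @inheritParams remap_symmetric
#' @return `track_data` with the channels appended to `use`.
#' @export
add_angles <- function(ds, use = "trajectories") {
  arr <- map_trials(get_trajectories(ds, use), function(m, i) {
    L <- nrow(m)
    dx <- diff(m[, "xpos"]); dy <- diff(m[, "ypos"])
    av <- ifelse(dx == 0 & dy == 0, NA_real_, atan2(-dx, dy))
    angle_v <- c(NA_real_, av)
    angle_p <- rep(NA_real_, L)
    if (L >= 3L) {
      for (k in 2:(L - 1L)) {
        a <- c(m[k - 1L, "xpos"] - m[k, "xpos"], m[k - 1L, "ypos"] - m[k, "ypos"])
        b <- c(m[k + 1L, "xpos"] - m[k, "xpos"], m[k + 1L, "ypos"] - m[k, "ypos"])
        na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
        if (na > 0 && nb > 0)
          angle_p[k] <- acos(max(-1, min(1, sum(a * b) / (na * nb))))
      }
    }
    cbind(m, angle_v = angle_v, angle_p = angle_p)
  })
  ds <- set_trajectories(ds, use, arr)
  add_provenance(ds, "add_angles", list(use = use))
}
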