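#' Remap trajectories to a common side
#'
#' Mirrors each trajectory about the vertical line through its start point
#' so that all movements end on the same side. The side of a trajectory is
#' decided by the x sign of its last point relative to its first point; an
#' exact tie (no net horizontal displacement) counts as already being on the
#' target side and is left untouched. The operation is idempotent.
#'
#' @param ds A `track_data` object.
#' @param use Representation to transform (in place).
#' @param target_side `"left"` or `"right"`.
#' @param remap_y Also mirror vertically (about the start y) trials that end
#'   below their start; for designs with vertically mirrored layouts.
#' @return The transformed `track_data` object.
#' @export
remap_symmetric <- function(ds, use = "trajectories",
                            target_side = c("left", "right"),
                            remap_y = FALSE) {
  target_side <- match.arg(target_side)
  sgn <- if (target_side == "left") -1 else 1
  n_flipped <- 0L
  arr <- map_trials(get_trajectories(ds, use), function(m, i) {
    dx <- m[nrow(m), "xpos"] - m[1L, "xpos"]
    if (sign(dx) == -sgn) {      # ends on the non-target side
      m[, "xpos"] <- 2 * m[1L, "xpos"] - m[, "xpos"]
      n_flipped <<- n_flipped + 1L
    }
    if (remap_y) {
      dy <- m[nrow(m), "ypos"] - m[1L, "ypos"]
      if (dy < 0) m[, "ypos"] <- 2 * m[1L, "ypos"] - m[, "ypos"]
    }
    m
  })
  ds <- set_trajectories(ds, use, arr)
  add_provenance(ds, "remap_symmetric",
                 list(use = use, target_side = target_side,
                      remap_y = remap_y, flipped = n_flipped))
}

#' Align trajectory start positions
#'
#' Translates every trial so that its first point lies at `start`. A rigid
#' motion: all pairwise point distances are preserved exactly.
#'
#' @inheritParams remap_symmetric
#' @param start numeric length-2 target start position `(x, y)`.
#' @return The transformed `track_data` object.
#' @export
align_start <- function(ds, use = "trajectories", start = c(0, 0)) {
  arr <- map_trials(get_trajectories(ds, use), function(m, i) {
    m[, "xpos"] <- m[, "xpos"] - m[1L, "xpos"] + start[1L]
    m[, "ypos"] <- m[, "ypos"] - m[1L, "ypos"] + start[2L]
    m
  })
  ds <- set_trajectories(ds, use, arr)
  add_provenance(ds, "align_start", list(use = use, start = start))
}

#' Align trajectory start and end positions
#'
#' Applies, per trial and per axis, the affine map sending the trial's
#' (start, end) to the requested (start, end). This stretches or compresses
#' the dimensions and therefore loses the original pixel metric.
#'
#' @inheritParams align_start
#' @param end numeric length-2 target end position.
#' @return The transformed `track_data` object.
#' @export
align_start_end <- function(ds, use = "trajectories",
                            start = c(0, 0), end = c(-1, 1.5)) {
  arr <- map_trials(get_trajectories(ds, use), function(m, i) {
    L <- nrow(m)
    for (ax in c("xpos", "ypos")) {
      j <- if (ax == "xpos") 1L else 2L
      extent <- m[L, ax] - m[1L, ax]
      if (extent == 0)
        stop("trial '", dimnames(get_trajectories(ds, use))[[1L]][i],
             "' has zero extent on ", ax, "; cannot rescale")
      m[, ax] <- start[j] + (m[, ax] - m[1L, ax]) * (end[j] - start[j]) / extent
    }
    m
  })
  ds <- set_trajectories(ds, use, arr)
  add_provenance(ds, "align_start_end",
                 list(use = use, start = start, end = end))
}

# --- resampling -------------------------------------------------------------

# Linear interpolation of every feature channel against a reference axis,
# tolerating duplicated reference values (first occurrence wins).
interp_features <- function(m, ref, ref_out, features) {
  keep <- !duplicated(ref)
  out <- matrix(NA_real_, nrow = length(ref_out), ncol = length(features),
                dimnames = list(NULL, features))
  for (f in features) {
    v <- m[keep, f]
    ok <- !is.na(v)
    if (sum(ok) >= 2L)
      out[, f] <- stats::approx(ref[keep][ok], v[ok], xout = ref_out,
                                rule = 2)$y
    else if (sum(ok) == 1L) out[, f] <- v[ok]
  }
  out
}

resample_one <- function(m, mode, n_steps, n_points, interval_ms, trial_id) {
  features <- colnames(m)
  t <- m[, "timestamps"]
  L <- nrow(m)
  if (mode == "time") {
    t_new <- seq(t[1L], t[L], length.out = n_steps)
    out <- interp_features(m, t, t_new, setdiff(features, "timestamps"))
    out <- cbind(timestamps = t_new, out)
    # endpoints exactly preserved
    out[1L, features] <- m[1L, features]
    out[n_steps, features] <- m[L, features]
    out[, colnames(m), drop = FALSE]
  } else if (mode == "length") {
    seg <- sqrt(diff(m[, "xpos"])^2 + diff(m[, "ypos"])^2)
    s <- c(0, cumsum(seg))
    if (s[L] == 0) {
      warning("trial '", trial_id, "' has zero path length; ",
              "all points set to its single location")
      out <- m[rep(1L, n_points), , drop = FALSE]
      out[, "timestamps"] <- seq(t[1L], t[L], length.out = n_points)
      return(out)
    }
    s_new <- seq(0, s[L], length.out = n_points)
    out <- interp_features(m, s, s_new, features)
    out[1L, features] <- m[1L, features]
    out[n_points, features] <- m[L, features]
    out
  } else { # constant interval
    t_new <- seq(t[1L], t[L], by = interval_ms)
    if (t_new[length(t_new)] < t[L] - 1e-9) t_new <- c(t_new, t[L])
    out <- interp_features(m, t, t_new, setdiff(features, "timestamps"))
    cbind(timestamps = t_new, out)[, colnames(m), drop = FALSE]
  }
}

#' Resample trajectories
#'
#' Three interpolation-based resampling modes, all piecewise linear:
#' \describe{
#'   \item{time}{`n_steps` temporally equidistant points spanning each
#'     trial's recorded duration (time normalization; conventionally 101).}
#'   \item{length}{`n_points` spatially equidistant points along the x/y
#'     polyline (length normalization; conventionally 20); timestamps are
#'     carried by linear interpolation in arc length.}
#'   \item{constant}{timestamps at multiples of `interval_ms` from the first
#'     timestamp; the final timestamp is appended when the grid misses it.}
#' }
#' Endpoints are always preserved exactly. The source representation is left
#' untouched; the result is stored under `save_as`.
#'
#' @inheritParams remap_symmetric
#' @param mode one of `"time"`, `"length"`, `"constant"`.
#' @param n_steps points for time normalization (>= 2).
#' @param n_points points for length normalization (>= 2).
#' @param interval_ms sampling interval for constant-interval resampling.
#' @param save_as name of the new representation.
#' @return `track_data` with the resampled representation added.
#' @export
resample_trajectories <- function(ds, use = "trajectories",
                                  mode = c("time", "length", "constant"),
                                  n_steps = 101L, n_points = 20L,
                                  interval_ms = NULL,
                                  save_as = NULL) {
  mode <- match.arg(mode)
  if (mode == "time" && n_steps < 2L) stop("n_steps must be >= 2")
  if (mode == "length" && n_points < 2L) stop("n_points must be >= 2")
  if (mode == "constant" && (is.null(interval_ms) || interval_ms <= 0))
    stop("interval_ms must be a positive number")
  if (is.null(save_as))
    save_as <- switch(mode, time = "tn_trajectories",
                      length = "ln_trajectories", constant = "ci_trajectories")
  arr <- get_trajectories(ds, use)
  if (any(valid_lengths(ds, use) < 2L))
    stop("all trials need at least 2 valid points")
  ids <- dimnames(arr)[[1L]]
  new <- map_trials(arr, function(m, i)
    resample_one(m, mode, n_steps, n_points, interval_ms, ids[i]))
  ds <- set_trajectories(ds, save_as, new)
  add_provenance(ds, "resample_trajectories",
                 list(use = use, mode = mode, n_steps = n_steps,
                      n_points = n_points, interval_ms = interval_ms,
                      save_as = save_as))
}

#' @rdname resample_trajectories
#' @export
time_normalize <- function(ds, use = "trajectories", n_steps = 101L,
                           save_as = "tn_trajectories")
  resample_trajectories(ds, use, "time", n_steps = n_steps, save_as = save_as)

#' @rdname resample_trajectories
#' @export
length_normalize <- function(ds, use = "trajectories", n_points = 20L,
                             save_as = "ln_trajectories")
  resample_trajectories(ds, use, "length", n_points = n_points,
                        save_as = save_as)

#' Flag outlier trials by prototype distance
#'
#' Maps every trajectory to its closest prototype (see
#' [map_to_prototypes()]), standardizes the distances within each mapped
#' prototype group, and flags trials whose standardized distance exceeds
#' `z_threshold` (default 2 standard deviations) as anomalous.
#'
#' @inheritParams remap_symmetric
#' @param prototypes a [standard_prototypes()]-style prototype set.
#' @param n_points length-normalization resolution used for the mapping.
#' @param z_threshold flag trials with z-distance above this value.
#' @return `track_data` whose trial table gains the columns
#'   `prototype_label`, `prototype_distance`, `z_distance`, and `outlier`.
#' @export
flag_outliers_by_prototype <- function(ds, use = "trajectories",
                                       prototypes = standard_prototypes(),
                                       n_points = 20L, z_threshold = 2) {
  asg <- map_to_prototypes(ds, use = use, prototypes = prototypes,
                           n_points = n_points)
  z <- asg$z_distance
  small <- table(asg$label)[as.character(asg$label)] < 3L
  if (any(small, na.rm = TRUE)) {
    warning("prototype group(s) with fewer than 3 members; ",
            "z-distance undefined there, not flagged")
    z[small] <- NA_real_
  }
  flag <- !is.na(z) & z > z_threshold
  tt <- ds$trial_table
  tt$prototype_label <- asg$label
  tt$prototype_distance <- asg$distance
  tt$z_distance <- z
  tt$outlier <- flag
  ds$trial_table <- tt
  add_provenance(ds, "flag_outliers_by_prototype",
                 list(use = use, z_threshold = z_threshold,
                      flagged = sum(flag)))
}
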