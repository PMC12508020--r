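#' Specification for the synthetic two-option tracking generator
#'
#' Describes a simulated forced-choice categorization study: participants
#' click a start button at the bottom center of the screen and move to one
#' of two response boxes in the top corners. Defaults emulate the scale of a
#' typical 60-participant, 19-trials-each categorization experiment on a
#' full-HD screen: chosen option at `(-665, 974)` px relative to the start,
#' 100-Hz sampling, trajectories clamped to 72--2159 samples, and per-trial
#' movement-type mixtures (straight / curved / cCoM / dCoM / dCoM2) that
#' shift mass from straight (68% vs 52%) toward change-of-mind types in the
#' `atypical` condition.
#'
#' @param n_subjects number of simulated participants.
#' @param trials_per_condition named counts of trials per subject and
#'   condition.
#' @param start,chosen,nonchosen layout positions in px (y up).
#' @param type_mixture named list (one entry per condition) of probability
#'   vectors over the five movement types, each summing to 1.
#' @param noise_sd isotropic Gaussian positional noise (px) added to moving
#'   samples; idle samples repeat their position exactly, as a resting
#'   physical pointer does.
#' @param sampling_interval_ms nominal sampling interval.
#' @param jitter_ms uniform sampling jitter on interior timestamps
#'   (must stay below half the interval).
#' @param initiation_meanlog,initiation_sdlog lognormal parameters of the
#'   pre-movement idle duration (ms).
#' @param move_meanlog,move_sdlog lognormal parameters of the total
#'   movement duration (ms); change-of-mind paths take proportionally
#'   longer because their arcs are longer.
#' @param pause_mean_ms,pause_sd_ms normal parameters (truncated at 20 ms)
#'   of the stationary pause between successive submovements of discrete
#'   change-of-mind movements.
#' @param min_samples,max_samples clamp on the per-trial sample count.
#' @param error_rate probability that a trial is marked as an erroneous
#'   response in the `correct` column.
#' @param seed integer RNG seed (mandatory: generated datasets are
#'   reproducible by construction).
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(n_subjects = 60L,
                       trials_per_condition = c(typical = 10L, atypical = 9L),
                       start = c(0, 0), chosen = c(-665, 974),
                       nonchosen = c(665, 974),
                       type_mixture = list(
                         typical = c(straight = 506, curved = 116,
                                     cCoM = 54, dCoM = 52, dCoM2 = 16) / 744,
                         atypical = c(straight = 165, curved = 38,
                                      cCoM = 37, dCoM = 56, dCoM2 = 24) / 320),
                       noise_sd = 8, sampling_interval_ms = 10,
                       jitter_ms = 1,
                       initiation_meanlog = log(250), initiation_sdlog = 0.4,
                       move_meanlog = log(1100), move_sdlog = 0.35,
                       pause_mean_ms = 150, pause_sd_ms = 50,
                       min_samples = 72L, max_samples = 2159L,
                       error_rate = 0.067, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  if (!identical(sort(names(type_mixture)),
                 sort(names(trials_per_condition))))
    stop("type_mixture and trials_per_condition must name the same conditions")
  for (cond in names(type_mixture)) {
    p <- type_mixture[[cond]]
    if (any(p < 0)) stop("negative mixture probability in ", cond)
    if (abs(sum(p) - 1) > 1e-8) stop("mixture for ", cond, " must sum to 1")
  }
  stopifnot(sampling_interval_ms > 0, jitter_ms >= 0,
            jitter_ms < sampling_interval_ms / 2,
            noise_sd >= 0, min_samples >= 2L, max_samples > min_samples,
            error_rate >= 0, error_rate <= 1)
  structure(list(n_subjects = as.integer(n_subjects),
                 trials_per_condition = trials_per_condition,
                 start = start, chosen = chosen, nonchosen = nonchosen,
                 type_mixture = type_mixture, noise_sd = noise_sd,
                 sampling_interval_ms = sampling_interval_ms,
                 jitter_ms = jitter_ms,
                 initiation_meanlog = initiation_meanlog,
                 initiation_sdlog = initiation_sdlog,
                 move_meanlog = move_meanlog, move_sdlog = move_sdlog,
                 pause_mean_ms = pause_mean_ms, pause_sd_ms = pause_sd_ms,
                 min_samples = min_samples, max_samples = max_samples,
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "synth_spec")
}

# Scale a unit-space prototype polyline to the spec layout and return the
# dense path plus the arc positions of submovement boundaries.
scaled_path <- function(label, spec, prototypes) {
  p <- prototypes[[which(prototype_labels(prototypes) == label)]]
  pts <- p$points
  sx <- (spec$chosen[1L] - spec$start[1L]) / -1
  sy <- (spec$chosen[2L] - spec$start[2L]) / 1.5
  xy <- cbind(spec$start[1L] + pts[, 1L] * sx,
              spec$start[2L] + pts[, 2L] * sy)
  # submovement split points: interior vertices of the discrete types
  splits <- switch(label,
                   dCoM = 2L, dCoM2 = c(2L, 3L), integer(0))
  # densify each leg separately so split arc positions stay exact
  seg <- sqrt(diff(xy[, 1L])^2 + diff(xy[, 2L])^2)
  s <- c(0, cumsum(seg))
  dense_s <- sort(unique(c(seq(0, s[length(s)], length.out = 200L), s)))
  u <- !duplicated(s)
  dense <- cbind(stats::approx(s[u], xy[u, 1L], xout = dense_s)$y,
                 stats::approx(s[u], xy[u, 2L], xout = dense_s)$y)
  list(path = dense, arc = dense_s, split_arc = s[splits],
       total = s[length(s)])
}

# Minimum-jerk position fraction for normalized time in [0, 1]: a smooth
# single-peaked (bell) speed profile.
min_jerk <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

# Continuous arc position s(t) for one trial: idle, then submovements with
# bell speed profiles separated by stationary pauses.
arc_at <- function(t, init, seg_start, seg_end, seg_t0, seg_t1) {
  s <- numeric(length(t))
  s[t <= init] <- 0
  for (k in seq_along(seg_t0)) {
    inside <- t > seg_t0[k] & t <= seg_t1[k]
    tau <- (t[inside] - seg_t0[k]) / (seg_t1[k] - seg_t0[k])
    s[inside] <- seg_start[k] + (seg_end[k] - seg_start[k]) * min_jerk(tau)
    after <- t > seg_t1[k]
    s[after] <- seg_end[k]
  }
  s
}

#' Generate a synthetic tracking dataset with ground truth
#'
#' Simulates every trial of the study described by a [synth_spec()]: a
#' movement type is drawn from the condition's mixture, the corresponding
#' prototype path (scaled to the layout) is traversed by one bell-profiled
#' submovement per path leg with stationary pauses between legs of discrete
#' change-of-mind types, pre-movement idle time is prepended, positions are
#' sampled at the (jittered) sampling interval, and isotropic Gaussian noise
#' is added to moving samples. Deterministic given the seed.
#'
#' @param spec a `synth_spec`.
#' @return list with `data` (a [track_data()] whose trial table holds
#'   `subject_id`, `condition`, `correct`) and `truth` (per-trial type
#'   label, timing decomposition, and submovement boundaries in
#'   `attr(truth, "boundaries")`).
#' @export
#' @examples
#' out <- generate_tracking_data(synth_spec(n_subjects = 3, seed = 42))
#' out$data
#' table(out$truth$type)
generate_tracking_data <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  prototypes <- standard_prototypes()
  conds <- names(spec$trials_per_condition)
  iv <- spec$sampling_interval_ms
  min_T <- (spec$min_samples - 1L) * iv
  max_T <- (spec$max_samples - 1L) * iv

  mats <- list(); meta <- list(); truth <- list(); bounds <- list()
  trial_no <- 0L
  for (subj in seq_len(spec$n_subjects)) {
    sid <- sprintf("S%02d", subj)
    cond_seq <- sample(rep(conds, times = spec$trials_per_condition))
    for (k in seq_along(cond_seq)) {
      trial_no <- trial_no + 1L
      cond <- cond_seq[k]
      mix <- spec$type_mixture[[cond]]
      label <- sample(names(mix), 1L, prob = mix)
      sp <- scaled_path(label, spec, prototypes)

      init <- stats::rlnorm(1L, spec$initiation_meanlog, spec$initiation_sdlog)
      move <- stats::rlnorm(1L, spec$move_meanlog, spec$move_sdlog) *
        sp$total / sqrt(sum((spec$chosen - spec$start)^2))
      seg_bounds <- c(0, sp$split_arc, sp$total)
      n_sub <- length(seg_bounds) - 1L
      seg_len <- diff(seg_bounds)
      seg_dur <- move * seg_len / sum(seg_len)
      pauses <- if (n_sub > 1L)
        pmax(20, stats::rnorm(n_sub - 1L, spec$pause_mean_ms,
                              spec$pause_sd_ms)) else numeric(0)
      total <- init + sum(seg_dur) + sum(pauses)
      # clamp the trial duration into the supported sample-count range by
      # rescaling the moving part (idle kept as drawn)
      if (total < min_T || total > max_T) {
        target <- min(max(total, min_T), max_T)
        f <- (target - init) / (sum(seg_dur) + sum(pauses))
        if (f <= 0) { init <- target * 0.2; f <- target * 0.8 /
          (sum(seg_dur) + sum(pauses)) }
        seg_dur <- seg_dur * f
        pauses <- pauses * f
        total <- init + sum(seg_dur) + sum(pauses)
      }
      seg_t0 <- init + c(0, cumsum(seg_dur[-n_sub] +
                                   pauses))[seq_len(n_sub)]
      seg_t1 <- seg_t0 + seg_dur

      K <- round(total / iv)
      t <- (0:K) * iv
      if (K >= 2L && spec$jitter_ms > 0)
        t[2:K] <- t[2:K] + stats::runif(K - 1L, -spec$jitter_ms,
                                        spec$jitter_ms)
      s_t <- arc_at(t, init, seg_bounds[-(n_sub + 1L)], seg_bounds[-1L],
                    seg_t0, seg_t1)
      s_t <- pmin(pmax(s_t, 0), sp$total)   # guard rounding overshoot
      u <- !duplicated(sp$arc)
      xs <- stats::approx(sp$arc[u], sp$path[u, 1L], xout = s_t)$y
      ys <- stats::approx(sp$arc[u], sp$path[u, 2L], xout = s_t)$y
      if (spec$noise_sd > 0) {
        moving <- c(FALSE, diff(s_t) > 0)
        nm <- sum(moving)
        xs[moving] <- xs[moving] + stats::rnorm(nm, 0, spec$noise_sd)
        ys[moving] <- ys[moving] + stats::rnorm(nm, 0, spec$noise_sd)
      }
      tid <- paste0(sid, "_", k)
      mats[[trial_no]] <- cbind(timestamps = t, xpos = xs, ypos = ys)
      meta[[trial_no]] <- data.frame(
        trial_id = tid, subject_id = sid, condition = cond,
        correct = stats::rbinom(1L, 1L, 1 - spec$error_rate),
        stringsAsFactors = FALSE)
      truth[[trial_no]] <- data.frame(
        trial_id = tid, subject_id = sid, condition = cond, type = label,
        init_ms = init, move_ms = sum(seg_dur), pause_ms = sum(pauses),
        rt_ms = t[length(t)], n_samples = length(t),
        stringsAsFactors = FALSE)
      bounds[[tid]] <- cbind(start = seg_t0, end = seg_t1)
    }
  }
  tt <- do.call(rbind, meta)
  rownames(tt) <- NULL
  ids <- tt$trial_id
  arr <- build_array(mats, ids, c("timestamps", "xpos", "ypos"))
  ds <- track_data(tt, list(trajectories = arr))
  ds <- add_provenance(ds, "generate_tracking_data",
                       list(seed = spec$seed,
                            n_subjects = spec$n_subjects,
                            n_trials = length(ids)))
  tr <- do.call(rbind, truth)
  rownames(tr) <- NULL
  attr(tr, "boundaries") <- bounds
  list(data = ds, truth = tr)
}

#' Inject a condition effect into a window of time steps
#'
#' Adds `magnitude` to one feature channel for the trials of `target`
#' condition, but only inside the given step window of a time-normalized
#' representation -- a controlled ground truth for validating per-step
#' tests.
#'
#' @inheritParams remap_symmetric
#' @param truth ground-truth table from [generate_tracking_data()].
#' @param feature feature channel to shift.
#' @param window integer `c(first, last)` step window.
#' @param magnitude additive shift (a `magnitude` of 0 leaves the dataset
#'   unchanged).
#' @param condition_col,target trial-table column and value receiving the
#'   shift.
#' @return list with the modified `data` and a `truth` table whose
#'   `attr(, "effect")` records the programmed window.
#' @export
inject_step_effect <- function(ds, truth, feature = "xpos",
                               window, magnitude,
                               use = "tn_trajectories",
                               condition_col = "condition",
                               target = "atypical") {
  arr <- get_trajectories(ds, use)
  if (!feature %in% dimnames(arr)[[3L]])
    stop("unknown feature '", feature, "'")
  nsteps <- dim(arr)[2L]
  stopifnot(length(window) == 2L, window[1L] >= 1L, window[2L] <= nsteps,
            window[1L] <= window[2L])
  rows <- ds$trial_table[[condition_col]] == target
  arr[rows, window[1L]:window[2L], feature] <-
    arr[rows, window[1L]:window[2L], feature] + magnitude
  ds <- set_trajectories(ds, use, arr)
  ds <- add_provenance(ds, "inject_step_effect",
                       list(feature = feature, window = window,
                            magnitude = magnitude, target = target))
  attr(truth, "effect") <- list(feature = feature, window = window,
                                magnitude = magnitude, target = target)
  list(data = ds, truth = truth)
}
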