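# Sign factor shared by the deviation and area computations. Raw deviations
# are measured along the left-of-travel normal; positive final deviations
# must point toward the nonchosen side, i.e. the horizontal side opposite
# the endpoint (positive x after left-remapping; a trial ending on the
# start vertical counts as leftward). For a purely horizontal ideal line
# the convention degenerates; "above the line" is taken as positive.
deviation_sign <- function(m) {
  L <- nrow(m)
  dxL <- m[L, "xpos"] - m[1L, "xpos"]
  dyL <- m[L, "ypos"] - m[1L, "ypos"]
  len <- sqrt(dxL^2 + dyL^2)
  if (len == 0) return(NULL)
  nrm <- c(-dyL, dxL) / len              # left-of-travel unit normal
  target <- if (dxL > 0) -1 else 1       # x sign of the nonchosen side
  ff <- if (nrm[1L] != 0) {
    if (sign(nrm[1L]) == target) 1 else -1
  } else sign(nrm[2L])
  list(nrm = nrm, ff = ff, len = len)
}

# Signed perpendicular deviations of recorded points from the straight
# segment joining a trial's first and last point.
signed_deviations <- function(m) {
  g <- deviation_sign(m)
  if (is.null(g)) return(NULL)
  raw <- (m[, "xpos"] - m[1L, "xpos"]) * g$nrm[1L] +
         (m[, "ypos"] - m[1L, "ypos"]) * g$nrm[2L]
  g$ff * raw
}

# Shoelace area of the polygon formed by the trajectory closed with the
# reversed ideal segment, with the same side convention as the deviations
# (the shoelace orientation term is positive for right-of-travel bulges,
# hence the -ff factor).
signed_auc <- function(m) {
  g <- deviation_sign(m)
  if (is.null(g)) return(NULL)
  L <- nrow(m)
  x <- m[, "xpos"]; y <- m[, "ypos"]
  area <- 0.5 * (sum(x[-L] * y[-1L] - x[-1L] * y[-L]) +
                 x[L] * y[1L] - x[1L] * y[L])
  -g$ff * area
}

count_flips <- function(v, threshold = 0) {
  d <- diff(v)
  d <- d[abs(d) > threshold]
  if (length(d) < 2L) return(0L)
  s <- sign(d)
  sum(s[-1L] != s[-length(s)])
}

count_reversals <- function(x) {
  rel <- x - x[1L]
  rel <- rel[rel != 0]
  if (length(rel) < 2L) return(0L)
  s <- sign(rel)
  sum(s[-1L] != s[-length(s)])
}

#' Trial-level trajectory indices
#'
#' Computes, per trial, the standard curvature, complexity, and temporal
#' indices of two-option reach trajectories. The idealized trajectory is the
#' straight segment from the trial's first to its last recorded point;
#' pointwise deviations are signed perpendicular distances to that segment,
#' positive toward the nonchosen side (positive x after left-remapping).
#'
#' \describe{
#'   \item{MAD}{signed deviation of maximal absolute value (ties: earliest
#'     point); `MAD_time` is its timestamp.}
#'   \item{MD_above}{largest deviation toward the nonchosen side, floored at
#'     0.}
#'   \item{AD}{mean signed deviation over all recorded points.}
#'   \item{AUC}{signed area between trajectory and ideal segment (shoelace
#'     over the closed polygon); area on the chosen side is subtracted.}
#'   \item{x_flips, y_flips}{direction changes along an axis: sign
#'     alternations among successive deltas after discarding deltas with
#'     absolute value `<= flip_threshold`.}
#'   \item{x_reversals}{strict sign changes of the x position relative to
#'     the start x (midline crossings); samples exactly on the midline are
#'     skipped.}
#'   \item{RT}{`t_last - t_first` (ms).}
#'   \item{movement_time}{summed inter-sample intervals with nonzero
#'     displacement (beyond `jitter_tol`).}
#'   \item{idle_time}{`RT - movement_time`.}
#'   \item{initiation_time}{idle duration before movement onset: the
#'     timestamp of the last sample still at the start position
#'     (`initiation = "last_still"`, the default) or of the first moved
#'     sample (`initiation = "first_moved"`).}
#'   \item{motor_pauses}{`idle_time - initiation_time` (computed under the
#'     `last_still` definition).}
#'   \item{vel_max, acc_max}{maxima of the velocity and acceleration
#'     channels when [add_derivatives()] has been applied.}
#' }
#'
#' Trials whose first and last points coincide have no ideal segment; their
#' curvature indices are `NA` and a message reports the count.
#'
#' @inheritParams remap_symmetric
#' @param flip_threshold ignore per-sample deltas up to this magnitude (px)
#'   when counting flips.
#' @param jitter_tol displacement (px) up to which a sample still counts as
#'   stationary for the temporal indices.
#' @param initiation onset convention, see above.
#' @return data.frame (one row per trial) keyed by `trial_id`.
#' @export
#' @examples
#' ds <- generate_tracking_data(synth_spec(n_subjects = 2, seed = 1))$data
#' head(compute_measures(ds))
compute_measures <- function(ds, use = "trajectories", flip_threshold = 0,
                             jitter_tol = 0,
                             initiation = c("last_still", "first_moved")) {
  initiation <- match.arg(initiation)
  arr <- get_trajectories(ds, use)
  ids <- dimnames(arr)[[1L]]
  has_kin <- all(c("vel", "acc") %in% dimnames(arr)[[3L]])
  n <- length(ids)
  out <- data.frame(trial_id = ids,
                    MAD = NA_real_, MAD_time = NA_real_, MD_above = NA_real_,
                    AD = NA_real_, AUC = NA_real_,
                    x_flips = NA_integer_, y_flips = NA_integer_,
                    x_reversals = NA_integer_,
                    initiation_time = NA_real_, idle_time = NA_real_,
                    movement_time = NA_real_, motor_pauses = NA_real_,
                    RT = NA_real_, stringsAsFactors = FALSE)
  if (has_kin) { out$vel_max <- NA_real_; out$acc_max <- NA_real_ }
  degenerate <- 0L
  for (i in seq_len(n)) {
    keep <- !is.na(arr[i, , "timestamps"])
    m <- matrix(arr[i, keep, ], nrow = sum(keep),
                dimnames = list(NULL, dimnames(arr)[[3L]]))
    L <- nrow(m)
    t <- m[, "timestamps"]
    dev <- signed_deviations(m)
    if (is.null(dev)) {
      degenerate <- degenerate + 1L
    } else {
      imax <- which.max(abs(dev))
      out$MAD[i] <- dev[imax]
      out$MAD_time[i] <- t[imax]
      out$MD_above[i] <- max(0, max(dev))
      out$AD[i] <- mean(dev)
      out$AUC[i] <- signed_auc(m)
    }
    out$x_flips[i] <- count_flips(m[, "xpos"], flip_threshold)
    out$y_flips[i] <- count_flips(m[, "ypos"], flip_threshold)
    out$x_reversals[i] <- count_reversals(m[, "xpos"])

    disp <- sqrt(diff(m[, "xpos"])^2 + diff(m[, "ypos"])^2)
    moving <- disp > jitter_tol
    rt <- t[L] - t[1L]
    mt <- sum(diff(t)[moving])
    from_start <- sqrt((m[, "xpos"] - m[1L, "xpos"])^2 +
                       (m[, "ypos"] - m[1L, "ypos"])^2)
    first_moved <- which(from_start > jitter_tol)[1L]
    init <- if (is.na(first_moved)) rt
            else if (initiation == "last_still") t[first_moved - 1L]
            else t[first_moved]
    out$RT[i] <- rt
    out$movement_time[i] <- mt
    out$idle_time[i] <- rt - mt
    out$initiation_time[i] <- init
    out$motor_pauses[i] <- (rt - mt) -
      (if (is.na(first_moved)) rt else t[first_moved - 1L])
    if (has_kin) {
      if (any(!is.na(m[, "vel"]))) out$vel_max[i] <- max(m[, "vel"], na.rm = TRUE)
      if (any(!is.na(m[, "acc"]))) out$acc_max[i] <- max(m[, "acc"], na.rm = TRUE)
    }
  }
  if (degenerate > 0L)
    message(degenerate, " trial(s) with coincident first and last point; ",
            "curvature indices set to NA")
  out
}

#' Sample entropy of a numeric series
#'
#' Quantifies temporal self-similarity: `-log(A/B)` where `B` counts ordered
#' pairs of distinct m-length templates whose Chebyshev distance is at most
#' `r`, and `A` counts the same for (m+1)-length templates. Self-matches are
#' excluded. Low values indicate high self-similarity; a constant or
#' strictly periodic series yields 0.
#'
#' @param series numeric vector (length > m + 1; `NA`s removed).
#' @param m template length (default 3).
#' @param r matching tolerance; defaults to `0.2 * sd(series)`.
#' @return Sample entropy (non-negative), or `NA` with a warning when no
#'   template pair matches at either length.
#' @export
sample_entropy <- function(series, m = 3L, r = NULL) {
  series <- as.numeric(series[!is.na(series)])
  N <- length(series)
  if (N < m + 2L) stop("series must be longer than m + 1")
  if (is.null(r)) r <- 0.2 * stats::sd(series)
  if (!is.finite(r) || r <= 0) stop("tolerance r must be positive")
  n_tpl <- N - m              # templates usable at both lengths
  idx <- seq_len(n_tpl)
  cheb_m <- matrix(0, n_tpl, n_tpl)
  for (k in 0:(m - 1L)) {
    v <- series[idx + k]
    cheb_m <- pmax(cheb_m, abs(outer(v, v, "-")))
  }
  v <- series[idx + m]
  cheb_m1 <- pmax(cheb_m, abs(outer(v, v, "-")))
  B <- sum(cheb_m <= r) - n_tpl   # exclude self-matches
  A <- sum(cheb_m1 <= r) - n_tpl
  if (A == 0L || B == 0L) {
    warning("no matching templates; sample entropy undefined")
    return(NA_real_)
  }
  log(B) - log(A)   # == -log(A/B), avoiding a negative-zero result
}

#' Per-trial sample entropy of a trajectory dimension
#'
#' Applies [sample_entropy()] to one feature channel of each trial
#' (conventionally the x positions of time-normalized trajectories, where
#' all trials share the same series length).
#'
#' @inheritParams remap_symmetric
#' @param dimension feature channel to analyze.
#' @param m,r see [sample_entropy()]; `r = NULL` uses 0.2 x the per-trial SD.
#' @param measures optional measures table to merge the result into.
#' @return data.frame `trial_id`, `sample_entropy` (merged into `measures`
#'   when supplied).
#' @export
add_sample_entropy <- function(ds, use = "tn_trajectories",
                               dimension = "xpos", m = 3L, r = NULL,
                               measures = NULL) {
  arr <- get_trajectories(ds, use)
  ids <- dimnames(arr)[[1L]]
  se <- vapply(seq_along(ids), function(i) {
    s <- arr[i, , dimension]
    s <- s[!is.na(s)]
    tryCatch(suppressWarnings(sample_entropy(s, m = m, r = r)),
             error = function(e) NA_real_)
  }, numeric(1))
  res <- data.frame(trial_id = ids, sample_entropy = se,
                    stringsAsFactors = FALSE)
  if (is.null(measures)) res else merge(measures, res, by = "trial_id",
                                        sort = FALSE)
}

#' Standardize variables within groups
#'
#' Z-scores the requested columns, optionally within a grouping column
#' (typically the subject), writing `z_`-prefixed columns.
#'
#' @param data data.frame.
#' @param variables columns to standardize.
#' @param within optional grouping column name (e.g. `"subject_id"`).
#' @param prefix prefix for the standardized columns.
#' @return `data` with the standardized columns appended/replaced.
#' @export
standardize_variables <- function(data, variables, within = NULL,
                                  prefix = "z_") {
  stopifnot(all(variables %in% names(data)))
  g <- if (is.null(within)) rep(1L, nrow(data)) else data[[within]]
  warned <- FALSE
  for (v in variables) {
    z <- stats::ave(data[[v]], g, FUN = function(x) {
      ok <- !is.na(x)
      if (sum(ok) < 2L || stats::sd(x[ok]) == 0) return(rep(NA_real_, length(x)))
      (x - mean(x[ok])) / stats::sd(x[ok])
    })
    if (anyNA(z) && !all(is.na(data[[v]]) == is.na(z))) warned <- TRUE
    data[[paste0(prefix, v)]] <- z
  }
  if (warned)
    warning("group(s) with zero spread or fewer than 2 values; z set to NA")
  data
}

#' Aggregate measures within conditions and/or subjects
#'
#' Arithmetic means per group. When both `by` and `subject_col` are given,
#' values are first averaged within subject x group and the subject means
#' are then averaged per group (unweighted), so subjects contribute equally
#' regardless of trial counts.
#'
#' @param data measures joined with trial metadata (see
#'   [export_measures()]).
#' @param use_variables numeric columns to aggregate; defaults to all
#'   numeric columns except identifiers.
#' @param by grouping column name(s), e.g. a condition.
#' @param subject_col optional subject column for two-stage aggregation.
#' @return data.frame of group means.
#' @export
aggregate_measures <- function(data, use_variables = NULL, by = NULL,
                               subject_col = NULL) {
  if (is.null(use_variables))
    use_variables <- setdiff(names(data)[vapply(data, is.numeric, TRUE)],
                             c("trial_id", by, subject_col))
  stopifnot(all(use_variables %in% names(data)))
  agg <- function(d, keys) {
    if (is.null(keys)) {
      out <- as.data.frame(lapply(d[use_variables], mean, na.rm = TRUE))
      return(out)
    }
    stats::aggregate(d[use_variables], by = d[keys],
                     FUN = mean, na.rm = TRUE)
  }
  if (!is.null(subject_col)) {
    lvl1 <- agg(data, c(subject_col, by))
    agg(lvl1, by)
  } else {
    agg(data, by)
  }
}

# Default index set: four curvature, three complexity, four temporal.
.default_indices <- c("MAD", "MD_above", "AD", "AUC",
                      "x_flips", "x_reversals", "sample_entropy",
                      "RT", "initiation_time", "idle_time", "movement_time")

#' Correlation report across trajectory indices
#'
#' Pairwise-complete correlations between the trial-level indices. With
#' `method = "both"` the lower triangle holds Pearson and the upper triangle
#' Spearman correlations (the conventional display).
#'
#' @param measures measures table (see [compute_measures()],
#'   [add_sample_entropy()]).
#' @param method `"pearson"`, `"spearman"`, or `"both"`.
#' @param variables index columns to include; defaults to the standard
#'   eleven (intersected with what is present).
#' @return correlation matrix.
#' @export
index_correlations <- function(measures,
                               method = c("pearson", "spearman", "both"),
                               variables = NULL) {
  method <- match.arg(method)
  if (is.null(variables))
    variables <- intersect(.default_indices, names(measures))
  x <- as.matrix(measures[variables])
  if (sum(stats::complete.cases(x)) < 3L)
    stop("need at least 3 complete rows")
  const <- apply(x, 2L, function(v) stats::sd(v, na.rm = TRUE) == 0)
  if (any(const, na.rm = TRUE))
    warning("constant column(s): ", paste(variables[const], collapse = ", "),
            "; correlations undefined there")
  cor2 <- function(meth) suppressWarnings(
    stats::cor(x, use = "pairwise.complete.obs", method = meth))
  if (method == "both") {
    p <- cor2("pearson"); s <- cor2("spearman")
    out <- p
    out[upper.tri(out)] <- s[upper.tri(s)]
    out
  } else cor2(method)
}
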