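# Step x trial value matrix of one feature from an equal-length
# representation (time-normalized by convention).
step_matrix <- function(ds, use, feature) {
  arr <- get_trajectories(ds, use)
  if (!feature %in% dimnames(arr)[[3L]])
    stop("feature '", feature, "' not present in '", use, "'; compute it ",
         "first (add_derivatives()/add_angles())")
  vl <- valid_lengths(ds, use)
  if (length(unique(vl)) != 1L)
    stop("trials differ in point counts; time-normalize first")
  M <- arr[, , feature, drop = FALSE]
  dim(M) <- dim(arr)[1:2]         # trials x steps, robust to single trials
  rownames(M) <- dimnames(arr)[[1L]]
  M
}

#' Per-time-step aggregates of a trajectory feature
#'
#' Means, SDs, and counts of one feature channel at every time step,
#' optionally split by a trial-table grouping column. Requires a
#' representation in which all trials share the same number of points
#' (see [time_normalize()]).
#'
#' @inheritParams remap_symmetric
#' @param feature feature channel (e.g. `"xpos"`, `"angle_v"`).
#' @param group_by optional trial-table column name.
#' @return data.frame with `step`, `group`, `mean`, `sd`, `n`.
#' @export
step_aggregate <- function(ds, use = "tn_trajectories", feature = "xpos",
                           group_by = NULL) {
  M <- step_matrix(ds, use, feature)
  grp <- if (is.null(group_by)) rep("all", nrow(M))
         else as.character(ds$trial_table[[group_by]])
  out <- list()
  for (g in unique(grp)) {
    sub <- M[grp == g, , drop = FALSE]
    n <- colSums(!is.na(sub))
    out[[g]] <- data.frame(
      step = seq_len(ncol(M)), group = g,
      mean = colMeans(sub, na.rm = TRUE),
      sd = apply(sub, 2L, stats::sd, na.rm = TRUE),
      n = n, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$mean[is.nan(res$mean)] <- NA_real_
  rownames(res) <- NULL
  res
}

# OLS fit of the same design matrix against many step outcomes at once,
# with classical or CR1 cluster-robust (by subject) standard errors.
fit_steps <- function(X, Y, cluster = NULL) {
  qrX <- qr(X)
  p <- qrX$rank
  if (p < ncol(X)) return(NULL)                 # singular design
  coef <- qr.coef(qrX, Y)                       # p x nsteps
  res <- Y - X %*% coef
  XtXinv <- chol2inv(qr.R(qrX))
  n <- nrow(X)
  if (is.null(cluster)) {
    sigma2 <- colSums(res^2) / (n - p)
    se <- sqrt(pmax(outer(diag(XtXinv), sigma2), 0))
    df <- n - p
  } else {
    cl <- split(seq_len(n), cluster)
    G <- length(cl)
    meat <- array(0, dim = c(ncol(X), ncol(X), ncol(Y)))
    for (idx in cl) {
      S <- crossprod(X[idx, , drop = FALSE], res[idx, , drop = FALSE])
      for (s in seq_len(ncol(Y)))
        meat[, , s] <- meat[, , s] + tcrossprod(S[, s])
    }
    corr <- G / (G - 1) * (n - 1) / (n - p)
    se <- vapply(seq_len(ncol(Y)), function(s)
      sqrt(pmax(diag(XtXinv %*% (corr * meat[, , s]) %*% XtXinv), 0)),
      numeric(ncol(X)))
    df <- G - 1
  }
  se <- matrix(se, nrow = ncol(X))
  tval <- coef / se
  pval <- 2 * stats::pt(-abs(tval), df = df)
  pval[se == 0] <- NA_real_   # degenerate step (constant outcome)
  list(coef = coef, se = se, t = tval, p = pval, df = df)
}

# Maximal runs of consecutive TRUE at least min_run long.
significant_runs <- function(sig, min_run) {
  r <- rle(sig & !is.na(sig))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  data.frame(start = starts[keep], end = ends[keep],
             length = r$lengths[keep])
}

#' Per-time-step regression tests
#'
#' Fits, at every time step, an ordinary linear model of the feature on the
#' given trial-level predictors. With a `subject` column, standard errors
#' are cluster-robust by subject (CR1 small-sample correction, t reference
#' with G - 1 degrees of freedom) -- a pragmatic single-level substitute for
#' per-step mixed models, whose estimation is left to dedicated statistical
#' tooling. Steps with `p < alpha` for a predictor are screened into maximal
#' runs of consecutive significance, and only runs of at least `min_run`
#' steps are reported, the usual guard against the multiplicity of per-step
#' testing.
#'
#' @inheritParams step_aggregate
#' @param predictors character vector of trial-table columns.
#' @param subject optional trial-table column defining error clusters.
#' @param alpha per-step significance level.
#' @param min_run minimum length of a reported significant run.
#' @return object of class `step_tests`: list with `table` (step x term
#'   estimates, SEs, p-values) and `runs` (per-term significant intervals).
#' @export
step_tests <- function(ds, use = "tn_trajectories", feature = "xpos",
                       predictors, subject = NULL, alpha = 0.05,
                       min_run = 10L) {
  stopifnot(alpha > 0, alpha < 1, min_run >= 1L)
  M <- step_matrix(ds, use, feature)
  tt <- ds$trial_table
  stopifnot(all(predictors %in% names(tt)))
  fml <- stats::as.formula(paste("~", paste(predictors, collapse = " + ")))
  X <- stats::model.matrix(fml, tt)
  cluster <- if (is.null(subject)) NULL else as.character(tt[[subject]])
  nsteps <- ncol(M)
  terms <- colnames(X)
  tab <- expand.grid(step = seq_len(nsteps), term = terms,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab$estimate <- NA_real_; tab$se <- NA_real_; tab$p <- NA_real_

  na_steps <- apply(M, 2L, anyNA)
  fill <- function(steps, fit) {
    for (j in seq_along(terms)) {
      rows <- tab$term == terms[j] & tab$step %in% steps
      tab$estimate[rows] <<- fit$coef[j, ]
      tab$se[rows] <<- fit$se[j, ]
      tab$p[rows] <<- fit$p[j, ]
    }
  }
  clean <- which(!na_steps)
  if (length(clean)) {
    fit <- fit_steps(X, M[, clean, drop = FALSE], cluster)
    if (is.null(fit)) stop("singular design matrix")
    fill(clean, fit)
  }
  for (s in which(na_steps)) {
    ok <- !is.na(M[, s])
    if (sum(ok) <= ncol(X)) { warning("step ", s, ": too few cases"); next }
    fit <- fit_steps(X[ok, , drop = FALSE], M[ok, s, drop = FALSE],
                     if (is.null(cluster)) NULL else cluster[ok])
    if (is.null(fit)) { warning("step ", s, ": singular design"); next }
    fill(s, fit)
  }

  runs <- list()
  for (term in setdiff(terms, "(Intercept)")) {
    pv <- tab$p[tab$term == term][order(tab$step[tab$term == term])]
    r <- significant_runs(pv < alpha, min_run)
    if (nrow(r)) { r$term <- term; runs[[term]] <- r }
  }
  runs <- if (length(runs)) do.call(rbind, runs) else
    data.frame(start = integer(), end = integer(), length = integer(),
               term = character())
  rownames(runs) <- NULL
  structure(list(table = tab, runs = runs, alpha = alpha,
                 min_run = min_run), class = "step_tests")
}

#' @export
print.step_tests <- function(x, ...) {
  cat("<step_tests> ", length(unique(x$table$step)), " steps, terms: ",
      paste(unique(x$table$term), collapse = ", "), "\n", sep = "")
  if (nrow(x$runs)) {
    cat("significant runs (alpha = ", x$alpha, ", min_run = ", x$min_run,
        "):\n", sep = "")
    print(x$runs)
  } else cat("no significant runs of length >= ", x$min_run, "\n", sep = "")
  invisible(x)
}

#' Response-time-stratified per-step aggregates
#'
#' Re-runs [step_aggregate()] within response-time strata so that temporal
#' effects can be checked where absolute durations are comparable. Trials
#' slower than the last break are excluded (with a message); empty strata
#' are dropped with a warning.
#'
#' @inheritParams step_aggregate
#' @param rt_breaks strictly increasing upper stratum bounds in ms
#'   (e.g. `c(1500, 2500, 5000)`).
#' @param rt optional per-trial response times; defaults to the
#'   trial-table `RT` column or, failing that, each trial's last timestamp.
#' @return data.frame of step aggregates with a `stratum` column.
#' @export
stratified_step_aggregate <- function(ds, use = "tn_trajectories",
                                      feature = "xpos", rt_breaks,
                                      group_by = NULL, rt = NULL) {
  if (any(diff(rt_breaks) <= 0)) stop("rt_breaks must be strictly increasing")
  if (is.null(rt)) {
    rt <- if ("RT" %in% names(ds$trial_table)) ds$trial_table$RT
          else {
            arr <- get_trajectories(ds, "trajectories")
            apply(arr[, , "timestamps", drop = FALSE], 1L, max, na.rm = TRUE)
          }
  }
  over <- rt > rt_breaks[length(rt_breaks)]
  if (any(over))
    message(sum(over), " trial(s) above ", rt_breaks[length(rt_breaks)],
            " ms excluded")
  breaks <- c(0, rt_breaks)
  labels <- paste0(breaks[-length(breaks)] + c(0, rep(1, length(rt_breaks) - 1)),
                   "-", rt_breaks, " ms")
  stratum <- cut(rt, breaks = breaks, labels = labels, include.lowest = TRUE)
  out <- list()
  for (lv in labels) {
    idx <- which(!is.na(stratum) & stratum == lv & !over)
    if (!length(idx)) { warning("empty stratum ", lv, " dropped"); next }
    sub <- subset_trials(ds, trial_ids = ds$trial_table$trial_id[idx])
    agg <- step_aggregate(sub, use = use, feature = feature,
                          group_by = group_by)
    agg$stratum <- lv
    out[[lv]] <- agg
  }
  if (!length(out)) stop("all strata are empty")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Gaussian smoothing with reflected boundaries; sd in steps, 0 = identity.
gaussian_smooth <- function(v, sd) {
  if (sd <= 0) return(v)
  r <- ceiling(3 * sd)
  w <- stats::dnorm(seq(-r, r), sd = sd)
  w <- w / sum(w)
  n <- length(v)
  padded <- c(v[pmin(r + 1L - seq_len(r), n)], v,
              v[pmax(n - seq_len(r), 1L)])
  stats::filter(padded, w, sides = 2L)[(r + 1L):(r + n)]
}

#' Per-type velocity and acceleration profiles
#'
#' For each trial: leading samples still at the start position and trailing
#' stationary samples (initiation and pre-choice idle) are cropped, velocity
#' and acceleration are computed on the remaining raw samples,
#' time-normalized to `n_steps`, optionally Gaussian-smoothed across steps
#' (`smooth_sd` steps, reflected boundaries), and averaged per assigned
#' type. Discrete change-of-mind movements built from separate ballistic
#' submovements show interior velocity dips near zero.
#'
#' @inheritParams remap_symmetric
#' @param assignment a `type_assignment` aligned with the dataset.
#' @param n_steps number of normalized time steps.
#' @param smooth_sd Gaussian SD in steps (0 = no smoothing).
#' @param crop remove leading/trailing stationary samples first.
#' @return data.frame with `label`, `step`, `vel`, `acc`, `n`.
#' @export
type_kinematic_profiles <- function(ds, assignment, use = "trajectories",
                                    n_steps = 101L, smooth_sd = 2,
                                    crop = TRUE) {
  arr <- get_trajectories(ds, use)
  ids <- dimnames(arr)[[1L]]
  lab <- assignment$label[match(ids, assignment$trial_id)]
  vels <- matrix(NA_real_, length(ids), n_steps)
  accs <- matrix(NA_real_, length(ids), n_steps)
  excluded <- 0L
  for (i in seq_along(ids)) {
    keep <- !is.na(arr[i, , "timestamps"])
    t <- arr[i, keep, "timestamps"]
    xs <- arr[i, keep, "xpos"]; ys <- arr[i, keep, "ypos"]
    disp <- sqrt(diff(xs)^2 + diff(ys)^2)
    if (crop) {
      moving <- which(disp > 0)
      if (!length(moving)) { excluded <- excluded + 1L; next }
      lo <- moving[1L]            # last still sample before onset
      hi <- moving[length(moving)] + 1L   # last sample that moved
      t <- t[lo:hi]; xs <- xs[lo:hi]; ys <- ys[lo:hi]
      disp <- disp[lo:(hi - 1L)]
    }
    if (length(t) < 3L) { excluded <- excluded + 1L; next }
    vel <- disp / diff(t)
    tv <- t[-1L]
    acc <- diff(vel) / diff(t)[-1L]
    ta <- t[2:(length(t) - 1L)]
    grid <- seq(t[1L], t[length(t)], length.out = n_steps)
    vels[i, ] <- stats::approx(tv, vel, xout = grid, rule = 2)$y
    accs[i, ] <- stats::approx(ta, acc, xout = grid, rule = 2)$y
    if (smooth_sd > 0) {
      vels[i, ] <- gaussian_smooth(vels[i, ], smooth_sd)
      accs[i, ] <- gaussian_smooth(accs[i, ], smooth_sd)
    }
  }
  if (excluded > 0L)
    warning(excluded, " stationary trial(s) excluded from profiles")
  out <- list()
  for (g in levels(factor(lab))) {
    idx <- which(!is.na(lab) & lab == g & !is.na(vels[, 1L]))
    if (!length(idx)) next
    out[[g]] <- data.frame(
      label = g, step = seq_len(n_steps),
      vel = colMeans(vels[idx, , drop = FALSE]),
      acc = colMeans(accs[idx, , drop = FALSE]),
      n = length(idx), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
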