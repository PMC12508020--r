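# Independent brute-force oracles used to validate the package's index
# computations, plus small fixture builders. All fixtures are generated in
# code; nothing is read from disk.

# Build a track_data object from a list of per-trial matrices with columns
# timestamps/xpos/ypos (plus optional metadata columns).
make_ds <- function(trials, meta = NULL) {
  ids <- names(trials)
  if (is.null(ids)) ids <- paste0("t", seq_along(trials))
  long <- do.call(rbind, lapply(seq_along(trials), function(i) {
    m <- trials[[i]]
    data.frame(trial_id = ids[i], timestamps = m[, 1], xpos = m[, 2],
               ypos = m[, 3], stringsAsFactors = FALSE)
  }))
  if (!is.null(meta)) long <- merge(long, meta, by = "trial_id", sort = FALSE)
  import_long(long, id_columns = "trial_id")
}

# Random jagged trajectory for property tests.
random_trial <- function(n = NULL, amp = 100) {
  if (is.null(n)) n <- sample(5:40, 1)
  cbind(timestamps = cumsum(c(0, runif(n - 1, 5, 30))),
        xpos = cumsum(c(0, rnorm(n - 1, sd = amp / 4))),
        ypos = cumsum(c(0, rnorm(n - 1, sd = amp / 4))))
}

# Oracle: signed perpendicular deviation via explicit projection geometry,
# written independently of the package's cross-product route.
oracle_deviations <- function(m) {
  p1 <- m[1, c("xpos", "ypos")]
  p2 <- m[nrow(m), c("xpos", "ypos")]
  u <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
  nrm <- c(-u[2], u[1])                       # left normal of travel direction
  d <- as.numeric((t(t(m[, c("xpos", "ypos")]) - p1)) %*% nrm)
  # positive must point to the side opposite the endpoint's x displacement
  pos_is_right <- nrm[1] > 0 || (nrm[1] == 0 && nrm[2] > 0)
  endpoint_left <- p2[1] <= p1[1]
  if (endpoint_left != pos_is_right) d <- -d
  d
}

# Oracle: AUC via trapezoidal integration of signed deviation over the
# projection of each point onto the ideal segment.
oracle_auc <- function(m) {
  p1 <- m[1, c("xpos", "ypos")]
  p2 <- m[nrow(m), c("xpos", "ypos")]
  u <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
  s <- as.numeric((t(t(m[, c("xpos", "ypos")]) - p1)) %*% u)
  d <- oracle_deviations(m)
  sum(diff(s) * (d[-1] + d[-length(d)]) / 2)
}

# Oracle: linear scan counters.
oracle_flips <- function(v, threshold = 0) {
  last_sign <- 0; flips <- 0
  for (dd in diff(v)) {
    if (abs(dd) <= threshold) next
    s <- if (dd > 0) 1 else -1
    if (last_sign != 0 && s != last_sign) flips <- flips + 1
    last_sign <- s
  }
  flips
}
oracle_reversals <- function(x) {
  rel <- x - x[1]
  last_sign <- 0; rev <- 0
  for (r in rel) {
    if (r == 0) next
    s <- if (r > 0) 1 else -1
    if (last_sign != 0 && s != last_sign) rev <- rev + 1
    last_sign <- s
  }
  rev
}

# Oracle: sample entropy by naive double loop.
oracle_sampen <- function(x, m = 3, r) {
  N <- length(x); n <- N - m
  cnt <- function(len) {
    tot <- 0
    for (i in 1:n) for (j in 1:n) {
      if (i == j) next
      if (max(abs(x[i:(i + len - 1)] - x[j:(j + len - 1)])) <= r)
        tot <- tot + 1
    }
    tot
  }
  -log(cnt(m + 1) / cnt(m))
}

# Random smooth reach-like trajectory: a quadratic curve with bounded
# lateral bow (no hairpins), sampled densely as a recording device would.
random_smooth_trial <- function(n = 60) {
  p0 <- c(0, 0)
  p2 <- c(runif(1, -800, 800), runif(1, 300, 1100))
  perp <- c(-p2[2], p2[1]) / sqrt(sum(p2^2))
  p1 <- p2 / 2 + perp * runif(1, -0.6, 0.6) * sqrt(sum(p2^2))
  tt <- seq(0, 1, length.out = n)
  cbind(timestamps = tt * runif(1, 500, 3000),
        xpos = (1 - tt)^2 * p0[1] + 2 * (1 - tt) * tt * p1[1] + tt^2 * p2[1],
        ypos = (1 - tt)^2 * p0[2] + 2 * (1 - tt) * tt * p1[2] + tt^2 * p2[2])
}

# Oracle: arc-length position of query points along a polyline, via dense
# numeric resampling of the polyline (independent of the package's
# interpolation code path).
oracle_arc_positions <- function(poly, query, dense_n = 20000) {
  seg <- sqrt(diff(poly[, "xpos"])^2 + diff(poly[, "ypos"])^2)
  s <- c(0, cumsum(seg))
  u <- !duplicated(s)
  sd_ <- seq(0, s[length(s)], length.out = dense_n)
  dx <- stats::approx(s[u], poly[u, "xpos"], xout = sd_)$y
  dy <- stats::approx(s[u], poly[u, "ypos"], xout = sd_)$y
  vapply(seq_len(nrow(query)), function(i) {
    d2 <- (dx - query[i, 1])^2 + (dy - query[i, 2])^2
    sd_[which.min(d2)]
  }, numeric(1))
}

# Oracle: polyline arc length.
oracle_pathlen <- function(m) sum(sqrt(diff(m[, "xpos"])^2 +
                                       diff(m[, "ypos"])^2))

# Oracle: pairwise pointwise-Euclidean trajectory distance.
oracle_traj_dist <- function(a, b)
  sum(sqrt((a[, 1] - b[, 1])^2 + (a[, 2] - b[, 2])^2))
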