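#' Bimodality coefficient
#'
#' `BC = (g1^2 + 1) / (g2 + 3(n-1)^2 / ((n-2)(n-3)))` with `g1` the
#' finite-sample-corrected skewness and `g2` the corrected excess kurtosis.
#' A standard normal sample approaches 1/3, a uniform sample 5/9, and a
#' symmetric two-point mass 1. Values above 5/9 are conventionally read as
#' pointing to bimodality, but no threshold is applied here. The coefficient
#' is invariant under affine transforms of the data.
#'
#' @param values numeric vector, `n >= 4`, non-zero variance.
#' @return the coefficient (a value in (0, 1] up to sampling noise).
#' @export
bimodality_coefficient <- function(values) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 4L) stop("need at least 4 values")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("zero variance")
  b1 <- mean((x - m)^3) / m2^1.5
  b2 <- mean((x - m)^4) / m2^2 - 3
  g1 <- b1 * sqrt(n * (n - 1)) / (n - 2)
  g2 <- ((n + 1) * b2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}

# Hartigan & Hartigan's dip statistic: the maximal distance between the
# empirical CDF and the closest unimodal CDF, computed by iteratively
# refining the modal interval between the greatest convex minorant and the
# least concave majorant of the ECDF.
dip_value <- function(x) {
  x <- sort(as.numeric(x[!is.na(x)]))
  n <- length(x)
  if (n < 2L) return(0)
  if (x[n] == x[1L]) return(1 / (2 * n))

  # mn[j]: previous touch point of the greatest convex minorant up to j
  mn <- integer(n); mn[1L] <- 1L
  for (j in 2:n) {
    mn[j] <- j - 1L
    repeat {
      mnj <- mn[j]
      if (mnj == 1L) break
      mnmnj <- mn[mnj]
      if ((x[j] - x[mnj]) * (mnj - mnmnj) <
          (x[mnj] - x[mnmnj]) * (j - mnj)) break
      mn[j] <- mnmnj
    }
  }
  # mj[k]: next touch point of the least concave majorant from k on
  mj <- integer(n); mj[n] <- n
  for (k in (n - 1L):1L) {
    mj[k] <- k + 1L
    repeat {
      mjk <- mj[k]
      if (mjk == n) break
      mjmjk <- mj[mjk]
      if ((x[k] - x[mjk]) * (mjk - mjmjk) <
          (x[mjk] - x[mjmjk]) * (k - mjk)) break
      mj[k] <- mjmjk
    }
  }

  # the scan below works on twice the dip's scale; halved on return
  low <- 1L; high <- n
  dip <- 1 / n
  repeat {
    gcm <- high                                   # change points, high -> low
    while (gcm[length(gcm)] > low)
      gcm <- c(gcm, mn[gcm[length(gcm)]])
    l_gcm <- length(gcm)
    lcm <- low                                    # change points, low -> high
    while (lcm[length(lcm)] < high)
      lcm <- c(lcm, mj[lcm[length(lcm)]])
    l_lcm <- length(lcm)

    ig <- l_gcm; ih <- l_lcm
    ix <- l_gcm - 1L; iv <- 2L
    d <- 0
    if (l_gcm != 2L || l_lcm != 2L) {
      repeat {
        gcmix <- gcm[ix]; lcmiv <- lcm[iv]
        if (gcmix > lcmiv) {
          # next change point comes from the LCM
          gcmi1 <- gcm[ix + 1L]
          dx <- (lcmiv - gcmi1 + 1L) / n -
            (x[lcmiv] - x[gcmi1]) * (gcmix - gcmi1) /
            (n * (x[gcmix] - x[gcmi1]))
          iv <- iv + 1L
          if (dx >= d) { d <- dx; ig <- ix + 1L; ih <- iv - 1L }
        } else {
          # next change point comes from the GCM
          lcmiv1 <- lcm[iv - 1L]
          dx <- (x[gcmix] - x[lcmiv1]) * (lcmiv - lcmiv1) /
            (n * (x[lcmiv] - x[lcmiv1])) -
            (gcmix - lcmiv1 - 1L) / n
          ix <- ix - 1L
          if (dx >= d) { d <- dx; ig <- ix + 1L; ih <- iv }
        }
        if (ix < 1L) ix <- 1L
        if (iv > l_lcm) iv <- l_lcm
        if (gcm[ix] == lcm[iv]) break
      }
    } else {
      d <- 1 / n
    }
    if (d < dip) break

    # largest deviation of the ECDF within the GCM fit below the mode ...
    dip_l <- 0
    if (ig <= l_gcm - 1L) for (j in ig:(l_gcm - 1L)) {
      max_t <- 1 / n
      jb <- gcm[j + 1L]; je <- gcm[j]
      if (je - jb > 1L && x[je] != x[jb]) {
        C <- (je - jb) / (n * (x[je] - x[jb]))
        for (jj in jb:je) {
          tt <- (jj - jb + 1L) / n - (x[jj] - x[jb]) * C
          if (max_t < tt) max_t <- tt
        }
      }
      if (dip_l < max_t) dip_l <- max_t
    }
    # ... and within the LCM fit above the mode
    dip_u <- 0
    if (ih <= l_lcm - 1L) for (j in ih:(l_lcm - 1L)) {
      max_t <- 1 / n
      jb <- lcm[j]; je <- lcm[j + 1L]
      if (je - jb > 1L && x[je] != x[jb]) {
        C <- (je - jb) / (n * (x[je] - x[jb]))
        for (jj in jb:je) {
          tt <- (x[jj] - x[jb]) * C - (jj - jb - 1L) / n
          if (max_t < tt) max_t <- tt
        }
      }
      if (dip_u < max_t) dip_u <- max_t
    }
    if (dip < dip_l) dip <- dip_l
    if (dip < dip_u) dip <- dip_u
    if (low == gcm[ig] && high == lcm[ih]) break
    low <- gcm[ig]; high <- lcm[ih]
  }
  dip / 2
}

#' Hartigan's dip statistic
#'
#' Maximal difference between the empirical CDF and the closest unimodal
#' CDF. The statistic is bounded below by `1/(2n)` (attained e.g. by any
#' two-point sample, where it equals 0.25) and, being rank-based, is
#' invariant under strictly monotone transforms of the values. An optional
#' bootstrap p-value is computed against the standard uniform(0, 1) null.
#'
#' @param values numeric vector.
#' @param n_boot number of bootstrap null samples (0 = no p-value).
#' @param seed optional integer seed for the bootstrap.
#' @return list with `dip`, `dip_p` (`NA` when `n_boot = 0`), and `n`.
#' @export
dip_statistic <- function(values, n_boot = 0L, seed = NULL) {
  x <- values[!is.na(values)]
  d <- dip_value(x)
  p <- NA_real_
  if (n_boot > 0L) {
    if (!is.null(seed)) set.seed(seed)
    null <- vapply(seq_len(n_boot),
                   function(i) dip_value(stats::runif(length(x))),
                   numeric(1))
    p <- mean(null >= d)
  }
  list(dip = d, dip_p = p, n = length(x))
}

#' Bimodality diagnostics for a vector of trajectory indices
#'
#' Convenience wrapper returning the bimodality coefficient and Hartigan's
#' dip statistic together.
#'
#' @inheritParams dip_statistic
#' @return list with `bc`, `dip`, `dip_p`, `n`.
#' @export
check_bimodality <- function(values, n_boot = 0L, seed = NULL) {
  d <- dip_statistic(values, n_boot = n_boot, seed = seed)
  list(bc = bimodality_coefficient(values), dip = d$dip, dip_p = d$dip_p,
       n = d$n)
}

# Mass-conserving 1-D Gaussian spread: each input cell's mass is distributed
# over a clipped, renormalized kernel window, so boundaries lose nothing.
spread_gauss_1d <- function(v, sd) {
  if (sd <= 0) return(v)
  r <- ceiling(3 * sd)
  w <- stats::dnorm(seq(-r, r), sd = sd)
  n <- length(v)
  out <- numeric(n)
  for (i in which(v != 0)) {
    lo <- max(1L, i - r); hi <- min(n, i + r)
    k <- w[(lo - i + r + 1L):(hi - i + r + 1L)]
    out[lo:hi] <- out[lo:hi] + v[i] * k / sum(k)
  }
  out
}

smooth_grid <- function(mat, radius) {
  if (radius <= 0) return(mat)
  sd <- radius / 2
  mat <- apply(mat, 2L, spread_gauss_1d, sd = sd)
  t(apply(mat, 1L, spread_gauss_1d, sd = sd))
}

#' Trajectory density grid (heatmap)
#'
#' Rasterizes trajectory lines onto a regular grid. Each trajectory polyline
#' is first resampled at a constant arc-length step no larger than one grid
#' cell, so cell intensity reflects line coverage rather than the recording
#' rate; the resampled points are then binned and optionally smoothed with a
#' mass-conserving Gaussian of standard deviation `smooth_radius / 2` cells
#' (truncated at `smooth_radius`).
#'
#' @inheritParams remap_symmetric
#' @param bounds `c(xmin, xmax, ymin, ymax)` in px; defaults to the data
#'   range.
#' @param resolution `c(nx, ny)` grid cells.
#' @param smooth_radius smoothing radius in cells (0 = none).
#' @return object of class `density_grid`: list with `bounds`, `resolution`,
#'   `intensity` (an `nx` x `ny` matrix), `smooth_radius`, `n_shades`.
#' @export
density_grid <- function(ds, use = "trajectories", bounds = NULL,
                         resolution = c(100L, 100L), smooth_radius = 0) {
  arr <- get_trajectories(ds, use)
  if (is.null(bounds)) {
    bounds <- c(range(arr[, , "xpos"], na.rm = TRUE),
                range(arr[, , "ypos"], na.rm = TRUE))
  }
  nx <- resolution[1L]; ny <- resolution[2L]
  cw <- (bounds[2L] - bounds[1L]) / nx
  ch <- (bounds[4L] - bounds[3L]) / ny
  step <- min(cw, ch)
  counts <- matrix(0, nx, ny)
  for (i in seq_len(dim(arr)[1L])) {
    keep <- !is.na(arr[i, , "timestamps"])
    xs <- arr[i, keep, "xpos"]; ys <- arr[i, keep, "ypos"]
    seg <- sqrt(diff(xs)^2 + diff(ys)^2)
    s <- c(0, cumsum(seg))
    if (s[length(s)] > 0) {
      s_new <- seq(0, s[length(s)], by = step)
      u <- !duplicated(s)
      xs <- stats::approx(s[u], xs[u], xout = s_new)$y
      ys <- stats::approx(s[u], ys[u], xout = s_new)$y
    }
    ix <- pmin(pmax(ceiling((xs - bounds[1L]) / cw), 1L), nx)
    iy <- pmin(pmax(ceiling((ys - bounds[3L]) / ch), 1L), ny)
    for (k in seq_along(ix)) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1
  }
  structure(list(bounds = bounds, resolution = c(nx, ny),
                 intensity = smooth_grid(counts, smooth_radius),
                 smooth_radius = smooth_radius, n_shades = NULL),
            class = "density_grid")
}

#' Density difference map
#'
#' Normalizes two density grids to unit total mass and subtracts them;
#' optionally quantizes the signed result to `n_shades` levels per sign.
#'
#' @param a,b `density_grid` objects sharing bounds and resolution.
#' @param n_shades optional number of signed quantization levels.
#' @return a `density_grid` whose intensity may be negative.
#' @export
diff_grid <- function(a, b, n_shades = NULL) {
  stopifnot(inherits(a, "density_grid"), inherits(b, "density_grid"))
  if (!isTRUE(all.equal(a$bounds, b$bounds)) ||
      !identical(a$resolution, b$resolution))
    stop("grids differ in bounds or resolution")
  norm <- function(m) if (sum(m) > 0) m / sum(m) else m
  d <- norm(a$intensity) - norm(b$intensity)
  if (!is.null(n_shades) && max(abs(d)) > 0)
    d <- round(d / max(abs(d)) * n_shades) / n_shades * max(abs(d))
  structure(list(bounds = a$bounds, resolution = a$resolution,
                 intensity = d, smooth_radius = a$smooth_radius,
                 n_shades = n_shades),
            class = "density_grid")
}

#' @export
plot.density_grid <- function(x, ...) {
  nx <- x$resolution[1L]; ny <- x$resolution[2L]
  xs <- seq(x$bounds[1L], x$bounds[2L], length.out = nx)
  ys <- seq(x$bounds[3L], x$bounds[4L], length.out = ny)
  neg <- min(x$intensity) < 0
  pal <- if (neg) grDevices::hcl.colors(21, "Blue-Red 2")
         else grDevices::hcl.colors(21, "YlOrRd", rev = TRUE)
  graphics::image(xs, ys, x$intensity, col = pal, xlab = "xpos (px)",
                  ylab = "ypos (px)", useRaster = TRUE, ...)
  invisible(x)
}
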