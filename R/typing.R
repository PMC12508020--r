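# Resample a bare x/y polyline to n spatially equidistant points.
ln_polyline <- function(xy, n) {
  seg <- sqrt(diff(xy[, 1L])^2 + diff(xy[, 2L])^2)
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  if (L == 0) return(xy[rep(1L, n), , drop = FALSE])
  s_new <- seq(0, L, length.out = n)
  u <- !duplicated(s)
  cbind(stats::approx(s[u], xy[u, 1L], xout = s_new)$y,
        stats::approx(s[u], xy[u, 2L], xout = s_new)$y)
}

# Quadratic Bezier through fixed endpoints with a given control point.
bezier2 <- function(p0, p1, p2, n = 41L) {
  tt <- seq(0, 1, length.out = n)
  cbind((1 - tt)^2 * p0[1L] + 2 * (1 - tt) * tt * p1[1L] + tt^2 * p2[1L],
        (1 - tt)^2 * p0[2L] + 2 * (1 - tt) * tt * p1[2L] + tt^2 * p2[2L])
}

#' The canonical five-prototype set
#'
#' Reference polylines for top-down trajectory typing, in a unit space with
#' start `(0, 0)` and chosen option at `(-1, 1.5)` (the nonchosen option
#' mirrored at `(+1, 1.5)`). Ordered by the level of response competition
#' they reflect:
#' \enumerate{
#'   \item `straight` -- direct segment to the chosen option.
#'   \item `curved` -- arc bulging toward the nonchosen side (quadratic
#'     curve through `(+0.25, 0.75)`).
#'   \item `cCoM` -- continuous change of mind: a smooth excursion through
#'     `(+0.6, 0.9)` before turning to the chosen option.
#'   \item `dCoM` -- discrete change of mind: straight to the nonchosen
#'     corner `(+1, 1.5)`, then straight across to the chosen one.
#'   \item `dCoM2` -- discrete double change of mind: toward the chosen
#'     side, reversal toward the nonchosen side (`(+0.7, 1.3)`), and back.
#' }
#' The exact vertices are this package's canonical, fully overridable
#' choice: any list with elements `label`, `rank`, and a two-column `points`
#' polyline starting at `(0, 0)` and ending at `(-1, 1.5)` works wherever a
#' prototype set is accepted.
#'
#' @return object of class `prototype_set`: a list of entries with `label`,
#'   `rank`, `points`.
#' @export
standard_prototypes <- function() {
  p0 <- c(0, 0); pe <- c(-1, 1.5)
  protos <- list(
    list(label = "straight", rank = 1L, points = rbind(p0, pe)),
    list(label = "curved", rank = 2L,
         points = bezier2(p0, c(1.0, 0.75), pe)),
    list(label = "cCoM", rank = 3L,
         points = bezier2(p0, c(1.7, 1.05), pe)),
    list(label = "dCoM", rank = 4L,
         points = rbind(p0, c(1, 1.5), pe)),
    list(label = "dCoM2", rank = 5L,
         points = rbind(p0, c(-0.5, 0.75), c(0.7, 1.3), pe)))
  protos <- lapply(protos, function(p) {
    dimnames(p$points) <- NULL
    p
  })
  structure(protos, class = "prototype_set")
}

#' @export
print.prototype_set <- function(x, ...) {
  cat("<prototype_set> ", length(x), " prototypes\n", sep = "")
  for (p in x)
    cat(sprintf("  %d. %-9s %d vertices\n", p$rank, p$label, nrow(p$points)))
  invisible(x)
}

prototype_labels <- function(prototypes)
  vapply(prototypes, `[[`, "", "label")

#' Pointwise Euclidean distance matrix between trajectories
#'
#' For trajectories represented by the same number of points,
#' `d[i, j] = sum_k sqrt((x[i,k] - x[j,k])^2 + (y[i,k] - y[j,k])^2)`.
#' Conventionally computed on length-normalized trajectories, which weight
#' all parts of a movement equally and so emphasize shape differences.
#'
#' @inheritParams remap_symmetric
#' @return symmetric matrix with zero diagonal, dimnames = trial ids.
#' @export
trajectory_distances <- function(ds, use = "ln_trajectories") {
  arr <- get_trajectories(ds, use)
  vl <- valid_lengths(ds, use)
  if (length(unique(vl)) != 1L)
    stop("trials differ in point counts; resample first ",
         "(e.g. length_normalize())")
  X <- arr[, , "xpos", drop = TRUE]
  Y <- arr[, , "ypos", drop = TRUE]
  n <- nrow(X)
  D <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
  for (k in seq_len(ncol(X)))
    D <- D + sqrt(outer(X[, k], X[, k], "-")^2 +
                  outer(Y[, k], Y[, k], "-")^2)
  D
}

#' Bottom-up trajectory clustering
#'
#' Agglomerative hierarchical clustering (`ward.D` linkage by default) of
#' the trajectory distance matrix, cut at `n_clusters` groups. Cluster
#' labels are relabeled in order of descending cluster size
#' (`cluster_1` is the largest). The partition does not depend on trial
#' order.
#'
#' @param x a `track_data` object or a precomputed distance matrix.
#' @param use representation used when `x` is a dataset (length-normalized
#'   by convention).
#' @param n_clusters number of clusters to extract (>= 2).
#' @param method linkage passed to [stats::hclust()].
#' @return object of class `type_assignment`: data.frame with `trial_id`,
#'   `label`, `distance` (to the pointwise mean trajectory of the assigned
#'   cluster), `z_distance` (standardized within cluster); the per-cluster
#'   mean trajectories are in `attr(, "centers")`.
#' @export
cluster_trajectories <- function(x, use = "ln_trajectories",
                                 n_clusters = 5L, method = "ward.D") {
  if (n_clusters < 2L) stop("n_clusters must be >= 2")
  if (inherits(x, "track_data")) {
    D <- trajectory_distances(x, use)
    arr <- get_trajectories(x, use)
  } else {
    D <- as.matrix(x)
    arr <- NULL
  }
  if (n_clusters > nrow(D)) stop("more clusters than trials")
  hc <- stats::hclust(stats::as.dist(D), method = method)
  raw <- stats::cutree(hc, k = n_clusters)
  sizes <- sort(table(raw), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  cl <- relabel[as.character(raw)]
  label <- factor(paste0("cluster_", cl),
                  levels = paste0("cluster_", seq_len(n_clusters)))
  centers <- NULL
  dist_to_center <- rep(NA_real_, nrow(D))
  if (!is.null(arr)) {
    X <- arr[, , "xpos", drop = TRUE]; Y <- arr[, , "ypos", drop = TRUE]
    centers <- lapply(seq_len(n_clusters), function(k) {
      idx <- which(cl == k)
      cbind(xpos = colMeans(X[idx, , drop = FALSE]),
            ypos = colMeans(Y[idx, , drop = FALSE]))
    })
    names(centers) <- levels(label)
    for (i in seq_len(nrow(D))) {
      cen <- centers[[cl[i]]]
      dist_to_center[i] <- sum(sqrt((X[i, ] - cen[, "xpos"])^2 +
                                    (Y[i, ] - cen[, "ypos"])^2))
    }
  }
  out <- data.frame(trial_id = rownames(D), label = label,
                    distance = dist_to_center, stringsAsFactors = FALSE)
  out$z_distance <- stats::ave(out$distance, out$label, FUN = function(v) {
    if (sum(!is.na(v)) < 2L || stats::sd(v, na.rm = TRUE) == 0)
      rep(NA_real_, length(v))
    else (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
  })
  structure(out, class = c("type_assignment", "data.frame"),
            centers = centers, method = method)
}

#' Top-down prototype mapping
#'
#' Assigns every trajectory to the closest prototype under the pointwise
#' Euclidean distance. Per trial, each prototype polyline is rescaled (one
#' affine map per axis) so its start and end coincide with the trial's, both
#' curves are length-normalized to `n_points`, and the prototype minimizing
#' the distance wins; ties go to the lowest competition rank. Rigidly
#' transforming all trajectories does not change the labels.
#'
#' @inheritParams remap_symmetric
#' @param prototypes a [standard_prototypes()]-style set.
#' @param n_points length-normalization resolution (conventionally 20).
#' @return object of class `type_assignment`: data.frame with `trial_id`,
#'   `label` (factor in prototype order), `rank`, `distance`, `z_distance`
#'   (standardized within label). Trials whose start and end coincide are
#'   unassignable (`NA` label, with a warning).
#' @export
map_to_prototypes <- function(ds, use = "trajectories",
                              prototypes = standard_prototypes(),
                              n_points = 20L) {
  arr <- get_trajectories(ds, use)
  ids <- dimnames(arr)[[1L]]
  labels <- prototype_labels(prototypes)
  ranks <- vapply(prototypes, `[[`, 1L, "rank")
  n <- length(ids)
  lab <- rep(NA_character_, n)
  rnk <- rep(NA_integer_, n)
  dst <- rep(NA_real_, n)
  unassignable <- 0L
  for (i in seq_len(n)) {
    keep <- !is.na(arr[i, , "timestamps"])
    xy <- cbind(arr[i, keep, "xpos"], arr[i, keep, "ypos"])
    L <- nrow(xy)
    if (all(xy[L, ] == xy[1L, ])) { unassignable <- unassignable + 1L; next }
    tln <- ln_polyline(xy, n_points)
    dists <- vapply(prototypes, function(p) {
      pp <- p$points
      # per-axis affine map prototype (0,0)->(-1,1.5) onto trial start/end
      px <- xy[1L, 1L] + (pp[, 1L] - 0) * (xy[L, 1L] - xy[1L, 1L]) / (-1 - 0)
      py <- xy[1L, 2L] + (pp[, 2L] - 0) * (xy[L, 2L] - xy[1L, 2L]) / (1.5 - 0)
      pln <- ln_polyline(cbind(px, py), n_points)
      sum(sqrt((tln[, 1L] - pln[, 1L])^2 + (tln[, 2L] - pln[, 2L])^2))
    }, numeric(1))
    best <- which(dists == min(dists))
    if (length(best) > 1L) best <- best[which.min(ranks[best])]
    lab[i] <- labels[best]
    rnk[i] <- ranks[best]
    dst[i] <- dists[best]
  }
  if (unassignable > 0L)
    warning(unassignable, " trial(s) with coincident start and end; ",
            "label set to NA")
  out <- data.frame(trial_id = ids,
                    label = factor(lab, levels = labels),
                    rank = rnk, distance = dst, stringsAsFactors = FALSE)
  out$z_distance <- stats::ave(out$distance, out$label, FUN = function(v) {
    if (sum(!is.na(v)) < 2L || stats::sd(v, na.rm = TRUE) == 0)
      rep(NA_real_, length(v))
    else (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
  })
  structure(out, class = c("type_assignment", "data.frame"),
            prototypes = prototypes)
}

#' Type frequency table
#'
#' Cross-tabulates assigned trajectory types against a grouping variable.
#'
#' @param assignment a `type_assignment` (or any data.frame with `trial_id`
#'   and `label`).
#' @param group grouping values: either a vector aligned with the
#'   assignment or the name of a column in `trial_table`.
#' @param trial_table trial table (or `track_data`) supplying `group` when
#'   it is a column name.
#' @param percent return row percentages instead of counts.
#' @return group x label matrix.
#' @export
type_frequency_table <- function(assignment, group, trial_table = NULL,
                                 percent = FALSE) {
  if (is.character(group) && length(group) == 1L && !is.null(trial_table)) {
    if (inherits(trial_table, "track_data"))
      trial_table <- trial_table$trial_table
    group <- trial_table[[group]][match(assignment$trial_id,
                                        trial_table$trial_id)]
  }
  keep <- !is.na(assignment$label)
  O <- table(group = group[keep], label = assignment$label[keep])
  O <- unclass(O)
  if (percent) O <- prop.table(O, 1L) * 100
  O
}

#' Chi-square test of independence for a type frequency table
#'
#' Pearson chi-square without continuity correction: expected counts
#' `E = row_total * col_total / grand_total`, statistic
#' `sum((O - E)^2 / E)` with `(R-1)(C-1)` degrees of freedom, and Pearson
#' residuals `(O - E) / sqrt(E)` whose squares sum to the statistic.
#'
#' @param observed matrix of counts with at least 2 rows and 2 columns.
#' @return object of class `freq_test`: list with `observed`, `expected`,
#'   `statistic`, `df`, `p_value`, `residuals`.
#' @export
#' @examples
#' O <- rbind(typical = c(506, 116, 54, 52, 16),
#'            atypical = c(165, 38, 37, 56, 24))
#' chi_square_independence(O)
chi_square_independence <- function(observed) {
  O <- as.matrix(observed)
  if (nrow(O) < 2L || ncol(O) < 2L) stop("need at least a 2 x 2 table")
  if (any(O < 0)) stop("counts must be non-negative")
  if (any(rowSums(O) == 0) || any(colSums(O) == 0))
    stop("zero row or column total")
  ht <- stats::chisq.test(O, correct = FALSE)
  structure(list(observed = O, expected = ht$expected,
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = unname(ht$p.value),
                 residuals = unclass(ht$residuals)),
            class = "freq_test")
}

#' @export
print.freq_test <- function(x, ...) {
  cat(sprintf("Chi-square test of independence: X2(%d) = %.2f, p %s\n",
              x$df, x$statistic,
              if (x$p_value < .001) "< .001" else
                sprintf("= %.3f", x$p_value)))
  cat("Pearson residuals:\n")
  print(round(x$residuals, 2))
  invisible(x)
}

#' Ordinal export of trajectory types
#'
#' Tidy table of per-trial type assignments with their competition ranks
#' (1 = straight ... 5 = dCoM2 for the standard set), merged with trial
#' metadata -- ready for external ordinal regression tooling.
#'
#' @inheritParams type_frequency_table
#' @param prototypes prototype set defining the rank order.
#' @return data.frame with `trial_id`, `label`, `rank`, plus trial-table
#'   columns.
#' @export
ordinal_types <- function(assignment, prototypes = standard_prototypes(),
                          trial_table = NULL) {
  ranks <- stats::setNames(vapply(prototypes, `[[`, 1L, "rank"),
                           prototype_labels(prototypes))
  keep <- !is.na(assignment$label)
  out <- data.frame(trial_id = assignment$trial_id[keep],
                    label = assignment$label[keep],
                    rank = unname(ranks[as.character(assignment$label[keep])]),
                    stringsAsFactors = FALSE)
  if (!is.null(trial_table)) {
    if (inherits(trial_table, "track_data"))
      trial_table <- trial_table$trial_table
    out <- merge(out, trial_table, by = "trial_id", sort = FALSE)
  }
  out
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same items
#' (1 = identical partitions, ~0 = chance agreement).
#'
#' @param a,b label vectors of equal length.
#' @return the index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
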