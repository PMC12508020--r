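test_that("distance matrix implements the pointwise Euclidean formula", {
  a <- cbind(timestamps = c(0, 10), xpos = c(0, 1), ypos = c(0, 0))
  b <- cbind(timestamps = c(0, 10), xpos = c(0, 1), ypos = c(1, 1))
  ds <- make_ds(list(a = a, b = b, c = a))
  D <- trajectory_distances(ds, use = "trajectories")
  expect_equal(D["a", "b"], 2)            # two unit offsets
  expect_equal(D["a", "c"], 0)
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), c(0, 0, 0))
  # joint translation leaves distances unchanged
  shift <- lapply(list(a = a, b = b, c = a), function(m) {
    m[, "xpos"] <- m[, "xpos"] + 40; m[, "ypos"] <- m[, "ypos"] - 7; m
  })
  expect_equal(trajectory_distances(make_ds(shift), use = "trajectories"), D)
  # unequal point counts are refused with advice
  ragged <- make_ds(list(a = a, b = random_trial(n = 9)))
  expect_error(trajectory_distances(ragged, use = "trajectories"), "resample")
})

test_that("distance matrix matches the naive oracle on random data", {
  set.seed(8)
  out <- generate_tracking_data(synth_spec(n_subjects = 2, seed = 8))
  ds <- length_normalize(out$data)
  D <- trajectory_distances(ds)
  arr <- get_trajectories(ds, "ln_trajectories")
  for (pair in list(c(1, 2), c(3, 17), c(5, 30))) {
    i <- pair[1]; j <- pair[2]
    expect_equal(D[i, j],
                 oracle_traj_dist(cbind(arr[i, , "xpos"], arr[i, , "ypos"]),
                                  cbind(arr[j, , "xpos"], arr[j, , "ypos"])),
                 tolerance = 1e-12)
  }
})

test_that("clustering separates toy shapes and is order-invariant", {
  up <- cbind(timestamps = seq(0, 100, 25), xpos = 0, ypos = seq(0, 100, 25))
  flat <- cbind(timestamps = seq(0, 100, 25), xpos = seq(0, 100, 25), ypos = 0)
  trials <- list(u1 = up, u2 = up, u3 = up, f1 = flat, f2 = flat, f3 = flat)
  ds <- length_normalize(make_ds(trials), n_points = 5)
  asg <- cluster_trajectories(ds, n_clusters = 2)
  grp <- split(asg$trial_id, asg$label)
  expect_setequal(vapply(grp, length, 1L), c(3L, 3L))
  expect_true(all(substr(grp[[1]], 1, 1) == substr(grp[[1]][1], 1, 1)))

  perm <- sample(names(trials))
  asg2 <- cluster_trajectories(length_normalize(make_ds(trials[perm]),
                                                n_points = 5), n_clusters = 2)
  part <- function(a) unname(lapply(split(a$trial_id, a$label), sort))
  expect_setequal(part(asg2), part(asg))
  expect_error(cluster_trajectories(ds, n_clusters = 1), ">= 2")
})

test_that("clustering recovers the generating five-type mixture", {
  out <- generate_tracking_data(synth_spec(n_subjects = 15, noise_sd = 4,
                                           seed = 21))
  ds <- length_normalize(align_start(remap_symmetric(out$data)))
  asg <- cluster_trajectories(ds)
  truth <- out$truth$type[match(asg$trial_id, out$truth$trial_id)]
  ari <- adjusted_rand_index(asg$label, truth)
  expect_gte(ari, 0.9)
  # labels are ordered by cluster size, largest first
  sizes <- table(asg$label)
  expect_true(all(diff(as.integer(sizes)) <= 0))
})

test_that("internal adjusted Rand index agrees with mclust", {
  skip_if_not_installed("mclust")
  set.seed(12)
  for (i in 1:5) {
    a <- sample(letters[1:4], 60, replace = TRUE)
    b <- sample(1:3, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b))
  }
  expect_equal(adjusted_rand_index(1:10, rep(1:5, 2)),
               mclust::adjustedRandIndex(1:10, rep(1:5, 2)))
})

test_that("prototype mapping assigns exact tracings with zero distance", {
  layout_scale <- function(pts) cbind(timestamps = seq(0, 1000,
                                                       length.out = nrow(pts)),
                                      xpos = pts[, 1] * 665,
                                      ypos = pts[, 2] * (974 / 1.5))
  protos <- standard_prototypes()
  trials <- stats::setNames(lapply(protos, function(p) layout_scale(p$points)),
                            prototype_labels(protos))
  asg <- map_to_prototypes(make_ds(trials))
  expect_equal(as.character(asg$label), prototype_labels(protos))
  expect_equal(asg$distance, rep(0, 5), tolerance = 1e-6)
  expect_equal(asg$rank, 1:5)
})

test_that("prototype mapping is invariant to rigid transforms of the data", {
  out <- generate_tracking_data(synth_spec(n_subjects = 3, seed = 14))
  ds <- align_start(remap_symmetric(out$data))
  a0 <- map_to_prototypes(ds)
  arr <- get_trajectories(ds)
  arr[, , "xpos"] <- arr[, , "xpos"] * 2.5 + 300
  arr[, , "ypos"] <- arr[, , "ypos"] * 2.5 - 50
  moved <- track_data(ds$trial_table, list(trajectories = arr))
  a1 <- map_to_prototypes(moved)
  expect_equal(as.character(a1$label), as.character(a0$label))
})

test_that("prototype mapping recovers generator truth at low noise", {
  out <- generate_tracking_data(synth_spec(n_subjects = 15, noise_sd = 4,
                                           seed = 22))
  ds <- align_start(remap_symmetric(out$data))
  asg <- map_to_prototypes(ds)
  truth <- out$truth$type[match(asg$trial_id, out$truth$trial_id)]
  expect_gte(mean(as.character(asg$label) == truth), 0.95)
})

test_that("chi-square machinery reproduces the worked 2x5 frequency table", {
  O <- rbind(typical = c(506, 116, 54, 52, 16),
             atypical = c(165, 38, 37, 56, 24))
  colnames(O) <- c("straight", "curved", "cCoM", "dCoM", "dCoM2")
  ht <- chi_square_independence(O)
  expect_equal(ht$statistic, 57.97, tolerance = 0.005)
  expect_equal(ht$df, 4)
  expect_lt(ht$p_value, 0.001)
  expect_equal(ht$residuals["typical", "straight"], 1.70, tolerance = 0.005)
  expect_equal(ht$residuals["atypical", "dCoM"], 4.13, tolerance = 0.005)
  expect_equal(sum(ht$residuals^2), ht$statistic, tolerance = 1e-9)
  # row percentages from the printed counts
  pct <- prop.table(O, 1) * 100
  expect_equal(round(pct["typical", "straight"]), 68)

  uniform <- matrix(10, 2, 2)
  hu <- chi_square_independence(uniform)
  expect_equal(hu$statistic, 0)
  expect_true(all(hu$residuals == 0))
  expect_error(chi_square_independence(matrix(c(1, 2), 1)), "2 x 2")
  expect_error(chi_square_independence(rbind(c(0, 0), c(1, 2))), "zero row")
})

test_that("shifting mixture mass toward dCoM raises its cell residual", {
  base <- c(straight = .6, curved = .1, cCoM = .1, dCoM = .1, dCoM2 = .1)
  res_at <- function(d, seed) {
    shifted <- base
    shifted["dCoM"] <- shifted["dCoM"] + d
    shifted["straight"] <- shifted["straight"] - d
    sim <- generate_tracking_data(synth_spec(
      n_subjects = 12, type_mixture = list(typical = base,
                                           atypical = shifted), seed = seed))
    ds <- align_start(remap_symmetric(sim$data))
    asg <- map_to_prototypes(ds)
    O <- type_frequency_table(asg, "condition", ds)
    chi_square_independence(O)$residuals["atypical", "dCoM"]
  }
  expect_lt(res_at(0.05, 41), res_at(0.35, 41))
})

test_that("frequency table respects prototype order and percent mode", {
  out <- generate_tracking_data(synth_spec(n_subjects = 6, seed = 25))
  ds <- align_start(remap_symmetric(out$data))
  asg <- map_to_prototypes(ds)
  O <- type_frequency_table(asg, "condition", ds)
  expect_equal(colnames(O), c("straight", "curved", "cCoM", "dCoM", "dCoM2"))
  P <- type_frequency_table(asg, "condition", ds, percent = TRUE)
  expect_equal(unname(rowSums(P)), c(100, 100))
})

test_that("ordinal export carries competition ranks for every assigned trial", {
  asg <- data.frame(trial_id = c("t1", "t2", "t3"),
                    label = factor(c("straight", "cCoM", "dCoM2"),
                                   levels = c("straight", "curved", "cCoM",
                                              "dCoM", "dCoM2")))
  ord <- ordinal_types(asg)
  expect_equal(ord$rank, c(1L, 3L, 5L))
  expect_equal(nrow(ord), 3L)
  # full label-to-rank order
  all5 <- data.frame(trial_id = paste0("p", 1:5),
                     label = factor(c("straight", "curved", "cCoM", "dCoM",
                                      "dCoM2")))
  expect_equal(ordinal_types(all5)$rank, 1:5)
})

test_that("cluster means map onto the same dominant prototypes", {
  out <- generate_tracking_data(synth_spec(n_subjects = 15, noise_sd = 4,
                                           seed = 26))
  ds <- length_normalize(align_start(remap_symmetric(out$data)))
  cl <- cluster_trajectories(ds)
  top <- map_to_prototypes(ds)
  tab <- table(cl$label, top$label)
  # each cluster's dominant top-down label is unique across clusters
  dominant <- apply(tab, 1, which.max)
  expect_equal(length(unique(dominant)), 5L)
})
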