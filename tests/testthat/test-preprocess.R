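test_that("symmetric remapping mirrors only wrong-side trials, idempotently", {
  right <- cbind(timestamps = c(0, 50, 100), xpos = c(0, 150, 300),
                 ypos = c(0, 40, 90))
  left <- cbind(timestamps = c(0, 50, 100), xpos = c(0, -10, -250),
                ypos = c(0, 40, 90))
  ds <- make_ds(list(r = right, l = left))
  out <- remap_symmetric(ds, target_side = "left")
  arr <- get_trajectories(out)
  expect_equal(arr["r", , "xpos"], c(0, -150, -300))   # mirrored about start
  expect_equal(arr["l", , "xpos"], left[, "xpos"])     # untouched
  twice <- remap_symmetric(out, target_side = "left")
  expect_equal(get_trajectories(twice), arr)           # idempotent
})

test_that("start alignment translates rigidly and preserves curvature", {
  set.seed(11)
  trials <- replicate(5, random_trial() , simplify = FALSE)
  for (i in seq_along(trials)) {
    trials[[i]][, "xpos"] <- trials[[i]][, "xpos"] + 960
    trials[[i]][, "ypos"] <- trials[[i]][, "ypos"] + 1040
  }
  ds <- make_ds(trials)
  before <- compute_measures(ds)
  out <- align_start(ds)
  arr <- get_trajectories(out)
  expect_equal(unname(arr[, 1, "xpos"]), rep(0, 5))
  expect_equal(unname(arr[, 1, "ypos"]), rep(0, 5))
  after <- compute_measures(out)
  expect_equal(after$MAD, before$MAD)                  # translation invariant
  expect_equal(after$AUC, before$AUC)
  expect_equal(get_trajectories(align_start(out)), arr)  # identity when aligned
})

test_that("start-end alignment applies the per-axis affine map exactly", {
  m <- cbind(timestamps = c(0, 50, 100), xpos = c(0, -250, -500),
             ypos = c(0, 200, 400))
  ds <- make_ds(list(t1 = m))
  out <- align_start_end(ds, start = c(0, 0), end = c(-1, 1.5))
  arr <- get_trajectories(out)
  expect_equal(arr["t1", 2, "xpos"], -0.5)
  expect_equal(arr["t1", 2, "ypos"], 0.75)
  # inverse map recovers the original
  back <- align_start_end(out, start = c(0, 0), end = c(-500, 400))
  expect_equal(get_trajectories(back), get_trajectories(ds),
               tolerance = 1e-9)
  flat <- make_ds(list(bad = cbind(timestamps = c(0, 10), xpos = c(0, 5),
                                   ypos = c(3, 3))))
  expect_error(align_start_end(flat), "zero extent")
})

test_that("time normalization is exact for coordinates linear in time", {
  m <- cbind(timestamps = c(0, 100), xpos = c(0, 10), ypos = c(0, -4))
  ds <- time_normalize(make_ds(list(t1 = m)), n_steps = 11)
  arr <- get_trajectories(ds, "tn_trajectories")
  expect_equal(arr["t1", , "timestamps"], seq(0, 100, by = 10))
  expect_equal(arr["t1", 6, "xpos"], 5)                 # x at t = 50
  expect_equal(arr["t1", , "xpos"], seq(0, 10, length.out = 11))
})

test_that("randomized resampling invariants: spacing, endpoints, length", {
  set.seed(77)
  for (rep in 1:40) {
    tr <- random_smooth_trial(n = sample(30:80, 1))
    ds <- make_ds(list(t1 = tr))
    tn <- get_trajectories(time_normalize(ds, n_steps = 51),
                           "tn_trajectories")["t1", , ]
    expect_equal(diff(tn[, "timestamps"]),
                 rep(diff(range(tr[, "timestamps"])) / 50, 50))
    expect_equal(tn[1, c("xpos", "ypos")], tr[1, c("xpos", "ypos")])
    expect_equal(tn[51, c("xpos", "ypos")], tr[nrow(tr), c("xpos", "ypos")])

    ln <- get_trajectories(length_normalize(ds, n_points = 20),
                           "ln_trajectories")["t1", , ]
    # spacing along the path is exactly uniform: arc positions recovered by
    # an independent dense-resampling oracle sit on a regular grid
    L <- oracle_pathlen(tr)
    arcs <- oracle_arc_positions(tr, ln[, c("xpos", "ypos")])
    expect_lt(max(abs(arcs - seq(0, L, length.out = 20))), 2e-3 * L)
    gaps <- diff(arcs)
    expect_lt(stats::sd(gaps) / mean(gaps), 5e-3)   # oracle grid resolution
    expect_equal(ln[1, c("xpos", "ypos")], tr[1, c("xpos", "ypos")])
    expect_equal(ln[20, c("xpos", "ypos")], tr[nrow(tr), c("xpos", "ypos")])
    # path length conserved within 0.5% for realistic smooth inputs
    expect_lt(abs(oracle_pathlen(ln) - L) / L, 0.005)
  }
})

test_that("arc spacing is exactly uniform in the resampler's own metric", {
  set.seed(78)
  for (rep in 1:10) {
    tr <- random_trial(n = sample(20:60, 1))   # jagged is fine here
    ln <- get_trajectories(length_normalize(make_ds(list(t1 = tr)),
                                            n_points = 20),
                           "ln_trajectories")["t1", , ]
    arcs <- oracle_arc_positions(tr, ln[, c("xpos", "ypos")])
    gaps <- diff(arcs)
    expect_lt(stats::sd(gaps) / mean(gaps), 2e-3)
  }
})

test_that("arc-length spacing matches the dense-resampling oracle", {
  m <- cbind(timestamps = c(0, 50, 100), xpos = c(0, 3, 6), ypos = c(0, 4, 8))
  ln <- get_trajectories(length_normalize(make_ds(list(t1 = m)), n_points = 6),
                         "ln_trajectories")["t1", , ]
  gaps <- sqrt(diff(ln[, "xpos"])^2 + diff(ln[, "ypos"])^2)
  expect_equal(unname(gaps), rep(2, 5))                 # 10 / 5 segments
})

test_that("constant-interval resampling reproduces the sampling arithmetic", {
  # a 2-s trial at 10-ms intervals must give 201 positions
  tr <- random_trial(n = 40)
  tr[, "timestamps"] <- tr[, "timestamps"] / max(tr[, "timestamps"]) * 2000
  ds <- resample_trajectories(make_ds(list(t1 = tr)), mode = "constant",
                              interval_ms = 10)
  expect_equal(unname(valid_lengths(ds, "ci_trajectories")), 201L)
  # off-grid duration: final timestamp appended
  tr2 <- tr; tr2[, "timestamps"] <- tr2[, "timestamps"] / 2000 * 1995
  ds2 <- resample_trajectories(make_ds(list(t1 = tr2)), mode = "constant",
                               interval_ms = 10)
  arr <- get_trajectories(ds2, "ci_trajectories")
  expect_equal(unname(valid_lengths(ds2, "ci_trajectories")), 201L)
  expect_equal(arr["t1", 201, "timestamps"], 1995)
})

test_that("resampling adds a representation without touching the source", {
  out <- generate_tracking_data(synth_spec(n_subjects = 2, seed = 2))
  ds <- out$data
  before <- get_trajectories(ds)
  tt_before <- ds$trial_table
  ds2 <- time_normalize(ds)
  expect_identical(get_trajectories(ds2, "trajectories"), before)
  expect_identical(ds2$trial_table, tt_before)
  expect_true("tn_trajectories" %in% names(ds2$representations))
})

test_that("preprocessing commutes with trial subsetting", {
  out <- generate_tracking_data(synth_spec(n_subjects = 3, seed = 8))
  pipeline <- function(d) time_normalize(align_start(remap_symmetric(d)))
  ids <- out$data$trial_table$trial_id[out$data$trial_table$condition ==
                                         "atypical"]
  a <- pipeline(subset_trials(out$data, trial_ids = ids))
  b <- subset_trials(pipeline(out$data), trial_ids = ids)
  expect_equal(get_trajectories(a, "tn_trajectories"),
               get_trajectories(b, "tn_trajectories"))
})

test_that("prototype-distance outlier flagging isolates a constructed loop", {
  set.seed(4)
  # 99 noisy straight reaches plus one wildly looping trial
  base <- seq(0, 1, length.out = 30)
  trials <- lapply(1:99, function(i) {
    cbind(timestamps = base * 1000,
          xpos = -600 * base + rnorm(30, sd = 4),
          ypos = 900 * base + rnorm(30, sd = 4))
  })
  theta <- seq(0, 4 * pi, length.out = 30)
  trials[[100]] <- cbind(timestamps = base * 1000,
                         xpos = -600 * base + 350 * sin(theta),
                         ypos = 900 * base + 350 * cos(theta) - 350)
  names(trials) <- sprintf("t%03d", 1:100)
  ds <- flag_outliers_by_prototype(make_ds(trials))
  expect_equal(sum(ds$trial_table$outlier), 1L)
  expect_true(ds$trial_table$outlier[100])
  expect_gt(ds$trial_table$z_distance[100], 2)
})

test_that("a trial equal to a prototype has zero distance and is not flagged", {
  proto <- standard_prototypes()
  straight <- cbind(timestamps = c(0, 500, 1000),
                    xpos = c(0, -0.5, -1), ypos = c(0, 0.75, 1.5))
  curved <- proto[[2]]$points
  curved <- cbind(timestamps = seq(0, 1000, length.out = nrow(curved)),
                  xpos = curved[, 1], ypos = curved[, 2])
  ds <- make_ds(list(s1 = straight, s2 = straight, s3 = straight, c1 = curved))
  asg <- map_to_prototypes(ds)
  expect_equal(as.character(asg$label), c("straight", "straight", "straight",
                                          "curved"))
  expect_equal(asg$distance[1], 0, tolerance = 1e-9)
  flagged <- suppressWarnings(flag_outliers_by_prototype(ds))
  expect_false(any(flagged$trial_table$outlier))
})
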