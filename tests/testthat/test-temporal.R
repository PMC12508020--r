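make_tn <- function(n_subjects = 6, seed = 1, ...) {
  out <- generate_tracking_data(synth_spec(n_subjects = n_subjects,
                                           seed = seed, ...))
  list(ds = time_normalize(align_start(remap_symmetric(out$data))),
       truth = out$truth)
}

test_that("step aggregates are plain per-step group means", {
  a <- cbind(timestamps = seq(0, 100, length.out = 11),
             xpos = seq(0, 100, length.out = 11), ypos = 0)
  b <- cbind(timestamps = seq(0, 100, length.out = 11),
             xpos = seq(0, 200, length.out = 11), ypos = 0)
  ds <- time_normalize(make_ds(list(t1 = a, t2 = b),
                               meta = data.frame(trial_id = c("t1", "t2"),
                                                 g = c("x", "x"))),
                       n_steps = 11)
  agg <- step_aggregate(ds, feature = "xpos", group_by = "g")
  expect_equal(agg$mean[agg$step == 11], 150)
  expect_equal(agg$n, rep(2L, 11))
  single <- step_aggregate(subset_trials(ds, trial_ids = "t1"),
                           feature = "xpos")
  expect_equal(single$mean, seq(0, 100, length.out = 11))
  expect_true(all(is.na(single$sd)))
})

test_that("aggregate of a disjoint equal-n union is the mean of group aggregates", {
  sim <- make_tn(n_subjects = 4, seed = 44)
  ds <- sim$ds
  ids <- ds$trial_table$trial_id
  half <- seq_len(length(ids) %/% 2 * 2)          # even count
  g <- rep(c("p", "q"), each = length(half) / 2)
  ds <- subset_trials(ds, trial_ids = ids[half])
  ds$trial_table$half <- g
  whole <- step_aggregate(ds, feature = "xpos")
  parts <- step_aggregate(ds, feature = "xpos", group_by = "half")
  m <- tapply(parts$mean, parts$step, mean)
  expect_equal(as.vector(m), whole$mean)
})

test_that("cluster-robust per-step inference matches sandwich/lmtest", {
  skip_if_not_installed("sandwich")
  skip_if_not_installed("lmtest")
  sim <- make_tn(n_subjects = 8, seed = 45)
  st <- step_tests(sim$ds, predictors = "condition", subject = "subject_id")
  M <- get_trajectories(sim$ds, "tn_trajectories")[, , "xpos"]
  tt <- sim$ds$trial_table
  for (s in c(30, 60, 90)) {
    fit <- stats::lm(M[, s] ~ condition, data = tt)
    G <- length(unique(tt$subject_id))
    ct <- lmtest::coeftest(fit,
                           vcov = sandwich::vcovCL(fit,
                                                   cluster = tt$subject_id,
                                                   type = "HC1"),
                           df = G - 1)
    row <- st$table[st$table$step == s &
                    st$table$term == "conditiontypical", ]
    expect_equal(row$estimate, unname(ct[2, 1]), tolerance = 1e-9)
    expect_equal(row$se, unname(ct[2, 2]), tolerance = 1e-9)
    expect_equal(row$p, unname(ct[2, 4]), tolerance = 1e-9)
  }
})

test_that("an injected effect window is detected in roughly the right place", {
  out <- generate_tracking_data(synth_spec(
    n_subjects = 20,
    type_mixture = list(
      typical = c(straight = 1, curved = 0, cCoM = 0, dCoM = 0, dCoM2 = 0),
      atypical = c(straight = 1, curved = 0, cCoM = 0, dCoM = 0, dCoM2 = 0)),
    seed = 46))
  ds <- time_normalize(align_start(remap_symmetric(out$data)))
  inj <- inject_step_effect(ds, out$truth, feature = "xpos",
                            window = c(40, 80), magnitude = 60)
  st <- step_tests(inj$data, predictors = "condition",
                   subject = "subject_id")
  runs <- st$runs
  expect_gte(nrow(runs), 1L)
  main <- runs[which.max(runs$length), ]
  expect_gte(main$start, 35)
  expect_lte(main$end, 85)
  expect_lte(main$start, 45)
  expect_gte(main$end, 75)
  # magnitude 0 leaves the dataset unchanged
  null_inj <- inject_step_effect(ds, out$truth, feature = "xpos",
                                 window = c(40, 80), magnitude = 0)
  expect_equal(get_trajectories(null_inj$data, "tn_trajectories"),
               get_trajectories(ds, "tn_trajectories"))
})

test_that("an orthogonal noise predictor leaves the real effect's run intact", {
  sim <- make_tn(n_subjects = 15, seed = 47)
  ds <- sim$ds
  set.seed(48)
  ds$trial_table$noisevar <- rnorm(nrow(ds$trial_table))
  st1 <- step_tests(ds, predictors = "condition", subject = "subject_id")
  st2 <- step_tests(ds, predictors = c("condition", "noisevar"),
                    subject = "subject_id")
  nv <- st2$table[st2$table$term == "noisevar", ]
  expect_lt(mean(nv$p < 0.05, na.rm = TRUE), 0.15)
  r1 <- st1$runs[st1$runs$term == "conditiontypical", ]
  r2 <- st2$runs[st2$runs$term == "conditiontypical", ]
  expect_equal(nrow(r2), nrow(r1))
  if (nrow(r1)) expect_lte(abs(r1$start[1] - r2$start[1]), 3)
})

test_that("RT stratification partitions trials and drops the slowest", {
  sim <- make_tn(n_subjects = 6, seed = 49)
  ds <- sim$ds
  rt <- apply(get_trajectories(ds)[, , "timestamps", drop = FALSE], 1,
              max, na.rm = TRUE)
  breaks <- c(1500, 2500, 5000)
  suppressMessages(suppressWarnings(
    agg <- stratified_step_aggregate(ds, rt_breaks = breaks,
                                     group_by = "condition")))
  n_in <- tapply(agg$n[agg$step == 1], agg$stratum[agg$step == 1], sum)
  expect_equal(sum(n_in), sum(rt <= 5000))
  expect_error(stratified_step_aggregate(ds, rt_breaks = c(2000, 1000)),
               "increasing")
  # explicit toy partition: sizes 1/1/1 with one exclusion
  toy <- make_ds(lapply(c(800, 2000, 3000, 6000), function(rt) {
    cbind(timestamps = seq(0, rt, length.out = 20),
          xpos = seq(0, -100, length.out = 20),
          ypos = seq(0, 100, length.out = 20))
  }))
  toy <- time_normalize(toy, n_steps = 11)
  expect_message(
    tagg <- stratified_step_aggregate(toy, use = "tn_trajectories",
                                      rt_breaks = breaks),
    "1 trial")
  sizes <- tapply(tagg$n[tagg$step == 1], tagg$stratum[tagg$step == 1], sum)
  expect_equal(as.vector(sizes), c(1L, 1L, 1L))
})

test_that("kinematic profiles are flat for constant-speed movements and dip for dCoM", {
  # constant-speed straight synthetic movement => flat velocity, zero acc
  tmono <- seq(0, 1000, by = 10)
  m <- cbind(timestamps = tmono, xpos = -0.6 * tmono, ypos = 0.9 * tmono)
  asg <- data.frame(trial_id = "t1",
                    label = factor("straight",
                                   levels = prototype_labels(
                                     standard_prototypes())))
  pr <- type_kinematic_profiles(make_ds(list(t1 = m)), asg, smooth_sd = 0)
  expect_lt(stats::sd(pr$vel), 1e-9)
  expect_lt(max(abs(pr$acc)), 1e-12)
  # smoothing with SD 0 equals the unsmoothed profile by construction;
  # nonzero smoothing changes it
  pr2 <- type_kinematic_profiles(make_ds(list(t1 = m)), asg, smooth_sd = 2)
  expect_equal(pr2$vel, pr$vel, tolerance = 1e-9)  # constant stays constant

  # dCoM with a programmed pause: interior dip reaching ~0 between two peaks
  out <- generate_tracking_data(synth_spec(
    n_subjects = 8, noise_sd = 2,
    type_mixture = list(
      typical = c(straight = 0, curved = 0, cCoM = 0, dCoM = 1, dCoM2 = 0),
      atypical = c(straight = 0, curved = 0, cCoM = 0, dCoM = 1, dCoM2 = 0)),
    seed = 50))
  dsd <- out$data
  asgd <- data.frame(trial_id = dsd$trial_table$trial_id,
                     label = factor("dCoM"))
  prd <- type_kinematic_profiles(dsd, asgd)
  v <- prd$vel
  mid <- v[35:70]
  expect_lt(min(mid), 0.15 * max(v))             # near-zero interior dip
  expect_gt(max(v[1:40]), 3 * min(mid))          # a peak on each side
  expect_gt(max(v[60:101]), 3 * min(mid))
})

test_that("profiles ignore synthetic pre-movement idle time (crop)", {
  tmono <- seq(0, 1000, by = 20)
  m <- cbind(timestamps = tmono, xpos = -0.5 * tmono, ypos = 0.8 * tmono)
  idle <- cbind(timestamps = seq(-400, -20, by = 20), xpos = 0, ypos = 0)
  m2 <- rbind(cbind(timestamps = idle[, 1] + 400, xpos = m[1, "xpos"],
                    ypos = m[1, "ypos"]),
              cbind(timestamps = m[, 1] + 400, xpos = m[, "xpos"],
                    ypos = m[, "ypos"]))
  asg <- data.frame(trial_id = c("a", "b"), label = factor(c("s", "s")))
  pa <- type_kinematic_profiles(make_ds(list(a = m)),
                                asg[1, , drop = FALSE], smooth_sd = 0)
  pb <- type_kinematic_profiles(make_ds(list(b = m2)),
                                asg[2, , drop = FALSE], smooth_sd = 0)
  expect_equal(pb$vel, pa$vel, tolerance = 1e-9)
})
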