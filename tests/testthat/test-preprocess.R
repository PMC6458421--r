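test_that("baselines average the valid pre-onset window", {
  smp <- flat_samples(1500, x = 600, y = 450)
  bl <- compute_baseline(smp, scene_onset_ms = 1000)
  expect_equal(bl$x_px, 600)
  expect_equal(bl$y_px, 450)
  expect_equal(bl$n_valid, 300L)
  expect_true(bl$valid)

  # window fully inside a blink: invalid record
  smp$pupil[701:1000] <- NA
  bl <- compute_baseline(smp, scene_onset_ms = 1000)
  expect_false(bl$valid)
  expect_true(is.na(bl$x_px))
})

test_that("noisy baselines concentrate around the true fixation point", {
  scn <- fixture_scene()
  part <- fixture_partition()
  p <- noiseless_params(noise_sd_px = 2)
  err <- vapply(1:30, function(s) {
    tr <- generate_gaze_trial(scn, part, p, "free_viewing", seed = s)
    bl <- compute_baseline(tr)
    abs(bl$x_px - scn$width_px / 2)
  }, numeric(1))
  expect_lt(max(err), 3 * 2 / sqrt(300) + 0.2)
})

test_that("recursive outlier removal matches the direct criterion", {
  # a single gross outlier among 39 tight values: the criterion evaluated
  # directly on the remaining distribution flags exactly that value
  set.seed(11)
  vals <- c(runif(39, 599, 601), 900)
  keep <- recursive_outlier_removal(vals)
  expect_identical(which(!keep), 40L)
  # direct evaluation: 900 exceeds mean +/- 3 sd of the others
  others <- vals[1:38]  # min and max temporarily removed; 900 is the max
  expect_gt(abs(900 - mean(vals[order(vals)][2:39])),
            3 * sd(vals[order(vals)][2:39]))
  # and every retained value survives one more application
  expect_true(all(recursive_outlier_removal(vals[keep])))
})

test_that("degenerate and guarded inputs are left untouched", {
  expect_true(all(recursive_outlier_removal(rep(1, 5))))
  expect_true(all(recursive_outlier_removal(c(0, 100))))
  expect_true(all(recursive_outlier_removal(c(0, 1, 2, 100))))  # n = 4 guard
  # zero-spread remainder still expels an extreme that differs from it
  expect_identical(which(!recursive_outlier_removal(c(5, 5, 5, 5, 9))), 5L)
})

test_that("removal is order-independent and terminates", {
  set.seed(21)
  vals <- c(rnorm(50, 0, 1), 8, -9, 15)
  keep1 <- recursive_outlier_removal(vals)
  perm <- sample(length(vals))
  keep2 <- recursive_outlier_removal(vals[perm])
  expect_equal(sort(vals[keep1]), sort(vals[perm][keep2]))
  # pathological equal-spread input exits rather than looping
  expect_true(all(recursive_outlier_removal(seq(0, 1, length.out = 30))))
})

test_that("drift correction maps the baseline onto screen centre", {
  geom <- fixture_geometry()
  fx <- tibble::tibble(x_px = c(100, 500), y_px = c(100, 300))
  centre_bl <- tibble::tibble(x_px = 320, y_px = 240)
  expect_equal(drift_correct(fx, centre_bl, geom), fx)
  off_bl <- tibble::tibble(x_px = 330, y_px = 235)
  out <- drift_correct(fx, off_bl, geom)
  expect_equal(out$x_px, fx$x_px - 10)
  expect_equal(out$y_px, fx$y_px + 5)
  bad <- tibble::tibble(x_px = NA_real_, y_px = NA_real_)
  expect_error(drift_correct(fx, bad, geom), "invalid baseline")
})

test_that("injected calibration drift is recovered by the correction", {
  scn <- fixture_scene()
  part <- fixture_partition()
  geom <- fixture_geometry()
  p <- noiseless_params()
  err <- c()
  for (s in 1:10) {
    tr <- generate_gaze_trial(scn, part, p, "free_viewing", seed = s)
    drift <- tr$drift_px
    ev <- detect_events(tr$samples, geom)
    fx <- ev[ev$kind == "fixation" & ev$onset_ms >= tr$scene_onset_ms &
               ev$onset_ms < tr$scene_offset_ms, ]
    bl <- compute_baseline(tr)
    # baseline recovers drift, so corrected landing matches the truth target
    corr <- drift_correct(fx, bl, geom)
    ft <- tr$truth[tr$truth$kind == "fixation" &
                     tr$truth$onset_ms >= tr$scene_onset_ms, ]
    m <- min(nrow(corr), nrow(ft))
    err <- c(err, abs(corr$x_px[1:m] - (ft$x_px[1:m] - drift[1])))
  }
  expect_lt(max(err), 1)
})

test_that("trial exclusion drops exactly the planted faults", {
  set.seed(99)
  n_trials <- 40
  per_participant <- function(p) {
    tibble::tibble(
      participant_id = p, trial_id = seq_len(n_trials),
      # bounded noise: a uniform sample never strays past ~1.7 sd of its
      # own spread, so no clean trial can trip the 3 sd criterion
      baseline_x = runif(n_trials, 318, 322),
      baseline_y = runif(n_trials, 238, 242),
      baseline_valid = TRUE, blink_fraction = runif(n_trials, 0, 0.1)
    )
  }
  info <- dplyr::bind_rows(lapply(1:4, per_participant))
  # plant 3 bad baselines and 2 blink-heavy trials per participant
  bad_bl <- info$trial_id %in% c(3, 17, 30)
  info$baseline_x[bad_bl] <- info$baseline_x[bad_bl] + c(150, -200, 180)
  info$baseline_valid[info$trial_id == 17] <- FALSE
  blinky <- info$trial_id %in% c(8, 25)
  info$blink_fraction[blinky] <- c(0.25, 0.20)

  out <- exclude_trials(info)
  expect_equal(sort(unique(out$trial_id[!out$retained])), c(3, 8, 17, 25, 30))
  expect_equal(sum(!out$retained), 4 * 5)
  expect_equal(unique(out$reason[out$trial_id == 17]), "missing_baseline")
  expect_equal(unique(out$reason[out$trial_id == 3]), "baseline_outlier")
  expect_equal(unique(out$reason[out$trial_id == 8]), "blink")
  # a trial at exactly the 20% blink limit is excluded, clean ones retained
  expect_equal(unique(out$reason[out$trial_id == 25]), "blink")
  expect_true(all(out$retained[out$trial_id == 1]))
})
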