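test_that("the degenerate spec renders a uniform scene with empty masks", {
  spec <- scene_spec(64, 48)
  scn <- generate_scene(spec, seed = 1)
  expect_true(all(scn$image == 0.5))
  expect_false(any(scn$head_mask))
  expect_false(any(scn$body_mask))
})

test_that("scene rendering is deterministic and validates shapes", {
  spec <- random_scene_spec(seed = 5, 320, 240)
  s1 <- generate_scene(spec, seed = 9)
  s2 <- generate_scene(spec, seed = 9)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$head_mask, s2$head_mask)
  s3 <- generate_scene(spec, seed = 10)
  expect_false(identical(s1$image, s3$image))

  expect_error(
    scene_spec(100, 100, head_regions = list(
      list(type = "ellipse", cx = 95, cy = 50, rx = 10, ry = 10,
           colour = c(0.6, 0.5, 0.4)))), "off-screen")
  expect_error(
    scene_spec(100, 100, distractor_patches = list(
      list(cx = 2, cy = 50, radius = 10))), "off-screen")
})

test_that("mask geometry matches the analytic shape areas", {
  spec <- scene_spec(200, 200,
    head_regions = list(list(type = "ellipse", cx = 100, cy = 60, rx = 20,
                             ry = 30, colour = c(0.6, 0.5, 0.4))),
    body_regions = list(list(type = "polygon",
                             x = c(60, 140, 140, 60), y = c(100, 100, 180, 180),
                             colour = c(0.5, 0.5, 0.5))))
  scn <- generate_scene(spec, seed = 1)
  expect_equal(sum(scn$head_mask), pi * 20 * 30, tolerance = 0.01)
  expect_equal(sum(scn$body_mask), 80 * 80, tolerance = 0.01)
})

test_that("blink-free parameters produce a complete pupil signal", {
  scn <- fixture_scene(); part <- fixture_partition()
  tr <- generate_gaze_trial(scn, part, behaviour_params(blink_rate_hz = 0),
                            "free_viewing", seed = 3)
  expect_false(anyNA(tr$samples$pupil))
  # timestamps are gapless at the 1 ms clock
  expect_true(all(diff(tr$samples$t_ms) == 1))
  # pre-onset span covers at least the baseline window
  expect_gte(tr$scene_onset_ms, 300)
  expect_lt(tr$scene_onset_ms, tr$scene_offset_ms)
})

test_that("forced first-target probabilities appear verbatim in the truth log", {
  scn <- fixture_scene(); part <- fixture_partition()
  p <- behaviour_params(first_target_probs = c(head = 1, body = 0, lower = 0,
                                               higher = 0),
                        scene_duration_ms = 1500)
  firsts <- vapply(1:50, function(s) {
    tr <- generate_gaze_trial(scn, part, p, "social_detection", seed = s)
    sac <- tr$truth[tr$truth$kind == "saccade", ]
    sac$roi[1]
  }, character(1))
  expect_true(all(firsts == "head"))
})

test_that("zero drift and noise centre the pre-onset gaze exactly", {
  scn <- fixture_scene(); part <- fixture_partition()
  tr <- generate_gaze_trial(scn, part, noiseless_params(), "free_viewing",
                            seed = 4)
  pre <- tr$samples[tr$samples$t_ms < tr$scene_onset_ms, ]
  expect_equal(mean(pre$x_px), scn$width_px / 2)
  expect_equal(mean(pre$y_px), scn$height_px / 2)
})

test_that("generated saccades exceed the detection velocity threshold", {
  scn <- fixture_scene(); part <- fixture_partition()
  geom <- fixture_geometry()
  dpp <- (30.6 / 640) / 52.5 * 180 / pi
  for (s in 1:10) {
    tr <- generate_gaze_trial(scn, part, noiseless_params(), "free_viewing",
                              seed = 100 + s)
    sac <- tr$truth[tr$truth$kind == "saccade", ]
    expect_true(all(sac$peak_vel_px_ms * 1000 * dpp > 30))
  }
})

test_that("excessive latency demands are rejected", {
  expect_error(behaviour_params(latency_mean_ms = 11000), "latency")
  expect_error(behaviour_params(first_target_probs = c(head = 0.9, body = 0.2,
                                                       lower = 0, higher = 0)),
               "sum to 1")
})

test_that("first-fixation ROI frequencies converge to the configured law", {
  scn <- fixture_scene(); part <- fixture_partition()
  probs <- c(head = 0.35, body = 0.16, lower = 0.23, higher = 0.26)
  p <- behaviour_params(first_target_probs = probs, scene_duration_ms = 1200)
  firsts <- vapply(1:2000, function(s) {
    tr <- generate_gaze_trial(scn, part, p, "free_viewing", seed = s)
    tr$truth$roi[tr$truth$kind == "saccade"][1]
  }, character(1))
  counts <- table(factor(firsts, levels = names(probs)))
  gof <- suppressWarnings(chisq.test(counts, p = probs))
  expect_gt(gof$p.value, 0.01)
})

test_that("the dataset plan balances scenes and reproduces under its seed", {
  plan <- dataset_plan(33, 40, seq_len(80), seed = 7)
  expect_equal(nrow(plan), 2640)
  per_part <- dplyr::count(plan, .data$participant_id)
  expect_true(all(per_part$n == 80))
  # each scene appears exactly once per participant
  dup <- dplyr::count(plan, .data$participant_id, .data$scene_id)
  expect_true(all(dup$n == 1))
  expect_identical(plan, dataset_plan(33, 40, seq_len(80), seed = 7))
  expect_false(identical(plan$scene_id, dataset_plan(33, 40, seq_len(80),
                                                     seed = 8)$scene_id))
  expect_error(dataset_plan(5, 40, seq_len(30), seed = 1), "smaller")
  # per-participant jitter induces between-participant variance
  expect_gt(sd(unique(plan$latency_shift_ms)), 0)
  expect_gt(sd(unique(plan$head_logit_shift)), 0)
})

test_that("generated datasets are reproducible end to end", {
  scenes <- build_scene_bank(4, seed = 2, width_px = 320, height_px = 240)
  parts <- lapply(scenes, function(s) {
    build_roi_partition(s, compute_saliency_map(s, saliency_params()))
  })
  p <- default_task_params()
  p <- lapply(p, function(x) { x$scene_duration_ms <- 1500; x })
  d1 <- generate_dataset(2, 2, scenes, parts, p, seed = 11)
  d2 <- generate_dataset(2, 2, scenes, parts, p, seed = 11)
  expect_equal(nrow(d1), 8)
  expect_identical(d1$trial[[1]]$samples, d2$trial[[1]]$samples)
  expect_identical(d1$trial[[8]]$truth, d2$trial[[8]]$truth)
})

test_that("between-participant jitter spreads first-fixation head shares", {
  scn <- fixture_scene(); part <- fixture_partition()
  p <- behaviour_params(scene_duration_ms = 1200)
  share <- vapply(1:8, function(pp) {
    shift <- rnorm(1, 0, p$participant_head_logit_sd)
    firsts <- vapply(1:40, function(s) {
      tr <- generate_gaze_trial(scn, part, p, "free_viewing",
                                seed = pp * 1000 + s, head_logit_shift = shift)
      tr$truth$roi[tr$truth$kind == "saccade"][1]
    }, character(1))
    mean(firsts == "head")
  }, numeric(1))
  expect_gt(var(share), 0)
})

test_that("behaviour params list structure survives YAML round-trip", {
  cfg <- run_config(n_participants = 2, n_trials_per_task = 2, n_scenes = 4,
                    seed = 5)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_run_config(cfg, path)
  back <- read_run_config(path)
  expect_equal(back$n_participants, 2)
  expect_equal(back$tasks$social_detection$latency_mean_ms,
               cfg$tasks$social_detection$latency_mean_ms)
  expect_equal(back$tasks$free_viewing$first_target_probs,
               cfg$tasks$free_viewing$first_target_probs)
  expect_equal(back$saliency$scales, cfg$saliency$scales)
})
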