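test_that("a stable trace yields no saccades and one spanning fixation", {
  geom <- fixture_geometry()
  ev <- detect_events(flat_samples(500), geom)
  expect_equal(sum(ev$kind == "saccade"), 0)
  expect_equal(sum(ev$kind == "fixation"), 1)
  expect_equal(ev$onset_ms[1], 0)
  expect_equal(ev$offset_ms[1], 499)
  expect_equal(ev$x_px[1], 320)

  # slow drift below both thresholds: still no saccade
  smp <- flat_samples(1000)
  smp$x_px <- smp$x_px + seq_len(1000) * 0.1  # 100 px/s ~ 5 deg/s
  ev <- detect_events(smp, geom)
  expect_equal(sum(ev$kind == "saccade"), 0)
})

test_that("a constructed saccade is detected with tight boundaries", {
  geom <- fixture_geometry()
  smp <- saccade_samples(amp_px = 150, dur_ms = 40, pre_ms = 300, post_ms = 300)
  ev <- detect_events(smp, geom)
  sac <- ev[ev$kind == "saccade", ]
  expect_equal(nrow(sac), 1)
  # peak velocity of the raised-cosine profile: 2 * amp / dur
  peak_expected <- 2 * 150 / 40 * 1000 * (30.6 / 640) / 52.5 * 180 / pi
  expect_equal(sac$peak_vel_deg_s, peak_expected, tolerance = 0.05)
  expect_lt(abs(sac$onset_ms - 300), 6)
  expect_lt(abs(sac$offset_ms - 340), 6)
  fix <- ev[ev$kind == "fixation", ]
  expect_equal(nrow(fix), 2)
  expect_equal(fix$x_px, c(200, 350), tolerance = 0.5)
})

test_that("detection reproduces the generator truth on noiseless trials", {
  scn <- fixture_scene()
  part <- fixture_partition()
  geom <- fixture_geometry()
  p0 <- noiseless_params(scene_duration_ms = 3000)
  n_match <- 0
  for (s in 1:150) {
    tr <- generate_gaze_trial(scn, part, p0, "free_viewing", seed = s)
    ev <- detect_events(tr$samples, geom)
    if (sum(ev$kind == "saccade") == sum(tr$truth$kind == "saccade")) {
      n_match <- n_match + 1
    }
  }
  expect_equal(n_match, 150)

  # fixation boundaries track the truth log within a few milliseconds
  tr <- generate_gaze_trial(scn, part, p0, "free_viewing", seed = 977)
  ev <- detect_events(tr$samples, geom)
  fx <- ev[ev$kind == "fixation" & ev$onset_ms >= tr$scene_onset_ms, ]
  ft <- tr$truth[tr$truth$kind == "fixation" &
                   tr$truth$onset_ms >= tr$scene_onset_ms, ]
  m <- min(nrow(fx), nrow(ft))
  expect_gt(m, 0)
  expect_lt(max(abs(fx$onset_ms[1:m] - ft$onset_ms[1:m])), 5)
})

test_that("event kinds partition the valid timeline", {
  scn <- fixture_scene()
  part <- fixture_partition()
  geom <- fixture_geometry()
  tr <- generate_gaze_trial(scn, part, behaviour_params(blink_rate_hz = 0),
                            "free_viewing", seed = 42)
  ev <- detect_events(tr$samples, geom)
  ev <- ev[order(ev$onset_ms), ]
  # without blinks, fixations and saccades tile the trace without overlap
  expect_true(all(diff(ev$onset_ms) > 0))
  expect_true(all(ev$offset_ms[-nrow(ev)] < ev$onset_ms[-1]))
  covered <- sum(ev$offset_ms - ev$onset_ms + 1)
  expect_equal(covered, nrow(tr$samples))
})

test_that("doubling the sample rate leaves event counts unchanged", {
  geom <- fixture_geometry()
  smp1 <- saccade_samples(amp_px = 120, dur_ms = 40)
  # same trajectory sampled at 2 kHz
  t2 <- seq(0, max(smp1$t_ms), by = 0.5)
  x2 <- approx(smp1$t_ms, smp1$x_px, t2)$y
  smp2 <- tibble::tibble(t_ms = t2, x_px = x2, y_px = 240, pupil = 1000)
  ev1 <- detect_events(smp1, geom)
  ev2 <- detect_events(smp2, geom)
  expect_equal(table(ev1$kind), table(ev2$kind))
})

test_that("blink handling isolates missing-pupil runs", {
  geom <- fixture_geometry()
  smp <- flat_samples(1000)
  smp$pupil[400:499] <- NA
  ev <- detect_events(smp, geom)
  bl <- ev[ev$kind == "blink", ]
  expect_equal(nrow(bl), 1)
  expect_equal(bl$onset_ms, 399)  # t starts at 0
  expect_equal(bl$offset_ms, 498)
  # classification never labels padded blink samples as saccade
  expect_equal(sum(ev$kind == "saccade"), 0)

  all_na <- flat_samples(100)
  all_na$pupil <- NA
  expect_warning(ev <- detect_events(all_na, geom), "missing")
  expect_true(isTRUE(attr(ev, "all_missing")))
})

test_that("blink fraction measures scene-window contamination", {
  smp <- flat_samples(11000)
  expect_equal(blink_fraction(smp, 1000, 11000), 0)
  smp$pupil[3001:5500] <- NA  # 2.5 s inside a 10 s scene
  expect_equal(blink_fraction(smp, 1000, 11000), 0.25)

  # generator with a configured 15% blink load
  scn <- fixture_scene()
  part <- fixture_partition()
  heavy <- behaviour_params(blink_rate_hz = 1,
                            blink_duration_mean_ms = 150,
                            blink_duration_sd_ms = 1)
  fr <- vapply(1:40, function(s) {
    blink_fraction(generate_gaze_trial(scn, part, heavy, "free_viewing",
                                       seed = s))
  }, numeric(1))
  # nominal load = rate x duration = 0.15; overlap and window edges shave
  # a little off, so allow a generous band around it
  expect_gt(mean(fr), 0.10)
  expect_lt(mean(fr), 0.18)
})

test_that("sample streams round-trip through delimited text and ASC lines", {
  smp <- flat_samples(50)
  smp$pupil[10:12] <- NA
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gaze_samples(smp, path)
  back <- read_gaze_samples(path)
  expect_equal(as.data.frame(back), as.data.frame(smp))

  asc <- withr::local_tempfile(fileext = ".asc")
  writeLines(c(
    "MSG 1 TRIALID 1",
    "100 320.1 240.2 1000.0",
    "101 320.2 240.1 999.0",
    "102 . . .",
    "EFIX R 100 102"
  ), asc)
  back <- read_gaze_samples(asc, format = "asc")
  expect_equal(nrow(back), 3)
  expect_true(is.na(back$pupil[3]))
  expect_equal(back$x_px[1], 320.1)
})
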