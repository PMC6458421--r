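#' Behavioural parameters of the gaze simulator
#'
#' Describes how a simulated participant behaves in one task condition.
#' The trial structure mirrors a central fixation cross for 1 s followed by
#' the scene for 10 s, sampled at 1000 Hz. After scene onset the first
#' saccade is launched at a normally distributed latency towards a point
#' drawn uniformly from a ROI chosen with `first_target_probs`; subsequent
#' fixation targets are drawn from the task-independent
#' `subsequent_target_probs`. Saccades follow a symmetric raised-cosine
#' velocity profile whose duration scales with amplitude
#' (`21 ms + 2.2 ms/deg`, a main-sequence-like rule), so peak velocity
#' grows with amplitude and comfortably exceeds detection thresholds.
#' Blinks arrive as a Poisson process; during a blink the pupil signal is
#' missing and the reported position freezes at the last valid sample.
#' A constant per-trial calibration drift offset shifts all samples; with
#' probability `misfixation_prob` the participant additionally fails to
#' fixate the cross, displacing only the pre-onset samples — the failure
#' mode the baseline outlier removal is designed to catch.
#'
#' @param first_target_probs Named probabilities over
#'   `c("head", "body", "lower", "higher")` for the first fixation target;
#'   must sum to 1.
#' @param subsequent_target_probs Same, for later fixations.
#' @param latency_mean_ms,latency_sd_ms,latency_min_ms First-saccade
#'   latency distribution (normal, truncated below).
#' @param fixation_mean_ms,fixation_sd_ms,fixation_min_ms Fixation duration
#'   distribution.
#' @param min_saccade_amp_px Minimum saccade amplitude; landing points
#'   closer than this to the current position are redrawn, so that every
#'   generated saccade's peak velocity clears standard detection
#'   thresholds (scene viewing shows essentially no saccades below about
#'   one degree).
#' @param drift_sd_px Per-trial calibration drift (s.d. of a constant
#'   offset, each axis).
#' @param misfixation_prob,misfixation_range_px Probability and offset
#'   magnitude range of pre-onset fixation failure.
#' @param noise_sd_px Gaussian position noise per sample.
#' @param blink_rate_hz,blink_duration_mean_ms,blink_duration_sd_ms Blink
#'   process.
#' @param sample_rate_hz Sampling rate (the trial clock is 1 ms at the
#'   default 1000 Hz).
#' @param pre_onset_ms,scene_duration_ms Trial phase durations.
#' @param post_offset_ms Recording continued after scene offset (the
#'   inter-trial fixation cross period), so movements in flight at offset
#'   complete inside the sample stream.
#' @param participant_latency_sd_ms Between-participant s.d. of the latency
#'   mean.
#' @param participant_head_logit_sd Between-participant s.d. of the head
#'   first-target probability on the logit scale.
#' @return An object of class `behaviour_params`.
#' @export
behaviour_params <- function(first_target_probs = c(head = 0.35, body = 0.16,
                                                    lower = 0.23, higher = 0.26),
                             subsequent_target_probs = c(head = 0.30, body = 0.25,
                                                         lower = 0.25, higher = 0.20),
                             latency_mean_ms = 280, latency_sd_ms = 40,
                             latency_min_ms = 80,
                             fixation_mean_ms = 250, fixation_sd_ms = 50,
                             fixation_min_ms = 80,
                             min_saccade_amp_px = 15,
                             drift_sd_px = 5,
                             misfixation_prob = 0.02,
                             misfixation_range_px = c(50, 150),
                             noise_sd_px = 0.2,
                             blink_rate_hz = 0.02,
                             blink_duration_mean_ms = 150,
                             blink_duration_sd_ms = 30,
                             sample_rate_hz = 1000,
                             pre_onset_ms = 1000,
                             scene_duration_ms = 10000,
                             post_offset_ms = 200,
                             participant_latency_sd_ms = 8,
                             participant_head_logit_sd = 0.3) {
  p <- as.list(environment())
  for (nm in c("first_target_probs", "subsequent_target_probs")) {
    pr <- p[[nm]]
    if (!setequal(names(pr), roi_levels()) || any(pr < 0) ||
        abs(sum(pr) - 1) > 1e-8) {
      abort(sprintf("`%s` must be non-negative over %s and sum to 1",
                    nm, paste(roi_levels(), collapse = "/")))
    }
    p[[nm]] <- pr[roi_levels()]
  }
  durs <- c(p$latency_mean_ms, p$fixation_mean_ms, p$blink_duration_mean_ms,
            p$pre_onset_ms, p$scene_duration_ms)
  if (any(durs <= 0)) abort("all durations must be positive")
  if (p$latency_mean_ms >= p$scene_duration_ms) {
    abort("first-saccade latency cannot exceed the scene duration")
  }
  if (p$pre_onset_ms < 300) abort("pre-onset span must be at least 300 ms")
  structure(p, class = "behaviour_params")
}

#' Default per-task behaviour parameters
#'
#' The study conditions the simulator emulates: under social detection the
#' first fixation targets heads (and bodies) more often and is launched
#' 20 ms earlier than under free viewing; everything downstream of the
#' first fixation is task-independent.
#'
#' @return Named list with `free_viewing` and `social_detection`
#'   [behaviour_params()].
#' @export
default_task_params <- function() {
  list(
    free_viewing = behaviour_params(
      first_target_probs = c(head = 0.35, body = 0.16, lower = 0.23, higher = 0.26),
      latency_mean_ms = 280
    ),
    social_detection = behaviour_params(
      first_target_probs = c(head = 0.50, body = 0.22, lower = 0.11, higher = 0.17),
      latency_mean_ms = 260
    )
  )
}

# uniform landing point inside a ROI, by rejection over the label grid
sample_roi_point <- function(partition, roi) {
  lab <- match(roi, roi_levels())
  h <- nrow(partition$labels); w <- ncol(partition$labels)
  for (round in 1:50) {
    x <- runif(400, 0, w); y <- runif(400, 0, h)
    hit <- partition$labels[cbind(floor(y) + 1, floor(x) + 1)] == lab
    if (any(hit)) {
      i <- which(hit)[1]
      return(c(x = x[i], y = y[i]))
    }
  }
  abort(sprintf("ROI '%s' appears to be empty; cannot place a fixation", roi))
}

rtruncnorm1 <- function(n, mean, sd, lower) pmax(lower, rnorm(n, mean, sd))

#' Simulate one gaze trial
#'
#' Generates a 1000 Hz sample stream for a single presentation of `scene`:
#' 1 s of central fixation, then a sequence of saccades and fixations over
#' the scene as described in [behaviour_params()], with a ground-truth
#' event log attached. Deterministic under a fixed seed.
#'
#' @param scene A [generate_scene()] object.
#' @param partition The scene's [build_roi_partition()]; fixation targets
#'   are drawn from its labels.
#' @param params A [behaviour_params()].
#' @param task Task label, e.g. `"free_viewing"` or `"social_detection"`.
#' @param seed Integer seed.
#' @param participant_id,trial_id Identifiers carried through.
#' @param latency_shift_ms,head_logit_shift Participant-level adjustments:
#'   added to the latency mean, and to the logit of the head first-target
#'   probability (other ROIs are rescaled proportionally).
#' @return An object of class `gaze_trial`: `samples` tibble (`t_ms`,
#'   `x_px`, `y_px`, `pupil`), `scene_onset_ms`, `scene_offset_ms`, `truth`
#'   event log tibble, identifiers.
#' @examples
#' scn <- generate_scene(random_scene_spec(seed = 3, 160, 120), seed = 3)
#' sal <- compute_saliency_map(scn, saliency_params(reference_scale = 0.05))
#' part <- build_roi_partition(scn, sal)
#' trial <- generate_gaze_trial(scn, part, behaviour_params(), "free_viewing", seed = 9)
#' head(trial$truth)
#' @export
generate_gaze_trial <- function(scene, partition, params, task, seed,
                                participant_id = 1L, trial_id = 1L,
                                latency_shift_ms = 0, head_logit_shift = 0) {
  stopifnot(inherits(scene, "scene"), inherits(partition, "roi_partition"),
            inherits(params, "behaviour_params"))
  dt <- 1000 / params$sample_rate_hz
  onset <- params$pre_onset_ms
  offset <- onset + params$scene_duration_ms
  t <- seq(0, offset + params$post_offset_ms, by = dt)
  n <- length(t)
  ctr <- c(x = scene$width_px / 2, y = scene$height_px / 2)

  first_probs <- shift_head_prob(params$first_target_probs, head_logit_shift)

  withr::with_seed(seed, {
    drift <- rnorm(2, 0, params$drift_sd_px)
    x <- rep(ctr["x"] + drift[1], n)
    y <- rep(ctr["y"] + drift[2], n)

    latency <- rtruncnorm1(1, params$latency_mean_ms + latency_shift_ms,
                           params$latency_sd_ms, params$latency_min_ms)
    latency <- min(latency, params$scene_duration_ms - 200)

    truth <- list()
    cur <- c(ctr["x"] + drift[1], ctr["y"] + drift[2])
    t_cursor <- onset + latency
    truth[[1]] <- list(kind = "fixation", onset_ms = 0, offset_ms = t_cursor,
                       roi = NA_character_, x_px = cur[1], y_px = cur[2],
                       peak_vel_px_ms = NA_real_)
    first <- TRUE
    while (t_cursor < offset) {
      probs <- if (first) first_probs else params$subsequent_target_probs
      roi <- sample(roi_levels(), 1, prob = probs)
      for (try in 1:20) {
        target <- sample_roi_point(partition, roi) + drift
        amp <- sqrt(sum((target - cur)^2))
        if (amp >= params$min_saccade_amp_px) break
      }
      # main-sequence-like duration; amplitude in px scaled by a nominal
      # 0.05 deg/px stimulus pitch
      dur <- max(12, round(21 + 2.2 * amp * 0.05))
      s0 <- t_cursor; s1 <- min(t_cursor + dur, offset + 0)
      idx <- which(t >= s0 & t < s0 + dur)
      if (length(idx) > 0) {
        tau <- (t[idx] - s0) / dur
        f <- tau - sin(2 * pi * tau) / (2 * pi)
        x[idx] <- cur[1] + (target[1] - cur[1]) * f
        y[idx] <- cur[2] + (target[2] - cur[2]) * f
      }
      x[t >= s0 + dur] <- target[1]
      y[t >= s0 + dur] <- target[2]
      truth[[length(truth) + 1]] <- list(
        kind = "saccade", onset_ms = s0, offset_ms = s0 + dur,
        roi = roi, x_px = target[1], y_px = target[2],
        peak_vel_px_ms = 2 * amp / dur
      )
      fdur <- rtruncnorm1(1, params$fixation_mean_ms, params$fixation_sd_ms,
                          params$fixation_min_ms)
      truth[[length(truth) + 1]] <- list(
        kind = "fixation", onset_ms = s0 + dur,
        offset_ms = min(s0 + dur + fdur, max(t)),
        roi = roi, x_px = target[1], y_px = target[2],
        peak_vel_px_ms = NA_real_
      )
      cur <- target
      t_cursor <- s0 + dur + fdur
      first <- FALSE
    }

    if (params$misfixation_prob > 0 && runif(1) < params$misfixation_prob) {
      ang <- runif(1, 0, 2 * pi)
      mag <- runif(1, params$misfixation_range_px[1], params$misfixation_range_px[2])
      pre <- t < onset
      x[pre] <- x[pre] + mag * cos(ang)
      y[pre] <- y[pre] + mag * sin(ang)
    }

    if (params$noise_sd_px > 0) {
      x <- x + rnorm(n, 0, params$noise_sd_px)
      y <- y + rnorm(n, 0, params$noise_sd_px)
    }

    pupil <- 1000 + rnorm(n, 0, 5)
    n_blinks <- rpois(1, params$blink_rate_hz * (offset / 1000))
    blink_log <- list()
    if (n_blinks > 0) {
      for (bi in seq_len(n_blinks)) {
        b0 <- runif(1, 0, offset)
        bd <- rtruncnorm1(1, params$blink_duration_mean_ms,
                          params$blink_duration_sd_ms, 40)
        sel <- t >= b0 & t < b0 + bd
        if (!any(sel)) next
        pupil[sel] <- NA
        i0 <- which(sel)[1]
        if (i0 > 1) {  # freeze position at last valid sample
          x[sel] <- x[i0 - 1]
          y[sel] <- y[i0 - 1]
        }
        blink_log[[length(blink_log) + 1]] <- list(
          kind = "blink", onset_ms = b0, offset_ms = min(b0 + bd, max(t)),
          roi = NA_character_, x_px = NA_real_, y_px = NA_real_,
          peak_vel_px_ms = NA_real_
        )
      }
    }

    truth_tbl <- dplyr::bind_rows(c(truth, blink_log))
    truth_tbl <- truth_tbl[order(truth_tbl$onset_ms), ]

    structure(
      list(
        participant_id = participant_id, task = task,
        scene_id = scene$scene_id, trial_id = trial_id,
        samples = tibble(t_ms = t, x_px = x, y_px = y, pupil = pupil),
        scene_onset_ms = onset, scene_offset_ms = offset,
        truth = truth_tbl, seed = seed,
        drift_px = drift, first_latency_ms = latency
      ),
      class = "gaze_trial"
    )
  })
}

shift_head_prob <- function(probs, logit_shift) {
  if (logit_shift == 0) return(probs)
  ph <- probs[["head"]]
  ph2 <- stats::plogis(stats::qlogis(ph) + logit_shift)
  rest <- probs[setdiff(names(probs), "head")]
  out <- c(head = ph2, rest / sum(rest) * (1 - ph2))
  out[names(probs)]
}

#' @export
print.gaze_trial <- function(x, ...) {
  cat(sprintf(
    "<gaze_trial> participant %s, %s, scene %s: %d samples, %d truth events\n",
    format(x$participant_id), x$task, format(x$scene_id),
    nrow(x$samples), nrow(x$truth)))
  invisible(x)
}

#' Write a ground-truth event log as delimited text
#'
#' @param trial A [generate_gaze_trial()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_log <- function(trial, path) {
  write.table(as.data.frame(trial$truth), path, sep = "\t",
              row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Plan the trial structure of a simulated study
#'
#' Each participant sees every scene at most once: the scene bank is
#' shuffled per participant and split between the two task blocks
#' (free viewing first, social detection second, as in a blocked design).
#' Per-trial seeds are derived deterministically from the master seed.
#'
#' @param n_participants,n_trials_per_task Positive counts.
#' @param scene_ids Vector of scene identifiers (needs at least
#'   `2 * n_trials_per_task`).
#' @param seed Master seed.
#' @return A tibble with one row per trial: `participant_id`, `task`,
#'   `trial_id` (sequential within participant), `scene_id`, `trial_seed`,
#'   plus per-participant `latency_shift_ms` and `head_logit_shift` drawn
#'   from the jitter parameters in `params`.
#' @param params Named list of [behaviour_params()] per task (jitter
#'   s.d.s are read from the first element).
#' @export
dataset_plan <- function(n_participants, n_trials_per_task, scene_ids, seed,
                         params = default_task_params()) {
  if (n_participants < 1 || n_trials_per_task < 1) abort("counts must be positive")
  if (length(scene_ids) < 2 * n_trials_per_task) {
    abort("scene bank is smaller than the number of trials per participant")
  }
  p0 <- params[[1]]
  withr::with_seed(derive_seed(seed, 1), {
    rows <- purrr::map(seq_len(n_participants), function(p) {
      lat <- rnorm(1, 0, p0$participant_latency_sd_ms)
      hls <- rnorm(1, 0, p0$participant_head_logit_sd)
      scn <- sample(scene_ids, 2 * n_trials_per_task)
      tibble(
        participant_id = p,
        task = rep(c("free_viewing", "social_detection"),
                   each = n_trials_per_task),
        trial_id = seq_len(2 * n_trials_per_task),
        scene_id = scn,
        trial_seed = vapply(seq_len(2 * n_trials_per_task),
                            function(i) derive_seed(seed, p * 100003 + i),
                            integer(1)),
        latency_shift_ms = lat,
        head_logit_shift = hls
      )
    })
    dplyr::bind_rows(rows)
  })
}

#' Generate a full synthetic dataset
#'
#' Materializes every trial of a [dataset_plan()]. Intended for small to
#' moderate designs; for study-sized runs prefer [run_study()], which
#' processes trials in a stream without holding all sample data in memory.
#'
#' @param n_participants,n_trials_per_task,seed See [dataset_plan()].
#' @param scenes List of [generate_scene()] objects.
#' @param partitions Named/indexed list of [build_roi_partition()] objects
#'   aligned with `scenes`.
#' @param params Named list of [behaviour_params()] per task.
#' @return The plan tibble with a list-column `trial` of `gaze_trial`
#'   objects.
#' @export
generate_dataset <- function(n_participants, n_trials_per_task, scenes,
                             partitions, params = default_task_params(),
                             seed = 1L) {
  ids <- vapply(scenes, function(s) s$scene_id, integer(1))
  plan <- dataset_plan(n_participants, n_trials_per_task, ids, seed, params)
  plan$trial <- purrr::pmap(plan, function(participant_id, task, trial_id,
                                           scene_id, trial_seed,
                                           latency_shift_ms, head_logit_shift) {
    k <- match(scene_id, ids)
    generate_gaze_trial(scenes[[k]], partitions[[k]], params[[task]], task,
                        seed = trial_seed, participant_id = participant_id,
                        trial_id = trial_id,
                        latency_shift_ms = latency_shift_ms,
                        head_logit_shift = head_logit_shift)
  })
  plan
}
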