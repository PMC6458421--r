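#' Baseline gaze position before scene onset
#'
#' The mean of the valid (non-missing-pupil) sample positions in the
#' `window_ms` interval directly preceding scene onset, i.e.
#' `[onset - window_ms, onset)`. Used for drift correction: during this
#' window the participant is assumed to fixate the central cross, so any
#' offset of the baseline from screen centre reflects calibration drift.
#'
#' @param samples Sample tibble or a [generate_gaze_trial()] object.
#' @param scene_onset_ms Scene onset time (taken from the trial object if
#'   one is supplied).
#' @param window_ms Baseline window length, default 300 ms.
#' @return A one-row tibble: `x_px`, `y_px`, `n_valid`, `valid`. The record
#'   is invalid (positions `NA`) when no valid sample falls in the window.
#' @export
compute_baseline <- function(samples, scene_onset_ms = NULL, window_ms = 300) {
  if (inherits(samples, "gaze_trial")) {
    scene_onset_ms <- scene_onset_ms %||% samples$scene_onset_ms
    samples <- samples$samples
  }
  stopifnot(!is.null(scene_onset_ms))
  sel <- samples$t_ms >= scene_onset_ms - window_ms &
    samples$t_ms < scene_onset_ms & !is.na(samples$pupil)
  n <- sum(sel)
  if (n == 0) {
    return(tibble(x_px = NA_real_, y_px = NA_real_, n_valid = 0L, valid = FALSE))
  }
  tibble(x_px = mean(samples$x_px[sel]), y_px = mean(samples$y_px[sel]),
         n_valid = n, valid = TRUE)
}

#' Recursive outlier removal over a distribution of values
#'
#' The procedure applied to a participant's per-trial baseline coordinates:
#' the current minimum and maximum are temporarily taken out of the
#' distribution; if either lies more than `sd_mult` standard deviations
#' (sample s.d., n - 1 denominator) from the mean of the remaining values,
#' it is discarded permanently. This is iterated on the shrinking
#' distribution until neither extreme meets the criterion. Both extremes
#' may be discarded in the same iteration. Recursion stops when fewer than
#' three values would remain after the temporary removal (the s.d. of the
#' remainder is then degenerate), so inputs of fewer than five values are
#' returned untouched. A zero-spread remainder removes an extreme only if
#' it actually differs from the remainder mean.
#'
#' @param values Numeric vector; `NA`s are never retained but do not
#'   participate in the criterion.
#' @param sd_mult Removal criterion in standard deviations, default 3.
#' @return A logical vector, `TRUE` for retained entries.
#' @examples
#' keep <- recursive_outlier_removal(c(rnorm(39, 600, 0.5), 900))
#' which(!keep)
#' @export
recursive_outlier_removal <- function(values, sd_mult = 3) {
  keep <- !is.na(values)
  repeat {
    active <- which(keep)
    if (length(active) < 5) break  # fewer than 3 would remain; sd degenerate
    v <- values[active]
    i_min <- active[which.min(v)]
    i_max <- active[which.max(v)]
    rest <- setdiff(active, c(i_min, i_max))
    m <- mean(values[rest])
    s <- sd(values[rest])
    drop_min <- abs(values[i_min] - m) > sd_mult * s
    drop_max <- abs(values[i_max] - m) > sd_mult * s
    if (!drop_min && !drop_max) break
    if (drop_min) keep[i_min] <- FALSE
    if (drop_max) keep[i_max] <- FALSE
  }
  keep
}

#' Drift-correct fixation centroids against a baseline
#'
#' Shifts every fixation centroid by the vector from the baseline position
#' to the screen centre, so that gaze recorded while the participant
#' fixated the central cross maps exactly onto the centre.
#'
#' @param fixations Tibble with `x_px`, `y_px` columns (other columns pass
#'   through).
#' @param baseline A one-row tibble from [compute_baseline()] (or anything
#'   with `x_px`, `y_px`).
#' @param geometry A [geometry()] object.
#' @return `fixations` with corrected coordinates.
#' @export
drift_correct <- function(fixations, baseline, geometry) {
  stopifnot(inherits(geometry, "gaze_geometry"))
  if (is.na(baseline$x_px[1]) || is.na(baseline$y_px[1])) {
    abort("cannot drift-correct against an invalid baseline; exclude the trial")
  }
  ctr <- screen_centre(geometry)
  fixations$x_px <- fixations$x_px + (ctr["x"] - baseline$x_px[1])
  fixations$y_px <- fixations$y_px + (ctr["y"] - baseline$y_px[1])
  fixations
}

#' Apply the trial exclusion criteria
#'
#' A trial is retained only if (a) its baseline record is valid and
#' survives the recursive outlier removal applied, separately for x and y,
#' to the participant's baseline distribution across all their trials, and
#' (b) less than `max_blink_fraction` of the scene presentation was
#' contaminated by blinks.
#'
#' @param trial_info Tibble with one row per trial and columns
#'   `participant_id`, `trial_id`, `baseline_x`, `baseline_y`,
#'   `baseline_valid` (logical), `blink_fraction`.
#' @param max_blink_fraction Blink exclusion threshold (trials with a
#'   fraction at or above it are dropped), default 0.20.
#' @param sd_mult Outlier criterion passed to
#'   [recursive_outlier_removal()].
#' @return `trial_info` with added logical `retained` and a `reason` column
#'   (`NA` for retained trials; otherwise `"missing_baseline"`,
#'   `"baseline_outlier"` or `"blink"`, the first criterion that fired).
#' @export
exclude_trials <- function(trial_info, max_blink_fraction = 0.20, sd_mult = 3) {
  needed <- c("participant_id", "trial_id", "baseline_x", "baseline_y",
              "baseline_valid", "blink_fraction")
  stopifnot(all(needed %in% names(trial_info)))
  out <- dplyr::group_by(trial_info, .data$participant_id)
  out <- dplyr::mutate(
    out,
    .keep_x = recursive_outlier_removal(.data$baseline_x, sd_mult = sd_mult),
    .keep_y = recursive_outlier_removal(.data$baseline_y, sd_mult = sd_mult)
  )
  out <- dplyr::ungroup(out)
  out$reason <- dplyr::case_when(
    !out$baseline_valid ~ "missing_baseline",
    !(out$.keep_x & out$.keep_y) ~ "baseline_outlier",
    out$blink_fraction >= max_blink_fraction ~ "blink",
    TRUE ~ NA_character_
  )
  out$retained <- is.na(out$reason)
  out$.keep_x <- NULL
  out$.keep_y <- NULL
  out
}

#' Write an exclusion audit table
#'
#' @param trial_info Output of [exclude_trials()].
#' @param path Output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_exclusion_audit <- function(trial_info, path) {
  cols <- c("participant_id", "trial_id", "retained", "reason")
  write.table(as.data.frame(trial_info[, cols]), path, sep = "\t",
              row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
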