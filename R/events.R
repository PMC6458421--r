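#' Read and write gaze sample streams
#'
#' The native format is tab-delimited text with columns `t_ms`, `x_px`,
#' `y_px`, `pupil`; an empty `pupil` field marks missing pupil data (a
#' blink). `read_gaze_samples()` also accepts EyeLink-ASC-style sample
#' lines (`format = "asc"`): whitespace-separated
#' `timestamp x y pupil`, with `.` for missing fields; non-sample lines
#' (messages, events) are skipped.
#'
#' @param path File to read or write.
#' @param format `"tsv"` or `"asc"`.
#' @param samples A tibble with columns `t_ms`, `x_px`, `y_px`, `pupil`.
#' @return A tibble of samples; the writer returns `path` invisibly.
#' @export
read_gaze_samples <- function(path, format = c("tsv", "asc")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read.delim(path, na.strings = c("", "NA", "."))
    stopifnot(all(c("t_ms", "x_px", "y_px", "pupil") %in% names(df)))
    return(as_tibble(df[, c("t_ms", "x_px", "y_px", "pupil")]))
  }
  lines <- readLines(path)
  # ASC sample lines start with a numeric timestamp
  keep <- grepl("^\\s*\\d", lines)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  fields <- fields[vapply(fields, length, integer(1)) >= 4]
  num <- function(i) {
    v <- vapply(fields, `[[`, character(1), i)
    suppressWarnings(as.numeric(ifelse(v == ".", NA, v)))
  }
  tibble(t_ms = num(1), x_px = num(2), y_px = num(3), pupil = num(4))
}

#' @rdname read_gaze_samples
#' @export
write_gaze_samples <- function(samples, path) {
  df <- as.data.frame(samples[, c("t_ms", "x_px", "y_px", "pupil")])
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Parse gaze samples into saccades, fixations and blinks
#'
#' Saccades are maximal runs of samples whose angular velocity exceeds
#' `vel_thresh` or whose acceleration exceeds `acc_thresh`, sustained for at
#' least `min_saccade_ms`. Velocity is estimated by a five-sample central
#' difference of position, converted to degrees with the small-angle factor
#' at screen centre; acceleration applies the same five-sample operator to
#' the speed, keeping sample noise out of the acceleration criterion.
#' Blinks are runs of missing pupil data, padded by `blink_pad_ms` on each
#' side when classifying (pupil-edge position artefacts); the reported
#' blink events span the raw missing-pupil run. All remaining time is
#' classified as fixation, with the sample centroid as position. No minimum
#' fixation duration is imposed.
#'
#' @param samples Tibble with `t_ms`, `x_px`, `y_px`, `pupil` at a constant
#'   sample rate.
#' @param geometry A [geometry()] object.
#' @param vel_thresh Saccade velocity threshold, degrees/s.
#' @param acc_thresh Saccade acceleration threshold, degrees/s^2.
#' @param min_saccade_ms Minimum sustained threshold crossing.
#' @param blink_pad_ms Blink padding for classification.
#'
#' @return A tibble of events: `kind` (`saccade`/`fixation`/`blink`),
#'   `onset_ms`, `offset_ms` (time of last sample in the event), `x_px`,
#'   `y_px` (fixation centroid), `peak_vel_deg_s` (saccades), `off_screen`
#'   flag for fixation centroids outside the screen. If every sample is
#'   missing, an empty tibble with attribute `all_missing = TRUE`.
#' @examples
#' geom <- geometry()
#' smp <- tibble::tibble(t_ms = 0:499, x_px = 320, y_px = 240, pupil = 1000)
#' detect_events(smp, geom)
#' @export
detect_events <- function(samples, geometry,
                          vel_thresh = 30, acc_thresh = 8000,
                          min_saccade_ms = 4, blink_pad_ms = 25) {
  stopifnot(inherits(geometry, "gaze_geometry"))
  n <- nrow(samples)
  if (n < 3) abort("need at least 3 samples to parse events")
  t <- samples$t_ms
  if (any(diff(t) <= 0)) abort("sample timestamps must be strictly increasing")
  dt <- median(diff(t))

  empty <- tibble(kind = character(), onset_ms = numeric(),
                  offset_ms = numeric(), x_px = numeric(), y_px = numeric(),
                  peak_vel_deg_s = numeric(), off_screen = logical())
  missing <- is.na(samples$pupil)
  if (all(missing)) {
    warn("all samples have missing pupil data")
    ev <- rbind(empty, run_events(rep(TRUE, n), t, "blink"))
    attr(ev, "all_missing") <- TRUE
    return(ev)
  }

  # five-sample central-difference velocity, per axis, px/ms -> deg/s
  vx <- five_point_velocity(samples$x_px, dt) * deg_per_px(geometry, "x") * 1000
  vy <- five_point_velocity(samples$y_px, dt) * deg_per_px(geometry, "y") * 1000
  speed <- sqrt(vx^2 + vy^2)
  acc <- abs(five_point_velocity(speed, dt)) * 1000  # deg/s^2

  pad <- ceiling(blink_pad_ms / dt)
  in_blink <- dilate_runs(missing, pad)

  cand <- (speed > vel_thresh | acc > acc_thresh) & !in_blink
  cand[is.na(cand)] <- FALSE
  min_len <- max(1, ceiling(min_saccade_ms / dt))
  sacc <- keep_long_runs(cand, min_len)

  events <- empty
  if (any(missing)) {
    events <- rbind(events, run_events(missing, t, "blink"))
  }
  if (any(sacc)) {
    sv <- run_events(sacc, t, "saccade")
    rr <- run_ranges(sacc)
    sv$peak_vel_deg_s <- vapply(seq_len(nrow(rr)), function(i) {
      max(speed[rr$start[i]:rr$end[i]], na.rm = TRUE)
    }, numeric(1))
    events <- rbind(events, sv)
  }
  fix <- !sacc & !in_blink
  if (any(fix)) {
    fx <- run_events(fix, t, "fixation")
    rr <- run_ranges(fix)
    w <- geometry$screen_width_px; hh <- geometry$screen_height_px
    for (i in seq_len(nrow(rr))) {
      idx <- rr$start[i]:rr$end[i]
      fx$x_px[i] <- mean(samples$x_px[idx])
      fx$y_px[i] <- mean(samples$y_px[idx])
    }
    fx$off_screen <- fx$x_px < 0 | fx$x_px > w | fx$y_px < 0 | fx$y_px > hh
    events <- rbind(events, fx)
  }
  events[order(events$onset_ms, events$kind), ]
}

five_point_velocity <- function(x, dt) {
  n <- length(x)
  v <- rep(NA_real_, n)
  if (n >= 5) {
    i <- 3:(n - 2)
    v[i] <- (x[i + 2] + x[i + 1] - x[i - 1] - x[i - 2]) / (6 * dt)
  }
  v
}

central_diff <- function(x, dt) {
  n <- length(x)
  d <- rep(NA_real_, n)
  if (n >= 3) {
    i <- 2:(n - 1)
    d[i] <- (x[i + 1] - x[i - 1]) / (2 * dt)
  }
  d
}

# widen TRUE runs by `pad` samples on each side
dilate_runs <- function(flag, pad) {
  if (pad <= 0 || !any(flag)) return(flag)
  n <- length(flag)
  out <- flag
  idx <- which(flag)
  for (k in seq_len(pad)) {
    out[pmax(idx - k, 1)] <- TRUE
    out[pmin(idx + k, n)] <- TRUE
  }
  out
}

keep_long_runs <- function(flag, min_len) {
  r <- rle(flag)
  r$values <- r$values & r$lengths >= min_len
  inverse.rle(r)
}

run_ranges <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(start = starts[r$values], end = ends[r$values])
}

run_events <- function(flag, t, kind) {
  rr <- run_ranges(flag)
  tibble(
    kind = rep(kind, nrow(rr)),
    onset_ms = t[rr$start],
    offset_ms = t[rr$end],
    x_px = NA_real_, y_px = NA_real_,
    peak_vel_deg_s = NA_real_, off_screen = NA
  )
}

#' Fraction of scene-presentation time contaminated by blinks
#'
#' A blink is a period of missing pupil data. The fraction is the share of
#' samples inside the scene-presentation window whose pupil is missing.
#'
#' @param samples Sample tibble (see [detect_events()]), or a
#'   [generate_gaze_trial()] object (in which case onset/offset are taken
#'   from the trial).
#' @param scene_onset_ms,scene_offset_ms Scene window; samples with
#'   `scene_onset_ms <= t_ms < scene_offset_ms` count.
#' @return A fraction in `[0, 1]`.
#' @export
blink_fraction <- function(samples, scene_onset_ms = NULL, scene_offset_ms = NULL) {
  if (inherits(samples, "gaze_trial")) {
    scene_onset_ms <- scene_onset_ms %||% samples$scene_onset_ms
    scene_offset_ms <- scene_offset_ms %||% samples$scene_offset_ms
    samples <- samples$samples
  }
  stopifnot(!is.null(scene_onset_ms), !is.null(scene_offset_ms))
  sel <- samples$t_ms >= scene_onset_ms & samples$t_ms < scene_offset_ms
  if (!any(sel)) return(0)
  mean(is.na(samples$pupil[sel]))
}
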